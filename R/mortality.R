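#' Von Bertalanffy mean length at age
#'
#' \eqn{L(t) = L_\infty (1 - e^{-K (t - t_0)})}.
#'
#' @param age Age (yr), vectorized.
#' @param growth A [growth_params] or [life_history] object (or any list with
#'   `linf`, `k`, `t0`).
#' @return Mean length at age, in the units of `linf`.
#' @export
vb_length <- function(age, growth) {
  growth$linf * (1 - exp(-growth$k * (age - growth$t0)))
}

#' Growth parameter set
#'
#' @param linf Asymptotic length (same unit as the lengths to be analysed
#'   with it; cm by package convention).
#' @param k Growth coefficient (1/yr).
#' @param t0 Age at zero length (yr).
#' @param diagnostics Optional list of fit diagnostics.
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(linf, k, t0 = 0, diagnostics = NULL) {
  check_positive(linf, "linf")
  check_positive(k, "k")
  structure(list(linf = linf, k = k, t0 = t0, diagnostics = diagnostics),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("von Bertalanffy growth: Linf = %.4g, K = %.4g /yr, t0 = %.4g yr\n",
              x$linf, x$k, x$t0))
  if (!is.null(x$diagnostics$n)) {
    cat(sprintf("  fit to n = %d age-length pairs, residual SD = %.4g\n",
                x$diagnostics$n, x$diagnostics$sigma))
  }
  invisible(x)
}

#' Fit a von Bertalanffy growth curve to age-length data
#'
#' Nonlinear least squares on \eqn{L(t) = L_\infty(1 - e^{-K(t - t_0)})}.
#' With `anchor_origin = TRUE` the curve is forced through (0, 0) by fixing
#' \eqn{t_0 = 0}, the convention used when ageing data lack small fish.
#'
#' @param ages Ages (yr), all >= 0.
#' @param lengths Lengths at age, same unit as the desired `linf` (cm by
#'   package convention).
#' @param anchor_origin Fix `t0 = 0` so the fitted curve passes through the
#'   origin. Default `FALSE`.
#' @return A [growth_params] with `diagnostics` (`n`, `sigma`, `convergence`).
#' @examples
#' a <- 0:15
#' l <- 40 * (1 - exp(-0.3 * a))
#' fit_vb(a, l, anchor_origin = TRUE)
#' @export
fit_vb <- function(ages, lengths, anchor_origin = FALSE) {
  stopifnot(length(ages) == length(lengths))
  keep <- is.finite(ages) & is.finite(lengths)
  ages <- ages[keep]; lengths <- lengths[keep]
  if (length(ages) < 3L) stop("need at least 3 (age, length) pairs", call. = FALSE)
  if (any(ages < 0)) stop("ages must be >= 0", call. = FALSE)

  start <- c(linf = max(lengths) * 1.1, k = 0.3, t0 = 0)
  lower <- c(linf = 1e-8, k = 1e-8, t0 = -10)
  if (anchor_origin) {
    start <- start[c("linf", "k")]
    lower <- lower[c("linf", "k")]
  }
  resid_fn <- function(par) {
    t0 <- if (anchor_origin) 0 else par[["t0"]]
    lengths - par[["linf"]] * (1 - exp(-par[["k"]] * (ages - t0)))
  }
  # Levenberg-Marquardt on the raw residuals: robust to the zero-residual
  # case that defeats Gauss-Newton implementations.
  fit <- minpack.lm::nls.lm(par = start, lower = lower, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$info %in% 1:4) {
    stop(sprintf(
      "von Bertalanffy fit failed to converge (%s); last state Linf=%.4g, K=%.4g",
      fit$message, fit$par[["linf"]], fit$par[["k"]]), call. = FALSE)
  }
  cf <- fit$par
  growth_params(
    linf = cf[["linf"]], k = cf[["k"]],
    t0 = if (anchor_origin) 0 else cf[["t0"]],
    diagnostics = list(
      n = length(ages),
      sigma = sqrt(sum(fit$fvec^2) / max(1, length(ages) - length(cf))),
      convergence = fit$info)
  )
}

#' Invert the growth curve: relative age at length
#'
#' \eqn{t(L) = t_0 - \frac{1}{K}\ln(1 - L/L_\infty)}, the exact inverse of
#' [vb_length()] for lengths in \eqn{(0, L_\infty)}. "Relative" because a
#' length-converted age is only as good as the growth curve behind it.
#'
#' @param length Length, same unit as `growth$linf`; must satisfy
#'   `0 < length < linf`.
#' @inheritParams vb_length
#' @return Relative age (yr), vectorized over `length`.
#' @export
length_to_relative_age <- function(length, growth) {
  if (any(length <= 0)) stop("length must be > 0", call. = FALSE)
  if (any(length >= growth$linf)) {
    stop(sprintf("length >= Linf (%.4g): relative age undefined", growth$linf),
         call. = FALSE)
  }
  growth$t0 - log(1 - length / growth$linf) / growth$k
}

#' Length-converted catch curve estimate of total mortality
#'
#' Bins a length-frequency sample, converts bin boundaries to relative ages by
#' inverting the von Bertalanffy curve, and regresses
#' \eqn{\ln(N_i/\Delta t_i)} on the relative age at the bin midpoint over the
#' trailing (descending) arm of the distribution. Total mortality Z is the
#' negative slope. The \eqn{\Delta t_i} divisor corrects for the slowing of
#' growth with age: a fixed length bin spans more time for old fish.
#'
#' The trailing arm comprises bins strictly after the modal bin, excluding
#' empty bins and (when `t_max` is known) bins whose midpoint relative age
#' exceeds `0.95 * t_max`, where the near-asymptotic length-age conversion is
#' unstable.
#'
#' @param lengths Either a numeric vector of raw lengths, or a data frame of
#'   pre-binned frequencies with columns `bin_lo`, `bin_hi`, `count`
#'   (half-open bins `[lo, hi)`). Units must match `length_unit`.
#' @param growth A [growth_params] or [life_history]; `linf` in cm.
#' @param bin_width Bin width for raw lengths, in `length_unit` units
#'   (default 10 mm).
#' @param length_unit `"mm"` (default, field convention for fish lengths) or
#'   `"cm"`. Growth `linf` is always cm and is converted internally.
#' @param t_max Optional maximum age (yr) for the near-asymptote exclusion
#'   rule; taken from `growth$t_max` when present.
#' @return An object of class `catch_curve_result`: `z` (total mortality,
#'   1/yr), `slope`, `se`, `r_squared`, `n_bins_used`, and `bins` (a tibble of
#'   every bin with its midpoint relative age, \eqn{\Delta t}, and a
#'   `used` flag). Negative `z` is returned but flagged via `z_negative`.
#' @examples
#' lh <- grayling_life_history()
#' pop <- simulate_population(population_sim_config(lh, z = 0.4,
#'                            n_fish = 5000, seed = 1))
#' catch_curve(pop$length_mm, lh)
#' @export
catch_curve <- function(lengths, growth, bin_width = 10,
                        length_unit = c("mm", "cm"), t_max = NULL) {
  length_unit <- match.arg(length_unit)
  scale <- if (length_unit == "mm") 10 else 1
  linf <- growth$linf * scale   # growth linf is cm by convention
  g <- list(linf = linf, k = growth$k, t0 = growth$t0)
  if (is.null(t_max) && !is.null(growth$t_max) && !is.na(growth$t_max)) {
    t_max <- growth$t_max
  }

  if (is.data.frame(lengths)) {
    check_cols(lengths, c("bin_lo", "bin_hi", "count"), "pre-binned input")
    bins <- tibble::tibble(bin_lo = lengths$bin_lo, bin_hi = lengths$bin_hi,
                           count = lengths$count)
    if (any(bins$bin_hi <= bins$bin_lo)) {
      stop("bin_hi must exceed bin_lo in every bin", call. = FALSE)
    }
    bins <- bins[order(bins$bin_lo), ]
  } else {
    check_positive(bin_width, "bin_width")
    lengths <- lengths[is.finite(lengths) & lengths > 0]
    n_over <- sum(lengths >= linf)
    if (n_over > 0L) {
      message(sprintf("dropping %d length(s) >= Linf (no defined relative age)",
                      n_over))
      lengths <- lengths[lengths < linf]
    }
    if (length(lengths) == 0L) stop("no usable lengths", call. = FALSE)
    edges <- seq(floor(min(lengths) / bin_width) * bin_width,
                 ceiling((max(lengths) + 1e-9) / bin_width) * bin_width,
                 by = bin_width)
    idx <- findInterval(lengths, edges, rightmost.closed = FALSE)
    bins <- tibble::tibble(
      bin_lo = edges[-length(edges)],
      bin_hi = edges[-1],
      count = tabulate(idx, nbins = length(edges) - 1L)
    )
  }

  # a bin whose upper edge reaches Linf has no finite age span
  bins <- bins[bins$bin_hi < linf & bins$bin_lo > 0, ]
  if (nrow(bins) == 0L) stop("no bins below Linf", call. = FALSE)

  age_of <- function(l) g$t0 - log(1 - l / g$linf) / g$k
  bins$age_mid <- age_of((bins$bin_lo + bins$bin_hi) / 2)
  bins$dt <- age_of(bins$bin_hi) - age_of(bins$bin_lo)

  modal <- which.max(bins$count)
  bins$used <- seq_len(nrow(bins)) > modal & bins$count > 0
  if (!is.null(t_max)) bins$used <- bins$used & bins$age_mid <= 0.95 * t_max

  if (sum(bins$used) < 3L) {
    stop(sprintf("trailing arm has only %d usable bin(s); need >= 3",
                 sum(bins$used)), call. = FALSE)
  }

  arm <- bins[bins$used, ]
  fit <- lm(log(count / dt) ~ age_mid, data = arm)
  slope <- unname(coef(fit)["age_mid"])
  se <- unname(sqrt(diag(stats::vcov(fit)))["age_mid"])
  z <- -slope

  structure(
    list(z = z, slope = slope, se = se,
         r_squared = summary(fit)$r.squared,
         n_bins_used = nrow(arm), bins = bins,
         z_negative = z < 0),
    class = "catch_curve_result"
  )
}

#' @export
print.catch_curve_result <- function(x, ...) {
  cat(sprintf("Length-converted catch curve: Z = %.3f /yr (SE %.3f, r^2 = %.3f, %d bins)\n",
              x$z, x$se, x$r_squared, x$n_bins_used))
  if (x$z_negative) cat("  warning: negative Z (ascending trailing arm)\n")
  invisible(x)
}

#' Natural mortality from life-history invariants
#'
#' Empirical estimators of the instantaneous natural mortality rate M (1/yr):
#' \describe{
#'   \item{`hoenig_nls`}{\eqn{M = 4.899\, t_{max}^{-0.916}} — longevity-based.}
#'   \item{`pauly_nls_t`}{\eqn{M = 4.118\, K^{0.73} L_\infty^{-0.33}} —
#'     growth-based, \eqn{L_\infty} in cm.}
#'   \item{`gunderson`}{\eqn{M = 1.79\, GSI} — reproductive-investment-based.}
#' }
#'
#' @param life A [life_history] object.
#' @param method One of `"hoenig_nls"`, `"pauly_nls_t"`, `"gunderson"`, or
#'   `"all"` (every method whose inputs are available).
#' @param linf_unit Unit of `life$linf`; lengths arriving in mm are converted
#'   to cm (the calibration unit of the Pauly-type formula) with a message.
#' @return A tibble with columns `method`, `m`, and the inputs used.
#' @examples
#' natural_mortality(life_history(linf = 40, k = 0.2, t_max = 10, gsi = 0.15),
#'                   method = "all")
#' @export
natural_mortality <- function(life,
                              method = c("all", "hoenig_nls", "pauly_nls_t",
                                         "gunderson"),
                              linf_unit = c("cm", "mm")) {
  method <- match.arg(method)
  linf_unit <- match.arg(linf_unit)
  linf_cm <- life$linf
  if (linf_unit == "mm") {
    message("converting Linf from mm to cm for the Pauly-type estimator")
    linf_cm <- life$linf / 10
  }

  one <- function(meth) {
    switch(meth,
      hoenig_nls = {
        if (is.na(life$t_max) || life$t_max <= 0) {
          stop("hoenig_nls requires a positive `t_max`", call. = FALSE)
        }
        tibble::tibble(method = meth, m = 4.899 * life$t_max^(-0.916),
                       t_max = life$t_max, k = NA_real_, linf_cm = NA_real_,
                       gsi = NA_real_)
      },
      pauly_nls_t = {
        if (is.na(life$k) || life$k <= 0 || is.na(linf_cm) || linf_cm <= 0) {
          stop("pauly_nls_t requires positive `k` and `linf`", call. = FALSE)
        }
        tibble::tibble(method = meth,
                       m = 4.118 * life$k^0.73 * linf_cm^(-0.33),
                       t_max = NA_real_, k = life$k, linf_cm = linf_cm,
                       gsi = NA_real_)
      },
      gunderson = {
        if (is.na(life$gsi) || life$gsi < 0) {
          stop("gunderson requires a non-negative `gsi`", call. = FALSE)
        }
        tibble::tibble(method = meth, m = 1.79 * life$gsi,
                       t_max = NA_real_, k = NA_real_, linf_cm = NA_real_,
                       gsi = life$gsi)
      }
    )
  }

  if (method != "all") return(one(method))
  avail <- c(
    if (!is.na(life$t_max)) "hoenig_nls",
    "pauly_nls_t",
    if (!is.na(life$gsi)) "gunderson"
  )
  dplyr::bind_rows(lapply(avail, one))
}

#' Fishing mortality by subtraction
#'
#' \eqn{F = Z - M}: the part of total mortality not explained by natural
#' mortality. A negative result (M estimate exceeding the catch-curve Z) is
#' returned as-is with `f_negative = TRUE` rather than truncated, since it
#' signals estimator disagreement worth inspecting.
#'
#' @param z Total mortality (1/yr), >= 0.
#' @param m Natural mortality (1/yr), >= 0.
#' @return A list with `f` and `f_negative`.
#' @examples
#' fishing_mortality(z = 0.42, m = 0.27) # F = 0.15
#' @export
fishing_mortality <- function(z, m) {
  check_nonneg(z, "z")
  check_nonneg(m, "m")
  f <- z - m
  list(f = f, f_negative = f < 0)
}
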