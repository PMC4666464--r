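#' Life-history parameter set
#'
#' Bundles the life-history traits that feed the invariant-based natural
#' mortality estimators and the growth model: asymptotic length and growth
#' coefficient of the von Bertalanffy curve, theoretical age at zero length,
#' maximum observed age, and mean gonadosomatic index (gonad mass relative to
#' somatic mass, a proxy for reproductive investment).
#'
#' @param linf Asymptotic total length \eqn{L_\infty} (cm), > 0.
#' @param k von Bertalanffy growth coefficient \eqn{K} (1/yr), > 0.
#' @param t0 Theoretical age at zero length (yr); zero or negative values are
#'   typical, and `t0 = 0` anchors the curve at the origin.
#' @param t_max Maximum observed age (yr), > 0.
#' @param gsi Mean gonadosomatic index (dimensionless, in `[0, 1)`), or `NA`
#'   if unavailable (the Gunderson estimator then cannot be used).
#' @param species Optional species label carried through reports.
#'
#' @return An object of class `life_history` (a named list).
#' @examples
#' grayling <- life_history(linf = 40, k = 0.127, t0 = 0, t_max = 17,
#'                          gsi = 0.1676, species = "grayling")
#' natural_mortality(grayling, method = "hoenig_nls")
#' @export
life_history <- function(linf, k, t0 = 0, t_max = NA_real_, gsi = NA_real_,
                         species = NA_character_) {
  check_positive(linf, "linf")
  check_positive(k, "k")
  check_that(is.numeric(t0) && length(t0) == 1L && is.finite(t0) && t0 <= 0,
             "t0", "must be a single number <= 0")
  if (!is.na(t_max)) check_positive(t_max, "t_max")
  if (!is.na(gsi)) {
    check_that(is.numeric(gsi) && length(gsi) == 1L && gsi >= 0 && gsi < 1,
               "gsi", "must lie in [0, 1)")
  }
  structure(
    list(linf = linf, k = k, t0 = t0, t_max = t_max, gsi = gsi,
         species = species),
    class = "life_history"
  )
}

#' @export
print.life_history <- function(x, ...) {
  cat("Life history", if (!is.na(x$species)) paste0("(", x$species, ")"), "\n")
  cat(sprintf("  Linf = %.4g cm, K = %.4g /yr, t0 = %.4g yr\n",
              x$linf, x$k, x$t0))
  cat(sprintf("  t_max = %.4g yr, GSI = %.4g\n", x$t_max, x$gsi))
  invisible(x)
}

#' Default grayling life history used in examples and simulations
#'
#' An illustrative parameterization for a long-lived, slow-growing lacustrine
#' grayling: \eqn{L_\infty} = 40 cm, \eqn{K} = 0.127 /yr, \eqn{t_0} = 0
#' (growth anchored at the origin), maximum age 17 yr, mean GSI 0.1676.
#'
#' @return A [life_history] object.
#' @export
grayling_life_history <- function() {
  life_history(linf = 40, k = 0.127, t0 = 0, t_max = 17, gsi = 0.1676,
               species = "grayling")
}
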