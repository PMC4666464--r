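# Category vocabulary for beach-collected debris.
GILLNET_CATEGORIES <- c("whole_net", "net_fragment", "float_line",
                        "lead_line", "foam_float", "bottle_float")
HOOKLINE_CATEGORIES <- c("rod", "monofilament", "lure", "bobber")
GEAR_CATEGORIES <- c(GILLNET_CATEGORIES, HOOKLINE_CATEGORIES)
AMBIGUOUS_LABELS <- c("bottle", "string_rope", "stake")
ALL_LABELS <- c(GEAR_CATEGORIES, AMBIGUOUS_LABELS)

#' Classify a beach-collected item into a fishing-gear category
#'
#' Items already labelled with a gillnet category (`whole_net`,
#' `net_fragment`, `float_line`, `lead_line`, `foam_float`, `bottle_float`)
#' or a hook-and-line category (`rod`, `monofilament`, `lure`, `bobber`) keep
#' that category. Ambiguous beach debris — bottles, string/rope, and stakes —
#' counts as gear only if it carries fishing attachments: mesh makes it a net
#' fragment; floats or lines turn bottles into bottle floats and string/rope
#' into float line; weights turn string/rope into lead line. Anything else is
#' `non_gear`.
#'
#' @param label Raw item label; one of the category names above or
#'   `"bottle"`, `"string_rope"`, `"stake"`. Vectorized.
#' @param has_mesh,has_floats,has_weights,has_line Logical attachment flags
#'   (recycled along `label`).
#' @return Character vector of categories (`non_gear` included).
#' @examples
#' classify_gear("bottle")                      # non_gear
#' classify_gear("bottle", has_line = TRUE)     # bottle_float
#' classify_gear("string_rope", has_mesh = TRUE) # net_fragment
#' @export
classify_gear <- function(label, has_mesh = FALSE, has_floats = FALSE,
                          has_weights = FALSE, has_line = FALSE) {
  unknown <- setdiff(unique(label), ALL_LABELS)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown item label(s): %s. Permitted labels: %s",
                 paste(unknown, collapse = ", "),
                 paste(ALL_LABELS, collapse = ", ")), call. = FALSE)
  }
  n <- length(label)
  args <- data.frame(label = label,
                     has_mesh = rep_len(has_mesh, n),
                     has_floats = rep_len(has_floats, n),
                     has_weights = rep_len(has_weights, n),
                     has_line = rep_len(has_line, n))
  vapply(seq_len(n), function(i) {
    a <- args[i, ]
    if (a$label %in% GEAR_CATEGORIES) return(a$label)
    if (a$has_mesh) return("net_fragment")
    if (a$label == "bottle" && (a$has_floats || a$has_line)) {
      return("bottle_float")
    }
    if (a$label == "string_rope") {
      if (a$has_weights) return("lead_line")
      if (a$has_floats || a$has_line) return("float_line")
    }
    if (a$label == "stake" && (a$has_floats || a$has_weights || a$has_line)) {
      return("net_fragment")
    }
    "non_gear"
  }, character(1))
}

scope_categories <- function(scope) {
  switch(scope,
         all = GEAR_CATEGORIES,
         gillnet = GILLNET_CATEGORIES,
         hookline = HOOKLINE_CATEGORIES,
         stop("unknown scope", call. = FALSE))
}

#' Linear debris density on a single transect
#'
#' Count density is items per km of surveyed shoreline and weight density is
#' grams per km; transect widths vary in the field, so densities are linear
#' (per km) rather than areal. Items without a measured weight contribute to
#' the count density and are dropped from the weight density (with a
#' message).
#'
#' @param items Tibble of items with `transect_id`, `category`, `weight_g`
#'   (NA allowed); every item must reference `transect`.
#' @param transect One-row data frame (or list) with `transect_id` and
#'   `length_km` > 0.
#' @param scope `"all"` (all fishing gear), `"gillnet"`, `"hookline"`, or
#'   `"by_category"` (one row per category).
#' @return A tibble of density records: `transect_id`, `scope`, `category`
#'   (`NA` unless `by_category`), `n_items`, `count_per_km`, `g_per_km`.
#' @examples
#' tr <- data.frame(transect_id = "T1", length_km = 2)
#' it <- data.frame(transect_id = "T1",
#'                  category = c("foam_float", "net_fragment"),
#'                  weight_g = c(10, 115))
#' transect_density(it, tr)
#' @export
transect_density <- function(items, transect,
                             scope = c("all", "gillnet", "hookline",
                                       "by_category")) {
  scope <- match.arg(scope)
  if (is.null(transect$length_km) || !is.finite(transect$length_km) ||
      transect$length_km <= 0) {
    stop("transect length must be a positive number of km", call. = FALSE)
  }
  check_cols(items, c("transect_id", "category"), "items table")
  if (nrow(items) > 0 && !all(items$transect_id == transect$transect_id)) {
    stop("every item must reference the given transect", call. = FALSE)
  }
  if (!"weight_g" %in% names(items)) items$weight_g <- NA_real_
  n_unweighed <- sum(is.na(items$weight_g) & items$category %in% GEAR_CATEGORIES)
  if (n_unweighed > 0L) {
    message(sprintf("%d item(s) without weight excluded from weight density",
                    n_unweighed))
  }

  density_of <- function(sub, category = NA_character_) {
    tibble::tibble(
      transect_id = transect$transect_id,
      scope = scope, category = category,
      n_items = nrow(sub),
      count_per_km = nrow(sub) / transect$length_km,
      g_per_km = sum(sub$weight_g, na.rm = TRUE) / transect$length_km
    )
  }

  if (scope == "by_category") {
    dplyr::bind_rows(lapply(GEAR_CATEGORIES, function(cat) {
      density_of(items[items$category == cat, , drop = FALSE], cat)
    }))
  } else {
    keep <- scope_categories(scope)
    density_of(items[items$category %in% keep, , drop = FALSE])
  }
}

#' Density table across all transects
#'
#' Applies [transect_density()] to each transect, retaining transects with no
#' items as zero-density rows.
#'
#' @param items Items tibble (`transect_id`, `category`, `weight_g`).
#' @param transects Transects tibble (`transect_id`, `length_km`, and
#'   optionally `site`, `year`, carried through).
#' @inheritParams transect_density
#' @return Tibble of density records joined to transect metadata.
#' @export
density_table <- function(items, transects,
                          scope = c("all", "gillnet", "hookline",
                                    "by_category")) {
  scope <- match.arg(scope)
  check_cols(transects, c("transect_id", "length_km"), "transects table")
  orphans <- setdiff(items$transect_id, transects$transect_id)
  if (length(orphans) > 0L) {
    stop(sprintf("items reference unknown transect(s): %s",
                 paste(orphans, collapse = ", ")), call. = FALSE)
  }
  recs <- dplyr::bind_rows(lapply(seq_len(nrow(transects)), function(i) {
    tr <- transects[i, ]
    transect_density(items[items$transect_id == tr$transect_id, , drop = FALSE],
                     tr, scope)
  }))
  dplyr::left_join(recs, transects, by = "transect_id")
}

#' Length-weighted pooled density across transects
#'
#' The pooled density \eqn{\sum_i d_i \ell_i / \sum_i \ell_i} (densities
#' weighted by transect length), which equals total items over total km — so
#' short transects do not get an outsized vote.
#'
#' @param records Density records (one per transect) with `transect_id`,
#'   `count_per_km`, `g_per_km`.
#' @param transects Transects tibble with `transect_id` and `length_km`; its
#'   transect set must match `records` exactly.
#' @return One-row tibble: `count_per_km`, `g_per_km`, `total_items`,
#'   `total_km`.
#' @export
pooled_density <- function(records, transects) {
  check_cols(records, c("transect_id", "count_per_km", "g_per_km"),
             "density records")
  check_cols(transects, c("transect_id", "length_km"), "transects table")
  if (!setequal(records$transect_id, transects$transect_id) ||
      nrow(records) != nrow(transects)) {
    stop("records and transects must cover the same transect set, one record each",
         call. = FALSE)
  }
  records <- dplyr::select(records, -dplyr::any_of("length_km"))
  merged <- dplyr::left_join(records, transects[, c("transect_id", "length_km")],
                             by = "transect_id")
  total_km <- sum(merged$length_km)
  tibble::tibble(
    count_per_km = sum(merged$count_per_km * merged$length_km) / total_km,
    g_per_km = sum(merged$g_per_km * merged$length_km) / total_km,
    total_items = sum(merged$count_per_km * merged$length_km),
    total_km = total_km
  )
}

#' Mesh-size composition of derelict net material
#'
#' Histograms the mesh sizes of mesh-bearing items (whole nets and net
#' fragments) into half-open bins `[lo, hi)`, by count and by summed weight.
#'
#' @param items Items tibble with `mesh_cm` (NA for non-net items) and
#'   `weight_g`.
#' @param edges Increasing bin edges (cm). Default 1-cm bins spanning 2-8 cm.
#' @return Tibble: `bin_lo`, `bin_hi`, `n_items`, `weight_g`. Items whose
#'   mesh falls outside the edges are dropped with a message.
#' @export
mesh_composition <- function(items, edges = 2:8) {
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  meshy <- items[!is.na(items$mesh_cm), , drop = FALSE]
  if (!"weight_g" %in% names(meshy)) meshy$weight_g <- NA_real_
  out <- tibble::tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                        n_items = 0L, weight_g = 0)
  if (nrow(meshy) == 0L) return(out)
  idx <- findInterval(meshy$mesh_cm, edges, rightmost.closed = FALSE)
  outside <- idx == 0L | idx >= length(edges)
  if (any(outside)) {
    message(sprintf("%d mesh-bearing item(s) outside [%g, %g) dropped",
                    sum(outside), min(edges), max(edges)))
    meshy <- meshy[!outside, , drop = FALSE]
    idx <- idx[!outside]
  }
  out$n_items <- tabulate(idx, nbins = length(edges) - 1L)
  out$weight_g <- vapply(seq_len(length(edges) - 1L), function(b) {
    sum(meshy$weight_g[idx == b], na.rm = TRUE)
  }, numeric(1))
  out
}

#' Between-year re-accumulation of derelict gear
#'
#' Compares per-site densities between a baseline survey (in which all gear
#' was removed) and a resurvey: gear found in the later year must have
#' accumulated in between, so a positive difference is evidence of ongoing
#' fishing. Ratios at a zero baseline are flagged `NA` rather than infinite.
#'
#' @param dens_a Baseline densities: tibble with `site` and `count_per_km`.
#' @param dens_b Resurvey densities, same columns.
#' @return A list: `by_site` (tibble with `site`, `density_a`, `density_b`,
#'   `diff`, `ratio`, `ratio_undefined`), `n_sites`, `n_increasing`.
#' @export
accumulation_change <- function(dens_a, dens_b) {
  check_cols(dens_a, c("site", "count_per_km"), "baseline densities")
  check_cols(dens_b, c("site", "count_per_km"), "resurvey densities")
  shared <- intersect(dens_a$site, dens_b$site)
  if (length(shared) == 0L) {
    stop("no sites surveyed in both years", call. = FALSE)
  }
  a <- dens_a[match(shared, dens_a$site), ]
  b <- dens_b[match(shared, dens_b$site), ]
  by_site <- tibble::tibble(
    site = shared,
    density_a = a$count_per_km,
    density_b = b$count_per_km,
    diff = b$count_per_km - a$count_per_km,
    ratio_undefined = a$count_per_km == 0,
    ratio = ifelse(a$count_per_km == 0, NA_real_,
                   b$count_per_km / a$count_per_km)
  )
  list(by_site = by_site,
       n_sites = length(shared),
       n_increasing = sum(by_site$diff > 0))
}
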