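# Table schemas: required columns and their types ("c" character,
# "d" double, "i" integer); optional columns listed separately.
TABLE_SCHEMAS <- list(
  sets = list(required = c(set_id = "c", site = "c", year = "i", net = "i",
                           nights = "d"),
              optional = c(soak_hr = "d")),
  panels = list(required = c(set_id = "c", mesh_cm = "d", length_m = "d"),
                optional = character()),
  catch = list(required = c(set_id = "c", mesh_cm = "d", species = "c",
                            length_mm = "d"),
               optional = c(weight_g = "d")),
  transects = list(required = c(transect_id = "c", length_km = "d"),
                   optional = c(site = "c", year = "i")),
  debris = list(required = c(transect_id = "c", category = "c"),
                optional = c(weight_g = "d", mesh_cm = "d")),
  life_history = list(required = c(species = "c", linf_cm = "d", k = "d",
                                   t0 = "d", t_max = "d"),
                      optional = c(gsi = "d"))
)

#' Read and validate a pipeline input table
#'
#' Reads a comma-delimited, UTF-8, header-first table (lines starting with
#' `#` are treated as provenance comments and skipped), checks it against
#' one of the package's named schemas, and reports offending rows with data
#' line numbers.
#'
#' @param path Path to a CSV file.
#' @param schema One of `"sets"`, `"panels"`, `"catch"`, `"transects"`,
#'   `"debris"`, `"life_history"`.
#' @return A validated tibble with typed columns.
#' @export
load_table <- function(path, schema = names(TABLE_SCHEMAS)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  sch <- TABLE_SCHEMAS[[schema]]
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(names(sch$required), names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s table `%s` is missing required column(s): %s",
                 schema, basename(path), paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  types <- c(sch$required, sch$optional)
  for (col in intersect(names(types), names(df))) {
    if (types[[col]] == "c") next
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(parsed))
    if (length(bad) > 0L) {
      stop(sprintf("%s: column `%s` has unparsable value(s) at data row(s) %s",
                   basename(path), col,
                   paste(head(bad, 5), collapse = ", ")), call. = FALSE)
    }
    df[[col]] <- if (types[[col]] == "i") as.integer(parsed) else parsed
  }
  tibble::as_tibble(df)
}

#' Write a table with a provenance header
#'
#' Prepends `#`-prefixed comment lines recording the package version, seed,
#' and creation context, then the CSV body. Files written this way round-trip
#' through [load_table()].
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param seed Seed recorded in the header (or `NA`).
#' @param extra Named character vector of extra header fields.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, seed = NA, extra = character()) {
  hdr <- c(
    sprintf("# generated-by: gillnetr %s",
            as.character(utils::packageVersion("gillnetr"))),
    sprintf("# seed: %s", as.character(seed)),
    if (length(extra) > 0) sprintf("# %s: %s", names(extra), extra)
  )
  writeLines(hdr, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the three analysis stages over validated input tables:
#' \describe{
#'   \item{gear survey}{per-transect and pooled derelict-gear densities
#'     (all-gear and gillnet-only) and mesh composition;}
#'   \item{trends}{per-species set CPUE and body-size trend tests with site
#'     random intercepts, plus the optimal mesh;}
#'   \item{assessment}{the natural-mortality to effort-scenario chain, at
#'     full and display precision.}
#' }
#' Stages run only when their inputs are present in `config`. Any stage
#' failure aborts with the stage named. Given the same config and seed the
#' output is identical.
#'
#' @param config A named list (or path to a YAML file) with any of:
#'   `catch`, `sets`, `panels`, `debris`, `transects`, `life_history` (file
#'   paths or in-memory data frames), `species` (character filter),
#'   `assessment` (arguments for [assessment_inputs()]), `mesh_edges`,
#'   `out_dir` (write outputs as provenance-headed CSVs), `seed`.
#' @return A named list of stage results (`gear_survey`, `trends`,
#'   `assessment`), plus `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a config file requires the yaml package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- if (is.null(config$seed)) NA else config$seed

  grab <- function(name) {
    x <- config[[name]]
    if (is.null(x)) return(NULL)
    if (is.character(x)) load_table(x, schema = name) else tibble::as_tibble(x)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  out <- list()

  debris <- grab("debris"); transects <- grab("transects")
  if (!is.null(debris) && !is.null(transects)) {
    out$gear_survey <- stage("gear-survey", {
      per_tr_all <- density_table(debris, transects, scope = "all")
      per_tr_gn <- density_table(debris, transects, scope = "gillnet")
      edges <- if (is.null(config$mesh_edges)) 2:8 else config$mesh_edges
      list(
        per_transect_all = per_tr_all,
        per_transect_gillnet = per_tr_gn,
        pooled_all = pooled_density(per_tr_all, transects),
        pooled_gillnet = pooled_density(per_tr_gn, transects),
        mesh_composition = mesh_composition(debris, edges = edges)
      )
    })
  }

  catch <- grab("catch"); sets <- grab("sets"); panels <- grab("panels")
  if (!is.null(catch) && !is.null(sets)) {
    out$trends <- stage("trends", {
      species <- config$species %||% unique(catch$species)
      catch <- catch[catch$species %in% species, , drop = FALSE]
      if (!"weight_g" %in% names(catch)) catch$weight_g <- NA_real_
      lw <- lapply(split(catch, catch$species), function(d) {
        tryCatch(fit_length_weight(d), error = function(e) NULL)
      })
      lw <- lw[!vapply(lw, is.null, logical(1))]
      catch_full <- impute_weights(catch[catch$species %in% names(lw), ], lw)
      catch_rest <- catch[!catch$species %in% names(lw), ]
      if (nrow(catch_rest) > 0) catch_rest$imputed <- FALSE
      catch <- dplyr::bind_rows(catch_full, catch_rest)

      cpue <- set_cpue_table(catch, sets, by_species = TRUE)
      per_species <- lapply(setNames(nm = species), function(sp) {
        abund <- trend_test(cpue[cpue$species == sp, ], "cpue_kg")
        body <- catch[catch$species == sp, ]
        body <- dplyr::left_join(body, sets[, c("set_id", "site", "year")],
                                 by = "set_id")
        size <- tryCatch(
          trend_test(body[!body$imputed, ], "length_mm"),
          error = function(e) NULL)
        list(abundance = abund, body_size = size)
      })
      res <- list(length_weight = lw, set_cpue = cpue, tests = per_species)
      if (!is.null(panels)) {
        pt <- panel_cpue_table(catch, panels, sets)
        res$panel_cpue <- pt
        res$optimal_mesh_count <- as.numeric(optimal_mesh(pt, criterion = "count"))
        res$optimal_mesh_biomass <- as.numeric(optimal_mesh(pt, criterion = "biomass"))
      }
      res
    })
  }

  life <- grab("life_history")
  if (!is.null(life)) {
    out$assessment <- stage("assessment", {
      args <- config$assessment %||% list()
      inputs <- do.call(assessment_inputs, args)
      per_sp <- lapply(seq_len(nrow(life)), function(i) {
        row <- life[i, ]
        lh <- life_history(linf = row$linf_cm, k = row$k, t0 = min(row$t0, 0),
                           t_max = row$t_max,
                           gsi = if ("gsi" %in% names(row)) row$gsi else NA,
                           species = row$species)
        tbl <- assessment_table(lh, inputs = inputs)
        tbl$species <- row$species
        tbl
      })
      full <- dplyr::bind_rows(per_sp)
      list(full_precision = full, display = format_assessment(full))
    })
  }

  out$provenance <- list(
    package_version = as.character(utils::packageVersion("gillnetr")),
    seed = seed,
    config_hash = sum(utf8ToInt(paste(deparse(config[order(names(config))]),
                                      collapse = ""))),
    timestamp = NA  # omitted so identical configs give identical output
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(out$gear_survey)) {
      write_table(out$gear_survey$per_transect_all,
                  file.path(config$out_dir, "gear_density_by_transect.csv"),
                  seed = seed)
    }
    if (!is.null(out$trends)) {
      write_table(out$trends$set_cpue,
                  file.path(config$out_dir, "set_cpue.csv"), seed = seed)
    }
    if (!is.null(out$assessment)) {
      write_table(out$assessment$display,
                  file.path(config$out_dir, "assessment_table.csv"),
                  seed = seed)
    }
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
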