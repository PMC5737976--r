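# End-to-end orchestration: parse -> aggregate -> filter -> fit trends ->
# classify -> covariate models -> detectability, with deterministic
# outputs and a JSON run manifest.

#' Pipeline configuration
#'
#' Collects every knob of the full analysis. Inputs may be file paths
#' (weekly database in the [weekly_dialect()] text format, metadata and
#' covariates as CSV) or in-memory data.frames.
#'
#' @param weekly Weekly observation table or path.
#' @param metadata Station metadata table or path.
#' @param covariates Station covariate table or path (may be `NULL`: the
#'   covariate models are then skipped).
#' @param variables Variables to analyse; visibility is fitted from the
#'   Secchi record and is only available for reef and seagrass stations.
#' @param harmonics Named vector of annual harmonics per variable
#'   (temperature gets 2, visibility 0).
#' @param alpha Two-sided significance level for trend classification,
#'   in (0, 0.5].
#' @param min_years,min_records Long-term record filter thresholds.
#' @param covariate_sets Named list of covariate names per response.
#' @param omega0_detect Reference trend for the detectability table
#'   (units per year).
#' @param ridge_on_separation Ridge penalty used to refit a
#'   quasi-separated multinomial stage (small station networks separate
#'   easily); the refit is flagged `ridged` in the result.
#' @param out_dir Output directory for CSV/JSON artifacts, or `NULL` to
#'   return results in memory only.
#' @param seed Integer seed recorded in the manifest (the analysis
#'   itself is deterministic).
#' @param dialect [weekly_dialect()] used when `weekly` is a path.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(weekly, metadata, covariates = NULL,
                            variables = c("temperature", "visibility"),
                            harmonics = c(temperature = 2, visibility = 0),
                            alpha = 0.05, min_years = 3, min_records = 30,
                            covariate_sets = list(
                              temperature = c("wave_exposure",
                                              "current_speed"),
                              visibility = c("wave_exposure",
                                             "current_speed",
                                             "delta_population",
                                             "rainfall_trend")),
                            omega0_detect = 0.05, ridge_on_separation = 1,
                            out_dir = NULL,
                            seed = NULL, dialect = weekly_dialect()) {
  if (alpha <= 0 || alpha > 0.5) stop("alpha must lie in (0, 0.5]")
  for (inp in list(weekly, metadata, covariates))
    if (is.character(inp) && !file.exists(inp))
      stop("input path does not exist: ", inp)
  structure(list(weekly = weekly, metadata = metadata,
                 covariates = covariates, variables = variables,
                 harmonics = harmonics, alpha = alpha,
                 min_years = min_years, min_records = min_records,
                 covariate_sets = covariate_sets,
                 omega0_detect = omega0_detect,
                 ridge_on_separation = ridge_on_separation,
                 out_dir = out_dir,
                 seed = seed, dialect = dialect),
            class = "pipeline_config")
}

.load_input <- function(x, loader) if (is.character(x)) loader(x) else x

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full trend analysis
#'
#' Executes parse, monthly aggregation, the long-term filter, per-station
#' AR(1)-GLS trend fits and classification for each requested variable,
#' habitat-by-category tallies, multinomial covariate models with
#' drop-one tests and probability curves, and the temperature
#' detectability table. When `out_dir` is set, writes one CSV per table
#' plus a JSON manifest; re-running with an identical configuration
#' reproduces the outputs byte-identically.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with components `trend_tables`
#'   (per variable), `category_counts`, `habitat_tests`, `multinomial`
#'   (fit, covariate tests, curves per response), `detectability`,
#'   `filter_summaries`, `parse_report` and `manifest`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  parse_report <- NULL
  weekly <- .stage("parse", {
    if (is.character(config$weekly)) {
      parsed <- parse_weekly_database(config$weekly,
                                      dialect = config$dialect)
      parse_report <- parsed$report
      parsed$observations
    } else config$weekly
  })
  metadata <- .stage("metadata", {
    md <- .load_input(config$metadata, read_station_metadata)
    validate_station_metadata(md)
  })
  covariates <- if (!is.null(config$covariates))
    .load_input(config$covariates, function(p)
      utils::read.csv(p, stringsAsFactors = FALSE))
  else NULL

  src_col <- c(temperature = "temperature", visibility = "secchi",
               salinity = "salinity")
  trend_tables <- list()
  filter_summaries <- list()
  category_counts <- list()
  habitat_tests <- list()
  fits_by_var <- list()

  for (v in config$variables) {
    monthly <- .stage(paste0("aggregate:", v),
                      aggregate_monthly(weekly, src_col[[v]]))
    filt <- .stage(paste0("filter:", v),
                   filter_long_term(monthly, config$min_years,
                                    config$min_records))
    filter_summaries[[v]] <- filt$summary
    nh <- if (v %in% names(config$harmonics))
      unname(config$harmonics[[v]]) else 0
    tab <- .stage(paste0("fit:", v),
                  fit_trend_table(filt$retained, n_harmonics = nh,
                                  alpha = config$alpha))
    tab$habitat <- metadata$habitat[match(tab$station_id,
                                          metadata$station_id)]
    fits_by_var[[v]] <- attr(tab, "fits")
    attr(tab, "fits") <- NULL
    trend_tables[[v]] <- tab

    counts <- as.data.frame(table(category = factor(
      tab$category, levels = c("decreasing", "none", "increasing")),
      habitat = tab$habitat), stringsAsFactors = FALSE)
    names(counts)[3] <- "n_stations"
    counts$variable <- v
    category_counts[[v]] <- counts

    habitat_tests[[v]] <- tryCatch(
      habitat_category_chisq(tab$category, tab$habitat),
      error = function(e) list(error = conditionMessage(e)),
      warning = function(w) suppressWarnings(
        habitat_category_chisq(tab$category, tab$habitat)))
  }

  multinomial <- list()
  if (!is.null(covariates)) {
    for (v in config$variables) {
      tab <- trend_tables[[v]]
      cs <- config$covariate_sets[[v]]
      dat <- merge(tab[, c("station_id", "category")], covariates,
                   by = "station_id")
      dropped <- setdiff(tab$station_id, dat$station_id)
      if (length(dat$category) && length(unique(dat$category)) >= 2) {
        fit <- .stage(paste0("multinomial:", v),
                      fit_multinomial(dat$category,
                                      dat[, cs, drop = FALSE]))
        ridged <- FALSE
        if (fit$separated) {
          # quasi-separation at small n: refit with a small ridge so the
          # drop-one tests compare finite, stable optima (flagged below)
          fit <- .stage(paste0("multinomial:", v),
                        fit_multinomial(dat$category,
                                        dat[, cs, drop = FALSE],
                                        ridge = config$ridge_on_separation))
          ridged <- TRUE
        }
        tests <- lapply(stats::setNames(cs, cs), function(cv)
          tryCatch(test_covariate(fit, cv), error = function(e)
            list(lrt_statistic = NA_real_, lrt_p = NA_real_,
                 note = conditionMessage(e))))
        curves <- lapply(stats::setNames(cs, cs), function(cv)
          predict_probability_curve(fit, cv))
        multinomial[[v]] <- list(fit = fit, tests = tests,
                                 curves = curves, n = fit$n,
                                 ridged = ridged,
                                 dropped_stations = dropped)
      } else {
        multinomial[[v]] <- list(fit = NULL, tests = NULL, curves = NULL,
                                 n = nrow(dat), dropped_stations = dropped,
                                 note = "fewer than two observed classes")
      }
    }
  }

  detectability <- if ("temperature" %in% names(trend_tables))
    detectability_table(trend_tables$temperature,
                        omega0 = config$omega0_detect)
  else NULL

  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  cfg_json <- jsonlite::toJSON(.jsonable(cfg_for_hash), auto_unbox = TRUE,
                               digits = NA)
  manifest <- list(
    package = "caritrend",
    version = as.character(utils::packageVersion("caritrend")),
    seed = config$seed,
    alpha = config$alpha,
    min_years = config$min_years, min_records = config$min_records,
    variables = config$variables,
    config_hash = .hash_string(as.character(cfg_json)),
    stations_analysed = vapply(trend_tables, nrow, integer(1))
  )

  result <- structure(list(trend_tables = trend_tables,
                           category_counts = category_counts,
                           habitat_tests = habitat_tests,
                           multinomial = multinomial,
                           detectability = detectability,
                           filter_summaries = filter_summaries,
                           parse_report = parse_report,
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) .write_bundle(result, config$out_dir)
  result
}

# reduce a config to JSON-representable pieces (data.frames become their
# dimensions and column names; the content hash covers parameters, which
# is what reruns need to compare)
.jsonable <- function(x) {
  lapply(x, function(el) {
    if (is.data.frame(el)) list(rows = nrow(el), cols = names(el))
    else if (inherits(el, "weekly_dialect")) unclass(el)
    else el
  })
}

# dependency-free deterministic string fingerprint (polynomial rolling
# hash mod 2^32; collisions are irrelevant for a rerun check)
.hash_string <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.write_bundle <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  for (v in names(result$trend_tables))
    wr(result$trend_tables[[v]], paste0("trend_", v, ".csv"))
  wr(do.call(rbind, result$category_counts), "category_counts.csv")
  for (v in names(result$multinomial)) {
    m <- result$multinomial[[v]]
    if (is.null(m$fit)) next
    co <- as.data.frame(m$fit$coefficients)
    co$logit <- rownames(co)
    wr(co, paste0("multinomial_", v, "_coefficients.csv"))
    tests <- do.call(rbind, lapply(names(m$tests), function(cv) {
      tt <- m$tests[[cv]]
      data.frame(covariate = cv,
                 lrt_statistic = tt$lrt_statistic %||% NA_real_,
                 lrt_p = tt$lrt_p %||% NA_real_,
                 wald_statistic = tt$wald_statistic %||% NA_real_,
                 wald_p = tt$wald_p %||% NA_real_)
    }))
    wr(tests, paste0("covariate_tests_", v, ".csv"))
    for (cv in names(m$curves))
      wr(m$curves[[cv]], paste0("curve_", v, "_", cv, ".csv"))
  }
  if (!is.null(result$detectability))
    wr(result$detectability, "detectability_temperature.csv")
  for (v in names(result$filter_summaries))
    wr(result$filter_summaries[[v]], paste0("filter_summary_", v, ".csv"))
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_result <- function(x, ...) {
  cat("caritrend pipeline result\n")
  for (v in names(x$trend_tables)) {
    tab <- x$trend_tables[[v]]
    tallies <- table(factor(tab$category,
                            levels = c("decreasing", "none", "increasing")))
    cat(sprintf("  %s: %d stations | %d decreasing, %d none, %d increasing\n",
                v, nrow(tab), tallies["decreasing"], tallies["none"],
                tallies["increasing"]))
  }
  invisible(x)
}
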