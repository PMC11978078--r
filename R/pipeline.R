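#' Read and validate price records from CSV
#'
#' Expects the long-format schema written by
#' \code{\link{write_price_records}}: \code{date} (ISO 8601),
#' \code{market_id}, \code{lat}, \code{lon}, \code{admin1}, \code{admin2},
#' \code{segment}, \code{commodity}, \code{subtype}, \code{source},
#' \code{contributor_id}, \code{quantity}, \code{unit},
#' \code{price_total_ngn}. Rows with unparseable dates or numbers are not
#' fatal: they are collected into a rejects table (attribute
#' \code{"rejects"}, reason \code{"malformed_row"}).
#'
#' @param path CSV file path.
#' @return tibble of valid records; attribute \code{"rejects"} holds the
#'   malformed rows as raw text fields.
#' @export
read_price_records <- function(path) {
  if (!file.exists(path)) stop("cannot read records: no file at ", path,
                               call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  required <- names(empty_records())
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("records file lacks required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(raw) == 0) {
    warning("empty records file: ", path, call. = FALSE)
    out <- empty_records()
    attr(out, "rejects") <- raw
    return(out)
  }
  date <- suppressWarnings(as.Date(raw$date, format = "%Y-%m-%d"))
  num <- function(v) suppressWarnings(as.numeric(v))
  lat <- num(raw$lat); lon <- num(raw$lon)
  qty <- num(raw$quantity); price <- num(raw$price_total_ngn)
  bad <- is.na(date) | is.na(lat) | is.na(lon) | is.na(qty) | is.na(price)
  out <- tibble::tibble(
    date = date[!bad], market_id = raw$market_id[!bad],
    lat = lat[!bad], lon = lon[!bad],
    admin1 = raw$admin1[!bad], admin2 = raw$admin2[!bad],
    segment = raw$segment[!bad], commodity = raw$commodity[!bad],
    subtype = raw$subtype[!bad], source = raw$source[!bad],
    contributor_id = raw$contributor_id[!bad],
    quantity = as.integer(qty[!bad]), unit = raw$unit[!bad],
    price_total_ngn = price[!bad])
  rejects <- raw[bad, , drop = FALSE]
  if (nrow(rejects)) rejects$reason <- "malformed_row"
  attr(out, "rejects") <- rejects
  out
}

#' @rdname read_price_records
#' @param records tibble of price records.
#' @export
write_price_records <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Configuration for the demonstration pipeline
#'
#' Bundles the generation, preprocessing and analysis settings of
#' \code{\link{run_pipeline}}. Defaults give a small end-to-end demo: 540
#' daily periods of one latent maize price observed by a noisy crowd stream
#' (6 submissions/day, heterogeneous packaging, 2\% gross outliers), a sparse
#' enumerator stream, and a monthly model-imputed OHLC product.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed; every random stage derives its stream from it.
#' @param days daily horizon.
#' @param start first calendar day.
#' @param drift,sigma_innov latent daily drift and innovation scale.
#' @param crowd,enum \code{\link{observation_spec}}s for the two field
#'   sources.
#' @param ai_error_sd log-scale noise of the monthly imputed product.
#' @param tukey_k fence multiplier for outlier screening.
#' @param bounds optional plausibility bounds c(lo, hi) in NGN/kg.
#' @param frequencies aggregation frequencies to report.
#' @param max_lag monthly lead-lag window half-width.
#' @param alpha,tau,sw_alpha equivalence-test settings.
#' @return a \code{"pipeline_config"} list.
#' @export
pipeline_config <- function(out_dir, seed = 1, days = 540,
                            start = as.Date("2021-01-01"),
                            drift = 0.001, sigma_innov = 0.02,
                            crowd = observation_spec(
                              "crowd", intensity = 6, sigma_e = 0.25,
                              outlier_rate = 0.02, outlier_magnitude = 10,
                              unit_mix = c(kg = 0.3, mudu = 0.3,
                                           bag_5kg = 0.15, bag_25kg = 0.1,
                                           bag_50kg = 0.1, bag_100kg = 0.05)),
                            enum = observation_spec(
                              "enumerator", intensity = 0.5, sigma_e = 0.1),
                            ai_error_sd = 0.02, tukey_k = 1.5, bounds = NULL,
                            frequencies = c("daily", "weekly", "monthly"),
                            max_lag = 5, alpha = 0.05, tau = 0,
                            sw_alpha = 0.05) {
  stopifnot(all(frequencies %in% FREQUENCIES), max_lag >= 1)
  structure(list(out_dir = out_dir, seed = as.integer(seed), days = days,
                 start = start, drift = drift, sigma_innov = sigma_innov,
                 crowd = crowd, enum = enum, ai_error_sd = ai_error_sd,
                 tukey_k = tukey_k, bounds = bounds,
                 frequencies = frequencies, max_lag = max_lag,
                 alpha = alpha, tau = tau, sw_alpha = sw_alpha),
            class = "pipeline_config")
}

source_series <- function(aggr, src) {
  dplyr::filter(aggr, .data$source == src)
}

#' Run the demonstration pipeline end to end
#'
#' Generation -> standardisation -> outlier screening -> aggregation ->
#' concordance (including the monthly lead-lag profile and per-admin2
#' nearest-market correlations) -> formal equivalence reports. All
#' intermediate CSVs and a JSON + markdown report are written under
#' \code{config$out_dir}; given the same config (including seed) the outputs
#' are byte-identical across runs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return (invisibly) a list with the report and the paths written.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("`config` must come from pipeline_config()", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  dates <- config$start + seq_len(config$days) - 1
  seed <- config$seed

  # --- generate -------------------------------------------------------------
  walk <- latent_process_spec(config$days, log(500), config$drift,
                              innovation_spec(0, config$sigma_innov))
  latent <- simulate_latent_walk(walk, replicate_seed(seed, 1))
  rec_crowd <- generate_observations(latent, config$crowd, dates,
                                     seed = replicate_seed(seed, 2))
  rec_enum <- generate_observations(latent, config$enum, dates,
                                    seed = replicate_seed(seed, 3))
  records <- dplyr::bind_rows(rec_crowd, rec_enum)
  ohlc <- generate_ai_series(latent, dates, config$ai_error_sd,
                             seed = replicate_seed(seed, 4))
  paths <- c(records = file.path(config$out_dir, "records.csv"),
             truth = file.path(config$out_dir, "truth.csv"),
             ohlc = file.path(config$out_dir, "ohlc.csv"))
  write_price_records(records, paths[["records"]])
  readr::write_csv(tibble::tibble(date = dates, log_price = latent),
                   paths[["truth"]])
  readr::write_csv(ohlc, paths[["ohlc"]])
  message(sprintf("[generate] %d crowd + %d enumerator records, %d OHLC months",
                  nrow(rec_crowd), nrow(rec_enum), nrow(ohlc)))

  # --- standardise and screen ----------------------------------------------
  std <- to_price_per_kg(records)
  screened <- screen_prices(std$records, k = config$tukey_k,
                            bounds = config$bounds)
  n_in <- nrow(records)
  n_kept <- sum(screened$screen_flag == "kept")
  excl_pct <- 100 * (1 - n_kept / n_in)
  message(sprintf("[screen] %d in, %d kept (%.1f%% excluded, %d rejects)",
                  n_in, n_kept, excl_pct, nrow(std$rejects)))
  readr::write_csv(screened, file.path(config$out_dir, "clean_records.csv"))
  if (nrow(std$rejects))
    readr::write_csv(std$rejects, file.path(config$out_dir, "rejects.csv"))

  # --- aggregate ------------------------------------------------------------
  aggregates <- dplyr::bind_rows(lapply(config$frequencies, function(f)
    aggregate_prices(screened, f)))
  readr::write_csv(aggregates, file.path(config$out_dir, "aggregates.csv"))

  ai_monthly <- tibble::tibble(
    commodity = records$commodity[1], subtype = records$subtype[1],
    source = "ai", frequency = "monthly", period = ohlc$month,
    period_start = as.Date(paste0(ohlc$month, "-01")),
    mean_price = ohlc$close, n = 1L, sd = NA_real_)

  # --- concordance ----------------------------------------------------------
  correlations <- dplyr::bind_rows(lapply(config$frequencies, function(f) {
    a <- dplyr::filter(aggregates, .data$frequency == f, .data$source == "crowd")
    b <- dplyr::filter(aggregates, .data$frequency == f,
                       .data$source == "enumerator")
    res <- pearson_concordance(align_pairs(a, b))
    dplyr::mutate(res, pair = "crowd_vs_enumerator", frequency = f,
                  .before = 1)
  }))
  crowd_monthly <- dplyr::filter(aggregates, .data$frequency == "monthly",
                                 .data$source == "crowd")
  enum_weekly <- dplyr::filter(aggregates, .data$frequency == "weekly",
                               .data$source == "enumerator")
  crowd_weekly <- dplyr::filter(aggregates, .data$frequency == "weekly",
                                .data$source == "crowd")
  pair_ai <- align_pairs(crowd_monthly, ai_monthly)
  correlations <- dplyr::bind_rows(
    correlations,
    dplyr::mutate(pearson_concordance(pair_ai), pair = "crowd_vs_ai",
                  frequency = "monthly", .before = 1))
  lagprof <- lag_profile(crowd_monthly, ai_monthly, max_lag = config$max_lag)
  readr::write_csv(correlations, file.path(config$out_dir, "correlations.csv"))
  readr::write_csv(lagprof, file.path(config$out_dir, "lag_profile.csv"))

  # --- per-admin2 nearest-market correlations -------------------------------
  markets <- default_markets()
  admin_cor <- screened %>%
    dplyr::filter(.data$screen_flag == "kept", .data$source == "crowd") %>%
    dplyr::group_by(.data$admin2) %>%
    dplyr::group_map(function(g, key) {
      cen <- admin_centroid(g$lat, g$lon)
      agg <- aggregate_prices(g, "monthly", group = character(0))
      res <- tryCatch(pearson_concordance(align_pairs(agg, ai_monthly)),
                      error = function(e) tibble::tibble(
                        r = NA_real_, r2 = NA_real_, n = nrow(agg),
                        p = NA_real_))
      dplyr::mutate(res, admin2 = key$admin2,
                    nearest_market = nearest_market(cen["lat"], cen["lon"],
                                                    markets),
                    .before = 1)
    }) %>% dplyr::bind_rows()
  readr::write_csv(admin_cor, file.path(config$out_dir, "admin2_correlations.csv"))

  # --- equivalence ----------------------------------------------------------
  pair_we <- align_pairs(crowd_weekly, enum_weekly)
  eq_crowd_enum <- equivalence_report(pair_we, tau = config$tau,
                                      alpha = config$alpha,
                                      sw_alpha = config$sw_alpha)
  eq_crowd_ai <- equivalence_report(pair_ai, tau = config$tau,
                                    alpha = config$alpha,
                                    sw_alpha = config$sw_alpha)

  report <- list(
    schema_version = "1.0",
    seed = seed,
    counts = list(records_in = n_in, kept = n_kept,
                  excluded_pct = round(excl_pct, 2),
                  rejects = nrow(std$rejects)),
    correlations = correlations,
    lag_profile = lagprof,
    admin2 = admin_cor,
    equivalence = list(
      crowd_vs_enumerator_weekly = equivalence_to_list(eq_crowd_enum),
      crowd_vs_ai_monthly = equivalence_to_list(eq_crowd_ai)))
  report_paths <- write_report(report, config$out_dir)
  invisible(list(report = report, paths = c(paths, report_paths),
                 out_dir = config$out_dir))
}

equivalence_to_list <- function(x) {
  list(n = x$n, use_log = x$use_log, tau = x$tau, alpha = x$alpha,
       W = x$sw$W, sw_p = x$sw$p, t = x$t$t, t_p = x$t$p,
       F = x$vr$F, vr_p = x$vr$p,
       innovation_p = c(x = x$precondition$x$p, y = x$precondition$y$p),
       classification = x$classification, narrative = x$narrative)
}

#' Write the machine- and human-readable pipeline report
#'
#' @param report named list (see \code{\link{run_pipeline}}).
#' @param dir output directory.
#' @return character vector of the two paths written.
#' @export
write_report <- function(report, dir) {
  json_path <- file.path(dir, "report.json")
  md_path <- file.path(dir, "report.md")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  fmt_eq <- function(name, e) c(
    sprintf("## Equivalence: %s", name),
    sprintf("- n = %d, log scale = %s, tau = %g, alpha = %g",
            e$n, e$use_log, e$tau, e$alpha),
    sprintf("- Shapiro-Wilk on D: W = %.4f, p = %.4g", e$W, e$sw_p),
    sprintf("- Paired t: t = %.4f, p = %.4g", e$t, e$t_p),
    sprintf("- Variance ratio: F = %.4f, p = %.4g", e$F, e$vr_p),
    sprintf("- Innovation normality p: x = %.4g, y = %.4g",
            e$innovation_p[["x"]], e$innovation_p[["y"]]),
    sprintf("- **Classification: %s**", e$classification),
    e$narrative, "")
  lines <- c(
    "# Multi-source price validation report",
    sprintf("Seed %d; %d records in, %d kept (%.2f%% excluded).",
            report$seed, report$counts$records_in, report$counts$kept,
            report$counts$excluded_pct), "",
    "## Pearson concordance",
    sprintf("- %s @ %s: r = %.3f (r2 = %.3f, n = %d, p = %.3g)",
            report$correlations$pair, report$correlations$frequency,
            report$correlations$r, report$correlations$r2,
            report$correlations$n, report$correlations$p), "",
    "## Monthly lead-lag profile (positive lag: second series lags first)",
    sprintf("- lag %+d: r = %.3f (n = %d)", report$lag_profile$lag,
            report$lag_profile$r, report$lag_profile$n), "",
    fmt_eq("crowd vs enumerator (weekly)",
           report$equivalence$crowd_vs_enumerator_weekly),
    fmt_eq("crowd vs AI-imputed close (monthly)",
           report$equivalence$crowd_vs_ai_monthly))
  writeLines(lines, md_path)
  c(json = json_path, md = md_path)
}
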