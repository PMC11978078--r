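#' Standardise raw price records to NGN per kilogram
#'
#' Converts each record's total transaction price to a per-kg price by
#' dividing by quantity times the standard weight of its packaging unit.
#' Records whose unit is absent from the unit table, or with non-positive
#' price or quantity, are not dropped silently: they are routed to a rejects
#' table with a reason code.
#'
#' @param records tibble of price records (see
#'   \code{\link{generate_observations}} for the schema).
#' @param units unit table with columns \code{unit}, \code{weight_kg}
#'   (see \code{\link{default_unit_table}}).
#' @return list with \code{records} (input rows plus \code{price_per_kg}) and
#'   \code{rejects} (offending rows plus \code{reason}:
#'   \code{"unknown_unit"}, \code{"nonpositive_price"},
#'   \code{"nonpositive_quantity"}). Row counts conserve the input.
#' @export
to_price_per_kg <- function(records, units = default_unit_table()) {
  stopifnot(all(c("unit", "quantity", "price_total_ngn") %in% names(records)))
  if (anyDuplicated(units$unit))
    stop("unit table has duplicate unit names", call. = FALSE)
  if (any(units$weight_kg <= 0))
    stop("unit weights must be > 0", call. = FALSE)
  wt <- units$weight_kg[match(records$unit, units$unit)]
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(wt)] <- "unknown_unit"
  reason[is.na(reason) & records$price_total_ngn <= 0] <- "nonpositive_price"
  reason[is.na(reason) & records$quantity <= 0] <- "nonpositive_quantity"
  ok <- is.na(reason)
  out <- records[ok, , drop = FALSE]
  out$price_per_kg <- records$price_total_ngn[ok] /
    (records$quantity[ok] * wt[ok])
  rejects <- records[!ok, , drop = FALSE]
  rejects$reason <- reason[!ok]
  list(records = out, rejects = rejects)
}

#' Tukey-fence outlier mask with optional plausibility bounds
#'
#' Keeps values inside \eqn{[Q_1 - k\,\mathrm{IQR},\; Q_3 + k\,\mathrm{IQR}]}
#' and, if given, inside user-supplied plausibility bounds \code{[lo, hi]}
#' (the "expert knowledge of realistic price ranges" refinement). Quartiles
#' are computed once from all supplied values (single pass, not iterated).
#' With fewer than 4 values the fences are skipped and only the bounds apply.
#'
#' @param values numeric vector (NGN/kg).
#' @param k fence multiplier (>= 0; \code{Inf} disables the fences). Default
#'   1.5, the classic Tukey rule.
#' @param bounds optional length-2 numeric \code{c(lo, hi)}.
#' @return logical keep mask, same length as \code{values}.
#' @export
tukey_screen <- function(values, k = 1.5, bounds = NULL) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0)
    stop("fence multiplier `k` must be a single number >= 0", call. = FALSE)
  keep <- rep(TRUE, length(values))
  if (length(values) >= 4 && is.finite(k)) {
    q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    keep <- values >= q[1] - k * iqr & values <= q[2] + k * iqr
  }
  if (!is.null(bounds)) {
    stopifnot(length(bounds) == 2, bounds[1] <= bounds[2])
    keep <- keep & values >= bounds[1] & values <= bounds[2]
  }
  keep
}

#' Screen standardised records for outliers
#'
#' Applies \code{\link{tukey_screen}} per group (by default per
#' commodity-subtype-source over the full window) and labels each record
#' \code{"kept"}, \code{"bounds_removed"} (outside the plausibility bounds)
#' or \code{"tukey_removed"} (inside bounds but outside the fences). Fences
#' are computed from all values in the group, bounds included, in one pass.
#'
#' @param records tibble with a \code{price_per_kg} column.
#' @param k fence multiplier.
#' @param bounds optional \code{c(lo, hi)} plausibility bounds in NGN/kg.
#' @param group character vector of grouping columns for fence computation.
#' @return the input with a \code{screen_flag} column.
#' @export
screen_prices <- function(records, k = 1.5, bounds = NULL,
                          group = c("commodity", "subtype", "source")) {
  stopifnot("price_per_kg" %in% names(records))
  group <- intersect(group, names(records))
  flag_group <- function(v) {
    fence_ok <- tukey_screen(v, k = k, bounds = NULL)
    bound_ok <- if (is.null(bounds)) rep(TRUE, length(v))
                else v >= bounds[1] & v <= bounds[2]
    dplyr::case_when(!bound_ok ~ "bounds_removed",
                     !fence_ok ~ "tukey_removed",
                     TRUE ~ "kept")
  }
  records %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) %>%
    dplyr::mutate(screen_flag = flag_group(.data$price_per_kg)) %>%
    dplyr::ungroup()
}

#' Aggregate kept records to period means
#'
#' Unweighted arithmetic mean of per-kg prices over kept records, per period
#' and grouping key. Weeks are ISO-8601 weeks (Monday start); months are
#' calendar months. Periods with fewer than \code{min_n} submissions are
#' suppressed.
#'
#' @param records screened records (rows with \code{screen_flag != "kept"}
#'   are dropped if the column is present).
#' @param frequency \code{"daily"}, \code{"weekly"} or \code{"monthly"}.
#' @param group character vector of grouping columns.
#' @param min_n minimum submissions per emitted period (default 1).
#' @return tibble with the group columns plus \code{frequency}, \code{period}
#'   (string key), \code{period_start} (Date), \code{mean_price}, \code{n},
#'   \code{sd} (NA when n = 1), ordered by period within group.
#' @export
aggregate_prices <- function(records, frequency = "monthly",
                             group = c("commodity", "subtype", "source"),
                             min_n = 1) {
  check_frequency(frequency)
  stopifnot(all(c("date", "price_per_kg") %in% names(records)))
  group <- intersect(group, names(records))
  if ("screen_flag" %in% names(records))
    records <- dplyr::filter(records, .data$screen_flag == "kept")
  if (nrow(records) == 0) {
    return(tibble::tibble(frequency = character(), period = character(),
                          period_start = as.Date(character()),
                          mean_price = numeric(), n = integer(),
                          sd = numeric()))
  }
  records %>%
    dplyr::mutate(period_start = period_start(.data$date, frequency)) %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group, "period_start")))) %>%
    dplyr::summarise(mean_price = mean(.data$price_per_kg),
                     n = dplyr::n(),
                     sd = stats::sd(.data$price_per_kg),
                     .groups = "drop") %>%
    dplyr::filter(.data$n >= min_n) %>%
    dplyr::mutate(period = period_key(.data$period_start, .env$frequency),
                  frequency = .env$frequency) %>%
    dplyr::select(dplyr::all_of(group), "frequency", "period", "period_start",
                  "mean_price", "n", "sd") %>%
    dplyr::arrange(dplyr::across(dplyr::all_of(group)), .data$period_start)
}

#' Align two aggregate series on common periods
#'
#' Inner join of two single-group aggregate series of the same frequency;
#' the result is the paired series the concordance and equivalence tests
#' consume.
#'
#' @param a,b aggregate series (one group each) from
#'   \code{\link{aggregate_prices}}, or any tibble with \code{frequency},
#'   \code{period}, \code{period_start}, \code{mean_price}, \code{n}.
#' @return tibble of class \code{"paired_series"} with \code{period},
#'   \code{period_start}, \code{x}, \code{y}, \code{n_x}, \code{n_y} and a
#'   \code{"frequency"} attribute; one row per common period, ordered.
#' @export
align_pairs <- function(a, b) {
  for (d in list(a, b))
    stopifnot(all(c("frequency", "period", "period_start", "mean_price", "n")
                  %in% names(d)))
  fa <- unique(a$frequency); fb <- unique(b$frequency)
  if (length(fa) != 1L || length(fb) != 1L || fa != fb)
    stop("frequency mismatch: cannot pair a ", paste(fa, collapse = "/"),
         " series with a ", paste(fb, collapse = "/"), " series",
         call. = FALSE)
  if (anyDuplicated(a$period) || anyDuplicated(b$period))
    stop("each input must be a single series (one row per period); ",
         "filter to one group before pairing", call. = FALSE)
  paired <- dplyr::inner_join(
    dplyr::select(a, "period", "period_start", x = "mean_price", n_x = "n"),
    dplyr::select(b, "period", y = "mean_price", n_y = "n"),
    by = "period") %>%
    dplyr::arrange(.data$period_start)
  attr(paired, "frequency") <- fa
  class(paired) <- c("paired_series", class(paired))
  paired
}

#' Build a paired series directly from two value vectors
#'
#' Convenience constructor used by the simulation studies, where both sources
#' are already on a common period grid.
#'
#' @param x,y numeric vectors of equal length.
#' @param period_start optional Date vector; defaults to consecutive days.
#' @param frequency period label (default "daily").
#' @return a \code{"paired_series"} tibble as from \code{\link{align_pairs}}.
#' @export
paired_series <- function(x, y, period_start = NULL, frequency = "daily") {
  stopifnot(length(x) == length(y))
  check_frequency(frequency)
  if (is.null(period_start))
    period_start <- as.Date("2021-01-01") + seq_along(x) - 1
  out <- tibble::tibble(period = period_key(period_start, frequency),
                        period_start = period_start,
                        x = x, y = y, n_x = 1L, n_y = 1L)
  attr(out, "frequency") <- frequency
  class(out) <- c("paired_series", class(out))
  out
}
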