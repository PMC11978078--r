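#' @importFrom dplyr %>%
#' @importFrom rlang .data .env
NULL

FREQUENCIES <- c("daily", "weekly", "monthly")

check_frequency <- function(frequency) {
  if (!is.character(frequency) || length(frequency) != 1L ||
      !frequency %in% FREQUENCIES)
    stop("`frequency` must be one of: ", paste(FREQUENCIES, collapse = ", "),
         call. = FALSE)
  frequency
}

# first day of the period containing `date` (weeks start Monday, ISO style)
period_start <- function(date, frequency) {
  switch(check_frequency(frequency),
         daily   = date,
         weekly  = lubridate::floor_date(date, "week", week_start = 1),
         monthly = lubridate::floor_date(date, "month"))
}

# serialized period label: YYYY-MM-DD / YYYY-Www / YYYY-MM
period_key <- function(start, frequency) {
  switch(check_frequency(frequency),
         daily   = format(start, "%Y-%m-%d"),
         weekly  = sprintf("%d-W%02d", lubridate::isoyear(start),
                           lubridate::isoweek(start)),
         monthly = format(start, "%Y-%m"))
}

# integer index of a period start, consecutive periods differ by 1
period_index <- function(start, frequency) {
  switch(check_frequency(frequency),
         daily   = as.integer(start),
         weekly  = as.integer(start - as.Date("1970-01-05")) %/% 7L,
         monthly = lubridate::year(start) * 12L + lubridate::month(start))
}

# deterministic per-replicate seed stream: master + prime stride, mod 2^31 - 1
replicate_seed <- function(master, i) {
  as.integer((as.numeric(master) + 7919 * as.numeric(i)) %% 2147483647)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
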