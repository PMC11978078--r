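#' Paired difference sequence of two price series
#'
#' Builds \eqn{D_t = \ln X_t - \ln Y_t} (or \eqn{X_t - Y_t} on the level
#' scale) for a paired series. Under agreement up to normal measurement error,
#' \eqn{D} is i.i.d. normal around the fixed markup \eqn{\tau} with variance
#' \eqn{\sigma_e^2 + \sigma_v^2}; all three equivalence tests operate on or
#' alongside this sequence.
#'
#' @param pair a \code{\link{paired_series}} tibble.
#' @param use_log take logs first (default TRUE; the equivalence tests run on
#'   log prices).
#' @return object of class \code{"difference_series"}: list with
#'   \code{period}, \code{d}, \code{n}, \code{mean}, \code{sd},
#'   \code{use_log}.
#' @export
difference_series <- function(pair, use_log = TRUE) {
  stopifnot(all(c("x", "y") %in% names(pair)))
  x <- pair$x; y <- pair$y
  period <- if ("period" %in% names(pair)) pair$period else seq_along(x)
  if (use_log) {
    bad <- which(x <= 0 | y <= 0)
    if (length(bad))
      stop("non-positive prices at periods: ",
           paste(utils::head(period[bad], 5), collapse = ", "),
           if (length(bad) > 5) " ..." else "", call. = FALSE)
    d <- log(x) - log(y)
  } else {
    d <- x - y
  }
  structure(list(period = period, d = d, n = length(d),
                 mean = mean(d), sd = stats::sd(d), use_log = use_log),
            class = "difference_series")
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard AS R94 implementation
#' (\code{stats::shapiro.test}) with the domain checks the equivalence suite
#' needs. Failing to reject normality of the difference sequence is the
#' agreement criterion; it carries evidential weight only when the individual
#' series' innovations are themselves non-normal (see
#' \code{\link{classify_agreement}}).
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return list with \code{W} and \code{p}.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000, got n = ", n, call. = FALSE)
  if (stats::sd(values) == 0)
    stop("degenerate sample: all values identical", call. = FALSE)
  res <- stats::shapiro.test(values)
  list(W = unname(res$statistic), p = res$p.value)
}

#' Paired t-test against a fixed markup
#'
#' Tests \eqn{H_0: E[D] = \tau} with
#' \eqn{t = (\bar D - \tau) / (s_D / \sqrt n)} and a two-sided p-value from
#' the t distribution with n - 1 degrees of freedom. \eqn{\tau} defaults to 0
#' and must be supplied by the user when a known markup (transport cost,
#' packaging discount) is to be allowed for; it is never estimated from the
#' same differences being tested.
#'
#' @param diff a \code{\link{difference_series}} or numeric vector.
#' @param tau hypothesised fixed markup (same scale as the differences).
#' @return list with \code{t}, \code{p}, \code{df}, \code{tau}.
#' @export
paired_t <- function(diff, tau = 0) {
  d <- if (inherits(diff, "difference_series")) diff$d else diff
  n <- length(d)
  if (n < 2) stop("need at least 2 differences", call. = FALSE)
  s <- stats::sd(d)
  if (s == 0)
    stop("degenerate sample: all differences identical, s_D = 0",
         call. = FALSE)
  t <- (mean(d) - tau) / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1), df = n - 1, tau = tau)
}

#' Two-sided variance-ratio (F) test
#'
#' Tests equality of the two sources' variances with
#' \eqn{F = s_X^2 / s_Y^2} against the F distribution with
#' (n_x - 1, n_y - 1) degrees of freedom; the two-sided p-value is
#' \eqn{2\min\{P(F \le f), P(F \ge f)\}}.
#'
#' @param pair a \code{\link{paired_series}} tibble (or numeric vector with
#'   \code{y} supplied).
#' @param y optional numeric vector.
#' @param use_log compare variances of log prices (default TRUE).
#' @return list with \code{F}, \code{p}, \code{df1}, \code{df2}.
#' @export
variance_ratio <- function(pair, y = NULL, use_log = TRUE) {
  if (is.numeric(pair) && !is.null(y)) {
    x <- pair
  } else {
    stopifnot(all(c("x", "y") %in% names(pair)))
    x <- pair$x; y <- pair$y
  }
  if (use_log) {
    if (any(x <= 0) || any(y <= 0))
      stop("non-positive prices: cannot log-transform", call. = FALSE)
    x <- log(x); y <- log(y)
  }
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 observations per side", call. = FALSE)
  vy <- stats::var(y)
  if (vy == 0) stop("zero variance in denominator side y", call. = FALSE)
  f <- stats::var(x) / vy
  df1 <- length(x) - 1L; df2 <- length(y) - 1L
  pl <- stats::pf(f, df1, df2)
  list(F = f, p = min(1, 2 * min(pl, 1 - pl)), df1 = df1, df2 = df2)
}

#' Normality of a series' innovations (first differences of log price)
#'
#' Shapiro-Wilk test applied to \eqn{\Delta \ln p_t}. This is the
#' precondition probe of the equivalence logic: commodity price innovations
#' are typically skewed and heavy-tailed, and only then does normality of the
#' paired difference sequence discriminate between shared and divergent price
#' processes.
#'
#' @param series an aggregate series tibble (uses \code{mean_price}) or a
#'   numeric price vector.
#' @param use_log difference the log series (default TRUE).
#' @return list with \code{W}, \code{p}, \code{n_diff}.
#' @export
innovation_normality <- function(series, use_log = TRUE) {
  v <- if (is.numeric(series)) series else series$mean_price
  if (length(v) < 4)
    stop("need at least 4 periods to test innovation normality", call. = FALSE)
  if (use_log) {
    if (any(v <= 0)) stop("non-positive prices: cannot log-transform",
                          call. = FALSE)
    v <- log(v)
  }
  d <- diff(v)
  res <- shapiro_wilk(d)
  list(W = res$W, p = res$p, n_diff = length(d))
}

AGREEMENT_LEVELS <- c("full_equivalence", "equivalence_unequal_variance",
                      "equivalence_fixed_markup",
                      "equivalence_markup_and_variance",
                      "not_equivalent", "inconclusive_normal_innovations")

#' Three-level agreement classification
#'
#' Decision table combining the three tests and the innovation-normality
#' precondition:
#' \enumerate{
#'   \item Shapiro-Wilk on \eqn{D} rejects (\code{sw_p < sw_alpha}) —
#'     \code{not_equivalent}: the sources capture different price dynamics.
#'   \item \eqn{D} looks normal but so do both series' innovations —
#'     \code{inconclusive_normal_innovations}: with normal innovations a
#'     normal difference sequence carries no discriminating power, so no
#'     equivalence level is declared.
#'   \item Otherwise, by the paired-t and variance-ratio outcomes:
#'     neither rejects — \code{full_equivalence}; only the variance ratio —
#'     \code{equivalence_unequal_variance}; only the t-test —
#'     \code{equivalence_fixed_markup}; both —
#'     \code{equivalence_markup_and_variance}.
#' }
#'
#' @param sw_p Shapiro-Wilk p-value on the difference sequence.
#' @param t_p paired-t p-value.
#' @param vr_p variance-ratio p-value.
#' @param innov_p numeric vector (length 1 or 2) of innovation-normality
#'   p-values for the individual series; the precondition "innovations are
#'   non-normal" holds when at least one rejects at \code{alpha}.
#' @param alpha significance level for all component tests (default 0.05).
#' @param sw_alpha separate strictness threshold for the Shapiro-Wilk
#'   criterion (default \code{alpha}; 0.10 is a common stricter choice).
#' @return a single classification label (see \code{AGREEMENT_LEVELS}).
#' @examples
#' classify_agreement(sw_p = 0.34, t_p = 1e-4, vr_p = 0.93,
#'                    innov_p = c(0.001, 0.002))
#' @export
classify_agreement <- function(sw_p, t_p, vr_p, innov_p,
                               alpha = 0.05, sw_alpha = alpha) {
  ps <- c(sw_p, t_p, vr_p, innov_p)
  if (any(is.na(ps)) || length(innov_p) < 1)
    stop("all component p-values must be present and non-missing",
         call. = FALSE)
  if (any(ps < 0 | ps > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  if (sw_p < sw_alpha) return("not_equivalent")
  if (all(innov_p >= alpha)) return("inconclusive_normal_innovations")
  t_rej <- t_p < alpha
  vr_rej <- vr_p < alpha
  if (!t_rej && !vr_rej) "full_equivalence"
  else if (!t_rej && vr_rej) "equivalence_unequal_variance"
  else if (t_rej && !vr_rej) "equivalence_fixed_markup"
  else "equivalence_markup_and_variance"
}

#' Full equivalence report for a paired series
#'
#' Runs the complete suite on one pair of aggregated price series:
#' Shapiro-Wilk on the (log) difference sequence, the paired t-test against a
#' fixed markup, the two-sided variance-ratio test, the innovation-normality
#' precondition on each side, and the agreement classification.
#'
#' @param pair a \code{\link{paired_series}} tibble.
#' @param tau hypothesised fixed markup (log units when \code{use_log}).
#' @param alpha significance level.
#' @param sw_alpha strictness threshold for the normality-of-D criterion.
#' @param use_log analyse log prices (default TRUE).
#' @return object of class \code{"equivalence_report"}: list with \code{n},
#'   \code{diff}, \code{sw}, \code{t}, \code{vr}, \code{precondition}
#'   (x and y innovation tests), \code{alpha}, \code{sw_alpha}, \code{tau},
#'   \code{classification}, \code{narrative}.
#' @export
equivalence_report <- function(pair, tau = 0, alpha = 0.05,
                               sw_alpha = alpha, use_log = TRUE) {
  diff <- difference_series(pair, use_log = use_log)
  sw <- shapiro_wilk(diff$d)
  tt <- paired_t(diff, tau = tau)
  vr <- variance_ratio(pair, use_log = use_log)
  pre_x <- innovation_normality(pair$x, use_log = use_log)
  pre_y <- innovation_normality(pair$y, use_log = use_log)
  cls <- classify_agreement(sw$p, tt$p, vr$p, c(pre_x$p, pre_y$p),
                            alpha = alpha, sw_alpha = sw_alpha)
  narrative <- switch(cls,
    not_equivalent = "The difference sequence departs from normality: the two sources appear to capture different price dynamics; deviations cannot be attributed to measurement error alone.",
    inconclusive_normal_innovations = "Both series' innovations look normal, so a normal difference sequence cannot discriminate shared from divergent processes; no equivalence level is declared.",
    full_equivalence = "Differences are consistent with zero-mean normal measurement error of equal variance: the sources track the same price process.",
    equivalence_unequal_variance = "Same underlying price process, but one source has a larger measurement-error variance.",
    equivalence_fixed_markup = "Same underlying price process up to a fixed markup/markdown between the sources.",
    equivalence_markup_and_variance = "Same underlying price process, with both a fixed markup and unequal measurement-error variances.")
  structure(list(n = diff$n, diff = diff, sw = sw, t = tt, vr = vr,
                 precondition = list(x = pre_x, y = pre_y),
                 alpha = alpha, sw_alpha = sw_alpha, tau = tau,
                 use_log = use_log, classification = cls,
                 narrative = narrative),
            class = "equivalence_report")
}

#' @export
print.equivalence_report <- function(x, ...) {
  cat("Equivalence report", if (x$use_log) "(log prices)" else "(levels)", "\n")
  cat(sprintf("  n = %d,  alpha = %g,  tau = %g\n", x$n, x$alpha, x$tau))
  cat(sprintf("  Shapiro-Wilk on D: W = %.3f, p = %.3g\n", x$sw$W, x$sw$p))
  cat(sprintf("  Paired t (tau=%g): t = %.3f, p = %.3g\n",
              x$tau, x$t$t, x$t$p))
  cat(sprintf("  Variance ratio:    F = %.3f, p = %.3g\n", x$vr$F, x$vr$p))
  cat(sprintf("  Innovation normality p (x, y): %.3g, %.3g\n",
              x$precondition$x$p, x$precondition$y$p))
  cat("  Classification:", x$classification, "\n")
  cat(" ", x$narrative, "\n")
  invisible(x)
}
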