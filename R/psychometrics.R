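#' Reading accuracy in percent
#'
#' Number of correctly read words normalized by sentence length and
#' multiplied by 100.
#'
#' @param words_correct,words_total Counts (vectorized).
#' @return Percent correct in \[0, 100\].
#' @export
reading_accuracy <- function(words_correct, words_total) {
  if (any(words_total <= 0)) stop("words_total must be > 0", call. = FALSE)
  if (any(words_correct < 0 | words_correct > words_total)) {
    stop("words_correct must lie in [0, words_total]", call. = FALSE)
  }
  100 * words_correct / words_total
}

#' Reading speed in words per minute
#'
#' Correctly read words per minute over the reading interval (sentence
#' onset to Next Sentence dot foveation).
#'
#' @param words_correct Count of correctly read words (vectorized).
#' @param duration_ms Reading duration in ms (> 0).
#' @return Speed in WPM.
#' @export
reading_speed <- function(words_correct, duration_ms) {
  if (any(duration_ms <= 0)) stop("duration_ms must be > 0", call. = FALSE)
  words_correct * 60000 / duration_ms
}

#' Per-subject condition x size means over the two presentations
#'
#' Each condition x print-size combination appears twice in a session (once
#' per mini-block, with different sentences); a subject's performance on the
#' combination is the mean of the two presentations.
#'
#' @param log A `session_log` tibble (from [simulate_cohort()] or read from
#'   CSV) with columns `subject`, `block`, `condition`, `logmar`,
#'   `n_words`, `n_correct`, `reading_duration_ms`.
#' @return A tibble with one row per subject x condition x size:
#'   `accuracy_pct`, `speed_wpm`.
#' @export
condition_means <- function(log) {
  per_trial <- dplyr::mutate(
    tibble::as_tibble(log),
    accuracy_pct = reading_accuracy(.data$n_correct, .data$n_words),
    speed_wpm = reading_speed(.data$n_correct, .data$reading_duration_ms)
  )
  counts <- dplyr::count(per_trial, .data$subject, .data$condition,
                         .data$logmar)
  gaps <- dplyr::filter(counts, .data$n != 2)
  if (nrow(gaps) > 0) {
    stop(paste0(
      "incomplete session: expected two presentations per condition x size; gaps at ",
      paste(sprintf("%s/%s/%.1f (n=%d)", gaps$subject, gaps$condition,
                    gaps$logmar, gaps$n), collapse = ", ")), call. = FALSE)
  }
  dplyr::summarise(
    dplyr::group_by(per_trial, .data$subject, .data$condition, .data$logmar),
    accuracy_pct = mean(.data$accuracy_pct),
    speed_wpm = mean(.data$speed_wpm),
    .groups = "drop"
  )
}

#' Median with 16/84 percentile offsets
#'
#' The population summary used throughout: median, with the distances down
#' to the 16th and up to the 84th percentile (the nonparametric analogue of
#' mean +/- sd for bounded metrics). Percentiles use linear interpolation
#' (the inclusive method, `stats::quantile` type 7).
#'
#' @param values Non-empty numeric vector.
#' @return A one-row tibble: `median`, `lower` (median - p16), `upper`
#'   (p84 - median), `p16`, `p84`, `n`.
#' @export
#' @examples
#' summarize_percentiles(0:100)
summarize_percentiles <- function(values) {
  if (length(values) == 0 || any(is.na(values))) {
    stop("values must be non-empty and free of NA", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.16, 0.5, 0.84), type = 7, names = FALSE)
  tibble::tibble(median = q[2], lower = q[2] - q[1], upper = q[3] - q[2],
                 p16 = q[1], p84 = q[3], n = length(values))
}

#' Population psychometric curves from a session log
#'
#' Per condition and print size: the population median and 16/84 offsets of
#' the per-subject means, for reading accuracy and speed.
#'
#' @param log A `session_log` tibble.
#' @return A `psychometric_curve` tibble: `condition`, `logmar`, `metric`
#'   (`accuracy_pct` or `speed_wpm`), `median`, `lower`, `upper`, `n`.
#' @export
psychometric_curves <- function(log) {
  means <- condition_means(log)
  long <- tidyr::pivot_longer(means, c("accuracy_pct", "speed_wpm"),
                              names_to = "metric", values_to = "value")
  out <- dplyr::reframe(
    dplyr::group_by(long, .data$condition, .data$logmar, .data$metric),
    summarize_percentiles(.data$value)
  )
  class(out) <- c("psychometric_curve", class(out))
  out
}

# ---------------------------------------------------------------------------
# equivalent acuity

logistic100 <- function(x, m, k) 100 / (1 + exp(-k * (x - m)))

fit_logistic_ls <- function(sizes, accuracies) {
  sse <- function(par) {
    sum((accuracies - logistic100(sizes, par[1], exp(par[2])))^2)
  }
  # moderate-slope starts around the interpolated 50% crossing
  m0 <- tryCatch(stats::approx(accuracies, sizes, xout = 50, ties = "ordered",
                               rule = 2)$y,
                 error = function(e) stats::median(sizes))
  if (!is.finite(m0)) m0 <- stats::median(sizes)
  starts <- expand.grid(m = unique(c(m0, stats::median(sizes))),
                        logk = log(c(5, 20, 60)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(c(starts$m[i], starts$logk[i]), sse,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(m = best$par[1], k = exp(best$par[2]), sse = best$value)
}

#' Equivalent acuity from a constrained logistic fit
#'
#' Least-squares fit of `A(x) = 100 / (1 + exp(-k (x - m)))` to reading
#' accuracy versus print size, with floor 0 and ceiling 100 fixed; the 50%
#' point `m` is the equivalent acuity. The 95% CI comes from a seeded
#' nonparametric bootstrap over the points. The fit is flagged
#' non-converged when the curve does not cross 50% within half a logMAR of
#' the tested size range (extrapolated midpoints are unstable).
#'
#' @param sizes Print sizes (logMAR), at least 4.
#' @param accuracies Reading accuracies in \[0, 100\], same length.
#' @param bootstrap Number of bootstrap resamples for the CI (0 to skip).
#' @param seed Bootstrap seed.
#' @return An `acuity_fit` object; see [tidy.acuity_fit()].
#' @export
#' @examples
#' fit_equivalent_acuity(seq(0.9, 1.4, 0.1), c(13, 28, 75, 96, 100, 100))
fit_equivalent_acuity <- function(sizes, accuracies, bootstrap = 1000,
                                  seed = 1) {
  if (length(sizes) < 4 || length(sizes) != length(accuracies)) {
    stop("need >= 4 (size, accuracy) points of equal length", call. = FALSE)
  }
  if (any(accuracies < 0 | accuracies > 100)) {
    stop("accuracies must lie in [0, 100]", call. = FALSE)
  }
  fit <- fit_logistic_ls(sizes, accuracies)
  converged <- fit$m >= min(sizes) - 0.5 && fit$m <= max(sizes) + 0.5 &&
    is.finite(fit$m) && fit$k > 0

  ci <- c(NA_real_, NA_real_)
  boot_m <- numeric(0)
  if (bootstrap > 0) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    n <- length(sizes)
    boot_m <- vapply(seq_len(bootstrap), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(sizes[idx])) < 2) return(NA_real_)
      fit_logistic_ls(sizes[idx], accuracies[idx])$m
    }, 0)
    boot_m <- boot_m[is.finite(boot_m)]
    if (length(boot_m) > 10) {
      ci <- unname(stats::quantile(boot_m, c(0.025, 0.975), type = 7))
      ci[1] <- min(ci[1], fit$m)
      ci[2] <- max(ci[2], fit$m)
    }
  }
  structure(list(midpoint_logmar = fit$m, slope = fit$k, sse = fit$sse,
                 ci95 = ci, converged = converged,
                 sizes = sizes, accuracies = accuracies,
                 n_boot = length(boot_m)),
            class = "acuity_fit")
}

#' @export
print.acuity_fit <- function(x, ...) {
  cat(sprintf("<acuity_fit> equivalent acuity %.3f logMAR (95%% CI %.3f-%.3f), slope %.1f%s\n",
              x$midpoint_logmar, x$ci95[1], x$ci95[2], x$slope,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Tidy an equivalent-acuity fit
#'
#' @param x An `acuity_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter with estimate and CI;
#'   `glance()`: one-row model summary.
#' @export
tidy.acuity_fit <- function(x, ...) {
  tibble::tibble(
    term = c("midpoint_logmar", "slope"),
    estimate = c(x$midpoint_logmar, x$slope),
    conf.low = c(x$ci95[1], NA),
    conf.high = c(x$ci95[2], NA)
  )
}

#' @rdname tidy.acuity_fit
#' @export
glance.acuity_fit <- function(x, ...) {
  tibble::tibble(midpoint_logmar = x$midpoint_logmar, slope = x$slope,
                 sse = x$sse, converged = x$converged,
                 n_points = length(x$sizes), n_boot = x$n_boot)
}

#' Turn a fitted object into a tidy tibble
#'
#' Generics in the broom style; see [tidy.acuity_fit()].
#'
#' @param x A fitted object.
#' @param ... Method-specific arguments.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

# ---------------------------------------------------------------------------
# nonparametric tests

# midranks of a pooled sample
midranks <- function(v) rank(v, ties.method = "average")

#' Wilcoxon rank-sum test with normal approximation and exact small-sample null
#'
#' Two-sided rank-sum test with tie correction and continuity correction.
#' For pooled sample sizes of at most `exact_max` the p value comes from
#' full enumeration of all group assignments of the observed pooled values
#' (ties included); otherwise from the normal approximation. The effect
#' size follows the per-group convention `r = |z| / sqrt(n per group)`
#' (geometric mean of the two group sizes when unequal); the pooled-`N`
#' convention is reported alongside.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest pooled size for exact enumeration.
#' @return A one-row tibble: `z`, `p`, `r`, `r_total`, `w` (rank-sum
#'   statistic of `x`), `n_x`, `n_y`, `method`.
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6)) # exact two-sided p = 0.1
rank_sum_test <- function(x, y, exact_max = 12) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  nx <- length(x)
  ny <- length(y)
  n <- nx + ny
  pooled <- c(x, y)
  rk <- midranks(pooled)
  w <- sum(rk[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * (n + 1 - tie_term)
  if (sigma2 <= 0) { # all observations tied
    return(tibble::tibble(z = 0, p = 1, r = 0, r_total = 0, w = w,
                          n_x = nx, n_y = ny, method = "degenerate"))
  }
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  if (abs(w - mu) <= 0.5) z <- 0

  if (n <= exact_max) {
    combos <- utils::combn(n, nx)
    sums <- colSums(matrix(rk[combos], nrow = nx))
    dev <- abs(sums - mu)
    p <- mean(dev >= abs(w - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  p <- min(p, 1)
  n_group <- exp(mean(log(c(nx, ny)))) # geometric mean group size
  tibble::tibble(z = z, p = p,
                 r = abs(z) / sqrt(n_group),
                 r_total = abs(z) / sqrt(n),
                 w = w, n_x = nx, n_y = ny, method = method)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zeros are dropped; ranks of absolute differences use midranks. Exact
#' two-sided p by enumeration of all sign assignments when at most
#' `exact_max` nonzero differences remain; otherwise a tie-corrected normal
#' approximation with continuity correction.
#'
#' @param d Paired differences.
#' @param exact_max Largest n for exact enumeration.
#' @return A one-row tibble: `z`, `p`, `v` (positive-rank sum), `n_nonzero`,
#'   `method`.
#' @export
#' @examples
#' signed_rank_test(c(2, 1, 3, 5, 4, 6)) # all positive, exact p = 2/64
signed_rank_test <- function(d, exact_max = 12) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble::tibble(z = 0, p = 1, v = 0, n_nonzero = 0L,
                          method = "degenerate"))
  }
  rk <- rank(abs(d), ties.method = "average")
  v <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    sums <- as.vector(signs %*% rk)
    dev <- abs(sums - mu)
    p <- mean(dev >= abs(v - mu) - 1e-9)
    method <- "exact enumeration"
    z <- if (sigma2 > 0) (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2) else 0
  } else {
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  if (abs(v - mu) <= 0.5) z <- 0
  tibble::tibble(z = z, p = min(p, 1), v = v, n_nonzero = as.integer(n),
                 method = method)
}

#' Spearman rank correlation
#'
#' Midrank-based rank correlation with a t-approximation p value
#' (tie-aware since midranks enter the Pearson formula directly).
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return A one-row tibble: `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  n <- length(x)
  rho <- stats::cor(midranks(x), midranks(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  tibble::tibble(rho = rho, p = p, n = n)
}

#' Kolmogorov-Smirnov normality screen
#'
#' KS statistic of the sample against a normal with the sample mean and sd.
#' Estimating the parameters from the same sample makes the textbook KS p
#' value conservative (the Lilliefors caveat); the screen is used only to
#' justify falling back to nonparametric tests, not as a calibrated test.
#'
#' @param x Numeric sample, n >= 5.
#' @return A one-row tibble: `statistic`, `p`, `n`.
#' @export
normality_screen <- function(x) {
  if (length(x) < 5) stop("need at least 5 observations", call. = FALSE)
  ks <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  tibble::tibble(statistic = unname(ks$statistic), p = ks$p.value,
                 n = length(x))
}
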