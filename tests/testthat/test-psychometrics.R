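test_that("accuracy and speed follow their defining formulas", {
  expect_equal(reading_accuracy(12, 12), 100)
  expect_equal(reading_accuracy(6, 12), 50)
  expect_equal(reading_accuracy(0, 12), 0)
  expect_error(reading_accuracy(1, 0), "words_total")
  expect_error(reading_accuracy(13, 12), "words_correct")

  expect_equal(reading_speed(10, 60000), 10)
  expect_equal(reading_speed(0, 5000), 0)
  expect_equal(reading_speed(12, 6100), 118, tolerance = 0.01)
  expect_error(reading_speed(3, 0), "duration")
})

test_that("condition means average the two presentations", {
  log <- tidyr::expand_grid(
    subject = c("S1", "S2", "S3"),
    condition = c("normal", "full_gaze"),
    logmar = c(1.0, 1.2),
    block_rep = 1:2
  )
  log$n_words <- 10
  # subject S1 reads 8 then 10 words correct -> mean accuracy 90, etc.
  log$n_correct <- ifelse(log$block_rep == 1, 8, 10)
  log$n_correct[log$subject == "S2"] <- 5
  log$reading_duration_ms <- ifelse(log$block_rep == 1, 6000, 12000)
  log$block <- paste0(ifelse(log$condition == "normal", "A", "B"),
                      log$block_rep)

  m <- condition_means(log)
  s1 <- m[m$subject == "S1" & m$condition == "normal" & m$logmar == 1.0, ]
  expect_equal(s1$accuracy_pct, mean(c(80, 100)))
  expect_equal(s1$speed_wpm, mean(c(8 * 60000 / 6000, 10 * 60000 / 12000)))
  s2 <- m[m$subject == "S2" & m$condition == "full_gaze" & m$logmar == 1.2, ]
  expect_equal(s2$accuracy_pct, 50) # identical presentations pass through

  expect_error(condition_means(log[-1, ]), "incomplete session")
})

test_that("percentile summaries use inclusive linear interpolation", {
  s <- summarize_percentiles(c(5, 5, 5))
  expect_equal(s$median, 5)
  expect_equal(s$lower, 0)
  expect_equal(s$upper, 0)

  g <- summarize_percentiles(0:100)
  expect_equal(g$median, 50)
  expect_equal(g$p16, 16)
  expect_equal(g$p84, 84)

  set.seed(8)
  z <- summarize_percentiles(rnorm(1e5))
  expect_equal(z$median, 0, tolerance = 0.02)
  expect_equal(z$lower, qnorm(0.84), tolerance = 0.02)
  expect_equal(z$upper, qnorm(0.84), tolerance = 0.02)

  expect_error(summarize_percentiles(numeric(0)), "non-empty")
})

test_that("the constrained logistic recovers exact and tabulated data", {
  sizes <- seq(0.9, 1.4, by = 0.1)
  perfect <- 100 / (1 + exp(-20 * (sizes - 1.05)))
  fit <- fit_equivalent_acuity(sizes, perfect, bootstrap = 0)
  expect_equal(fit$midpoint_logmar, 1.05, tolerance = 1e-6)
  expect_equal(fit$slope, 20, tolerance = 1e-4)
  expect_true(fit$converged)

  # published full-gaze medians: 50% point lands near 1.02 logMAR
  fit_fg <- fit_equivalent_acuity(sizes, c(13, 28, 75, 96, 100, 100),
                                  bootstrap = 200, seed = 3)
  expect_equal(fit_fg$midpoint_logmar, 1.02, tolerance = 0.05)
  expect_true(fit_fg$converged)
  expect_true(fit_fg$ci95[1] <= fit_fg$midpoint_logmar &&
                fit_fg$midpoint_logmar <= fit_fg$ci95[2])

  # step data: midpoint between the two central sizes
  fit_step <- fit_equivalent_acuity(sizes, c(0, 0, 0, 100, 100, 100),
                                    bootstrap = 0)
  expect_equal(fit_step$midpoint_logmar, 1.15, tolerance = 0.05)

  # data whose 50% crossing lies far beyond the tested sizes: flagged,
  # not crashed (shallow logistic centered at 2.0 logMAR)
  far <- 100 / (1 + exp(-4 * (sizes - 2.0)))
  fit_flat <- fit_equivalent_acuity(sizes, far, bootstrap = 0)
  expect_false(fit_flat$converged)
  expect_equal(fit_flat$midpoint_logmar, 2.0, tolerance = 0.05)

  expect_error(fit_equivalent_acuity(1:3, c(0, 50, 100)), ">= 4")
  expect_error(fit_equivalent_acuity(sizes, rep(120, 6)), "0, 100")
})

test_that("acuity fits are equivariant to logMAR shifts and tidy-able", {
  sizes <- seq(0.9, 1.4, by = 0.1)
  acc <- c(10, 30, 60, 85, 97, 100)
  f0 <- fit_equivalent_acuity(sizes, acc, bootstrap = 0)
  f1 <- fit_equivalent_acuity(sizes + 0.3, acc, bootstrap = 0)
  expect_equal(f1$midpoint_logmar - f0$midpoint_logmar, 0.3,
               tolerance = 1e-4)

  td <- tidy(f0)
  expect_equal(td$term, c("midpoint_logmar", "slope"))
  gl <- glance(f0)
  expect_true(gl$converged)
  expect_equal(gl$n_points, 6)
})

test_that("rank-sum test matches exact enumeration and wilcox.test", {
  # all arrangements of {1..6}: one-tail 1/20, two-sided 0.1
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$p, 0.1)
  expect_equal(rs$method, "exact enumeration")

  ident <- rank_sum_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(ident$z, 0)
  expect_equal(ident$p, 1)

  # independent enumeration oracle for random small samples (with ties)
  set.seed(13)
  for (rep in 1:5) {
    x <- sample(1:8, 5, replace = TRUE)
    y <- sample(1:8, 5, replace = TRUE)
    rs <- rank_sum_test(x, y)
    pooled <- c(x, y)
    rk <- rank(pooled)
    mu <- 5 * 11 / 2
    combos <- combn(10, 5)
    sums <- colSums(matrix(rk[combos], nrow = 5))
    p_oracle <- mean(abs(sums - mu) >= abs(sum(rk[1:5]) - mu) - 1e-9)
    expect_equal(rs$p, p_oracle)
  }

  # large-sample normal approximation against stats::wilcox.test
  set.seed(21)
  x <- rnorm(25)
  y <- rnorm(30) + 0.6
  rs <- rank_sum_test(x, y)
  wt <- wilcox.test(x, y, correct = TRUE, exact = FALSE)
  expect_equal(rs$p, wt$p.value, tolerance = 0.01)
  expect_equal(rs$r, abs(rs$z) / sqrt(sqrt(25 * 30)))
  expect_equal(rs$r_total, abs(rs$z) / sqrt(55))
})

test_that("signed-rank test matches enumeration and handles degeneracies", {
  sr <- signed_rank_test(c(2, 1, 3, 5, 4, 6)) # all positive, n = 6
  expect_equal(sr$p, 2 / 2^6)
  expect_equal(signed_rank_test(c(-3, 3))$p, 1) # antisymmetric pair
  expect_equal(signed_rank_test(c(0, 0, 0))$p, 1) # all zeros dropped

  set.seed(17)
  for (rep in 1:5) {
    d <- sample(c(-4:-1, 1:6), 8, replace = TRUE)
    sr <- signed_rank_test(d)
    rk <- rank(abs(d))
    mu <- 8 * 9 / 4
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 8)))
    sums <- as.vector(signs %*% rk)
    p_oracle <- mean(abs(sums - mu) >= abs(sum(rk[d > 0]) - mu) - 1e-9)
    expect_equal(sr$p, p_oracle)
  }

  set.seed(23)
  d <- rnorm(40) + 0.4
  sr <- signed_rank_test(d)
  wt <- wilcox.test(d, correct = TRUE, exact = FALSE)
  expect_equal(sr$p, wt$p.value, tolerance = 0.01)
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(29)
  x <- rlnorm(10)
  y <- rlnorm(12) * 1.5
  f <- function(v) exp(v / 2) # strictly increasing
  expect_equal(rank_sum_test(x, y)$p, rank_sum_test(f(x), f(y))$p)
  expect_equal(rank_sum_test(x, y)$z, rank_sum_test(f(x), f(y))$z)
  d <- rnorm(15)
  # signed-rank needs an odd transform about zero to preserve |d| ranks
  g <- function(v) sign(v) * abs(v)^1.3
  expect_equal(signed_rank_test(d)$p, signed_rank_test(g(d))$p)
})

test_that("spearman correlation handles monotone, inverted and null cases", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  expect_equal(spearman_cor(1:10, (1:10)^3)$p, 0)
  set.seed(37)
  x <- rnorm(1000)
  y <- sample(x)
  expect_lt(abs(spearman_cor(x, y)$rho), 0.1)
  # t-approximation agrees with cor.test's
  a <- rnorm(40)
  b <- a + rnorm(40)
  ours <- spearman_cor(a, b)
  ct <- suppressWarnings(cor.test(a, b, method = "spearman"))
  expect_equal(ours$rho, unname(ct$estimate))
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 1:2), "length")
})

test_that("the KS normality screen behaves as a screen", {
  set.seed(41)
  normal_big <- rnorm(500)
  ks_n <- normality_screen(normal_big)
  expect_gt(ks_n$p, 0.05)
  uni <- runif(500)
  ks_u <- normality_screen(uni)
  expect_lt(ks_u$p, 0.05)
  expect_true(ks_n$statistic >= 0 && ks_n$statistic <= 1)
  expect_true(ks_u$statistic >= 0 && ks_u$statistic <= 1)
  expect_error(normality_screen(rnorm(4)), "at least 5")
})

test_that("psychometric curves respect bounds and ordering", {
  set.seed(43)
  # a compact synthetic log: 2 presentations x 3 conditions x 2 sizes x 4 subjects
  log <- tidyr::expand_grid(subject = paste0("S", 1:4),
                            condition = c("normal", "full_gaze", "head_only"),
                            logmar = c(1.0, 1.4), rep = 1:2)
  log$n_words <- 12
  base <- c(normal = 12, full_gaze = 8, head_only = 2)
  log$n_correct <- pmin(12, pmax(0, base[log$condition] +
                                   sample(-1:1, nrow(log), TRUE)))
  log$reading_duration_ms <- 8000
  log$block <- paste0(toupper(substr(log$condition, 1, 1)), log$rep)
  curves <- psychometric_curves(log)
  acc <- curves[curves$metric == "accuracy_pct", ]
  expect_true(all(acc$median >= 0 & acc$median <= 100))
  expect_true(all(acc$lower >= 0 & acc$upper >= 0))
  expect_true(all(curves[curves$metric == "speed_wpm", ]$median >= 0))
})
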