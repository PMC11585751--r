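test_that("rmse matches hand evaluation and is symmetric", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_equal(round(rmse(c(0, 0), c(3, 4)), 4), 3.5355)
  set.seed(41)
  a <- runif(50, 0, 100); b <- runif(50, 0, 100)
  expect_equal(rmse(a, b), rmse(b, a))
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("the RMSE matrix is symmetric with a zero diagonal", {
  set.seed(42)
  tab <- score_table(matrix(runif(4 * 30, 0, 100), 4, 30,
                            dimnames = list(paste0("P", 1:4), NULL)))
  m <- rmse_matrix(tab)
  expect_equal(unclass(m), t(unclass(m)))
  expect_equal(unname(diag(m)), rep(0, 4))
  expect_true(all(m >= 0))
})

test_that("duplicated readers force the expected zero and equal entries", {
  s <- matrix(c(10, 20, 30,
                15, 25, 20,
                10, 20, 30), 3, 3, byrow = TRUE,
              dimnames = list(c("P1", "P2", "P3"), NULL))
  m <- rmse_matrix(score_table(s))
  expect_equal(m["P1", "P3"], 0)
  expect_equal(m["P1", "P2"], m["P2", "P3"])
  # identical pair only
  m2 <- rmse_matrix(score_table(s[c(1, 3), ]))
  expect_equal(unclass(m2), matrix(0, 2, 2), ignore_attr = TRUE)
})

test_that("independent reader noise around a common truth gives ~sqrt(2)*sigma", {
  set.seed(43)
  truth <- runif(440, 15, 85) # keep noise clear of the [0, 100] clamp
  sigma <- 4
  s <- rbind(A = truth + rnorm(440, 0, sigma),
             B = truth + rnorm(440, 0, sigma))
  s <- pmin(pmax(s, 0), 100)
  m <- rmse_matrix(score_table(s))
  expect_equal(m["A", "B"], sqrt(2) * sigma, tolerance = 0.10)
})

test_that("mean pairwise discordance averages the upper triangle", {
  m <- matrix(0, 3, 3, dimnames = list(c("P1", "P2", "P3"),
                                       c("P1", "P2", "P3")))
  m[upper.tri(m)] <- c(18.10, 12.01, 12.12) # (1,2), (1,3), (2,3)
  m <- m + t(m)
  expect_equal(round(mean_pairwise_discordance(m), 2), 14.08)
  m2 <- matrix(0, 3, 3)
  m2[upper.tri(m2)] <- c(2.53, 2.10, 2.93)
  m2 <- m2 + t(m2)
  expect_equal(round(mean_pairwise_discordance(m2), 2), 2.52)
  same <- matrix(7.7, 3, 3); diag(same) <- 0
  expect_equal(mean_pairwise_discordance(same), 7.7)
  expect_error(mean_pairwise_discordance(matrix(0, 1, 1)), "two readers")
})

test_that("discordance reduction reproduces the headline arithmetic", {
  expect_equal(round(discordance_reduction(14.08, 2.52), 1), 82.1)
  expect_equal(discordance_reduction(5, 5), 0)
  expect_equal(discordance_reduction(10, 0), 100)
  expect_error(discordance_reduction(0, 1), "> 0")
})

test_that("Bland-Altman computes mean, sample SD and 1.96 limits", {
  ba0 <- bland_altman(c(1, 5, 9), c(1, 5, 9))
  expect_equal(ba0$mean_diff, 0); expect_equal(ba0$sd_diff, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  ba2 <- bland_altman(c(4, 4), c(2, 2)) # diffs 2, 2
  expect_equal(c(ba2$mean_diff, ba2$sd_diff), c(2, 0))
  ba <- bland_altman(c(2, 4), c(1, 1)) # diffs 1, 3
  expect_equal(ba$mean_diff, 2)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(c(ba$loa_low, ba$loa_high), 2 + c(-1, 1) * 1.96 * sqrt(2))
  expect_equal(c(ba$loa_low, ba$loa_high), c(-0.7718, 4.7718),
               tolerance = 1e-4)
  expect_true(ba$loa_low <= ba$mean_diff && ba$mean_diff <= ba$loa_high)
  expect_error(bland_altman(1, 2), "at least two")
})

test_that("swapping the Bland-Altman arguments negates mean and limits", {
  set.seed(44)
  a <- runif(30, 0, 100); b <- runif(30, 0, 100)
  f <- bland_altman(a, b); g <- bland_altman(b, a)
  expect_equal(g$mean_diff, -f$mean_diff)
  expect_equal(g$loa_low, -f$loa_high)
  expect_equal(g$loa_high, -f$loa_low)
  # population-SD variant is smaller by sqrt((n-1)/n)
  p <- bland_altman(a, b, sd_type = "population")
  expect_equal(p$sd_diff, f$sd_diff * sqrt(29 / 30))
})

test_that("rmse dominates the absolute mean difference", {
  set.seed(45)
  for (k in 1:10) {
    a <- runif(25, 0, 100); b <- runif(25, 0, 100)
    expect_gte(rmse(a, b), abs(mean(a - b)) - 1e-12)
  }
})

test_that("agreement rate is the accepted percentage", {
  expect_equal(round(agreement_rate(404, 440), 1), 91.8)
  expect_equal(round(agreement_rate(415, 440), 1), 94.3)
  expect_equal(agreement_rate(440, 440), 100)
  expect_error(agreement_rate(1, 0), "positive")
  expect_error(agreement_rate(-1, 10), "n_accepted")
})

test_that("error brackets bin absolute differences into 10-pp bins", {
  eh <- error_histogram(65.0, 7.5)
  expect_equal(eh$errors, 57.5)
  expect_equal(which(eh$counts == 1), 6) # the [50, 60) bracket
  eh2 <- error_histogram(c(10, 20, 30), c(10, 20, 30))
  expect_equal(eh2$counts, c(3, rep(0, 9)))
  eh3 <- error_histogram(c(5, 15, 15, 95), c(0, 0, 0, 0))
  expect_equal(eh3$counts, c(1, 2, 0, 0, 0, 0, 0, 0, 0, 1))
  expect_equal(sum(eh3$counts), 4)
  # the last bracket is closed at 100
  expect_equal(error_histogram(100, 0)$counts[10], 1)
})

test_that("a two-round study report combines matrix, means and reduction", {
  set.seed(46)
  truth <- runif(100, 0, 100)
  s <- rbind(P1 = truth + rnorm(100, 0, 10),
             P2 = truth + rnorm(100, 0, 10),
             A1 = truth + rnorm(100, 0, 2),
             A2 = truth + rnorm(100, 0, 2))
  s <- pmin(pmax(s, 0), 100)
  rep <- concordance_report(score_table(s), c("P1", "P2"), c("A1", "A2"))
  expect_gt(rep$discordance_pre, rep$discordance_post)
  expect_equal(rep$reduction_percent,
               100 * (1 - rep$discordance_post / rep$discordance_pre))
})

test_that("score tables reject missing or out-of-range cells and round-trip CSV", {
  expect_error(score_table(matrix(c(1, NA), 1, 2)), "missing")
  expect_error(score_table(matrix(c(5, 101), 1, 2)), "\\[0, 100\\]")
  expect_error(score_table(matrix(0, 2, 2,
                                  dimnames = list(c("P1", "P1"), NULL))),
               "duplicated")
  tab <- score_table(matrix(c(5, 10, 95.5, 0), 2, 2,
                            dimnames = list(c("P1", "AI"), c("r1", "r2"))))
  f <- tempfile(fileext = ".csv")
  write_score_table(tab, f)
  back <- read_score_table(f)
  expect_equal(back$scores, tab$scores)
  expect_equal(back$roi_ids, tab$roi_ids)
})
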