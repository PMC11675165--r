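# Likelihood-ratio oracle for the conditional-Gaussian MI statistic: within
# each stratum, twice the Gaussian log-likelihood ratio of regressing y on
# (x + continuous z) versus (continuous z) alone equals -N log(1 - r^2).
lr_oracle_micg <- function(tab, x, y, zc, strata) {
  stat <- 0
  for (idx in strata) {
    d <- tab[idx, , drop = FALSE]
    f1 <- stats::as.formula(paste(y, "~", paste(c(x, zc, "1"), collapse = "+")))
    f0 <- stats::as.formula(paste(y, "~", paste(c(zc, "1"), collapse = "+")))
    stat <- stat + 2 * (as.numeric(stats::logLik(stats::lm(f1, d))) -
                          as.numeric(stats::logLik(stats::lm(f0, d))))
  }
  stat
}

test_that("the MIcg statistic equals the stratified likelihood-ratio oracle", {
  tab <- generate_cohort(default_pbihb_like_config(n = 120, seed = 5))
  for (s in h1_statements()) {
    res <- micg_test(tab, s)
    strata <- split(seq_len(nrow(tab)), tab$G)
    zc <- setdiff(s$z, "G")
    expect_equal(res$statistic,
                 lr_oracle_micg(tab, s$x, s$y, zc, strata), tolerance = 1e-8)
    expect_identical(res$df, 2L)  # two gender strata
    expect_equal(res$p_value, pchisq(res$statistic, 2, lower.tail = FALSE))
  }
  # no discrete conditioning variable: one stratum, df = 1
  res1 <- micg_test(tab, ci_statement("M", "S", "A"))
  expect_identical(res1$df, 1L)
})

test_that("MIcg raises on degenerate and undersized inputs", {
  tab <- generate_cohort(default_pbihb_like_config(n = 60, seed = 2))
  tab$M2 <- tab$M
  expect_error(micg_test(tab, ci_statement("M", "M2", c("A", "G"))), "degenerate")
  tiny <- tab[1:8, ]
  tiny$G <- c(rep(0, 6), 1, 1)  # a 2-row stratum with 2 continuous z
  expect_error(micg_test(tiny, ci_statement("M", "S", c("A", "F", "G"))), "below the minimum")
  expect_error(micg_test(tab, ci_statement("M", "Q", "A")), "not in table")
})

test_that("MIcg is exactly symmetric in x and y", {
  tab <- generate_cohort(default_pbihb_like_config(n = 80, seed = 3))
  a <- micg_test(tab, ci_statement("M", "S", c("A", "G")))
  b <- micg_test(tab, ci_statement("S", "M", c("A", "G")))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
})

test_that("the GCM statistic matches explicit least-squares algebra on a fixed table", {
  # fixed 20-row worked table; the oracle solves the normal equations directly
  tab <- data.frame(
    x = c(2.1, -0.3, 1.4, 0.8, -1.7, 0.2, 3.0, -2.2, 0.9, 1.1,
          -0.6, 2.5, 0.4, -1.1, 1.8, -0.9, 0.6, 2.8, -1.4, 0.1),
    y = c(1.0, 0.4, -0.8, 2.2, 0.6, -1.3, 0.9, 1.7, -0.2, 0.3,
          2.0, -0.5, 1.2, 0.7, -1.9, 0.8, 1.5, -0.4, 0.2, 1.1),
    z = c(0.5, 1.2, -0.7, 0.3, 2.1, -1.5, 0.8, 0.9, -0.2, 1.7,
          0.1, -0.9, 1.3, 0.6, -1.1, 2.4, 0.0, 0.7, -1.8, 1.0)
  )
  res <- gcm_test(tab, ci_statement("x", "y", "z"), regressor = "linear")
  Z <- cbind(1, tab$z)
  hat <- Z %*% solve(t(Z) %*% Z, t(Z))
  ex <- tab$x - hat %*% tab$x
  ey <- tab$y - hat %*% tab$y
  r <- as.numeric(ex * ey)
  t_oracle <- sqrt(20) * mean(r) / sqrt(mean(r^2) - mean(r)^2)
  expect_equal(res$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pnorm(-abs(t_oracle)))
})

test_that("GCM is null-calibrated, symmetric, and affine-equivariant with a linear learner", {
  tstats <- vapply(1:100, function(i) {
    set.seed(i)
    tab <- data.frame(x = rnorm(500), y = rnorm(500), z = rnorm(500))
    gcm_test(tab, ci_statement("x", "y", "z"), regressor = "linear")$statistic
  }, numeric(1))
  expect_gte(mean(abs(tstats) < 3), 0.99)

  set.seed(11)
  tab <- data.frame(x = rnorm(100), y = rnorm(100), z = rnorm(100))
  a <- gcm_test(tab, ci_statement("x", "y", "z"), regressor = "linear")
  b <- gcm_test(tab, ci_statement("y", "x", "z"), regressor = "linear")
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)

  scaled <- transform(tab, x = 3.2 * x - 1, y = 0.5 * y + 4)
  s <- gcm_test(scaled, ci_statement("x", "y", "z"), regressor = "linear")
  expect_equal(s$statistic, a$statistic, tolerance = 1e-9)
  flipped <- transform(tab, y = -2 * y)
  f <- gcm_test(flipped, ci_statement("x", "y", "z"), regressor = "linear")
  expect_equal(f$statistic, -a$statistic, tolerance = 1e-9)

  tab$x2 <- tab$x
  expect_error(gcm_test(transform(tab[1:30, ], x = 0, y = 0),
                        ci_statement("x", "y", "z"), regressor = "linear"),
               "degenerate")
  expect_error(gcm_test(tab[1:10, ], ci_statement("x", "y", "z")), "at least 20")
})

test_that("the boosted-tree GCM is deterministic per seed and detects dependence", {
  tab <- generate_cohort(default_pbihb_like_config(n = 200, seed = 23,
                                                   theta = c(theta3 = -1.5)))
  a <- gcm_test(tab, ci_statement("M", "F", c("A", "G")), seed = 4)
  b <- gcm_test(tab, ci_statement("M", "F", c("A", "G")), seed = 4)
  expect_identical(a$statistic, b$statistic)
  expect_true(a$rejected)
})

test_that("KCI is calibrated under independence and powered against dependence", {
  pvals <- vapply(1:200, function(i) {
    set.seed(i)
    tab <- data.frame(x = rnorm(300), y = rnorm(300))
    kci_test(tab, ci_statement("x", "y"))$p_value
  }, numeric(1))
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.04)
  expect_lte(mean(pvals < 0.01), 0.035)

  set.seed(7)
  tab <- data.frame(x = rnorm(120))
  tab$y <- tab$x + 0.3 * rnorm(120)
  expect_lt(kci_test(tab, ci_statement("x", "y"))$p_value, 0.01)

  # conditional case: symmetric in (x, y) by construction
  set.seed(9)
  z <- rnorm(100)
  ctab <- data.frame(x = 0.8 * z + rnorm(100), y = -0.8 * z + rnorm(100), z = z)
  a <- kci_test(ctab, ci_statement("x", "y", "z"))
  b <- kci_test(ctab, ci_statement("y", "x", "z"))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-8)
  expect_false(a$rejected)

  ctab$c <- 1
  expect_error(kci_test(ctab, ci_statement("x", "c")), "degenerate")
  expect_error(kci_test(ctab[1:10, ], ci_statement("x", "y")), "at least 20")
})

test_that("Bonferroni re-decision uses the family-corrected level", {
  tab <- generate_cohort(default_pbihb_like_config(n = 60, seed = 13))
  res <- micg_test(tab, ci_statement("M", "S", c("A", "G")))
  fake <- function(p) { r <- res; r$p_value <- p; r }
  out <- bonferroni_decide(list(fake(0.001), fake(0.0101), fake(0.04)),
                           family_size = 5, family_alpha = 0.05)
  expect_true(out[[1]]$rejected)
  expect_false(out[[2]]$rejected)   # boundary: 0.0101 > 0.05/5
  expect_false(out[[3]]$rejected)
  expect_equal(out[[1]]$alpha, 0.01)
  plain <- bonferroni_decide(list(fake(0.04)), family_size = 1, family_alpha = 0.05)
  expect_true(plain[[1]]$rejected)
})

test_that("results tabulate and serialize to CSV", {
  tab <- generate_cohort(default_pbihb_like_config(n = 60, seed = 17))
  res <- lapply(h1_statements()[1:2], function(s) micg_test(tab, s))
  df <- ci_results_to_df(res)
  expect_identical(nrow(df), 2L)
  expect_named(df, c("x", "y", "z", "method", "statistic", "df",
                     "p_value", "alpha", "rejected", "n"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_ci_csv(res, f)
  expect_identical(nrow(utils::read.csv(f)), 2L)
})
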