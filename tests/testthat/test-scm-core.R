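ase_scm_with <- function(theta = numeric(0), n_override = NULL) {
  config_to_scm(default_pbihb_like_config(theta = theta))
}

test_that("SCM construction validates coefficients, noise and the interaction term", {
  g <- dag(c("X", "Y"), "X->Y")
  noise <- list(X = list(dist = "gaussian", mean = 0, sd = 1),
                Y = list(dist = "gaussian", mean = 0, sd = 1))
  expect_error(linear_gaussian_scm(g, c("Y->X" = 1), noise), "not an edge")
  bad <- noise; bad$X$sd <- 0
  expect_error(linear_gaussian_scm(g, noise = bad), "sd must be > 0")
  expect_error(
    linear_gaussian_scm(g, noise = noise,
                        interaction = list(parents = c("X", "Y"), child = "Y", coef = 1)),
    "requires edge"
  )
  expect_error(linear_gaussian_scm(g, noise = noise[1]), "every node")
})

test_that("observational sampling is seed-reproducible and matches noise laws when effects vanish", {
  scm <- ase_scm_with()
  a <- sample_observational(scm, 100, seed = 7)
  b <- sample_observational(scm, 100, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, sample_observational(scm, 100, seed = 8)))

  zero <- config_to_scm(default_pbihb_like_config(
    theta = stats::setNames(rep(0, 12), paste0("theta", 1:12))
  ))
  zero$intercepts[] <- 0
  tab <- sample_observational(zero, 10000, seed = 1)
  n <- nrow(tab)
  # each column is its own noise law: means within 4 standard errors
  expect_lt(abs(mean(tab$A) - 30), 4 * 8 / sqrt(n))
  expect_lt(abs(mean(tab$G) - 0.5), 4 * 0.5 / sqrt(n))
  expect_lt(abs(mean(tab$M) - 0), 4 * 1.5 / sqrt(n))
  expect_lt(abs(mean(tab$D) - 0), 4 * 5 / sqrt(n))
  expect_lt(abs(sd(tab$A) - 8), 4 * 8 / sqrt(2 * n))
  expect_lt(abs(sd(tab$S) - 4.5), 4 * 4.5 / sqrt(2 * n))
  expect_error(sample_observational(scm, 0, seed = 1), "positive")
})

test_that("least squares on simulated data recovers the generating M->F coefficient", {
  tab <- generate_cohort(default_pbihb_like_config(n = 50000, seed = 21))
  fit <- lm(F ~ M + A + G, data = tab)
  expect_lt(abs(coef(fit)[["M"]] - (-0.48)), 0.02)
})

test_that("interventions replace equations and leave the rest of the system alone", {
  scm <- ase_scm_with()
  centered <- scm
  centered$intercepts[] <- 0
  centered$noise$A$mean <- 0
  centered$noise$G$p <- 0.5
  tab0 <- sample_interventional(centered, c(M = 0), 20000, seed = 5)
  expect_true(all(tab0$M == 0))
  # with do(M:=0), E[F] = theta4 E[A] + theta5 E[G] = 0.6 * 0.5 here
  expect_lt(abs(mean(tab0$F) - 0.6 * 0.5), 4 * sd(tab0$F) / sqrt(nrow(tab0)))

  # finite-difference interventional contrast recovers theta3
  n <- 100000
  f1 <- mean(sample_interventional(scm, c(M = 1), n, seed = 9)$F)
  f0 <- mean(sample_interventional(scm, c(M = 0), n, seed = 10)$F)
  se <- sqrt(2) * 1.16 / sqrt(n)  # sd(F | do(M)) ~ sqrt(theta4^2 64 + theta5^2/4 + 1.21)
  expect_lt(abs((f1 - f0) - (-0.48)), 3 * se)

  # intervening on the childless depression node leaves upstream variables
  # distributionally unchanged
  obs <- sample_observational(scm, 4000, seed = 13)
  int <- sample_interventional(scm, c(D = 0), 4000, seed = 14)
  for (v in c("A", "M", "F", "S")) {
    expect_gt(suppressWarnings(ks.test(obs[[v]], int[[v]]))$p.value, 0.01)
  }
  # empty intervention is observational sampling exactly
  expect_identical(sample_observational(scm, 50, seed = 3),
                   sample_interventional(scm, list(), 50, seed = 3))
  expect_error(sample_interventional(scm, c(Q = 1), 10, seed = 1), "unknown")
})

test_that("independently drawn noise leaves no residual cross-correlation", {
  scm <- ase_scm_with()
  tab <- sample_observational(scm, 50000, seed = 31)
  res <- cbind(
    M = resid(lm(M ~ A + G, tab)),
    F = resid(lm(F ~ M + A + G, tab)),
    S = resid(lm(S ~ A + G, tab)),
    D = resid(lm(D ~ F + S + A + G, tab))
  )
  cors <- cor(res)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.02)
})

test_that("analytic effects are path-coefficient sums and match interventional simulation", {
  scm <- ase_scm_with()
  expect_equal(analytic_ace(scm, "M", "F"), -0.48)
  expect_equal(analytic_ace(config_to_scm(default_pbihb_like_config(theta = c(theta3 = 0))), "M", "F"), 0)
  expect_equal(analytic_ace(scm, "D", "M"), 0)  # no directed path
  # M -> D via fatigue: theta3 * theta8 (interaction off by default)
  expect_equal(analytic_ace(scm, "M", "D"), -0.48 * 2)
  n <- 200000
  d1 <- mean(sample_interventional(scm, c(M = 1), n, seed = 41)$D)
  d0 <- mean(sample_interventional(scm, c(M = 0), n, seed = 42)$D)
  expect_lt(abs((d1 - d0) - (-0.96)), 3 * sqrt(2) * 6.5 / sqrt(n))

  # a nonzero interaction on the path makes the per-unit effect undefined
  scm_ia <- config_to_scm(default_pbihb_like_config(theta = c(theta10 = -0.1)))
  expect_error(analytic_ace(scm_ia, "F", "D"), "unsupported structure")
  expect_error(analytic_ace(scm_ia, "M", "D"), "unsupported structure")
  expect_equal(analytic_ace(scm_ia, "M", "F"), -0.48)  # interaction not on this path
})

test_that("the analytic interaction effect equals the configured coefficient and its do-grid contrast", {
  scm_ia <- config_to_scm(default_pbihb_like_config(theta = c(theta10 = -0.1)))
  expect_equal(analytic_interaction_ace(scm_ia), -0.1)
  expect_equal(analytic_interaction_ace(config_to_scm(default_pbihb_like_config())), 0)
  plain <- linear_gaussian_scm(dag(c("X", "Y"), "X->Y"), c("X->Y" = 1),
                               list(X = list(dist = "gaussian", mean = 0, sd = 1),
                                    Y = list(dist = "gaussian", mean = 0, sd = 1)))
  expect_error(analytic_interaction_ace(plain), "no interaction")

  # mixed finite difference over a 2x2 do-grid
  n <- 200000
  m <- function(f, s, seed) mean(sample_interventional(scm_ia, c(F = f, S = s), n, seed = seed)$D)
  dd <- (m(4, 30, 51) - m(2, 30, 52) - m(4, 20, 53) + m(2, 20, 54)) / (2 * 10)
  expect_lt(abs(dd - (-0.1)), 3 * 2 * 5 / sqrt(n))  # 4 means / (2*10), sd(Nd)=5
})
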