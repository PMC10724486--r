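test_that("KMO equals the textbook anti-image formula (independent oracle)", {
  set.seed(41)
  x <- direct_grm_sample(toy_bank(4L), rnorm(400))
  kmo <- kmo_statistic(x)
  # oracle: partial correlations from regression residuals, never via the
  # inverse-correlation shortcut used by the implementation
  xs <- scale(x)
  J <- ncol(xs)
  q <- matrix(0, J, J)
  for (i in seq_len(J - 1)) for (j in (i + 1):J) {
    others <- xs[, -c(i, j), drop = FALSE]
    ri <- resid(lm(xs[, i] ~ others))
    rj <- resid(lm(xs[, j] ~ others))
    q[i, j] <- q[j, i] <- cor(ri, rj)
  }
  R <- cor(x)
  off <- upper.tri(R)
  oracle <- sum(R[off]^2) / (sum(R[off]^2) + sum(q[off]^2))
  expect_equal(kmo, oracle, tolerance = 1e-10)
})

test_that("KMO sits at 0.5 for two items and rises for strong one-factor data", {
  set.seed(42)
  th <- rnorm(600)
  x2 <- direct_grm_sample(toy_bank(2L, a = c(2, 2)), th)
  # with J = 2 the anti-image partial equals -r, so KMO = 0.5 identically
  expect_equal(kmo_statistic(x2), 0.5, tolerance = 1e-12)
  expect_gt(kmo_statistic(study_sim()), 0.9)
})

test_that("Bartlett's statistic matches direct arithmetic and its df bookkeeping", {
  set.seed(43)
  x <- direct_grm_sample(toy_bank(5L), rnorm(300))
  b <- bartlett_sphericity(x)
  n <- nrow(x); J <- ncol(x)
  expect_equal(b$chi2, -(n - 1 - (2 * J + 5) / 6) * log(det(cor(x))))
  expect_equal(b$df, J * (J - 1) / 2)
  sim <- study_sim()
  expect_equal(bartlett_sphericity(sim)$df, 253)
  expect_lt(bartlett_sphericity(sim)$p, 0.001)
})

test_that("eigenvalue ratio separates one-factor from two-factor structure", {
  ev <- eigenvalue_ratio(study_sim())
  expect_equal(sum(ev$eigenvalues), 23, tolerance = 1e-8)
  expect_true(all(diff(ev$eigenvalues) <= 1e-12))
  expect_gt(ev$ratio, 3)
  expect_true(ev$verdict)

  # two orthogonal latent traits, 11 + 12 items
  bank <- load_default_bank()
  s1 <- simulate_responses(bank[1:11], 700, seed = 44, covariate_spec = NULL)
  s2 <- simulate_responses(bank[12:23], 700, seed = 45, covariate_spec = NULL)
  two <- response_matrix(cbind(s1$responses, s2$responses), K = 5)
  ev2 <- eigenvalue_ratio(two)
  expect_lt(ev2$ratio, 3)
  expect_false(ev2$verdict)
})

test_that("Q3 residual correlations detect constructed local dependence", {
  sim <- study_sim()
  fit <- study_fit()
  q3 <- residual_correlations(sim, fit)
  expect_true(isSymmetric(unname(q3$q3)))
  expect_true(all(is.na(diag(q3$q3))))
  expect_true(q3$verdict)
  # known negative bias of Q3 under local independence: mean near -1/(J-1)
  expect_lt(abs(mean(q3$q3, na.rm = TRUE) - (-1 / 22)), 0.01)

  # duplicating an item creates perfect local dependence for that pair
  x <- grmbank:::complete_responses(sim)[, 1:10]
  dup <- cbind(x, DUP = x[, 1L])
  bank10 <- load_default_bank()[1:10]
  dup_bank <- item_bank(c(bank10$items,
                          list(item_params("DUP", bank10[[1L]]$a, bank10[[1L]]$b))),
                        K = 5)
  q3d <- residual_correlations(response_matrix(dup, K = 5), dup_bank)
  expect_gt(q3d$q3[1L, 11L], 0.8)
  expect_false(q3d$verdict)
})

test_that("monotonicity curves pass for GRM data and flag reversed coding", {
  sim <- study_sim()
  mono <- monotonicity_curves(sim)
  expect_true(mono$verdict)
  expect_true(all(vapply(mono$curves, function(cu) all(cu$n >= 30), logical(1))))

  x <- grmbank:::complete_responses(sim)
  x[, "EDANX05"] <- 6L - x[, "EDANX05"]
  mono2 <- monotonicity_curves(response_matrix(x, K = 5))
  expect_true(mono2$violations[["EDANX05"]])

  # a constant item yields a flat curve, not a violation
  x[, "EDANX05"] <- 3L
  mono3 <- monotonicity_curves(response_matrix(x, K = 5))
  expect_false(mono3$violations[["EDANX05"]])

  expect_error(monotonicity_curves(response_matrix(x[1:40, ], K = 5)), "too few")
})

test_that("check_assumptions aggregates the three verdicts", {
  rep <- check_assumptions(study_sim(), study_fit())
  expect_true(all(rep$verdicts))
  expect_gt(rep$kmo, 0.9)
  expect_lt(rep$bartlett$p, 0.001)
})
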