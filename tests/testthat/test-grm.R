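test_that("boundary probabilities honour logistic symmetry and ordering", {
  bank <- load_default_bank()
  it <- bank[["EDANX05"]]
  # at theta = b_k the boundary probability is exactly one half
  for (k in 1:4) expect_equal(boundary_prob(it, it$b[k])[1, k], 0.5)
  # P*_3 at theta 0 from the published parameters: 1/(1 + e^{5.47 * 0.05})
  expect_equal(boundary_prob(it, 0)[1, 3], 1 / (1 + exp(5.47 * 0.05)),
               tolerance = 1e-12)
  expect_equal(boundary_prob(it, 0)[1, 3], 0.432, tolerance = 1e-3)

  set.seed(51)
  for (rep in 1:20) {
    itr <- item_params("r", runif(1, 0.3, 6), sort(rnorm(4)))
    th <- runif(1, -4, 4)
    expect_true(all(diff(boundary_prob(itr, th)[1, ]) <= 0))
  }
  # large a: step function at b
  steep <- item_params("s", 500, c(-1, 0, 1, 2))
  expect_equal(boundary_prob(steep, -0.5)[1, ], c(1, 0, 0, 0), tolerance = 1e-10)
})

test_that("category probabilities are a simplex at every theta", {
  bank <- load_default_bank()
  th <- seq(-4, 4, by = 0.25)
  for (it in bank$items) {
    P <- category_prob(it, th)
    expect_true(all(P >= 0))
    expect_equal(rowSums(P), rep(1, length(th)), tolerance = 1e-12)
  }
  expect_equal(category_prob(bank[[1]], -30)[1, 1], 1, tolerance = 1e-10)
  # every category is modal somewhere on the grid, for every bank item
  for (it in bank$items) {
    modal <- apply(category_prob(it, seq(-4, 4, by = 0.1)), 1, which.max)
    expect_setequal(unique(modal), 1:5)
  }
})

test_that("marginal log-likelihood matches hand arithmetic on one response", {
  it <- item_params("x", 2, c(-1, 0, 1, 2))
  bank <- item_bank(list(it, item_params("y", 1.5, c(-2, -1, 0, 1))), K = 5)
  x <- matrix(c(3L, 2L, NA, 4L), 2, 2, dimnames = list(NULL, c("x", "y")))
  rm <- response_matrix(x, K = 5)
  grid2 <- structure(list(nodes = c(-1, 1), weights = c(0.5, 0.5)),
                     class = "theta_grid")
  # direct arithmetic over the two flat-prior nodes:
  # person 1 answered x = 3 only; person 2 answered x = 2, y = 4
  p3x <- function(th) category_prob(it, th)[1, 3]
  p2x <- function(th) category_prob(it, th)[1, 2]
  p4y <- function(th) category_prob(bank[[2]], th)[1, 4]
  ll1 <- log(0.5 * p3x(-1) + 0.5 * p3x(1))
  ll2 <- log(0.5 * p2x(-1) * p4y(-1) + 0.5 * p2x(1) * p4y(1))
  expect_equal(grm_loglik(bank, rm, grid2), ll1 + ll2, tolerance = 1e-12)
})

test_that("unanswered items do not change the likelihood and true beats perturbed", {
  bank <- toy_bank(4L)
  sim <- simulate_responses(bank, 300, seed = 52, covariate_spec = NULL)
  g <- theta_grid(31)
  base <- grm_loglik(bank, sim, g)
  x <- sim$responses
  x[, 4] <- NA
  dropped <- response_matrix(x, K = 5)
  expect_equal(grm_loglik(bank[1:3], response_matrix(x[, 1:3], K = 5), g),
               grm_loglik(bank, dropped, g), tolerance = 1e-10)

  worse <- 0
  for (s in 1:5) {
    simz <- simulate_responses(bank, 400, seed = 52 + s, covariate_spec = NULL)
    pert <- item_bank(lapply(bank$items, function(it)
      item_params(it$item_id, it$a * 1.5, it$b)), K = 5)
    worse <- worse + (grm_loglik(bank, simz, g) > grm_loglik(pert, simz, g))
  }
  expect_gte(worse, 4)
})

test_that("EM calibration recovers a small bank and keeps a monotone trace", {
  bank <- toy_bank(5L, a = c(1.2, 1.8, 2.4, 3.0, 3.6))
  sim <- simulate_responses(bank, 1500, seed = 53, covariate_spec = NULL)
  fit <- fit_grm(sim)
  expect_true(fit$converged)
  expect_true(all(diff(fit$trace) > -1e-8))
  est <- as.data.frame(fit$bank)
  true <- as.data.frame(bank)
  expect_lt(sqrt(mean(((est$a - true$a) / true$a)^2)), 0.15)
  bt <- as.matrix(true[, 3:6]); be <- as.matrix(est[, 3:6])
  expect_lt(sqrt(mean((be[abs(bt) < 2] - bt[abs(bt) < 2])^2)), 0.15)
})

test_that("estimation bias shrinks as the sample grows", {
  bank <- toy_bank(5L)
  err <- vapply(c(400L, 6000L), function(n) {
    sim <- simulate_responses(bank, n, seed = 54, covariate_spec = NULL)
    est <- as.data.frame(fit_grm(sim)$bank)
    true <- as.data.frame(bank)
    mean(abs(est$a - true$a) / true$a) +
      mean(abs(as.matrix(est[, 3:6]) - as.matrix(true[, 3:6])))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("small samples are refused and empty categories are collapsed", {
  bank <- toy_bank(3L)
  sim <- simulate_responses(bank, 150, seed = 55, covariate_spec = NULL)
  tiny <- response_matrix(sim$responses[1:10, ], K = 5)
  expect_error(fit_grm(tiny), "at least 100 persons")

  # an item whose top category is unreachable at this sample size
  rare <- item_bank(list(item_params("r1", 2, c(-1, 0, 1, 9)),
                         toy_bank(2L)[[1]], toy_bank(2L)[[2]]), K = 5)
  sim2 <- simulate_responses(rare, 300, seed = 56, covariate_spec = NULL)
  expect_true(all(sim2$responses[, "r1"] < 5L))
  fit2 <- fit_grm(sim2)
  expect_named(fit2$collapsed, "r1")
  expect_equal(fit2$collapsed$r1$K_j, 4L)
  expect_length(fit2$bank[["r1"]]$b, 3L)
})

test_that("screening applies the published rules to the packaged bank", {
  bank <- load_default_bank()
  scr <- screen_items(bank)
  expect_true(all(scr$a_ok))
  expect_true(all(scr$b_ok))
  bad <- scr[!scr$interval_ok, ]
  expect_equal(nrow(bad), 1L)
  expect_equal(bad$item_id, "EDANX09")
  expect_equal(bad$b2_b1, 0.74, tolerance = 1e-12)
  expect_equal(bad$flagged_intervals, "b2_b1")
  # intervals are exact threshold differences
  expect_equal(scr$b3_b2, vapply(bank$items, function(it) it$b[3] - it$b[2],
                                 numeric(1)))

  weak <- item_bank(list(item_params("w", 0.3, c(-1, 0, 1, 2)),
                         bank[[1]]), K = 5)
  expect_false(screen_items(weak)$a_ok[1])
})

test_that("fit indices separate a correct model from a forced one-factor fit", {
  bank12 <- load_default_bank()[seq(1, 23, by = 2)][1:12]
  sim <- simulate_responses(bank12, 700, seed = 57, covariate_spec = NULL)
  fit <- fit_grm(sim)
  fi <- fit_indices(sim, fit)
  expect_equal(fi$df, (12 + 66) - 12 * 5)   # moments minus item parameters
  expect_gt(fi$df, 0)
  expect_lt(fi$rmsea, 0.05)
  expect_gt(fi$cfi, 0.95)

  s1 <- simulate_responses(bank12[1:6], 700, seed = 58, covariate_spec = NULL)
  s2 <- simulate_responses(bank12[7:12], 700, seed = 59, covariate_spec = NULL)
  two <- response_matrix(cbind(s1$responses, s2$responses), K = 5)
  fi2 <- fit_indices(two, fit_grm(two))
  expect_gt(fi2$rmsea, fi$rmsea)

  # full-bank degrees of freedom: 23 + 253 moments, 115 parameters
  fi23 <- fit_indices(study_sim(), study_fit())
  expect_equal(fi23$df, 161)
})
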