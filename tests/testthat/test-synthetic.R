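test_that("simulation is seed-deterministic and leaves the caller's RNG alone", {
  bank <- toy_bank(3L)
  set.seed(999)
  before <- .Random.seed
  s1 <- simulate_responses(bank, 200, seed = 81)
  expect_identical(.Random.seed, before)
  s2 <- simulate_responses(bank, 200, seed = 81)
  s3 <- simulate_responses(bank, 200, seed = 82)
  expect_identical(s1$responses, s2$responses)
  expect_identical(s1$covariates, s2$covariates)
  expect_false(identical(s1$responses, s3$responses))
  expect_error(simulate_responses(bank, 200), "seed is mandatory")
})

test_that("the study-shaped dataset has the published dimensions and proportions", {
  sim <- study_sim()
  expect_equal(dim(sim), c(1075L, 23L))
  expect_named(sim$covariates, c("age_group", "gender", "education"))
  p <- prop.table(table(sim$covariates$age_group))
  expect_equal(unname(p[["18-59"]]), 0.645, tolerance = 0.05)
  p <- prop.table(table(sim$covariates$gender))
  expect_equal(unname(p[["female"]]), 0.620, tolerance = 0.05)
  # true thetas travel out of band, never inside the data
  expect_length(attr(sim, "theta"), 1075L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_responses(sim, f)
  expect_false(any(grepl("theta", readLines(f, n = 1L))))
})

test_that("simulated category frequencies match the quadrature-implied margins", {
  bank3 <- load_default_bank()[c(3, 10, 21)]     # high, low, mid discrimination
  n <- 100000L
  sim <- simulate_responses(bank3, n, seed = 83, covariate_spec = NULL)
  g <- theta_grid(201)
  for (j in 1:3) {
    marg <- as.vector(g$weights %*% category_prob(bank3[[j]], g$nodes))
    obs <- tabulate(sim$responses[, j], 5L) / n
    se <- sqrt(marg * (1 - marg) / n)
    expect_true(all(abs(obs - marg) < 3 * se + 1e-4))
  }
})

test_that("a degenerate prior pins every person to the same distribution", {
  bank <- toy_bank(3L)
  sim <- simulate_responses(bank, 20000, seed = 84, theta_sd = 0,
                            covariate_spec = NULL)
  for (j in 1:3) {
    expected <- sum(seq_len(5) * category_prob(bank[[j]], 0)[1, ])
    expect_equal(mean(sim$responses[, j]), expected, tolerance = 0.02)
  }
})

test_that("inject_dif shifts the focal group in the right direction", {
  bank <- load_default_bank()
  same <- inject_dif(bank, data.frame(item_id = "EDANX05", type = "uniform",
                                      magnitude = 0))
  expect_equal(as.data.frame(same), as.data.frame(bank))
  shifted <- inject_dif(bank, data.frame(item_id = "EDANX05", type = "uniform",
                                         magnitude = 0.75))
  th <- seq(-3, 3, by = 0.5)
  e_ref <- category_prob(bank[["EDANX05"]], th) %*% 1:5
  e_foc <- category_prob(shifted[["EDANX05"]], th) %*% 1:5
  expect_true(all(e_foc < e_ref))
  # reference bank untouched, other items untouched
  expect_equal(bank[["EDANX05"]]$b, c(-2.29, -1.17, 0.05, 1.46))
  expect_equal(shifted[["EDANX53"]]$b, bank[["EDANX53"]]$b)

  nonu <- inject_dif(bank, data.frame(item_id = "EDANX47", type = "nonuniform",
                                      magnitude = 0.5))
  expect_equal(nonu[["EDANX47"]]$a, 2.28 * 1.5)
  expect_error(inject_dif(bank, data.frame(item_id = "EDANX99", type = "uniform",
                                           magnitude = 1)), "unknown item")
})

test_that("recalibrating simulated data reproduces the marginal category tables", {
  bank5 <- load_default_bank()[c(2, 6, 11, 16, 20)]
  sim <- simulate_responses(bank5, 1200, seed = 85, covariate_spec = NULL)
  fit <- fit_grm(sim)
  resim <- simulate_responses(fit$bank, 1200, seed = 86, covariate_spec = NULL)
  for (j in 1:5) {
    tab <- rbind(tabulate(sim$responses[, j], 5L),
                 tabulate(resim$responses[, j], 5L))
    expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.01)
  }
})
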