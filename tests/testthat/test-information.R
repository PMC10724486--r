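test_that("item information matches the finite-difference Fisher definition", {
  bank <- load_default_bank()
  set.seed(61)
  h <- 1e-5
  for (rep in 1:20) {
    it <- bank[[sample(23, 1)]]
    th <- runif(1, -3.5, 3.5)
    P <- category_prob(it, th)[1, ]
    dlog <- (log(category_prob(it, th + h)[1, ]) -
             log(category_prob(it, th - h)[1, ])) / (2 * h)
    oracle <- sum(P * dlog^2)   # E[(d log P / d theta)^2]
    expect_equal(item_information(it, th), oracle, tolerance = 1e-4)
  }
})

test_that("a dichotomous item at its threshold yields exactly a^2/4", {
  it <- item_params("d", 2.6, 0.7)
  expect_equal(item_information(it, 0.7), 2.6^2 / 4, tolerance = 1e-12)
})

test_that("maximum information reproduces the published anchor items", {
  bank <- load_default_bank()
  m05 <- max_information(bank[["EDANX05"]])
  expect_equal(m05$max_info, 7.49, tolerance = 0.05)
  expect_equal(m05$theta_at_max, -2.3, tolerance = 1e-9)
  expect_equal(max_information(bank[["EDANX47"]])$max_info, 1.38,
               tolerance = 0.05)

  sym <- item_params("s", 2, c(-1.5, -0.5, 0.5, 1.5))
  ms <- max_information(sym)
  th <- seq(-4, 4, by = 0.1)
  v <- item_information(sym, th)
  expect_equal(v, rev(v), tolerance = 1e-10)    # even curve about 0
  expect_lte(ms$theta_at_max, 0)                # tie resolved to smaller theta
})

test_that("near-tied multimodal curves report the full tied-peak set", {
  bank <- load_default_bank()
  m53 <- max_information(bank[["EDANX53"]])
  expect_true(length(m53$tied_peaks) >= 2)
  expect_true(any(abs(m53$tied_peaks - (-2.3)) < 1e-9))
})

test_that("test information is additive and bounds the best single item", {
  bank <- load_default_bank()
  th <- seq(-4, 4, by = 0.5)
  tic <- test_information(bank, th)
  single <- test_information(bank[1], th)
  expect_equal(single$info, item_information(bank[[1]], th))
  per_item <- sapply(bank$items, function(it) item_information(it, th))
  expect_true(all(tic$info >= apply(per_item, 1, max)))
  expect_equal(tic$info, rowSums(per_item))
  expect_equal(tic$se, 1 / sqrt(tic$info))
  expect_equal(test_information(bank, 0)$info, 63.427, tolerance = 0.5)
})

test_that("OCC tables are simplex rows with the expected modal category", {
  bank <- load_default_bank()
  occ <- occ_table(bank[["EDANX05"]])
  expect_equal(rowSums(occ[, paste0("P", 1:5)]), rep(1, nrow(occ)),
               tolerance = 1e-12)
  at0 <- occ[abs(occ$theta) < 1e-9, ]
  expect_equal(at0$modal, 3)
  expect_equal(at0$P3, 0.566, tolerance = 0.01)
  # the boundary-curve slope is bounded by a/4 and attained near b
  steep <- max(abs(diff(boundary_prob(bank[["EDANX05"]], occ$theta)[, 1]) / 0.1))
  flat <- max(abs(diff(boundary_prob(bank[["EDANX47"]], occ$theta)[, 1]) / 0.1))
  expect_gt(steep, flat)
})

test_that("EAP scores order patterns, shrink, and track the posterior SE", {
  bank <- load_default_bank()
  x <- rbind(rep(1L, 23), rep(5L, 23), rep(3L, 23))
  colnames(x) <- item_ids(bank)
  sc <- eap_scores(bank, response_matrix(x, K = 5))
  expect_lt(sc$eap_theta[1], 0)
  expect_gt(sc$eap_theta[2], 0)
  expect_true(all(sc$posterior_sd < 1))

  sim1 <- simulate_responses(bank, 400, seed = 62, theta_mean = 1, theta_sd = 0,
                             covariate_spec = NULL)
  sc1 <- eap_scores(bank, sim1)
  expect_gt(mean(sc1$eap_theta), 0.8)
  expect_lt(mean(sc1$eap_theta), 1.0)

  # near the bank's centre 1/sqrt(T) approximates the posterior SD
  sim0 <- simulate_responses(bank, 400, seed = 63, covariate_spec = NULL)
  sc0 <- eap_scores(bank, sim0)
  centre <- abs(sc0$eap_theta) < 0.5
  se_info <- 1 / sqrt(test_information(bank, sc0$eap_theta[centre])$info)
  expect_lt(max(abs(sc0$posterior_sd[centre] / se_info - 1)), 0.15)

  # a person with no answered items gets an undefined score
  x2 <- x; x2[3, ] <- NA
  sc2 <- eap_scores(bank, response_matrix(x2, K = 5))
  expect_true(is.na(sc2$eap_theta[3]))
})

test_that("the information summary reproduces the published counts and range", {
  isum <- information_summary(load_default_bank())
  expect_equal(attr(isum, "n_high"), 10L)
  expect_gt(max(isum$max_info), 7.44); expect_lt(max(isum$max_info), 7.54)
  expect_gt(min(isum$max_info), 1.33); expect_lt(min(isum$max_info), 1.43)
  expect_true(all(isum$max_info >= isum$info_at_zero))
})
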