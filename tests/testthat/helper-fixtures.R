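# shared fixtures; the expensive study-scale objects are computed once per
# test run and memoized
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# canonical study-shaped simulation (1075 x 23, one fixed seed)
study_sim <- function() memo("study_sim", simulate_study(seed = 101))

# its MML-EM calibration
study_fit <- function() memo("study_fit", fit_grm(study_sim()))

# a small synthetic bank for cheap unit tests
toy_bank <- function(J = 4L, a = seq(1.5, 3, length.out = J)) {
  items <- lapply(seq_len(J), function(j)
    item_params(sprintf("it%02d", j), a[j],
                c(-1.5, -0.5, 0.5, 1.5) + (j - mean(seq_len(J))) * 0.2))
  item_bank(items, K = 5L)
}

# one-factor graded data without going through simulate_responses
# (independent route used when the generator itself is under test)
direct_grm_sample <- function(bank, theta) {
  x <- sapply(bank$items, function(it) {
    Ps <- boundary_prob(it, theta)
    1L + rowSums(stats::runif(length(theta)) < Ps)
  })
  colnames(x) <- item_ids(bank)
  x
}

# the published item-information table: item, max info, theta at max,
# info at theta 0
published_info_table <- function() {
  read.csv(text = 'item_id,max_info,theta_at_max,info_at_zero
EDANX27,4.15,0.1,3.92
EDANX53,6.64,-2.3,6.53
EDANX05,7.49,-2.3,7.33
EDANX12,4.31,0.3,3.09
EDANX55,3.83,0.7,2.30
EDANX01,6.03,2.0,3.81
EDANX02,4.22,1.1,3.26
EDANX33,4.92,1.3,4.75
EDANX08,1.93,1.7,1.82
EDANX47,1.38,-0.6,1.14
EDANX18,1.97,-0.4,1.68
EDANX26,2.11,-0.4,1.70
EDANX07,1.88,1.7,1.44
EDANX30,1.76,-1.5,1.72
EDANX46,2.98,-1.6,2.91
EDANX51,3.44,-1.0,2.61
EDANX54,2.14,-0.5,1.75
EDANX41,1.94,1.4,1.69
EDANX03,1.42,0.9,1.27
EDANX48,2.89,-1.6,2.50
EDANX09,4.67,-1.7,2.96
EDANX39,1.54,-0.1,1.53
EDANX40,1.88,1.5,1.73', stringsAsFactors = FALSE)
}

# independently checked-in copy of the published parameter table
published_param_table <- function() {
  read.csv(text = 'item_id,a,b1,b2,b3,b4
EDANX27,4.05,-2.52,-1.12,0.12,1.21
EDANX53,5.16,-2.33,-1.13,0.06,1.34
EDANX05,5.47,-2.29,-1.17,0.05,1.46
EDANX12,4.13,-2.68,-0.84,0.33,1.66
EDANX55,3.88,-2.31,-0.50,0.71,1.95
EDANX01,4.90,-1.63,-0.30,0.93,2.01
EDANX02,4.08,-1.75,-0.27,1.04,2.07
EDANX33,4.37,-1.60,0.04,1.29,2.13
EDANX08,2.68,-1.55,0.10,1.58,2.63
EDANX47,2.28,-2.01,-0.54,1.06,3.21
EDANX18,2.76,-1.81,-0.37,1.06,2.66
EDANX26,2.86,-1.92,-0.42,0.98,2.58
EDANX07,2.62,-1.48,0.37,1.63,2.62
EDANX30,2.60,-2.87,-1.48,0.10,1.66
EDANX46,3.39,-2.48,-1.52,0.00,1.38
EDANX51,3.66,-2.08,-0.98,0.32,1.67
EDANX54,2.87,-1.98,-0.49,0.79,2.30
EDANX41,2.69,-1.72,0.24,1.39,2.66
EDANX03,2.30,-2.43,-0.49,0.89,2.23
EDANX48,3.32,-2.57,-1.59,-0.22,1.28
EDANX09,4.23,-2.42,-1.68,-0.33,1.13
EDANX39,2.37,-2.94,-1.67,-0.23,0.88
EDANX40,2.70,-1.55,0.22,1.57,3.21', stringsAsFactors = FALSE)
}
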