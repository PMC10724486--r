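#' Fisher information of one item
#'
#' \eqn{I_j(\theta) = \sum_k P'_k(\theta)^2 / P_k(\theta)} where
#' \eqn{P'_k} is the theta-derivative of the category probability
#' (boundary derivative \eqn{a P^*(1 - P^*)}, category derivative by
#' differencing). Categories with vanishing probability contribute zero.
#'
#' @param item an [item_params()].
#' @param theta numeric vector of trait values.
#' @return Numeric vector of information values, one per theta.
#' @examples
#' bank <- load_default_bank()
#' item_information(bank[["EDANX05"]], 0)   # ~7.36 (published: 7.33)
#' @export
item_information <- function(item, theta) {
  pd <- category_prob_deriv(item, theta)
  contrib <- pd$dP^2 / pmax(pd$P, 1e-300)
  contrib[pd$P < 1e-300] <- 0
  rowSums(contrib)
}

#' Locate the maximum of an item information curve
#'
#' Exhaustive evaluation on a fixed grid (default step 0.1 on \[-4, 4\],
#' the resolution at which peak locations are conventionally reported);
#' exact ties break toward the smaller theta. Because graded items with
#' high discrimination have multimodal information curves whose peaks can
#' agree to within the precision of two-decimal published parameters, the
#' result also carries the locations of all near-tied local peaks (height
#' within `tie_tol` of the maximum): for such curves the argmax itself is
#' not identifiable from rounded parameters, only the tied set is.
#'
#' @param item an [item_params()].
#' @param grid_step grid resolution (default 0.1).
#' @param range search range (default `c(-4, 4)`).
#' @param tie_tol height difference under which a local peak counts as
#'   tied with the maximum (default 0.02, two units in the last published
#'   decimal).
#' @return List with `max_info`, `theta_at_max`, and `tied_peaks`
#'   (thetas of near-tied local maxima, always including `theta_at_max`).
#' @export
max_information <- function(item, grid_step = 0.1, range = c(-4, 4),
                            tie_tol = 0.02) {
  th <- seq(range[1L], range[2L], by = grid_step)
  v <- item_information(item, th)
  i <- which.max(v)   # first index on exact tie = smaller theta
  # local maxima of the gridded curve (endpoints count)
  up <- c(TRUE, diff(v) >= 0)
  dn <- c(diff(v) <= 0, TRUE)
  loc <- which(up & dn)
  tied <- th[loc[v[loc] >= v[i] - tie_tol]]
  list(max_info = v[i], theta_at_max = th[i],
       tied_peaks = sort(unique(c(th[i], tied))))
}

#' Test information and conditional standard error
#'
#' \eqn{T(\theta) = \sum_j I_j(\theta)} over the bank (no prior term); the
#' conditional standard error of measurement \eqn{1/\sqrt{T(\theta)}} is
#' reported alongside.
#'
#' @param bank an [item_bank()].
#' @param theta numeric vector of trait values.
#' @return Data frame with columns `theta`, `info`, `se`.
#' @examples
#' test_information(load_default_bank(), 0)$info   # ~63.48 (published: 63.427)
#' @export
test_information <- function(bank, theta) {
  stopifnot(inherits(bank, "item_bank"), length(bank) >= 1L)
  info <- rowSums(matrix(vapply(bank$items, function(it) item_information(it, theta),
                                numeric(length(theta))), nrow = length(theta)))
  data.frame(theta = theta, info = info, se = 1 / sqrt(info))
}

#' Operating characteristic curve table for one item
#'
#' Category probabilities of one item on a theta grid, one column per
#' category plus the modal category, in a layout ready for plotting or
#' CSV export.
#'
#' @param item an [item_params()].
#' @param theta numeric vector of trait values (default a 0.1 grid on
#'   \[-4, 4\]).
#' @return Data frame: `theta`, `P1..PK`, `modal`.
#' @export
occ_table <- function(item, theta = seq(-4, 4, by = 0.1)) {
  P <- category_prob(item, theta)
  colnames(P) <- paste0("P", seq_len(ncol(P)))
  data.frame(theta = theta, P, modal = max.col(P, ties.method = "first"))
}

#' EAP trait scores
#'
#' Expected a posteriori estimate of theta per person: posterior mean and
#' SD over the quadrature grid given the person's observed responses
#' (missing items are skipped). Persons with no answered item get `NA`.
#'
#' @param bank a calibrated [item_bank()].
#' @param responses a [response_matrix()].
#' @param grid a [theta_grid()] prior.
#' @return Data frame with `person_id`, `eap_theta`, `posterior_sd`,
#'   `n_answered`.
#' @export
eap_scores <- function(bank, responses, grid = theta_grid()) {
  stopifnot(inherits(responses, "response_matrix"))
  x <- responses$responses
  ll <- person_node_loglik(bank, x, grid$nodes)
  post <- posterior_weights(ll, grid$weights)
  n_ans <- rowSums(!is.na(x))
  eap <- as.vector(post %*% grid$nodes)
  v <- as.vector(post %*% grid$nodes^2) - eap^2
  eap[n_ans == 0L] <- NA_real_
  v[n_ans == 0L] <- NA_real_
  data.frame(person_id = rownames(x), eap_theta = eap,
             posterior_sd = sqrt(pmax(v, 0)), n_answered = n_ans,
             stringsAsFactors = FALSE)
}

#' Per-item information summary table
#'
#' For every item: the maximum information with its theta location (on the
#' reporting grid), and the information at theta = 0 (a medium trait
#' level). Also counts the items whose maximum information exceeds
#' `high_info`, with the theta window those maxima span.
#'
#' @param bank an [item_bank()].
#' @param grid_step,range,tie_tol passed to [max_information()].
#' @param high_info threshold defining a highly informative item
#'   (default 3.0).
#' @return Data frame (class `information_summary`) with columns
#'   `item_id`, `max_info`, `theta_at_max`, `n_tied_peaks`, `info_at_zero`;
#'   attributes `n_high` and `high_theta_window`.
#' @export
information_summary <- function(bank, grid_step = 0.1, range = c(-4, 4),
                                tie_tol = 0.02, high_info = 3.0) {
  stopifnot(inherits(bank, "item_bank"))
  if (length(bank) == 0L) stop("empty bank", call. = FALSE)
  rows <- lapply(bank$items, function(it) {
    mi <- max_information(it, grid_step, range, tie_tol)
    data.frame(item_id = it$item_id, max_info = mi$max_info,
               theta_at_max = mi$theta_at_max,
               n_tied_peaks = length(mi$tied_peaks),
               info_at_zero = item_information(it, 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  high <- out$max_info > high_info
  attr(out, "n_high") <- sum(high)
  attr(out, "high_theta_window") <-
    if (any(high)) range(out$theta_at_max[high]) else c(NA_real_, NA_real_)
  attr(out, "tied_peaks") <- lapply(bank$items, function(it)
    max_information(it, grid_step, range, tie_tol)$tied_peaks)
  class(out) <- c("information_summary", "data.frame")
  out
}
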