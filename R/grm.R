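#' Quadrature grid over the latent trait
#'
#' Equally spaced nodes with renormalized normal prior masses, used as the
#' fixed N(mean, sd^2) prior in marginal-maximum-likelihood estimation and
#' EAP scoring. A dense rectangular grid is robust for the heavy-tailed
#' posteriors that high-discrimination items produce, and doubles as the
#' evaluation grid for curve tables.
#'
#' @param n number of nodes (default 61).
#' @param range theta range covered (default `c(-6, 6)`).
#' @param mean,sd prior mean and standard deviation (defaults 0, 1: the
#'   standard identification of the trait metric).
#' @return Object of class `theta_grid`: list with strictly increasing
#'   `nodes` and `weights` summing to one.
#' @export
theta_grid <- function(n = 61L, range = c(-6, 6), mean = 0, sd = 1) {
  stopifnot(n >= 3L, range[2L] > range[1L], sd > 0)
  nodes <- seq(range[1L], range[2L], length.out = n)
  w <- stats::dnorm(nodes, mean, sd)
  structure(list(nodes = nodes, weights = w / sum(w)), class = "theta_grid")
}

#' @export
print.theta_grid <- function(x, ...) {
  cat(sprintf("<theta_grid> %d nodes on [%.2f, %.2f]\n",
              length(x$nodes), min(x$nodes), max(x$nodes)))
  invisible(x)
}

#' GRM boundary (cumulative) probabilities
#'
#' \eqn{P^*_k(\theta) = P(X > k \mid \theta) = 1/(1 + e^{-a(\theta - b_k)})}
#' for k = 1..K-1, on the logistic metric with scaling constant D = 1.
#' Threshold ordering implies \eqn{P^*_1 \ge \dots \ge P^*_{K-1}} at every
#' theta.
#'
#' @param item an [item_params()] (or any list with elements `a`, `b`).
#' @param theta numeric vector of trait values.
#' @return `length(theta)` x `K-1` matrix of boundary probabilities.
#' @export
boundary_prob <- function(item, theta) {
  stats::plogis(item$a * outer(theta, item$b, "-"))
}

#' GRM category probabilities
#'
#' Adjacent differences of the boundary probabilities:
#' \eqn{P_1 = 1 - P^*_1}, \eqn{P_k = P^*_{k-1} - P^*_k},
#' \eqn{P_K = P^*_{K-1}}. Rows are nonnegative and sum to one.
#'
#' @inheritParams boundary_prob
#' @return `length(theta)` x `K` matrix of category probabilities.
#' @export
category_prob <- function(item, theta) {
  Ps <- boundary_prob(item, theta)
  cbind(1, Ps) - cbind(Ps, 0)
}

# category probabilities and their theta-derivatives in one pass
category_prob_deriv <- function(item, theta) {
  Ps <- boundary_prob(item, theta)
  dPs <- item$a * Ps * (1 - Ps)
  list(P = cbind(1, Ps) - cbind(Ps, 0),
       dP = cbind(0, dPs) - cbind(dPs, 0))
}

# log category-probability table for every item: list of K x Q matrices
log_prob_tables <- function(bank, nodes, floor = 1e-300) {
  lapply(bank$items, function(it)
    t(log(pmax(category_prob(it, nodes), floor))))
}

#' Marginal log-likelihood of a response matrix under a bank
#'
#' \eqn{\sum_i \log \sum_q w_q \prod_{j \in obs(i)} P_{x_{ij}}(\theta_q)},
#' computed in log space (missing responses are skipped, never imputed).
#'
#' @param bank an [item_bank()].
#' @param responses a [response_matrix()] coded `1..K`.
#' @param grid a [theta_grid()] prior.
#' @return The marginal log-likelihood (scalar).
#' @export
grm_loglik <- function(bank, responses, grid = theta_grid()) {
  stopifnot(inherits(bank, "item_bank"), inherits(responses, "response_matrix"))
  ll <- person_node_loglik(bank, responses$responses, grid$nodes)
  sum(log_weighted_rowsums(ll, grid$weights))
}

# n x Q matrix of log P(response pattern_i | theta_q)
person_node_loglik <- function(bank, x, nodes) {
  n <- nrow(x); Q <- length(nodes)
  ids <- item_ids(bank)
  stopifnot(all(colnames(x) %in% ids) || ncol(x) == length(ids))
  cols <- if (all(colnames(x) %in% ids)) match(colnames(x), ids) else seq_len(ncol(x))
  tabs <- log_prob_tables(bank, nodes)
  ll <- matrix(0, n, Q)
  for (j in seq_len(ncol(x))) {
    xi <- x[, j]
    obs <- !is.na(xi)
    if (any(obs)) ll[obs, ] <- ll[obs, ] + tabs[[cols[j]]][xi[obs], , drop = FALSE]
  }
  ll
}

# log(sum_q w_q exp(ll_iq)) per row, underflow-safe
log_weighted_rowsums <- function(ll, w) {
  m <- apply(ll, 1L, max)
  m + log(as.vector(exp(ll - m) %*% w))
}

# posterior node weights per person (rows sum to 1)
posterior_weights <- function(ll, w) {
  m <- apply(ll, 1L, max)
  p <- exp(ll - m) * rep(w, each = nrow(ll))
  p / rowSums(p)
}

# ---- M-step machinery -------------------------------------------------------

# expected complete-data log-likelihood for one item and its gradient.
# par = c(a, d_1..d_{K-1}) in slope/intercept form z_k = a*theta + d_k,
# d decreasing <=> b = -d/a increasing. r is a K x Q expected-count table.
item_obj <- function(par, nodes, r, eps = 1e-10) {
  a <- par[1L]; d <- par[-1L]
  z <- outer(nodes, d, function(th, dk) a * th + dk)   # Q x (K-1)
  Ps <- stats::plogis(z)
  P <- pmax(cbind(1, Ps) - cbind(Ps, 0), eps)          # Q x K
  sum(t(r) * log(P))
}

item_grad <- function(par, nodes, r, eps = 1e-10) {
  a <- par[1L]; d <- par[-1L]
  z <- outer(nodes, d, function(th, dk) a * th + dk)
  Ps <- stats::plogis(z)
  w <- Ps * (1 - Ps)
  P <- pmax(cbind(1, Ps) - cbind(Ps, 0), eps)
  A <- t(r) / P                                        # Q x K
  dif <- A[, -1L, drop = FALSE] - A[, -ncol(A), drop = FALSE]  # Q x (K-1)
  g_d <- colSums(w * dif)
  g_a <- sum(nodes * rowSums(w * dif))
  c(g_a, g_d)
}

# one-item M-step: Newton with finite-difference Hessian of the analytic
# gradient and step-halving; keeps d strictly decreasing (ordered b).
mstep_item <- function(par, nodes, r, max_iter = 25L, tol = 1e-7) {
  f <- item_obj(par, nodes, r)
  for (iter in seq_len(max_iter)) {
    g <- item_grad(par, nodes, r)
    if (max(abs(g)) < tol) break
    p <- length(par)
    H <- matrix(0, p, p)
    h <- pmax(abs(par), 1) * 1e-6
    for (k in seq_len(p)) {
      pk <- par; pk[k] <- pk[k] + h[k]
      H[, k] <- (item_grad(pk, nodes, r) - g) / h[k]
    }
    H <- (H + t(H)) / 2
    step <- tryCatch(-solve(H, g), error = function(e) g)
    if (sum(step * g) <= 0) step <- g      # ensure ascent direction
    ok <- FALSE
    for (half in 0:12) {
      cand <- par + step / 2^half
      if (cand[1L] <= 0) next               # a must stay positive
      if (length(cand) > 2L && any(diff(cand[-1L]) >= 0)) next  # keep b ordered
      fc <- item_obj(cand, nodes, r)
      if (fc >= f - 1e-12) { par <- cand; f <- fc; ok <- TRUE; break }
    }
    if (!ok) break
  }
  par
}

# collapse categories never observed for an item; returns remapped codes
# (contiguous 1..K_j) plus the remap log
collapse_empty_categories <- function(x, K) {
  remap <- list()
  for (j in seq_len(ncol(x))) {
    seen <- sort(unique(x[!is.na(x[, j]), j]))
    if (length(seen) < K) {
      map <- match(x[, j], seen)   # empty categories merge with the next
      remap[[colnames(x)[j]]] <- list(observed = seen, K_j = length(seen))
      x[, j] <- map
    }
  }
  list(x = x, remap = remap)
}

#' Calibrate a graded response model by MML-EM
#'
#' Marginal maximum likelihood over a fixed N(0,1) quadrature prior.
#' E-step: posterior node weights per person; M-step: per-item Newton
#' maximization of the expected complete-data log-likelihood in
#' slope/intercept form (\eqn{a\theta + d_k}, \eqn{d_k = -a b_k}), with
#' step-halving and threshold-order preservation. Missing responses are
#' omitted from the likelihood. Categories with no observations are
#' collapsed with their neighbour before fitting (logged in the result).
#'
#' @param responses a [response_matrix()].
#' @param grid a [theta_grid()] prior (default 61 nodes on \[-6, 6\]).
#' @param tol EM convergence tolerance on the maximum absolute parameter
#'   change per cycle (default 1e-4).
#' @param max_cycles maximum EM cycles (default 500).
#' @param newton_iter inner Newton iterations per item and cycle.
#' @param se if `TRUE`, compute standard errors from the empirical
#'   cross-product of per-person score contributions.
#' @param a_cap discriminations diverging past this cap are held at the
#'   cap and the item flagged (Heywood-like divergence guard).
#' @param min_n minimum number of persons accepted (default 100); tiny
#'   samples cannot support 5-category item calibration.
#' @param verbose print per-cycle log-likelihood.
#' @return Object of class `grm_fit`: `bank` (estimated [item_bank()]),
#'   `loglik`, `trace` (per-cycle marginal log-likelihood, non-decreasing),
#'   `n_cycles`, `converged`, `se`, `flagged` (capped items), `collapsed`
#'   (category remap log), `settings`.
#' @export
fit_grm <- function(responses, grid = theta_grid(), tol = 1e-4,
                    max_cycles = 500L, newton_iter = 25L, se = FALSE,
                    a_cap = 50, min_n = 100L, verbose = FALSE) {
  stopifnot(inherits(responses, "response_matrix"), inherits(grid, "theta_grid"))
  x <- responses$responses
  K <- responses$K
  if (nrow(x) < min_n)
    stop("calibration needs at least ", min_n, " persons (got ", nrow(x),
         "); collect more data or lower min_n deliberately", call. = FALSE)
  cc <- collapse_empty_categories(x, K)
  x <- cc$x
  Kj <- vapply(seq_len(ncol(x)), function(j)
    max(x[!is.na(x[, j]), j]), integer(1L))
  nodes <- grid$nodes; w <- grid$weights
  J <- ncol(x); n <- nrow(x)

  # start values: a = 1, d_k = logit of marginal P(X > k)
  par <- lapply(seq_len(J), function(j) {
    xi <- x[!is.na(x[, j]), j]
    pgt <- vapply(seq_len(Kj[j] - 1L), function(k) mean(xi > k), numeric(1L))
    pgt <- pmin(pmax(pgt, 1 / (length(xi) + 1)), 1 - 1 / (length(xi) + 1))
    c(1, stats::qlogis(pgt))
  })

  trace <- numeric(0)
  flagged <- character(0)
  converged <- FALSE
  xfac <- lapply(seq_len(J), function(j) factor(x[, j], levels = seq_len(Kj[j])))

  for (cycle in seq_len(max_cycles)) {
    # E-step
    ll <- matrix(0, n, length(nodes))
    for (j in seq_len(J)) {
      a <- par[[j]][1L]; d <- par[[j]][-1L]
      Ps <- stats::plogis(outer(nodes, d, function(th, dk) a * th + dk))
      logP <- t(log(pmax(cbind(1, Ps) - cbind(Ps, 0), 1e-300)))  # K_j x Q
      xi <- x[, j]; obs <- !is.na(xi)
      ll[obs, ] <- ll[obs, ] + logP[xi[obs], , drop = FALSE]
    }
    trace <- c(trace, sum(log_weighted_rowsums(ll, w)))
    if (verbose) message(sprintf("cycle %3d  loglik %.4f", cycle, trace[cycle]))
    post <- posterior_weights(ll, w)

    # M-step
    old <- par
    for (j in seq_len(J)) {
      obs <- !is.na(x[, j])
      r <- rowsum(post[obs, , drop = FALSE], xfac[[j]][obs])   # K_j x Q
      r[is.na(r)] <- 0
      pj <- mstep_item(par[[j]], nodes, r, max_iter = newton_iter)
      if (pj[1L] > a_cap) {
        pj[1L] <- a_cap
        flagged <- union(flagged, colnames(x)[j])
      }
      par[[j]] <- pj
    }
    delta <- max(vapply(seq_len(J), function(j)
      max(abs(par_to_ab(par[[j]]) - par_to_ab(old[[j]]))), numeric(1L)))
    if (delta < tol) { converged <- TRUE; break }
  }

  items <- lapply(seq_len(J), function(j) {
    ab <- par_to_ab(par[[j]])
    item_params(colnames(x)[j], ab[1L], sort(ab[-1L]))
  })
  bank <- if (all(Kj == K)) item_bank(items, K = K, metric = "logistic, D=1")
          else structure(list(items = items, K = K, metric = "logistic, D=1"),
                         class = "item_bank", collapsed = TRUE)
  fit <- structure(list(
    bank = bank, loglik = trace[length(trace)], trace = trace,
    n_cycles = length(trace), converged = converged,
    se = NULL, flagged = flagged,
    collapsed = if (length(cc$remap)) cc$remap else NULL,
    n_persons = n,
    settings = list(quadrature = length(nodes), range = range(nodes),
                    tol = tol, max_cycles = max_cycles,
                    newton_iter = newton_iter, a_cap = a_cap)),
    class = "grm_fit")
  if (!converged)
    warning("EM did not converge in ", max_cycles, " cycles (last max change ",
            signif(delta, 3), ")", call. = FALSE)
  if (se) fit$se <- grm_se(fit, x, grid)
  fit
}

par_to_ab <- function(par) c(par[1L], -par[-1L] / par[1L])

#' @export
print.grm_fit <- function(x, ...) {
  cat(sprintf("<grm_fit> %d items, %d persons, loglik %.2f, %d EM cycles (%s)\n",
              length(x$bank), x$n_persons, x$loglik, x$n_cycles,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# standard errors from the empirical cross-product of per-person analytic
# score contributions (outer-product-of-gradients information)
grm_se <- function(fit, x, grid) {
  bank <- fit$bank
  nodes <- grid$nodes; w <- grid$weights
  ll <- person_node_loglik(bank, x, nodes)
  post <- posterior_weights(ll, w)
  n <- nrow(x)
  scores <- NULL
  nms <- character(0)
  for (j in seq_len(length(bank))) {
    it <- bank[[j]]
    a <- it$a; b <- it$b; d <- -a * b
    z <- outer(nodes, d, function(th, dk) a * th + dk)
    Ps <- stats::plogis(z); wk <- Ps * (1 - Ps)
    P <- pmax(cbind(1, Ps) - cbind(Ps, 0), 1e-12)
    # d logP_k / d a and / d d_m at each node
    dPda <- (cbind(0, nodes * wk) - cbind(nodes * wk, 0)) / P   # Q x K
    xi <- x[, j]; obs <- !is.na(xi)
    sc_a <- numeric(n)
    sc_a[obs] <- rowSums(post[obs, , drop = FALSE] * t(dPda)[xi[obs], , drop = FALSE])
    block <- matrix(0, n, 1L + length(d))
    block[, 1L] <- sc_a
    for (m in seq_along(d)) {
      dPdm <- matrix(0, length(nodes), ncol(P))
      dPdm[, m] <- -wk[, m]; dPdm[, m + 1L] <- wk[, m]
      dPdm <- dPdm / P
      block[obs, m + 1L] <- rowSums(post[obs, , drop = FALSE] *
                                    t(dPdm)[xi[obs], , drop = FALSE])
    }
    scores <- cbind(scores, block)
    nms <- c(nms, paste0(it$item_id, c("_a", paste0("_d", seq_along(d)))))
  }
  colnames(scores) <- nms
  info <- crossprod(scores)
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) {
    warning("score cross-product information is singular; SEs unavailable",
            call. = FALSE)
    rep(NA_real_, ncol(scores))
  })
  stats::setNames(se, nms)
}

#' Screen calibrated items against bank-quality rules
#'
#' Applies the three published screening rules: an item is adequately
#' discriminating when a > 0.50; thresholds are in range when every
#' |b| < 10; and adjacent-threshold intervals (b2-b1, b3-b2, b4-b3) should
#' fall in \[0.81, 5\] for the response categories to be well separated.
#' Intervals are exact differences of the stored thresholds.
#'
#' @param bank an [item_bank()].
#' @param a_min minimum acceptable discrimination (default 0.50).
#' @param b_abs_max maximum acceptable |threshold| (default 10).
#' @param interval_range acceptable adjacent-threshold interval (default
#'   `c(0.81, 5)`).
#' @return A data frame (class `screening_report`) with per-item columns
#'   `a_ok`, `b_ok`, one column per interval, `interval_ok`, and
#'   `flagged_intervals`.
#' @export
screen_items <- function(bank, a_min = 0.5, b_abs_max = 10,
                         interval_range = c(0.81, 5)) {
  stopifnot(inherits(bank, "item_bank"))
  rows <- lapply(bank$items, function(it) {
    ints <- diff(it$b)
    names(ints) <- paste0("b", seq_along(ints) + 1L, "_b", seq_along(ints))
    ok <- ints >= interval_range[1L] & ints <= interval_range[2L]
    data.frame(item_id = it$item_id, a = it$a,
               a_ok = it$a > a_min,
               b_ok = all(abs(it$b) < b_abs_max),
               t(ints),
               interval_ok = all(ok),
               flagged_intervals = paste(names(ints)[!ok], collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "rules") <- list(a_min = a_min, b_abs_max = b_abs_max,
                             interval_range = interval_range)
  class(out) <- c("screening_report", "data.frame")
  out
}
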