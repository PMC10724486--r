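# ---- limited-information model fit ------------------------------------------
# M2-family statistic on univariate first moments and bivariate product
# moments of the ordinal responses: e = s - sigma(theta_hat), with
# M2 = n e' C e, C = Xi^-1 - Xi^-1 D (D' Xi^-1 D)^-1 D' Xi^-1, where Xi is
# the asymptotic covariance of the sample moments under the fitted model
# and D the Jacobian of the model moments in the item parameters.
# CFI/TLI are computed against the zero-association (independence) model
# evaluated on the same moment set.

# indexing of the moment vector: J univariate means, then pairs (j < k)
moment_index <- function(J) {
  pairs <- which(upper.tri(matrix(0, J, J)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  list(J = J, pairs = pairs, m = J + nrow(pairs))
}

# sample moments from a complete response matrix (codes 1..K)
sample_moments <- function(x, idx) {
  mu1 <- colMeans(x)
  prod_mat <- crossprod(x) / nrow(x)
  c(mu1, prod_mat[idx$pairs])
}

# per-node conditional moments of each item: E[X|theta], E[X^2|theta]
conditional_moments <- function(bank, nodes) {
  K <- bank$K
  M1 <- t(vapply(bank$items, function(it)
    as.vector(category_prob(it, nodes) %*% seq_len(K)), numeric(length(nodes))))
  M2 <- t(vapply(bank$items, function(it)
    as.vector(category_prob(it, nodes) %*% (seq_len(K)^2)), numeric(length(nodes))))
  list(M1 = M1, M2 = M2)
}

# model-implied moment vector
model_moments <- function(cm, w, idx) {
  mu1 <- as.vector(cm$M1 %*% w)
  mu2 <- vapply(seq_len(nrow(idx$pairs)), function(r)
    sum(w * cm$M1[idx$pairs[r, 1L], ] * cm$M1[idx$pairs[r, 2L], ]), numeric(1L))
  c(mu1, mu2)
}

# asymptotic covariance of the sample moments under the model
moment_covariance <- function(cm, w, idx) {
  J <- idx$J; P <- nrow(idx$pairs)
  # per-node value of each statistic (assuming distinct items)
  V <- rbind(cm$M1,
             cm$M1[idx$pairs[, 1L], , drop = FALSE] *
               cm$M1[idx$pairs[, 2L], , drop = FALSE])
  mu <- as.vector(V %*% w)
  Xi <- V %*% (w * t(V))
  # correct entries whose statistics share an item: the shared item's
  # conditional moment enters at order two
  ratio <- cm$M2 / cm$M1^2        # J x Q
  # univariate diagonal: E[X_j^2]
  for (j in seq_len(J)) Xi[j, j] <- sum(w * cm$M2[j, ])
  # univariate j x pair (j,k)
  for (r in seq_len(P)) {
    j <- idx$pairs[r, 1L]; k <- idx$pairs[r, 2L]; a <- J + r
    Xi[j, a] <- Xi[a, j] <- sum(w * cm$M2[j, ] * cm$M1[k, ])
    Xi[k, a] <- Xi[a, k] <- sum(w * cm$M1[j, ] * cm$M2[k, ])
  }
  # pair x pair with shared items
  pair_of <- lapply(seq_len(J), function(j)
    which(idx$pairs[, 1L] == j | idx$pairs[, 2L] == j))
  for (r in seq_len(P)) {
    jr <- idx$pairs[r, ]
    cand <- unique(c(pair_of[[jr[1L]]], pair_of[[jr[2L]]]))
    cand <- cand[cand >= r]
    for (s2 in cand) {
      js <- idx$pairs[s2, ]
      shared <- intersect(jr, js)
      val <- w * V[J + r, ] * V[J + s2, ]
      for (j in shared) val <- val * ratio[j, ]
      Xi[J + r, J + s2] <- Xi[J + s2, J + r] <- sum(val)
    }
  }
  list(Xi = Xi - tcrossprod(mu), mu = mu)
}

# Jacobian of the model moments in the item parameters (forward differences);
# each parameter touches only its own item's conditional mean
moment_jacobian <- function(bank, nodes, w, idx, h = 1e-5) {
  cm <- conditional_moments(bank, nodes)
  mu0 <- model_moments(cm, w, idx)
  J <- idx$J
  pair_of <- lapply(seq_len(J), function(j)
    which(idx$pairs[, 1L] == j | idx$pairs[, 2L] == j))
  cols <- list()
  for (j in seq_len(J)) {
    it <- bank[[j]]
    for (p in seq_len(1L + length(it$b))) {
      it2 <- it
      if (p == 1L) it2$a <- it2$a + h else it2$b[p - 1L] <- it2$b[p - 1L] + h
      m1j <- as.vector(category_prob(it2, nodes) %*% seq_len(bank$K))
      col <- numeric(idx$m)
      col[j] <- (sum(w * m1j) - mu0[j]) / h
      for (r in pair_of[[j]]) {
        other <- setdiff(idx$pairs[r, ], j)
        col[J + r] <- (sum(w * m1j * cm$M1[other, ]) - mu0[J + r]) / h
      }
      cols[[length(cols) + 1L]] <- col
    }
  }
  do.call(cbind, cols)
}

# orthogonal-complement form of the weight matrix,
# C = U (U' Xi U)^-1 U' with span(U) = null(D'): numerically stable even
# when D is badly scaled
m2_quadform <- function(e, Xi, D, n) {
  qrD <- qr(D)
  U <- qr.Q(qrD, complete = TRUE)[, -seq_len(qrD$rank), drop = FALSE]
  u <- crossprod(U, e)
  as.numeric(n * t(u) %*% solve(crossprod(U, Xi %*% U), u))
}

#' Limited-information fit indices for a calibrated GRM
#'
#' An M2-type statistic on the univariate means and bivariate product
#' moments of the responses, with RMSEA
#' \eqn{\sqrt{\max(M_2 - df, 0) / (df (n - 1))}} and CFI/TLI computed
#' against the zero-association (independence) model on the same moment
#' set. Rows with missing responses are dropped listwise.
#'
#' @param responses a [response_matrix()].
#' @param fit a [fit_grm()] result (or an [item_bank()] treated as the
#'   fitted model).
#' @param grid a [theta_grid()].
#' @return List of class `fit_indices`: `M2`, `df`, `p`, `rmsea`, `cfi`,
#'   `tli`, `M2_independence`, `df_independence`, `n`. TLI may exceed 1
#'   for a well-fitting model and is reported unclipped.
#' @export
fit_indices <- function(responses, fit, grid = theta_grid()) {
  bank <- if (inherits(fit, "grm_fit")) fit$bank else fit
  stopifnot(inherits(bank, "item_bank"))
  x <- resp_complete_matrix(responses)
  n <- nrow(x)
  J <- ncol(x)
  K <- bank$K
  idx <- moment_index(J)
  n_par <- sum(vapply(bank$items, function(it) 1L + length(it$b), integer(1L)))
  df <- idx$m - n_par
  if (df <= 0) stop("no positive degrees of freedom for the moment set", call. = FALSE)
  cellcounts <- apply(x, 2L, tabulate, nbins = K)
  if (any(cellcounts == 0))
    warning("some categories unobserved; bivariate moments may be unstable",
            call. = FALSE)

  s <- sample_moments(x, idx)
  w <- grid$weights; nodes <- grid$nodes
  cm <- conditional_moments(bank, nodes)
  sigma <- model_moments(cm, w, idx)
  Xi <- moment_covariance(cm, w, idx)$Xi
  D <- moment_jacobian(bank, nodes, w, idx)
  M2 <- m2_quadform(s - sigma, Xi, D, n)
  p <- stats::pchisq(M2, df, lower.tail = FALSE)
  rmsea <- sqrt(max(M2 - df, 0) / (df * (n - 1)))

  # independence model: free univariate margins, zero association;
  # its MLE is the observed margins, so its univariate residuals vanish
  pi_hat <- sweep(cellcounts, 2L, colSums(cellcounts), "/")   # K x J
  mu1_0 <- as.vector(seq_len(K) %*% pi_hat)
  mu2_raw <- as.vector((seq_len(K)^2) %*% pi_hat)
  sigma0 <- c(mu1_0, mu1_0[idx$pairs[, 1L]] * mu1_0[idx$pairs[, 2L]])
  Xi0 <- indep_moment_covariance(mu1_0, mu2_raw, idx)
  D0 <- indep_moment_jacobian(pi_hat, idx)
  M2_0 <- m2_quadform(s - sigma0, Xi0, D0, n)
  df_0 <- idx$m - J
  num <- max(M2 - df, 0)
  den <- max(M2_0 - df_0, M2 - df, 0)
  cfi <- if (den > 0) 1 - num / den else 1
  tli_den <- M2_0 / df_0 - 1
  tli <- if (tli_den > 0) (M2_0 / df_0 - M2 / df) / tli_den else 1
  structure(list(M2 = M2, df = df, p = p, rmsea = rmsea, cfi = cfi, tli = tli,
                 M2_independence = M2_0, df_independence = df_0, n = n),
            class = "fit_indices")
}

indep_moment_covariance <- function(mu1, mu2raw, idx) {
  J <- idx$J; P <- nrow(idx$pairs)
  V <- c(mu1, mu1[idx$pairs[, 1L]] * mu1[idx$pairs[, 2L]])
  Xi <- tcrossprod(V)    # then overwrite shared-item entries
  for (j in seq_len(J)) Xi[j, j] <- mu2raw[j]
  ratio <- mu2raw / mu1^2
  for (r in seq_len(P)) {
    j <- idx$pairs[r, 1L]; k <- idx$pairs[r, 2L]; a <- J + r
    Xi[j, a] <- Xi[a, j] <- mu2raw[j] * mu1[k]
    Xi[k, a] <- Xi[a, k] <- mu1[j] * mu2raw[k]
  }
  pair_of <- lapply(seq_len(J), function(j)
    which(idx$pairs[, 1L] == j | idx$pairs[, 2L] == j))
  for (r in seq_len(P)) {
    jr <- idx$pairs[r, ]
    cand <- unique(c(pair_of[[jr[1L]]], pair_of[[jr[2L]]]))
    cand <- cand[cand >= r]
    for (s2 in cand) {
      js <- idx$pairs[s2, ]
      shared <- intersect(jr, js)
      val <- V[J + r] * V[J + s2]
      for (j in shared) val <- val * ratio[j]
      Xi[J + r, J + s2] <- Xi[J + s2, J + r] <- val
    }
  }
  Xi - tcrossprod(V)
}

# Jacobian of independence-model moments in its free parameters. On this
# moment set the zero-association model is identified through the J item
# means only (all margin configurations with equal means give identical
# moments), so the null model has J parameters.
indep_moment_jacobian <- function(pi_hat, idx) {
  J <- idx$J; K <- nrow(pi_hat)
  mu1 <- as.vector(seq_len(K) %*% pi_hat)
  pair_of <- lapply(seq_len(J), function(j)
    which(idx$pairs[, 1L] == j | idx$pairs[, 2L] == j))
  cols <- list()
  for (j in seq_len(J)) {
    col <- numeric(idx$m)
    col[j] <- 1
    for (r in pair_of[[j]]) {
      other <- setdiff(idx$pairs[r, ], j)
      col[J + r] <- mu1[other]
    }
    cols[[length(cols) + 1L]] <- col
  }
  do.call(cbind, cols)
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("M2(%d) = %.2f, p = %.3g | RMSEA = %.3f, CFI = %.3f, TLI = %.3f (n = %d)\n",
              x$df, x$M2, x$p, x$rmsea, x$cfi, x$tli, x$n))
  invisible(x)
}
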