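# ---- proportional-odds core -------------------------------------------------
# P(Y <= k | x) = plogis(zeta_k - x'beta). Newton iterations with
# step-halving on the log-likelihood, convergence 1e-8; cutpoints kept
# ordered. Small well-conditioned models only (a matching variable, a
# binary group, their interaction).

polr_loglik <- function(zeta, beta, X, y, K) {
  eta <- if (length(beta)) as.vector(X %*% beta) else numeric(nrow(X))
  zu <- c(zeta, Inf)[y] - eta
  zl <- c(-Inf, zeta)[y] - eta
  sum(log(pmax(stats::plogis(zu) - stats::plogis(zl), 1e-300)))
}

polr_grad <- function(zeta, beta, X, y, K) {
  eta <- if (length(beta)) as.vector(X %*% beta) else numeric(nrow(X))
  u <- stats::plogis(c(zeta, Inf)[y] - eta)
  l <- stats::plogis(c(-Inf, zeta)[y] - eta)
  p <- pmax(u - l, 1e-300)
  fu <- u * (1 - u); fl <- l * (1 - l)
  gz <- numeric(K - 1L)
  for (m in seq_len(K - 1L)) {
    gz[m] <- sum(fu[y == m] / p[y == m]) - sum(fl[y == m + 1L] / p[y == m + 1L])
  }
  gb <- if (length(beta)) -as.vector(crossprod(X, (fu - fl) / p)) else numeric(0)
  c(gz, gb)
}

# y in 1..K (all categories observed), X a numeric matrix (may have 0 cols)
fit_polr <- function(X, y, K, tol = 1e-8, max_iter = 50L) {
  n <- length(y)
  cum <- cumsum(tabulate(y, K))[seq_len(K - 1L)] / n
  zeta <- stats::qlogis(pmin(pmax(cum, 1 / (n + 1)), 1 - 1 / (n + 1)))
  beta <- numeric(ncol(X))
  par <- c(zeta, beta)
  nz <- K - 1L
  ll <- polr_loglik(zeta, beta, X, y, K)
  conv <- FALSE
  for (iter in seq_len(max_iter)) {
    g <- polr_grad(par[seq_len(nz)], par[-seq_len(nz)], X, y, K)
    h <- pmax(abs(par), 1) * 1e-6
    H <- matrix(0, length(par), length(par))
    for (k in seq_along(par)) {
      pk <- par; pk[k] <- pk[k] + h[k]
      H[, k] <- (polr_grad(pk[seq_len(nz)], pk[-seq_len(nz)], X, y, K) - g) / h[k]
    }
    H <- (H + t(H)) / 2
    step <- tryCatch(-solve(H, g), error = function(e) g)
    if (sum(step * g) <= 0) step <- g
    improved <- FALSE
    for (half in 0:15) {
      cand <- par + step / 2^half
      if (nz > 1L && any(diff(cand[seq_len(nz)]) <= 0)) next
      llc <- polr_loglik(cand[seq_len(nz)], cand[-seq_len(nz)], X, y, K)
      if (llc >= ll - 1e-12) {
        improved <- llc > ll
        delta <- llc - ll
        par <- cand; ll <- llc
        if (delta < tol) conv <- TRUE
        break
      }
    }
    if (conv || !improved) { conv <- conv || !improved; break }
  }
  list(zeta = par[seq_len(nz)], beta = par[-seq_len(nz)], loglik = ll,
       converged = conv, n = n)
}

# intercept-only proportional-odds log-likelihood has a closed form
polr_null_loglik <- function(y, K) {
  cnt <- tabulate(y, K)
  sum(cnt[cnt > 0] * log(cnt[cnt > 0] / length(y)))
}

# ---- DIF analysis -----------------------------------------------------------

#' Differential item functioning by ordinal logistic regression
#'
#' For each item, three nested proportional-odds models of the item
#' response are fitted: M0 (matching variable only), M1 (+ group main
#' effect), M2 (+ matching x group interaction). Uniform DIF is the
#' likelihood-ratio test of M1 vs M0 (df 1), non-uniform DIF of M2 vs M1
#' (df 1). Effect size is the change in McFadden's pseudo-R2
#' (\eqn{R^2 = 1 - \ln L / \ln L_0}); DIF is treated as negligible when
#' both changes and their sum stay below `r2_threshold`. The matching
#' variable is the standardized rest score by default (total minus the
#' studied item, avoiding circularity without requiring a calibration);
#' EAP theta matching is available when a bank is supplied.
#'
#' @param responses a [response_matrix()].
#' @param group name of a binary covariate column of `responses`, or a
#'   vector of two levels (one per person).
#' @param matching `"rest"` or `"eap"`.
#' @param bank an [item_bank()], required for `matching = "eap"`.
#' @param alpha significance level for the LR flags (default 0.05, no
#'   multiplicity correction: flags and effect sizes are reported as the
#'   two tiers of evidence).
#' @param r2_threshold practical-salience gate on McFadden delta-R2
#'   (default 0.02).
#' @param min_group warn when either group has fewer persons than this
#'   (default 50).
#' @param items optional character vector restricting the analysis to
#'   these studied items (the matching rest score still uses the full
#'   response matrix).
#' @return Data frame of class `dif_result`, one row per item:
#'   LR statistics and p-values for uniform/non-uniform DIF, the two
#'   delta-R2 values, `flag_uniform`, `flag_nonuniform`, `negligible`,
#'   `converged`.
#' @export
dif_olr <- function(responses, group, matching = c("rest", "eap"),
                    bank = NULL, alpha = 0.05, r2_threshold = 0.02,
                    min_group = 50L, items = NULL) {
  matching <- match.arg(matching)
  stopifnot(inherits(responses, "response_matrix"))
  g <- if (is.character(group) && length(group) == 1L) {
    if (is.null(responses$covariates) || !group %in% names(responses$covariates))
      stop("no covariate column '", group, "'", call. = FALSE)
    responses$covariates[[group]]
  } else group
  x <- responses$responses
  keep <- stats::complete.cases(x) & !is.na(g)
  x <- x[keep, , drop = FALSE]
  g <- factor(g[keep])
  if (nlevels(g) < 2L) stop("grouping variable is constant", call. = FALSE)
  if (nlevels(g) > 2L) stop("grouping variable must be binary", call. = FALSE)
  if (min(table(g)) < min_group)
    warning("smallest group has ", min(table(g)), " persons (< ", min_group, ")",
            call. = FALSE)
  g01 <- as.numeric(g) - 1
  if (matching == "eap") {
    if (is.null(bank)) stop("matching = 'eap' needs a bank", call. = FALSE)
    m_all <- eap_scores(bank, response_matrix(x, K = responses$K))$eap_theta
  }
  total <- rowSums(x)
  studied <- if (is.null(items)) seq_len(ncol(x)) else {
    stopifnot(all(items %in% colnames(x)))
    match(items, colnames(x))
  }
  rows <- lapply(studied, function(j) {
    y0 <- x[, j]
    lev <- sort(unique(y0))
    y <- match(y0, lev)               # contiguous categories for this item
    Kj <- length(lev)
    m <- if (matching == "eap") m_all else as.vector(scale(total - y0))
    f0 <- fit_polr(cbind(m), y, Kj)
    f1 <- fit_polr(cbind(m, g01), y, Kj)
    f2 <- fit_polr(cbind(m, g01, m * g01), y, Kj)
    l_null <- polr_null_loglik(y, Kj)
    r2 <- function(f) 1 - f$loglik / l_null
    lr_u <- max(2 * (f1$loglik - f0$loglik), 0)
    lr_n <- max(2 * (f2$loglik - f1$loglik), 0)
    d_u <- max(r2(f1) - r2(f0), 0)
    d_n <- max(r2(f2) - r2(f1), 0)
    data.frame(item_id = colnames(x)[j],
               lr_uniform = lr_u, p_uniform = stats::pchisq(lr_u, 1, lower.tail = FALSE),
               lr_nonuniform = lr_n, p_nonuniform = stats::pchisq(lr_n, 1, lower.tail = FALSE),
               delta_r2_uniform = d_u, delta_r2_nonuniform = d_n,
               flag_uniform = stats::pchisq(lr_u, 1, lower.tail = FALSE) < alpha,
               flag_nonuniform = stats::pchisq(lr_n, 1, lower.tail = FALSE) < alpha,
               negligible = d_u < r2_threshold && d_n < r2_threshold &&
                 (d_u + d_n) < r2_threshold,
               converged = f0$converged && f1$converged && f2$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "matching") <- matching
  attr(out, "alpha") <- alpha
  attr(out, "r2_threshold") <- r2_threshold
  attr(out, "group_sizes") <- as.vector(table(g))
  class(out) <- c("dif_result", "data.frame")
  out
}

#' Summarise DIF results across grouping variables
#'
#' @param results a named list of [dif_olr()] results (one per grouping
#'   variable, e.g. age / gender / education), reported in input order.
#' @return Data frame of class `dif_report`, one row per grouping:
#'   the statistically flagged item lists (uniform and non-uniform) and
#'   the overall negligibility verdict (`TRUE` when every item's
#'   delta-R2 stays under the salience gate: significant-but-negligible
#'   DIF is the expected pattern in large samples).
#' @export
dif_report <- function(results) {
  if (!length(results))
    return(structure(data.frame(grouping = character(0),
                                uniform_items = character(0),
                                nonuniform_items = character(0),
                                max_delta_r2 = numeric(0),
                                negligible = logical(0)),
                     class = c("dif_report", "data.frame")))
  if (is.null(names(results)))
    names(results) <- paste0("grouping", seq_along(results))
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(grouping = nm,
               uniform_items = paste(r$item_id[r$flag_uniform], collapse = ";"),
               nonuniform_items = paste(r$item_id[r$flag_nonuniform], collapse = ";"),
               max_delta_r2 = max(r$delta_r2_uniform, r$delta_r2_nonuniform),
               negligible = all(r$negligible),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dif_report", "data.frame")
  out
}
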