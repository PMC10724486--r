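#' Cronbach's alpha
#'
#' Raw (covariance-form) internal consistency,
#' \eqn{\alpha = \frac{J}{J-1}\left(1 - \frac{\sum_j s_j^2}{s_{total}^2}\right)},
#' with n-1 denominators throughout. Rows with any missing response are
#' excluded listwise; the number dropped is attached as attribute
#' `n_dropped`.
#'
#' @param responses a [response_matrix()] (or plain numeric matrix).
#' @return Alpha (scalar) with attributes `n_used`, `n_dropped`.
#' @export
cronbach_alpha <- function(responses) {
  x <- resp_complete_matrix(responses)
  J <- ncol(x)
  if (J < 2L) stop("alpha needs at least 2 items", call. = FALSE)
  total_var <- stats::var(rowSums(x))
  if (total_var <= .Machine$double.eps)
    stop("total-score variance is zero; alpha undefined", call. = FALSE)
  a <- J / (J - 1) * (1 - sum(apply(x, 2L, stats::var)) / total_var)
  structure(a, n_used = nrow(x), n_dropped = attr(x, "n_dropped"))
}

#' Alpha if item deleted
#'
#' Entry j is [cronbach_alpha()] recomputed on the matrix with item j
#' removed; a homogeneous scale shows no material increase for any item.
#'
#' @inheritParams cronbach_alpha
#' @return Named numeric vector, one entry per item.
#' @export
alpha_if_deleted <- function(responses) {
  x <- resp_complete_matrix(responses)
  if (ncol(x) < 3L) stop("alpha-if-deleted needs at least 3 items", call. = FALSE)
  vapply(seq_len(ncol(x)), function(j)
    as.numeric(cronbach_alpha(x[, -j, drop = FALSE])), numeric(1L)) |>
    stats::setNames(colnames(x))
}

#' Corrected item-rest correlations
#'
#' Pearson correlation between each item and the rest score (total minus
#' that item). The uncorrected item-total variant (inflated by
#' self-correlation) is available with `corrected = FALSE`.
#'
#' @inheritParams cronbach_alpha
#' @param corrected if `FALSE`, correlate with the full total instead of
#'   the rest score.
#' @return Named numeric vector; an item with zero variance (or zero rest
#'   variance) gets `NA`.
#' @export
item_rest_correlations <- function(responses, corrected = TRUE) {
  x <- resp_complete_matrix(responses)
  total <- rowSums(x)
  vapply(seq_len(ncol(x)), function(j) {
    other <- if (corrected) total - x[, j] else total
    if (stats::var(x[, j]) == 0 || stats::var(other) == 0) return(NA_real_)
    stats::cor(x[, j], other)
  }, numeric(1L)) |> stats::setNames(colnames(x))
}

#' Classical reliability report
#'
#' One call bundling [cronbach_alpha()], [alpha_if_deleted()] and
#' [item_rest_correlations()].
#'
#' @inheritParams item_rest_correlations
#' @return List of class `reliability_report`: `alpha`, `n_used`,
#'   `n_dropped`, and a per-item data frame `items` with `item_rest_r`
#'   and `alpha_if_deleted`.
#' @export
reliability_report <- function(responses, corrected = TRUE) {
  a <- cronbach_alpha(responses)
  structure(list(
    alpha = as.numeric(a),
    n_used = attr(a, "n_used"), n_dropped = attr(a, "n_dropped"),
    items = data.frame(
      item_id = names(item_rest_correlations(responses)),
      item_rest_r = unname(item_rest_correlations(responses, corrected)),
      alpha_if_deleted = unname(alpha_if_deleted(responses)),
      stringsAsFactors = FALSE)),
    class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("Cronbach's alpha = %.3f  (n = %d used, %d dropped listwise)\n",
              x$alpha, x$n_used, x$n_dropped))
  cat(sprintf("item-rest r: %.3f .. %.3f\n",
              min(x$items$item_rest_r, na.rm = TRUE),
              max(x$items$item_rest_r, na.rm = TRUE)))
  invisible(x)
}

# accept a response_matrix or bare matrix; listwise-complete numeric matrix
resp_complete_matrix <- function(responses) {
  if (inherits(responses, "response_matrix")) return(complete_responses(responses))
  x <- as.matrix(responses)
  keep <- stats::complete.cases(x)
  structure(x[keep, , drop = FALSE], n_dropped = sum(!keep))
}
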