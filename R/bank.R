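#' Item parameters for one graded-response item
#'
#' Bundles the discrimination and ordered threshold parameters of a single
#' item under Samejima's graded response model in the logistic metric
#' (scaling constant D = 1), i.e. boundary probabilities
#' \eqn{P^*_k(\theta) = 1 / (1 + e^{-a(\theta - b_k)})}.
#'
#' @param item_id character scalar, unique item identifier.
#' @param a discrimination parameter, must be positive.
#' @param b numeric vector of K-1 strictly increasing thresholds (theta units).
#' @param wording optional item text.
#' @return An object of class `item_params`.
#' @export
item_params <- function(item_id, a, b, wording = NA_character_) {
  stopifnot(is.character(item_id), length(item_id) == 1L)
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != 1L || !is.finite(a) || a <= 0)
    stop("item '", item_id, "': discrimination a must be a positive number", call. = FALSE)
  if (length(b) < 1L || anyNA(b) || any(diff(b) <= 0))
    stop("item '", item_id, "': thresholds b must be strictly increasing", call. = FALSE)
  structure(list(item_id = item_id, a = a, b = b, wording = wording),
            class = "item_params")
}

#' @export
print.item_params <- function(x, ...) {
  cat(sprintf("<item_params> %s  a = %.3f  b = (%s)\n", x$item_id, x$a,
              paste(sprintf("%.3f", x$b), collapse = ", ")))
  invisible(x)
}

#' Construct an item bank
#'
#' An item bank is an ordered collection of [item_params()] sharing a common
#' number of response categories K and a parameter metric.
#'
#' @param items list of `item_params` objects.
#' @param K number of response categories (thresholds per item = K - 1).
#' @param metric character tag recording the parameter metric; the packaged
#'   bank and all fitting code use `"logistic, D=1"`.
#' @return Object of class `item_bank`.
#' @export
item_bank <- function(items, K = length(items[[1L]]$b) + 1L,
                      metric = "logistic, D=1") {
  stopifnot(is.list(items), length(items) >= 1L)
  ids <- vapply(items, function(it) it$item_id, character(1L))
  if (anyDuplicated(ids))
    stop("duplicate item_id in bank: ", ids[duplicated(ids)][1L], call. = FALSE)
  nb <- vapply(items, function(it) length(it$b), integer(1L))
  if (any(nb != K - 1L))
    stop("all items must have K - 1 = ", K - 1L, " thresholds", call. = FALSE)
  structure(list(items = items, K = as.integer(K), metric = metric),
            class = "item_bank")
}

#' @export
length.item_bank <- function(x) length(x$items)

#' @export
`[[.item_bank` <- function(x, i) {
  if (is.character(i)) {
    j <- match(i, item_ids(x))
    if (is.na(j)) stop("no item '", i, "' in bank", call. = FALSE)
    i <- j
  }
  x$items[[i]]
}

#' @export
`[.item_bank` <- function(x, i) {
  if (is.character(i)) i <- match(i, item_ids(x))
  item_bank(x$items[i], K = x$K, metric = x$metric)
}

#' Item identifiers of a bank or response matrix
#' @param x an `item_bank` or `response_matrix`.
#' @return Character vector of item ids.
#' @export
item_ids <- function(x) UseMethod("item_ids")

#' @export
item_ids.item_bank <- function(x) vapply(x$items, function(it) it$item_id, character(1L))

#' @export
item_ids.response_matrix <- function(x) colnames(x$responses)

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("<item_bank> %d items, K = %d categories, metric: %s\n",
              length(x), x$K, x$metric))
  print(as.data.frame(x), digits = 3)
  invisible(x)
}

#' @export
as.data.frame.item_bank <- function(x, ...) {
  b <- t(vapply(x$items, function(it) it$b, numeric(x$K - 1L)))
  colnames(b) <- paste0("b", seq_len(x$K - 1L))
  data.frame(item_id = item_ids(x),
             a = vapply(x$items, function(it) it$a, numeric(1L)),
             b,
             wording = vapply(x$items, function(it) as.character(it$wording), character(1L)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Load the packaged PROMIS-Cancer-Anxiety item bank
#'
#' Returns the calibrated 23-item, five-category Chinese
#' PROMIS-Cancer-Anxiety bank (items EDANX01..EDANX55) with the published
#' discrimination and threshold estimates on the logistic D = 1 metric.
#' Item wording is stored verbatim as published (including the apparent
#' typo "I felt fearly." for EDANX01).
#'
#' @return An [item_bank()] with 23 items and K = 5.
#' @examples
#' bank <- load_default_bank()
#' bank[["EDANX05"]]$a   # 5.47
#' @export
load_default_bank <- function() {
  path <- system.file("extdata", "promis_a_bank.csv", package = "grmbank",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  items <- lapply(seq_len(nrow(tab)), function(i)
    item_params(tab$item_id[i], tab$a[i],
                as.numeric(tab[i, c("b1", "b2", "b3", "b4")]),
                wording = tab$wording[i]))
  item_bank(items, K = 5L, metric = "logistic, D=1")
}

#' Serialize an item bank to JSON
#'
#' The file carries, per item, `item_id`, `wording`, `a` and the threshold
#' array `b`, plus bank-level `K` and the explicit `metric` tag so that a
#' reader never has to guess the scaling convention. [read_bank()] is the
#' exact inverse; the round trip is lossless to full double precision.
#'
#' @param bank an `item_bank`.
#' @param path file path to write to.
#' @return `path`, invisibly.
#' @export
write_bank <- function(bank, path) {
  stopifnot(inherits(bank, "item_bank"))
  obj <- list(K = bank$K, metric = bank$metric,
              items = lapply(bank$items, function(it)
                list(item_id = it$item_id, wording = it$wording,
                     a = it$a, b = it$b)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an item bank from JSON
#'
#' @param path a file written by [write_bank()] (or hand-authored in the
#'   same layout).
#' @return An [item_bank()].
#' @export
read_bank <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$items)) stop("bank file has no 'items' key: ", path, call. = FALSE)
  items <- lapply(obj$items, function(it) {
    id <- if (is.null(it$item_id)) "<unnamed>" else it$item_id
    if (is.null(it$a)) stop("bank file: item '", id, "' is missing 'a'", call. = FALSE)
    if (is.null(it$b)) stop("bank file: item '", id, "' is missing 'b'", call. = FALSE)
    item_params(id, it$a, unlist(it$b),
                wording = if (is.null(it$wording)) NA_character_ else it$wording)
  })
  K <- if (is.null(obj$K)) length(items[[1L]]$b) + 1L else obj$K
  item_bank(items, K = K,
            metric = if (is.null(obj$metric)) "logistic, D=1" else obj$metric)
}
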