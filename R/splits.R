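## Circular split systems and their nonnegative least-squares weights.

#' @rdname circular_split_weights
#' @param taxa,ordering,splits,weights,fit components of a split system
#'   (used by readers; normally produced by [circular_split_weights()]).
#' @export
new_split_system <- function(taxa, ordering, splits, weights, fit = NA_real_) {
  stopifnot(length(splits) == length(weights), all(weights >= 0))
  structure(list(taxa = taxa, ordering = ordering, splits = splits,
                 weights = weights, fit = fit),
            class = "split_system")
}

#' @export
print.split_system <- function(x, ...) {
  cat(sprintf("split_system: %d taxa, %d weighted splits", length(x$taxa),
              length(x$splits)))
  if (!is.na(x$fit)) cat(sprintf(", fit = %.2f%%", x$fit))
  cat("\n  ordering:", paste(x$ordering, collapse = " "), "\n")
  invisible(x)
}

## all interval splits of a circular ordering, as canonical sides (the side
## not containing the first taxon of the ordering): intervals [i, j] of
## positions 2..n. Returns list of integer position vectors.
interval_splits <- function(n) {
  out <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (i in 2:n) for (j in i:n) {
    k <- k + 1L
    out[[k]] <- i:j
  }
  out
}

## pair incidence matrix: rows = unordered taxon pairs (column order of
## combn), cols = splits; entry 1 iff the split separates the pair.
split_design_matrix <- function(n, splits_pos) {
  pairs <- utils::combn(n, 2)
  A <- matrix(0, ncol(pairs), length(splits_pos))
  for (s in seq_along(splits_pos)) {
    inside <- logical(n)
    inside[splits_pos[[s]]] <- TRUE
    A[, s] <- inside[pairs[1, ]] != inside[pairs[2, ]]
  }
  storage.mode(A) <- "double"
  A
}

#' Nonnegative least-squares weights for the circular splits of an ordering
#'
#' Given a distance matrix and a circular ordering of its taxa, fits
#' nonnegative weights to all \eqn{n(n-1)/2} interval splits of the
#' ordering, minimising \eqn{\|d - \sum_s w_s \delta_s\|^2} with
#' \eqn{w \ge 0}, where \eqn{\delta_s(i,j) = 1} iff split \eqn{s} separates
#' taxa \eqn{i} and \eqn{j} (Lawson–Hanson active-set NNLS). Splits with
#' zero weight are dropped. The recorded `fit` is the percentage of
#' distance variance explained, \eqn{100 (1 - \|r\|^2 / \|d\|^2)}.
#'
#' @param D symmetric distance matrix with taxa dimnames.
#' @param ordering circular ordering of the taxa (character vector), e.g.
#'   from [neighbor_net_ordering()].
#' @return a `split_system`: list with `taxa` (in `D`'s order), `ordering`,
#'   `splits` (list of character vectors, each the canonical split side
#'   not containing `ordering[1]`), `weights`, `fit`.
#' @export
circular_split_weights <- function(D, ordering) {
  taxa <- rownames(D)
  if (!setequal(ordering, taxa) || length(ordering) != length(taxa))
    stop("'ordering' must be a permutation of the taxa of D")
  n <- length(taxa)
  pos <- interval_splits(n)
  A <- split_design_matrix(n, pos)
  pairs <- utils::combn(n, 2)
  dvec <- D[cbind(match(ordering[pairs[1, ]], taxa),
                  match(ordering[pairs[2, ]], taxa))]
  sol <- pracma::lsqnonneg(A, dvec)
  w <- sol$x
  resid <- dvec - A %*% w
  ssd <- sum(dvec^2)
  fit <- if (ssd > 0) 100 * (1 - sum(resid^2) / ssd) else 100
  keep <- which(w > 0)
  new_split_system(
    taxa = taxa,
    ordering = ordering,
    splits = lapply(pos[keep], function(p) ordering[p]),
    weights = w[keep],
    fit = fit)
}

#' Drop splits below a weight threshold
#'
#' Splits with weight greater than or equal to `threshold` are retained
#' (boundary inclusive); ordering and fit are unchanged. The conventional
#' threshold for language data is 0.005.
#'
#' @param s a `split_system`.
#' @param threshold nonnegative weight cutoff (default 0.005).
#' @return a filtered `split_system`.
#' @export
filter_splits <- function(s, threshold = 0.005) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0)
    stop("'threshold' must be a single nonnegative number")
  keep <- s$weights >= threshold
  new_split_system(s$taxa, s$ordering, s$splits[keep], s$weights[keep], s$fit)
}

#' Distances implied by a weighted split system
#'
#' Sums, for every taxon pair, the weights of the splits separating the
#' pair. Used to assess fit and in round-trip tests.
#'
#' @param s a `split_system`.
#' @return symmetric matrix in the order of `s$taxa`.
#' @export
split_system_distance <- function(s) {
  n <- length(s$taxa)
  d <- matrix(0, n, n, dimnames = list(s$taxa, s$taxa))
  for (k in seq_along(s$splits)) {
    inside <- s$taxa %in% s$splits[[k]]
    sep <- outer(inside, inside, `!=`)
    d <- d + s$weights[k] * sep
  }
  d
}

#' Total weight of splits incompatible with a taxon partition
#'
#' A split is compatible with a partition of the taxa into groups if its
#' side is a union of whole groups or splits exactly one group (i.e. the
#' split does not cut across two or more groups while also separating
#' them). Used to quantify reticulation relative to the true family
#' partition on synthetic data.
#'
#' @param s a `split_system`.
#' @param groups named character vector: taxon -> group label.
#' @return total weight of splits that bisect more than one group.
#' @export
incompatible_split_weight <- function(s, groups) {
  groups <- groups[s$taxa]
  total <- 0
  for (k in seq_along(s$splits)) {
    side <- s$taxa %in% s$splits[[k]]
    cut_groups <- 0L
    for (g in unique(groups)) {
      in_g <- groups == g
      if (any(side[in_g]) && any(!side[in_g])) cut_groups <- cut_groups + 1L
    }
    if (cut_groups >= 2L) total <- total + s$weights[k]
  }
  total
}

#' Flat TSV export of a split system
#' @param s a `split_system`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_splits_tsv <- function(s, path) {
  df <- data.frame(
    split = seq_along(s$splits),
    weight = s$weights,
    size = lengths(s$splits),
    side = vapply(s$splits, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
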