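## GeneContent distances between doculect presence/absence profiles.
## Missing data ('?') is handled by pairwise deletion: a root missing in
## either member of a pair is excluded from that pair's tallies.

#' Pairwise presence/absence tallies for two doculects
#'
#' Counts, over all roots, `a` both-present, `b` present in `i` only,
#' `c` present in `j` only, `z` both-absent and `m` excluded because the
#' state is missing in at least one of the two (pairwise deletion).
#' `a + b + c + z + m` equals the number of roots.
#'
#' @param m a [root_matrix].
#' @param i,j doculect ids.
#' @return named list with elements `a`, `b`, `c`, `z`, `m`.
#' @export
pair_counts <- function(m, i, j) {
  if (identical(i, j)) stop("pair_counts requires two distinct doculects")
  for (d in c(i, j))
    if (!d %in% colnames(m$state)) stop("unknown doculect: ", d)
  x <- m$state[, i]
  y <- m$state[, j]
  miss <- is.na(x) | is.na(y)
  list(a = sum(!miss & x == 1L & y == 1L),
       b = sum(!miss & x == 1L & y == 0L),
       c = sum(!miss & x == 0L & y == 1L),
       z = sum(!miss & x == 0L & y == 0L),
       m = sum(miss))
}

#' GeneContent distance matrix between doculects
#'
#' Distance between the root inventories of two doculects, as used in
#' gene-content phylogenetics for whole-genome presence/absence profiles.
#' Two variants:
#' \describe{
#'   \item{`shared` (default)}{\eqn{d = 1 - 2a/(2a + b + c)}, the complement
#'     of the Dice coefficient of the two presence sets; bounded in
#'     \[0, 1\].}
#'   \item{`mle`}{\eqn{d = -\log(2a/(2a + b + c))}, the log-transformed
#'     shared fraction, additive under an exponential-decay model of shared
#'     content; unbounded, and infinite for disjoint inventories.}
#' }
#'
#' @param m a [root_matrix].
#' @param variant `"shared"` or `"mle"`.
#' @return symmetric numeric matrix with doculect ids as dimnames, zero
#'   diagonal.
#' @export
gene_content_distance <- function(m, variant = c("shared", "mle")) {
  variant <- match.arg(variant)
  s <- m$state
  n <- ncol(s)
  P <- (!is.na(s)) & s == 1L   # present
  K <- !is.na(s)               # known
  storage.mode(P) <- "double"
  storage.mode(K) <- "double"
  A <- crossprod(P)                 # both present (over known-in-both rows)
  pk <- crossprod(P, K)             # present in row doculect & known in col
  denom <- pk + t(pk)               # 2a + b + c
  bad <- denom == 0
  diag(bad) <- FALSE
  if (any(bad)) {
    idx <- sort(which(bad, arr.ind = TRUE)[1, ])
    stop(sprintf(paste0("distance undefined for pair (%s, %s): no root is ",
                        "present in either after pairwise deletion"),
                 colnames(s)[idx[1]], colnames(s)[idx[2]]))
  }
  frac <- 2 * A / denom
  d <- switch(variant, shared = 1 - frac, mle = -log(frac))
  diag(d) <- 0
  dimnames(d) <- list(colnames(s), colnames(s))
  d
}

#' Similarity matrix (1 - distance), ordered for heatmap display
#'
#' Elementwise \eqn{s = 1 - d}, with unit diagonal, rows/columns ordered by
#' family, then cluster, then doculect id, so that within-family blocks are
#' contiguous. Only defined for the bounded `shared` distance variant.
#'
#' @param D distance matrix from [gene_content_distance()] (`shared`
#'   variant).
#' @param doculects optional doculect metadata (data frame with `id`,
#'   `family`, `cluster_id`) used for the block ordering; without it the
#'   input order is kept.
#' @return symmetric similarity matrix.
#' @export
similarity_matrix <- function(D, doculects = NULL) {
  if (any(D > 1 + 1e-12))
    stop("similarity is only defined for the bounded 'shared' variant ",
         "(found distances > 1); recompute with variant = \"shared\"")
  s <- 1 - D
  diag(s) <- 1
  if (!is.null(doculects)) {
    meta <- doculects[match(rownames(s), doculects$id), , drop = FALSE]
    ord <- order(match(meta$family, SAK_FAMILIES), meta$cluster_id, meta$id)
    s <- s[ord, ord, drop = FALSE]
  }
  s
}

#' Write a square matrix as TSV (header row and column)
#' @param x square matrix with dimnames.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_square_tsv <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a distance matrix in square PHYLIP format
#' @param D square distance matrix with dimnames.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_phylip_dist <- function(D, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con, useBytes = TRUE)
  labs <- gsub("[ \t]", "_", rownames(D))
  for (i in seq_len(nrow(D)))
    writeLines(paste(c(sprintf("%-10s", labs[i]),
                       sprintf("%.8f", D[i, ])), collapse = "  "),
               con, useBytes = TRUE)
  invisible(path)
}
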