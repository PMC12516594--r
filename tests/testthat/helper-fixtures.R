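## Shared fixtures and independent oracles for the test suite.

example_dir <- function() system.file("extdata/example", package = "borrownet")

example_matrix <- function() {
  ex <- example_dir()
  read_root_matrix(file.path(ex, "matrix.tsv"), file.path(ex, "metadata.tsv"),
                   roots_path = file.path(ex, "roots.tsv"),
                   meanings_path = file.path(ex, "meanings.tsv"))
}

## quick builder: states is a roots x doculects matrix of 1/0/NA;
## families recycled over doculects
toy_matrix <- function(states, families = "KXA", origins = NULL,
                       clusters = NULL, lat = NULL, lon = NULL, ...) {
  nd <- ncol(states)
  if (is.null(rownames(states))) rownames(states) <- sprintf("r%02d", seq_len(nrow(states)))
  if (is.null(colnames(states))) colnames(states) <- sprintf("d%02d", seq_len(nd))
  doc <- data.frame(id = colnames(states),
                    family = rep_len(families, nd),
                    stringsAsFactors = FALSE)
  if (!is.null(clusters)) doc$cluster_id <- rep_len(clusters, nd)
  if (!is.null(lat)) { doc$latitude <- lat; doc$longitude <- lon }
  roots <- data.frame(id = rownames(states), stringsAsFactors = FALSE)
  if (!is.null(origins)) roots$origin <- origins
  root_matrix(states, doc, roots, ...)
}

## random 0/1/NA matrix for property tests
random_state_matrix <- function(n_roots, n_doc, p_present = 0.4,
                                p_missing = 0.1) {
  repeat {
    s <- matrix(sample(c(1L, 0L, NA_integer_), n_roots * n_doc, replace = TRUE,
                       prob = c(p_present, 1 - p_present - p_missing,
                                p_missing)),
                n_roots, n_doc,
                dimnames = list(sprintf("r%02d", seq_len(n_roots)),
                                sprintf("d%02d", seq_len(n_doc))))
    if (all(rowSums(s == 1L, na.rm = TRUE) > 0)) return(s)
  }
}

## ---- independent oracles ------------------------------------------------

## set-based Dice complement between two presence profiles with pairwise
## deletion, computed from first principles
dice_distance_oracle <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  A <- which(x[keep] == 1L)
  B <- which(y[keep] == 1L)
  1 - 2 * length(intersect(A, B)) / (length(A) + length(B))
}

## brute-force NNLS: the optimum of min ||Ax - b||, x >= 0 is the
## unconstrained least-squares solution on some support set; enumerate all
## supports, keep feasible solutions, take the minimal residual
nnls_bruteforce <- function(A, b) {
  p <- ncol(A)
  best <- list(x = rep(0, p), rss = sum(b^2))
  for (mask in seq_len(2^p - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    fit <- tryCatch(qr.solve(A[, sel, drop = FALSE], b),
                    error = function(e) NULL)
    if (is.null(fit) || any(fit < -1e-10)) next
    r <- b - A[, sel, drop = FALSE] %*% fit
    rss <- sum(r^2)
    if (rss < best$rss - 1e-12) {
      x <- rep(0, p)
      x[sel] <- pmax(fit, 0)
      best <- list(x = x, rss = rss)
    }
  }
  best
}

## independently coded origin-combination rule, written as literal nested
## conditions (kept deliberately separate from the package implementation)
origin_rule_oracle <- function(values, primary = c("P1", "P2"),
                               secondary = c("S1", "S2"),
                               min_primary = 1) {
  ## values: named list family -> named character vector criterion -> value
  fams <- names(values)
  score <- function(f, crits) {
    v <- values[[f]][crits]
    sum(v == "SUPPORTS") - sum(v == "CONTRADICTS")
  }
  supp <- function(f, crits) sum(values[[f]][crits] == "SUPPORTS")
  p <- vapply(fams, score, numeric(1), crits = primary)
  s <- vapply(fams, score, numeric(1), crits = secondary)
  if (max(p) < min_primary) return("UNIDENTIFIED")
  top <- fams[p == max(p)]
  others_with_support <- fams[!(fams %in% top) &
                                vapply(fams, supp, numeric(1),
                                       crits = primary) > 0]
  if (length(top) == 1 && length(others_with_support) == 0) return(top)
  contenders <- union(top, fams[vapply(fams, supp, numeric(1),
                                       crits = primary) > 0])
  sc <- s[contenders]
  winners <- contenders[sc == max(sc)]
  if (length(winners) == 1 && winners %in% top) return(winners)
  "UNIDENTIFIED"
}

## evidence data frame for one root from the oracle's value structure
evidence_from_values <- function(values, root_id = "r1") {
  do.call(rbind, lapply(names(values), function(f)
    data.frame(root_id = root_id, family = f,
               criterion = names(values[[f]]),
               value = unname(values[[f]]), stringsAsFactors = FALSE)))
}
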