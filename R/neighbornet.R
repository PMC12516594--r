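## NeighborNet circular ordering (agglomerative, Bryant & Moulton style).
##
## Nodes are grouped in clusters of size 1 or 2 (a linked pair). Each round:
##   1. pick the pair of clusters minimising the net-divergence-adjusted
##      distance Q (as in neighbor joining, but on clusters);
##   2. within the chosen clusters, pick the pair of nodes minimising the
##      analogous adjusted distance with the remaining companion nodes
##      treated as singleton clusters;
##   3. link the two nodes; chains of 3 (or 4) nodes are immediately reduced
##      to 2 new nodes with the standard 2/3-1/3 distance reduction, and the
##      reduction is recorded for later expansion.
## When at most 3 nodes remain they are closed into a cycle and all
## reductions are expanded in reverse, yielding a circular ordering of the
## original taxa. Ties are broken toward the lowest node index so runs are
## bit-reproducible.

#' NeighborNet circular ordering of taxa
#'
#' Computes the circular ordering underlying a NeighborNet splits graph by
#' iterative selection via net-divergence-adjusted distances, pairing, and
#' 3-to-2 node reductions, expanded back to a circular order of all taxa.
#' On circular-decomposable distances (in particular on additive tree
#' distances) the returned ordering supports an exact fit of the distance
#' matrix by nonnegative circular split weights.
#'
#' @param D symmetric distance matrix with zero diagonal and taxa ids as
#'   dimnames; at least 3 taxa.
#' @return character vector: the taxa in circular order, canonicalised to
#'   start at the first taxon of `D` with the lexicographically smaller
#'   direction.
#' @seealso [circular_split_weights()]
#' @export
neighbor_net_ordering <- function(D) {
  if (is.null(dimnames(D))) dimnames(D) <- list(seq_len(nrow(D)),
                                                seq_len(nrow(D)))
  taxa <- rownames(D)
  n <- length(taxa)
  if (n < 3) stop("NeighborNet needs at least 3 taxa")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8, check.attributes = FALSE)))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix must have zero diagonal")

  max_nodes <- 3L * n                 # each reduction adds <= 2 new nodes
  d <- matrix(0, max_nodes, max_nodes)
  d[1:n, 1:n] <- D
  active <- c(rep(TRUE, n), rep(FALSE, max_nodes - n))
  nbr <- integer(max_nodes)           # 0 = unlinked
  n_nodes <- n
  expansions <- list()                # LIFO of list(pair = c(p,q), triple)

  cluster_reps <- function() {
    # one representative per cluster: the smaller index of a linked pair
    act <- which(active)
    act[nbr[act] == 0 | act < nbr[act]]
  }
  cluster_members <- function(r) if (nbr[r] > 0) c(r, nbr[r]) else r

  ## 3 -> 2 reduction of chain (u, x, y): u,x,y replaced by nodes p,q with
  ## p at the u-end. Standard NeighborNet reduction distances.
  reduce3 <- function(u, x, y) {
    p <- n_nodes + 1L
    q <- n_nodes + 2L
    if (q > max_nodes) stop("internal: node buffer exhausted")
    others <- setdiff(which(active), c(u, x, y))
    d[p, others] <<- d[others, p] <<- (2/3) * d[u, others] + (1/3) * d[x, others]
    d[q, others] <<- d[others, q] <<- (2/3) * d[y, others] + (1/3) * d[x, others]
    d[p, q] <<- d[q, p] <<- (d[u, x] + d[x, y] + d[u, y]) / 3
    active[c(u, x, y)] <<- FALSE
    active[c(p, q)] <<- TRUE
    nbr[c(u, x, y)] <<- 0L
    nbr[p] <<- q
    nbr[q] <<- p
    n_nodes <<- q
    expansions[[length(expansions) + 1L]] <<- list(pair = c(p, q),
                                                   triple = c(u, x, y))
    c(p, q)
  }

  repeat {
    act <- which(active)
    if (length(act) <= 3L) break
    reps <- cluster_reps()
    m_cl <- length(reps)
    if (m_cl < 2L) break

    ## cluster-cluster average distances
    mem <- lapply(reps, cluster_members)
    cd <- matrix(0, m_cl, m_cl)
    for (i in seq_len(m_cl - 1L)) for (j in (i + 1L):m_cl) {
      cd[i, j] <- cd[j, i] <- mean(d[mem[[i]], mem[[j]], drop = FALSE])
    }
    rsum <- rowSums(cd)

    ## selection 1: clusters minimising Q = (m-2) d(A,B) - R(A) - R(B)
    best <- c(NA_integer_, NA_integer_)
    bestQ <- Inf
    for (i in seq_len(m_cl - 1L)) for (j in (i + 1L):m_cl) {
      Q <- (m_cl - 2) * cd[i, j] - rsum[i] - rsum[j]
      if (Q < bestQ - 1e-14) {
        bestQ <- Q
        best <- c(i, j)
      }
    }
    A <- best[1]; B <- best[2]
    memA <- mem[[A]]; memB <- mem[[B]]

    ## selection 2: nodes x in A, y in B minimising the adjusted distance
    ## with companion nodes of A and B treated as singleton clusters
    other_reps <- setdiff(seq_len(m_cl), c(A, B))
    x <- memA[1]; y <- memB[1]
    if (length(memA) > 1L || length(memB) > 1L) {
      bestQ2 <- Inf
      for (xx in memA) for (yy in memB) {
        companions <- c(setdiff(memA, xx), setdiff(memB, yy))
        m_hat <- length(other_reps) + length(companions) + 2L
        # net divergences over the temporary configuration in which the
        # companion nodes count as singleton clusters; like the first
        # selection's row sums, they include d(xx, yy) itself
        sx <- sum(vapply(other_reps, function(k) mean(d[xx, mem[[k]]]),
                         numeric(1))) + sum(d[xx, companions]) + d[xx, yy]
        sy <- sum(vapply(other_reps, function(k) mean(d[yy, mem[[k]]]),
                         numeric(1))) + sum(d[yy, companions]) + d[xx, yy]
        Q2 <- (m_hat - 2) * d[xx, yy] - sx - sy
        if (Q2 < bestQ2 - 1e-14) {
          bestQ2 <- Q2
          x <- xx; y <- yy
        }
      }
    }

    ## link / reduce
    xl <- nbr[x]; yl <- nbr[y]
    if (xl == 0L && yl == 0L) {
      nbr[x] <- y
      nbr[y] <- x
    } else if (xl != 0L && yl == 0L) {
      reduce3(xl, x, y)
    } else if (xl == 0L && yl != 0L) {
      reduce3(yl, y, x)
    } else {
      ## chain xl - x - y - yl: reduce twice
      pq <- reduce3(xl, x, y)          # p at xl end, q at y end
      reduce3(pq[1], pq[2], yl)
    }
  }

  ## close the remaining nodes into a cycle, respecting links
  act <- which(active)
  cycle <- if (length(act) == 2L) act else {
    linked <- act[nbr[act] != 0L]
    if (length(linked) == 2L) c(linked[1], linked[2], setdiff(act, linked))
    else act
  }

  ## expand reductions in reverse order
  for (k in rev(seq_along(expansions))) {
    e <- expansions[[k]]
    p <- e$pair[1]; q <- e$pair[2]
    ip <- match(p, cycle)
    iq <- match(q, cycle)
    if (is.na(ip) || is.na(iq)) stop("internal: reduction pair lost from cycle")
    nn <- length(cycle)
    tri <- e$triple                      # (u, x, y); u belongs at the p end
    if (iq == ip %% nn + 1L) {
      cycle <- append(cycle[-c(ip, iq)], tri,
                      after = if (iq > ip) ip - 1L else nn - 2L)
    } else if (ip == iq %% nn + 1L) {
      cycle <- append(cycle[-c(ip, iq)], rev(tri),
                      after = if (ip > iq) iq - 1L else nn - 2L)
    } else stop("internal: reduction pair not adjacent in cycle")
  }

  ord <- taxa[cycle]
  canonical_ordering(ord, taxa)
}

## rotate/reflect a circular ordering to a canonical representative:
## start at the first taxon (in reference order), direction chosen so the
## successor has the smaller reference index.
canonical_ordering <- function(ord, ref = sort(ord)) {
  n <- length(ord)
  i <- match(ref[1], ord)
  ord <- ord[((seq_len(n) + i - 2L) %% n) + 1L]
  if (n > 2 && match(ord[2], ref) > match(ord[n], ref))
    ord <- c(ord[1], rev(ord[-1]))
  ord
}
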