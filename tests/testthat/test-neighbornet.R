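tree_distance <- function(newick) {
  tr <- ape::read.tree(text = newick)
  D <- ape::cophenetic.phylo(tr)
  list(tree = tr, D = D)
}

## is `side` a contiguous arc of the circular ordering `ord`?
is_interval <- function(side, ord) {
  pos <- sort(match(side, ord))
  n <- length(ord)
  contiguous <- function(p) all(diff(p) == 1)
  contiguous(pos) || contiguous(sort(setdiff(seq_len(n), pos)))
}

test_that("ordering rejects degenerate input", {
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighbor_net_ordering(D), "at least 3")
  D3 <- matrix(c(0, 1, 2, 5, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_net_ordering(D3), "symmetric")
})

test_that("any ordering of 3 taxa solves the 3-taxon system exactly", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("t1", "t2", "t3"), c("t1", "t2", "t3")))
  ord <- neighbor_net_ordering(D)
  expect_setequal(ord, c("t1", "t2", "t3"))
  ss <- circular_split_weights(D, ord)
  # hand-solved trivial-split weights: w{i} = (d_ij + d_ik - d_jk)/2;
  # sides are canonical (never containing t1), so t1's split is "t2,t3"
  w <- setNames(ss$weights, vapply(ss$splits, function(s)
    paste(sort(s), collapse = ","), character(1)))
  expect_equal(w[["t2,t3"]], 0.5)
  expect_equal(w[["t2"]], 1.5)
  expect_equal(w[["t3"]], 2.5)
})

test_that("additive 4-taxon distances recover the tree splits and branch lengths", {
  td <- tree_distance("((a:1,b:2):0.7,(c:1.5,d:0.5):0.3);")
  ord <- neighbor_net_ordering(td$D)
  ss <- circular_split_weights(td$D, ord)
  key <- function(s) paste(sort(s), collapse = ",")
  canon <- function(s) {   # represent each split by the side without 'a'
    if ("a" %in% s) key(setdiff(c("a", "b", "c", "d"), s)) else key(s)
  }
  expected <- c(b = 2, c = 1.5, d = 0.5, `c,d` = 1, `b,c,d` = 1)
  got <- setNames(ss$weights, vapply(ss$splits, canon, character(1)))
  expect_setequal(names(got), names(expected))
  expect_equal(got[names(expected)], expected, tolerance = 1e-8)
})

test_that("caterpillar-tree ordering embeds every tree split as an arc", {
  td <- tree_distance("((((a:1,b:1):1,c:2):1,d:3):1,e:4);")
  ord <- neighbor_net_ordering(td$D)
  for (clade in list(c("a", "b"), c("a", "b", "c"), c("a", "b", "c", "d")))
    expect_true(is_interval(clade, ord))
})

test_that("tree distances are reproduced exactly for larger random trees", {
  set.seed(21)
  for (rep in 1:5) {
    tr <- ape::rtree(sample(6:10, 1))
    D <- ape::cophenetic.phylo(tr)
    ord <- neighbor_net_ordering(D)
    ss <- circular_split_weights(D, ord)
    expect_lt(max(abs(split_system_distance(ss)[rownames(D), colnames(D)] - D)),
              1e-8)
    expect_true(all(ss$weights >= 0))
    expect_gt(ss$fit, 100 - 1e-8)
  }
})

test_that("randomly weighted circular split systems are recovered exactly", {
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(5:9, 1)
    taxa <- paste0("x", seq_len(n))
    pos <- borrownet:::interval_splits(n)
    w <- ifelse(runif(length(pos)) < 0.4, runif(length(pos), 0.05, 2), 0)
    truth <- new_split_system(taxa, taxa,
                              lapply(pos[w > 0], function(p) taxa[p]),
                              w[w > 0])
    D <- split_system_distance(truth)
    ord <- neighbor_net_ordering(D)
    ss <- circular_split_weights(D, ord)
    expect_lt(max(abs(split_system_distance(ss) - D)), 1e-8)
  }
})

test_that("equal distances and all-zero distances terminate with valid output", {
  D <- matrix(1, 5, 5, dimnames = list(paste0("t", 1:5), paste0("t", 1:5)))
  diag(D) <- 0
  ord <- neighbor_net_ordering(D)
  expect_setequal(ord, paste0("t", 1:5))
  expect_identical(neighbor_net_ordering(D), ord)   # deterministic tie-break
  Dz <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  ss <- circular_split_weights(Dz, neighbor_net_ordering(Dz))
  expect_length(ss$splits, 0)
})

test_that("NNLS split weights match a brute-force constrained oracle (n <= 6)", {
  set.seed(41)
  for (n in 4:6) {
    taxa <- paste0("t", seq_len(n))
    D <- matrix(0, n, n, dimnames = list(taxa, taxa))
    D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0.2, 2)
    D <- D + t(D)
    ord <- neighbor_net_ordering(D)
    ss <- circular_split_weights(D, ord)
    pos <- borrownet:::interval_splits(n)
    A <- borrownet:::split_design_matrix(n, pos)
    pairs <- utils::combn(n, 2)
    b <- D[cbind(match(ord[pairs[1, ]], taxa), match(ord[pairs[2, ]], taxa))]
    oracle <- nnls_bruteforce(A, b)
    w_full <- rep(0, length(pos))
    key <- vapply(pos, paste, character(1), collapse = ",")
    got_key <- vapply(ss$splits, function(s)
      paste(sort(match(s, ord)), collapse = ","), character(1))
    w_full[match(got_key, key)] <- ss$weights
    expect_equal(w_full, oracle$x, tolerance = 1e-6)
  }
})

test_that("weight filtering keeps >= threshold and validates the threshold", {
  taxa <- paste0("t", 1:4)
  ss <- new_split_system(taxa, taxa,
                         list("t2", "t3", c("t2", "t3")),
                         c(0.004, 0.005, 0.1))
  f <- filter_splits(ss)
  expect_length(f$splits, 2)                    # boundary weight retained
  expect_equal(sort(f$weights), c(0.005, 0.1))
  expect_identical(filter_splits(ss, 0)$weights, ss$weights)
  expect_error(filter_splits(ss, -1), "nonnegative")
})

test_that("filtering a tree system keeps exactly the branches above threshold", {
  td <- tree_distance("((a:1,b:0.002):0.5,(c:0.004,d:0.3):0.006);")
  ord <- neighbor_net_ordering(td$D)
  ss <- filter_splits(circular_split_weights(td$D, ord), 0.005)
  # unrooted splits: a|*, b|*, c|*, d|* and ab|cd (the two internal edges
  # around the root join into one split of length 0.5 + 0.006)
  lens <- c(1, 0.002, 0.004, 0.3, 0.506)
  expect_length(ss$splits, sum(lens >= 0.005))
})

test_that("splits NEXUS export round-trips and is readable by phangorn", {
  sim <- simulate_root_matrix(sim_config_small(seed = 3))
  D <- gene_content_distance(sim$matrix)
  ord <- neighbor_net_ordering(D)
  ss <- filter_splits(circular_split_weights(D, ord), 0.005)
  p <- withr::local_tempfile(fileext = ".nex")
  export_splits_nexus(ss, p)
  lines <- readLines(p)
  expect_true(any(grepl(sprintf("NSPLITS=%d", length(ss$splits)), lines)))
  back <- read_splits_nexus(p)
  expect_identical(back$ordering, ss$ordering)
  expect_equal(back$weights, ss$weights, tolerance = 1e-9)
  expect_identical(lapply(back$splits, sort), lapply(ss$splits, sort))
  # byte-identical re-export
  p2 <- withr::local_tempfile(fileext = ".nex")
  back$fit <- ss$fit
  export_splits_nexus(back, p2)
  expect_identical(readLines(p, warn = FALSE), readLines(p2, warn = FALSE))
  # independent parser agrees on count and weights
  ph <- phangorn::read.nexus.splits(p)
  expect_length(ph, length(ss$splits))
  expect_equal(sort(attr(ph, "weights")), sort(ss$weights), tolerance = 1e-9)
  # empty split system still writes a valid file
  p3 <- withr::local_tempfile(fileext = ".nex")
  export_splits_nexus(new_split_system(ss$taxa, ss$ordering, list(),
                                       numeric(0)), p3)
  expect_true(any(grepl("NSPLITS=0", readLines(p3))))
  expect_length(read_splits_nexus(p3)$splits, 0)
})

test_that("borrowing increases the split weight conflicting with the family partition", {
  rates <- c(0, 1, 3)
  mean_incomp <- vapply(rates, function(f) {
    vals <- vapply(1:4, function(s) {
      cfg <- sim_config_small(seed = 500 + s)
      cfg$borrow_rate <- default_borrow_rate() * f
      sim <- simulate_root_matrix(cfg)
      D <- gene_content_distance(sim$matrix)
      ss <- filter_splits(circular_split_weights(D, neighbor_net_ordering(D)),
                          0.005)
      incompatible_split_weight(ss, doculect_families(sim$matrix))
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_incomp) >= 0))
})
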