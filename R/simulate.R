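## Synthetic root matrices with ground truth: Yule family trees, Dollo root
## evolution (each root innovated exactly once, then only lost), and
## geographically structured directional borrowing between extant
## doculects. Every cross-family presence in the emitted matrix is
## explained by at least one logged borrowing event.

KM_PER_DEGREE <- 111.195

#' Configuration for the synthetic root-matrix generator
#'
#' Defaults emulate the scale and structure of a three-family Kalahari
#' Basin data set: 3 families totalling 57 doculects, 228 meanings,
#' roughly 1,700 attested roots, synonymy, missing data and directional
#' cross-family borrowing concentrated where families are geographically
#' adjacent.
#'
#' @param n_families number of families (currently fixed at 3).
#' @param taxa_per_family named integer vector of doculects per family.
#' @param yule_rate birth rate of the per-family Yule trees (trees are
#'   rescaled to unit depth, so this shapes topology/branching times
#'   only).
#' @param n_meanings number of meanings; every family tree root starts
#'   with one ancestral root per meaning.
#' @param innovation_rate new roots per meaning per unit branch length.
#' @param loss_rate per-root loss rate per unit branch length.
#' @param borrow_rate 3x3 matrix (donor family x recipient family) of
#'   borrowing events per adjacent doculect pair per unit contact time.
#' @param contact_time duration of the tip-level contact phase.
#' @param contact_radius adjacency cutoff in km on the simulated plane.
#' @param geo_sd spread (km) of doculects around their family centroid.
#' @param centroids 3x2 matrix of family centroid x/y positions in km.
#' @param missing_rate fraction of cells masked to '?' (missing).
#' @param synonym_cap maximum present roots per meaning per doculect
#'   (`Inf` = unlimited).
#' @param seed integer seed; mandatory, so any run is reproducible across
#'   machines.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_families = 3,
                       taxa_per_family = c(KXA = 21, TUU = 15, KHOE_KWADI = 21),
                       yule_rate = 1,
                       n_meanings = 228,
                       innovation_rate = 0.28,
                       loss_rate = 0.45,
                       borrow_rate = default_borrow_rate(),
                       contact_time = 1,
                       contact_radius = 250,
                       geo_sd = 260,
                       centroids = default_centroids(),
                       missing_rate = 0.10,
                       synonym_cap = Inf,
                       seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (n_families != 3)
    stop("the generator models exactly the three families ",
         paste(SAK_FAMILIES, collapse = "/"))
  taxa_per_family <- unlist(taxa_per_family)
  if (is.null(names(taxa_per_family)))
    names(taxa_per_family) <- SAK_FAMILIES
  stopifnot(all(names(taxa_per_family) == SAK_FAMILIES),
            all(taxa_per_family >= 2))
  borrow_rate <- as.matrix(borrow_rate)
  if (!all(dim(borrow_rate) == c(3, 3)))
    stop("'borrow_rate' must be a 3x3 donor x recipient matrix")
  dimnames(borrow_rate) <- list(SAK_FAMILIES, SAK_FAMILIES)
  rates <- c(yule_rate, innovation_rate, loss_rate, borrow_rate,
             contact_time, contact_radius, geo_sd, missing_rate)
  if (any(rates < 0)) stop("all rates must be nonnegative")
  if (missing_rate >= 1) stop("'missing_rate' must be < 1")
  structure(list(n_families = 3, taxa_per_family = taxa_per_family,
                 yule_rate = yule_rate, n_meanings = n_meanings,
                 innovation_rate = innovation_rate, loss_rate = loss_rate,
                 borrow_rate = borrow_rate, contact_time = contact_time,
                 contact_radius = contact_radius, geo_sd = geo_sd,
                 centroids = centroids, missing_rate = missing_rate,
                 synonym_cap = synonym_cap, seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_borrow_rate <- function() {
  ## donor rows, recipient columns; Khoe-Kwadi the strongest donor,
  ## Tuu the weakest, no within-family transfer by default
  matrix(c(0.0, 3.9, 4.5,
           1.8, 0.0, 2.4,
           6.0, 7.5, 0.0),
         nrow = 3, byrow = TRUE,
         dimnames = list(SAK_FAMILIES, SAK_FAMILIES))
}

#' @rdname sim_config
#' @export
default_centroids <- function() {
  ## km on the simulated plane: Kx'a north-west, Tuu south, Khoe-Kwadi
  ## central/east, overlapping in a central contact zone
  matrix(c(-320, 260,
           -140, -340,
           240, 40),
         nrow = 3, byrow = TRUE,
         dimnames = list(SAK_FAMILIES, c("x", "y")))
}

## presence of each root at each node of one family tree, Dollo-style.
## Returns list(roots = data.frame, tip_presence = matrix roots x tips).
simulate_family_roots <- function(tree, family, config) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root_node <- n_tip + 1L
  edges <- tree$edge
  lens <- tree$edge.length
  n_meanings <- config$n_meanings

  ## ancestral roots: one per meaning at the family proto-language
  ids <- sprintf("%s_m%03d_r01", family, seq_len(n_meanings))
  meaning <- seq_len(n_meanings)
  counter <- rep(1L, n_meanings)
  origin_edge <- rep(0L, n_meanings)   # 0 = present at the root node
  pres <- matrix(FALSE, n_meanings, n_node)
  pres[, root_node] <- TRUE

  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1]
    chi <- edges[e, 2]
    len <- lens[e]
    surv <- stats::runif(nrow(pres)) < exp(-config$loss_rate * len)
    pres[, chi] <- pres[, par] & surv
    ## innovations on this edge: born at a uniform point, must survive the
    ## remainder of the edge to be present at the child
    n_new <- stats::rpois(n_meanings, config$innovation_rate * len)
    tot_new <- sum(n_new)
    if (tot_new > 0) {
      mng <- rep.int(seq_len(n_meanings), n_new)
      born_at <- stats::runif(tot_new) * len
      alive <- stats::runif(tot_new) < exp(-config$loss_rate * (len - born_at))
      counter_new <- counter[mng] + sequence(n_new)
      counter <- counter + n_new
      new_ids <- sprintf("%s_m%03d_r%02d", family, mng, counter_new)
      add <- matrix(FALSE, tot_new, n_node)
      add[, chi] <- alive
      pres <- rbind(pres, add)
      ids <- c(ids, new_ids)
      meaning <- c(meaning, mng)
      origin_edge <- c(origin_edge, rep(e, tot_new))
    }
  }
  tips <- seq_len(n_tip)
  tip_pres <- pres[, tips, drop = FALSE]
  colnames(tip_pres) <- tree$tip.label
  rownames(tip_pres) <- ids
  roots <- data.frame(id = ids, meaning = meaning, family = family,
                      origin_edge = origin_edge,
                      ancestral = origin_edge == 0L,
                      stringsAsFactors = FALSE)
  list(roots = roots, tip_presence = tip_pres)
}

#' Simulate a root matrix with ground-truth borrowing events
#'
#' Runs the full generative model: one Yule tree per family (unit depth),
#' Dollo root innovation and loss along the branches, doculect coordinates
#' scattered around family centroids on a plane, a tip-level contact phase
#' in which borrowing events copy roots from donor to adjacent recipient
#' doculects at the configured donor-by-recipient rates, then missing-data
#' masking. Identical config and seed give byte-identical output.
#'
#' @param config a [sim_config()].
#' @return list with elements `matrix` (a [root_matrix] whose root registry
#'   carries the true origins) and `truth`: trees, coordinates (km),
#'   adjacency, the borrowing event log (`time`, `donor`, `recipient`,
#'   `root_id`, `donor_family`, `recipient_family`), per-root innovation
#'   records, and bookkeeping of roots dropped as never-attested.
#' @export
simulate_root_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  exp_roots <- 3 * config$n_meanings *
    (1 + config$innovation_rate * 8 * max(config$taxa_per_family) / 10)
  if (exp_roots > 1e6)
    stop("configuration would generate >1e6 roots; lower innovation_rate")
  set.seed(config$seed, kind = "Mersenne-Twister", sample.kind = "Rejection")

  fams <- SAK_FAMILIES
  trees <- list()
  fam_sims <- list()
  doc_ids <- c()
  doc_fam <- c()
  for (f in fams) {
    n_f <- config$taxa_per_family[[f]]
    tr <- ape::rphylo(n_f, birth = config$yule_rate, death = 0)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / depth
    tr$tip.label <- sprintf("%s_d%02d", f, seq_len(n_f))
    trees[[f]] <- tr
    fam_sims[[f]] <- simulate_family_roots(tr, f, config)
    doc_ids <- c(doc_ids, tr$tip.label)
    doc_fam <- c(doc_fam, rep(f, n_f))
  }

  ## assemble presence matrix (roots x doculects), vertical inheritance only
  all_roots <- do.call(rbind, lapply(fam_sims, `[[`, "roots"))
  n_roots <- nrow(all_roots)
  pres <- matrix(FALSE, n_roots, length(doc_ids),
                 dimnames = list(all_roots$id, doc_ids))
  for (f in fams) {
    tp <- fam_sims[[f]]$tip_presence
    pres[rownames(tp), colnames(tp)] <- tp
  }

  ## geography
  coords <- matrix(NA_real_, length(doc_ids), 2,
                   dimnames = list(doc_ids, c("x", "y")))
  for (f in fams) {
    sel <- doc_fam == f
    coords[sel, 1] <- config$centroids[f, "x"] +
      stats::rnorm(sum(sel), 0, config$geo_sd)
    coords[sel, 2] <- config$centroids[f, "y"] +
      stats::rnorm(sum(sel), 0, config$geo_sd)
  }
  dkm <- as.matrix(stats::dist(coords))
  adjacency <- dkm <= config$contact_radius
  diag(adjacency) <- FALSE

  ## contact phase: Poisson borrowing events on adjacent cross-family
  ## (donor, recipient) ordered pairs, applied in time order so that a
  ## borrowed root can be passed on within the contact phase
  ev_donor <- ev_recip <- character(0)
  n_ev <- integer(0)
  for (di in seq_along(doc_ids)) for (ri in seq_along(doc_ids)) {
    if (!adjacency[di, ri]) next
    rate <- config$borrow_rate[doc_fam[di], doc_fam[ri]]
    if (rate <= 0) next
    k <- stats::rpois(1, rate * config$contact_time)
    if (k > 0) {
      ev_donor <- c(ev_donor, doc_ids[di])
      ev_recip <- c(ev_recip, doc_ids[ri])
      n_ev <- c(n_ev, k)
    }
  }
  events <- data.frame(
    time = stats::runif(sum(n_ev)) * config$contact_time,
    donor = rep(ev_donor, n_ev),
    recipient = rep(ev_recip, n_ev),
    root_id = rep(NA_character_, sum(n_ev)),
    stringsAsFactors = FALSE)
  events <- events[order(events$time), , drop = FALSE]
  fam_of <- setNames(doc_fam, doc_ids)
  for (i in seq_len(nrow(events))) {
    pool <- which(pres[, events$donor[i]])
    if (!length(pool)) next
    rt <- pool[[sample.int(length(pool), 1)]]
    events$root_id[i] <- rownames(pres)[rt]
    pres[rt, events$recipient[i]] <- TRUE
  }
  events <- events[!is.na(events$root_id), , drop = FALSE]
  events$donor_family <- fam_of[events$donor]
  events$recipient_family <- fam_of[events$recipient]
  rownames(events) <- NULL

  ## optional synonym cap: excess roots for one meaning in one doculect
  ## are dropped (newest first)
  if (is.finite(config$synonym_cap)) {
    for (d in doc_ids) {
      present <- which(pres[, d])
      mg <- all_roots$meaning[present]
      for (m in unique(mg[duplicated(mg)])) {
        rts <- present[mg == m]
        if (length(rts) > config$synonym_cap)
          pres[rts[-seq_len(config$synonym_cap)], d] <- FALSE
      }
    }
  }

  ## state matrix with missing-data masking
  state <- matrix(0L, n_roots, length(doc_ids),
                  dimnames = dimnames(pres))
  state[pres] <- 1L
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(length(state)) < config$missing_rate,
                   nrow(state), ncol(state))
    state[mask] <- NA_integer_
  }
  attested <- rowSums(state == 1L, na.rm = TRUE) > 0
  dropped <- rownames(state)[!attested]
  state <- state[attested, , drop = FALSE]

  ## registries
  clusters <- unlist(lapply(fams, function(f) {
    tr <- trees[[f]]
    k <- max(1L, round(length(tr$tip.label) / 4))
    hc <- stats::hclust(stats::as.dist(stats::cophenetic(tr)), "average")
    ct <- stats::cutree(hc, k = k)
    setNames(sprintf("%s_c%d", f, ct), names(ct))
  }))
  doculects <- data.frame(
    id = doc_ids, name = doc_ids, family = doc_fam,
    subgroup = doc_fam, cluster_id = clusters[doc_ids],
    latitude = coords[, "y"] / KM_PER_DEGREE,
    longitude = coords[, "x"] / KM_PER_DEGREE,
    subsistence = ifelse(doc_fam == "KHOE_KWADI", "herder", "forager"),
    source = "synthetic", stringsAsFactors = FALSE)
  reg <- all_roots[match(rownames(state), all_roots$id), , drop = FALSE]
  roots <- data.frame(
    id = reg$id,
    primary_meaning = sprintf("m%03d", reg$meaning),
    polysemy_meanings = NA_character_,
    bantu_flag = FALSE, complex_flag = FALSE,
    origin = reg$family,
    resolution_level = ifelse(reg$ancestral, paste0("Proto-", reg$family),
                              NA_character_),
    stringsAsFactors = FALSE)
  meanings <- data.frame(id = sprintf("m%03d", seq_len(config$n_meanings)),
                         gloss = sprintf("meaning-%03d", seq_len(config$n_meanings)),
                         swadesh200 = seq_len(config$n_meanings) <= 132,
                         stringsAsFactors = FALSE)
  m <- root_matrix(state, doculects, roots, meanings)
  truth <- list(config = config, trees = trees, coords_km = coords,
                adjacency = adjacency, events = events,
                innovations = all_roots, dropped_roots = dropped,
                origin = setNames(all_roots$family, all_roots$id))
  list(matrix = m, truth = truth)
}

#' Expected number of borrowing events under a configuration
#'
#' Analytic expectation given realised adjacency: the sum over ordered
#' adjacent cross-pairs of `rate * contact_time`. Used to validate the
#' generator against Monte-Carlo replicates.
#'
#' @param config a [sim_config()].
#' @param adjacency realised adjacency matrix (from a simulation's truth).
#' @param families named vector doculect -> family.
#' @return expected event count (numeric).
#' @export
expected_borrow_events <- function(config, adjacency, families) {
  total <- 0
  ids <- rownames(adjacency)
  for (di in seq_along(ids)) for (ri in seq_along(ids)) {
    if (adjacency[di, ri])
      total <- total + config$borrow_rate[families[[ids[di]]],
                                          families[[ids[ri]]]] *
        config$contact_time
  }
  total
}
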