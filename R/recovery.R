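## Validation harness: run the sharing analysis on simulated data and
## compare against the generator's ground truth.

#' Small configuration for replicate-based recovery experiments
#'
#' A scaled-down [sim_config()] (12 doculects, 60 meanings, fewer roots)
#' keeping the default geometry and rate structure, so that hundreds of
#' replicates run in seconds.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_config_small <- function(seed, ...) {
  args <- list(taxa_per_family = c(KXA = 4, TUU = 4, KHOE_KWADI = 4),
               n_meanings = 60, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

#' Replicate configuration for the donor-asymmetry recovery experiment
#'
#' A [sim_config_small()] in which every doculect pair is in contact (so
#' the signal under test is the rate asymmetry, not the contact geometry)
#' and Khoe-Kwadi donates into Tuu at `ratio` times the reverse rate;
#' the other directions are moderate and symmetric.
#'
#' @param seed integer seed.
#' @param ratio donor-asymmetry ratio for the Khoe-Kwadi/Tuu pair.
#' @return a `sim_config`.
#' @export
sim_config_asymmetric <- function(seed, ratio = 5) {
  base <- 0.2
  br <- matrix(c(0, 2 * base, 2 * base,
                 base, 0, base,
                 2 * base, ratio * base, 0), 3, 3, byrow = TRUE,
               dimnames = list(SAK_FAMILIES, SAK_FAMILIES))
  sim_config_small(seed, borrow_rate = br, contact_radius = 800,
                   n_meanings = 100)
}

#' True donor totals from a simulation's event log
#'
#' Number of borrowing events per donor family, counting only events into
#' recipient doculects of another family.
#'
#' @param truth the `truth` element of [simulate_root_matrix()] output.
#' @return named numeric vector over the three families.
#' @export
true_donor_totals <- function(truth) {
  ev <- truth$events
  ev <- ev[ev$donor_family != ev$recipient_family, , drop = FALSE]
  tab <- table(factor(ev$donor_family, levels = SAK_FAMILIES))
  as.numeric(tab) |> setNames(SAK_FAMILIES)
}

#' Run one simulate-analyse-compare replicate
#'
#' Simulates a matrix, runs [detect_shared()] and the proportion
#' estimators, and scores them against ground truth: the inferred donor
#' ordering (families ranked by share of identified borrowings) versus the
#' true event-count ordering, the error in pattern proportions versus the
#' truth computed from the unmasked attestation, and the shared-fraction
#' error.
#'
#' @param config a [sim_config()].
#' @return named list of metrics.
#' @export
recovery_replicate <- function(config) {
  sim <- simulate_root_matrix(config)
  m <- sim$matrix
  rec <- detect_shared(m)
  shared_n <- sum(rec$pattern != "NONE")
  op <- if (shared_n > 0) origin_proportions(rec) else
    setNames(rep(0, 4), c(SAK_FAMILIES, "UNIDENTIFIED"))
  inferred_donor <- op[SAK_FAMILIES]
  truth_donor <- true_donor_totals(sim$truth)
  rank_ok <- identical(order(-inferred_donor), order(-truth_donor))
  top_ok <- names(which.max(inferred_donor)) == names(which.max(truth_donor))
  ## truth sharing fraction from the pre-masking attestation: roots whose
  ## attested doculects (vertical + borrowed) span >= 2 families
  ev <- sim$truth$events
  cross_roots <- unique(ev$root_id[ev$donor_family != ev$recipient_family])
  truth_shared_fraction <- length(intersect(cross_roots,
                                            rownames(m$state))) / nrow(m$state)
  list(n_roots = nrow(m$state),
       n_shared = shared_n,
       shared_fraction = shared_n / nrow(m$state),
       truth_shared_fraction = truth_shared_fraction,
       shared_fraction_error = shared_n / nrow(m$state) - truth_shared_fraction,
       inferred_donor_share = inferred_donor,
       true_donor_events = truth_donor,
       donor_rank_correct = rank_ok,
       donor_top_correct = top_ok)
}

#' Replicated recovery experiment
#'
#' Runs [recovery_replicate()] over `n_reps` seeds derived from `seed`
#' and aggregates: the fraction of replicates in which the inferred donor
#' ordering (and top donor) matches truth, and mean absolute errors.
#'
#' @param n_reps number of replicates.
#' @param seed base seed; replicate r uses `seed + r`.
#' @param config_fn function(seed) returning a `sim_config` (default
#'   [sim_config_small()]).
#' @return list with `per_rep` (data frame) and aggregate metrics.
#' @export
recovery_experiment <- function(n_reps = 100, seed = 1,
                                config_fn = sim_config_small) {
  reps <- lapply(seq_len(n_reps), function(r) recovery_replicate(config_fn(seed + r)))
  per_rep <- data.frame(
    rep = seq_len(n_reps),
    n_shared = vapply(reps, `[[`, numeric(1), "n_shared"),
    shared_fraction = vapply(reps, `[[`, numeric(1), "shared_fraction"),
    shared_fraction_error = vapply(reps, `[[`, numeric(1),
                                   "shared_fraction_error"),
    donor_rank_correct = vapply(reps, `[[`, logical(1), "donor_rank_correct"),
    donor_top_correct = vapply(reps, `[[`, logical(1), "donor_top_correct"))
  list(per_rep = per_rep,
       donor_rank_accuracy = mean(per_rep$donor_rank_correct),
       donor_top_accuracy = mean(per_rep$donor_top_correct),
       mean_abs_shared_fraction_error = mean(abs(per_rep$shared_fraction_error)),
       mean_shared_fraction = mean(per_rep$shared_fraction))
}
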