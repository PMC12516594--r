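## Criteria-based attribution of the family of origin of a shared root.
##
## The linguistic judgements themselves (is the root reconstructable in
## family F? does its phonology violate F's sound laws?) are expert input;
## this module only formalises how coded judgements combine into an origin
## call, with the combination policy pluggable.

PRIMARY_CRITERIA <- c("RECONSTRUCTABILITY", "ATTESTATION_SCOPE", "PHONOLOGY",
                      "MORPH_ANALYSABILITY")
SECONDARY_CRITERIA <- c("LEXICAL_ALTERNATIVES", "GEOGRAPHY", "CULTURE",
                        "PARSIMONY")
CRITERION_VALUES <- c("SUPPORTS", "CONTRADICTS", "NEUTRAL", "NA")

#' Default policy for combining criterion evidence into an origin call
#'
#' The policy holds the criterion inventory (four named primary criteria —
#' reconstructability, scope of attestation, phonology, morphological
#' analysability — and four secondary ones — lexical alternatives,
#' geography, culture, historical parsimony; extra user-declared criteria
#' may be appended to either class) and the combination rule parameters.
#' The default rule: a family's primary score is its number of SUPPORTS
#' minus CONTRADICTS over primary criteria; the unique family with the
#' maximal primary score of at least `min_primary_score` wins outright if
#' no rival family has any primary SUPPORTS; otherwise the secondary score
#' must break the tie (the top family wins only if its secondary score
#' strictly exceeds every other contender's); otherwise the origin is
#' `UNIDENTIFIED`.
#'
#' @param primary,secondary criterion name vectors.
#' @param min_primary_score minimum primary score for a decided origin.
#' @return a `origin_policy` object.
#' @export
origin_policy <- function(primary = PRIMARY_CRITERIA,
                          secondary = SECONDARY_CRITERIA,
                          min_primary_score = 1) {
  if (length(intersect(primary, secondary)))
    stop("a criterion cannot be both primary and secondary")
  structure(list(primary = primary, secondary = secondary,
                 min_primary_score = min_primary_score),
            class = "origin_policy")
}

#' Read a combination policy from a YAML config file
#'
#' Keys: `primary`, `secondary` (criterion name lists) and
#' `min_primary_score`. Missing keys fall back to the defaults of
#' [origin_policy()].
#'
#' @param path YAML file.
#' @return an `origin_policy`.
#' @export
read_origin_policy <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), c("primary", "secondary", "min_primary_score"))
  if (length(unknown))
    stop("unknown policy key(s): ", paste(unknown, collapse = ", "))
  origin_policy(
    primary = if (!is.null(cfg$primary)) unlist(cfg$primary) else PRIMARY_CRITERIA,
    secondary = if (!is.null(cfg$secondary)) unlist(cfg$secondary)
    else SECONDARY_CRITERIA,
    min_primary_score = cfg$min_primary_score %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a long-format criterion-evidence table
#'
#' Expected columns: `root_id`, `family`, `criterion`, `value` with
#' `value` in SUPPORTS / CONTRADICTS / NEUTRAL / NA. Cells not stated in
#' the file are filled with `"NA"` so that every criterion is valued for
#' every (root, family) pair under evaluation.
#'
#' @param path TSV file.
#' @param policy an `origin_policy` (fixes the criterion inventory).
#' @return data frame of evidence with one row per
#'   root x family x criterion.
#' @export
load_evidence <- function(path, policy = origin_policy()) {
  ev <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   fileEncoding = "UTF-8", na.strings = character(0))
  need <- c("root_id", "family", "criterion", "value")
  if (!all(need %in% names(ev)))
    stop("evidence table needs columns: ", paste(need, collapse = ", "))
  inventory <- c(policy$primary, policy$secondary)
  bad <- setdiff(unique(ev$criterion), inventory)
  if (length(bad))
    stop("unknown criterion name(s): ", paste(bad, collapse = ", "))
  bad_v <- setdiff(unique(ev$value), CRITERION_VALUES)
  if (length(bad_v))
    stop("unknown criterion value(s): ", paste(bad_v, collapse = ", "))
  bad_f <- setdiff(unique(ev$family), SAK_FAMILIES)
  if (length(bad_f))
    stop("unknown family in evidence: ", paste(bad_f, collapse = ", "))
  full <- expand.grid(root_id = unique(ev$root_id),
                      family = unique(ev$family),
                      criterion = inventory,
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$root_id, d$family, d$criterion, sep = "\r")
  if (anyDuplicated(key(ev)))
    stop("duplicate evidence rows for the same root/family/criterion")
  full$value <- ev$value[match(key(full), key(ev))]
  full$value[is.na(full$value)] <- "NA"
  full[order(full$root_id, full$family, full$criterion), , drop = FALSE]
}

score_family <- function(ev_fam, criteria) {
  v <- ev_fam$value[ev_fam$criterion %in% criteria]
  sum(v == "SUPPORTS") - sum(v == "CONTRADICTS")
}

#' Decide the origin family for one root from its criterion evidence
#'
#' Applies the combination policy (see [origin_policy()]) to the evidence
#' rows of a single root, covering at least two candidate families. The
#' returned trace lists every applied rule, so the decision is reproducible
#' from evidence plus policy alone.
#'
#' @param evidence evidence rows (as from [load_evidence()]) for one root.
#' @param policy an `origin_policy`.
#' @return list with `root_id`, `origin` (family code or `"UNIDENTIFIED"`)
#'   and `trace` (character vector of applied rules).
#' @export
decide_origin <- function(evidence, policy = origin_policy()) {
  root_id <- unique(evidence$root_id)
  if (length(root_id) != 1) stop("evidence must concern exactly one root")
  fams <- sort(unique(evidence$family))
  if (length(fams) < 2)
    stop("origin decision needs evidence for at least 2 candidate families")
  per_crit <- table(evidence$family, evidence$criterion)
  if (any(per_crit != 1))
    stop("incomplete evidence grid for root ", root_id,
         " (run load_evidence to fill NA)")
  pscore <- vapply(fams, function(f)
    score_family(evidence[evidence$family == f, ], policy$primary), numeric(1))
  psupp <- vapply(fams, function(f)
    sum(evidence$family == f & evidence$criterion %in% policy$primary &
          evidence$value == "SUPPORTS"), numeric(1))
  sscore <- vapply(fams, function(f)
    score_family(evidence[evidence$family == f, ], policy$secondary),
    numeric(1))
  trace <- sprintf("primary scores: %s",
                   paste(sprintf("%s=%+d", fams, pscore), collapse = " "))
  maxp <- max(pscore)
  if (maxp < policy$min_primary_score) {
    trace <- c(trace, sprintf("no family reaches primary score >= %d -> UNIDENTIFIED",
                              policy$min_primary_score))
    return(list(root_id = root_id, origin = "UNIDENTIFIED", trace = trace))
  }
  top <- fams[pscore == maxp]
  rivals_with_support <- fams[psupp > 0 & !(fams %in% top)]
  if (length(top) == 1 && length(rivals_with_support) == 0) {
    trace <- c(trace, sprintf(
      "unique primary winner %s with no rival primary support", top))
    return(list(root_id = root_id, origin = top, trace = trace))
  }
  contenders <- union(top, fams[psupp > 0])
  ss <- sscore[contenders]
  trace <- c(trace, sprintf("primary contest unresolved (contenders: %s); secondary scores: %s",
                            paste(contenders, collapse = ","),
                            paste(sprintf("%s=%+d", contenders, ss), collapse = " ")))
  best <- contenders[ss == max(ss)]
  if (length(best) == 1 && best %in% top) {
    trace <- c(trace, sprintf("secondary tie-break -> %s", best))
    return(list(root_id = root_id, origin = best, trace = trace))
  }
  trace <- c(trace, "secondary evidence does not break the tie -> UNIDENTIFIED")
  list(root_id = root_id, origin = "UNIDENTIFIED", trace = trace)
}

#' Decide origins for every root in an evidence set
#'
#' One decision per root; when gold origin annotations are supplied an
#' agreement report is attached.
#'
#' @param evidence full evidence table from [load_evidence()].
#' @param policy an `origin_policy`.
#' @param gold optional named character vector root id -> annotated origin.
#' @return data frame with `root_id`, `origin`, `trace` (collapsed with
#'   `"; "`); when `gold` is given, attribute `"agreement"` holds the
#'   agreement fraction and the disagreeing root ids.
#' @export
batch_decide <- function(evidence, policy = origin_policy(), gold = NULL) {
  ids <- unique(evidence$root_id)
  dec <- lapply(ids, function(r)
    decide_origin(evidence[evidence$root_id == r, , drop = FALSE], policy))
  out <- data.frame(
    root_id = vapply(dec, `[[`, character(1), "root_id"),
    origin = vapply(dec, `[[`, character(1), "origin"),
    trace = vapply(dec, function(d) paste(d$trace, collapse = "; "),
                   character(1)),
    stringsAsFactors = FALSE)
  if (!is.null(gold)) {
    common <- intersect(out$root_id, names(gold))
    agree <- out$origin[match(common, out$root_id)] == gold[common]
    attr(out, "agreement") <- list(
      n = length(common),
      fraction = if (length(common)) mean(agree) else NA_real_,
      disagreements = common[!agree])
  }
  out
}
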