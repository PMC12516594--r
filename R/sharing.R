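## Cross-family sharing and borrowing profiles.

SHARING_PATTERNS <- c("KXA_TUU_KK", "KXA_KK", "TUU_KK", "KXA_TUU", "NONE")

pattern_of <- function(fams) {
  has <- SAK_FAMILIES %in% fams
  if (sum(has) < 2) return("NONE")
  if (all(has)) return("KXA_TUU_KK")
  if (has[1] && has[3]) return("KXA_KK")
  if (has[2] && has[3]) return("TUU_KK")
  "KXA_TUU"
}

#' Detect roots shared between language families
#'
#' For every root, collects the set of families in which it is attested
#' (present states only — a missing state never counts as attestation) and
#' classifies its cross-family sharing pattern: all three families, one of
#' the three two-family combinations, or `NONE` when fewer than two
#' families attest the root.
#'
#' @param m a [root_matrix].
#' @return data frame (one row per root) with columns `root_id`, `pattern`,
#'   `n_families`, `families` (comma-separated), `origin`,
#'   `resolution_level`, `n_doculects`, and a list column `doculects` of
#'   attesting doculect ids.
#' @export
detect_shared <- function(m) {
  fams <- doculect_families(m)
  pres <- !is.na(m$state) & m$state == 1L
  att_fams <- apply(pres, 1, function(p) unique(fams[p]), simplify = FALSE)
  data.frame(
    root_id = rownames(m$state),
    pattern = vapply(att_fams, pattern_of, character(1)),
    n_families = lengths(att_fams),
    families = vapply(att_fams, function(f)
      paste(SAK_FAMILIES[SAK_FAMILIES %in% f], collapse = ","), character(1)),
    origin = m$roots$origin,
    resolution_level = m$roots$resolution_level,
    n_doculects = rowSums(pres),
    doculects = I(apply(pres, 1, function(p) names(which(p)),
                        simplify = FALSE)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Proportion of shared roots in each sharing pattern
#'
#' Fractions over the shared roots (pattern != `NONE`); they sum to 1.
#'
#' @param records output of [detect_shared()].
#' @return named numeric vector over the four sharing patterns.
#' @export
pattern_proportions <- function(records) {
  shared <- records[records$pattern != "NONE", , drop = FALSE]
  if (nrow(shared) == 0) {
    warning("no shared roots; returning empty proportions")
    return(setNames(numeric(0), character(0)))
  }
  tab <- table(factor(shared$pattern, levels = setdiff(SHARING_PATTERNS, "NONE")))
  tab / nrow(shared)
}

#' Proportion of shared roots by family of origin
#'
#' Fractions of shared roots that originated in each family, or whose
#' origin remained `UNIDENTIFIED`; they sum to 1. Shared roots must carry
#' an origin annotation.
#'
#' @param records output of [detect_shared()].
#' @return named numeric vector over `KXA`, `TUU`, `KHOE_KWADI`,
#'   `UNIDENTIFIED`.
#' @export
origin_proportions <- function(records) {
  shared <- records[records$pattern != "NONE", , drop = FALSE]
  un <- shared$root_id[shared$origin == "UNANNOTATED"]
  if (length(un))
    stop("shared root(s) lack an origin annotation: ",
         paste(utils::head(un, 10), collapse = ", "))
  tab <- table(factor(shared$origin,
                      levels = c(SAK_FAMILIES, "UNIDENTIFIED")))
  tab / nrow(shared)
}

#' Per-doculect sharing, borrowing and donation fractions
#'
#' All fractions have as denominator the number of roots present in the
#' doculect. For a doculect of family F, a present root is:
#' \describe{
#'   \item{borrowed}{shared (pattern != NONE) with origin in another
#'     family — a loanword in this doculect;}
#'   \item{donated}{shared with origin = F — transferred from the
#'     doculect's own family to others;}
#'   \item{unresolved_shared}{shared with origin UNIDENTIFIED;}
#'   \item{unshared}{attested in one family only.}
#' }
#' The four fractions sum to 1.
#'
#' @param m a [root_matrix].
#' @param records output of [detect_shared()] for `m`.
#' @param d a doculect id.
#' @param denominator `"attested"` (default: roots present in the doculect)
#'   or `"all"` (all roots in the data set).
#' @return named list: `n_present`, `shared`, `borrowed`, `donated`,
#'   `unresolved_shared`, `unshared`, `by_pattern` (named vector),
#'   `borrowed_by_donor` (donor family -> fraction) and
#'   `borrowed_by_donor_level` (data frame donor family x resolution
#'   level).
#' @export
doculect_fractions <- function(m, records, d,
                               denominator = c("attested", "all")) {
  denominator <- match.arg(denominator)
  if (!d %in% colnames(m$state)) stop("unknown doculect: ", d)
  fam <- doculect_families(m)[[d]]
  pres <- !is.na(m$state[, d]) & m$state[, d] == 1L
  n_present <- sum(pres)
  if (n_present == 0)
    stop("doculect '", d, "' has no attested roots; fractions undefined")
  denom <- if (denominator == "attested") n_present else nrow(m$state)
  rec <- records[match(rownames(m$state), records$root_id), , drop = FALSE]
  shared <- pres & rec$pattern != "NONE"
  if (any(shared & rec$origin == "UNANNOTATED"))
    stop("shared root(s) present in '", d, "' lack origin annotations")
  borrowed <- shared & rec$origin %in% SAK_FAMILIES & rec$origin != fam
  donated <- shared & rec$origin == fam
  unresolved <- shared & rec$origin == "UNIDENTIFIED"
  by_pattern <- vapply(setdiff(SHARING_PATTERNS, "NONE"), function(p)
    sum(pres & rec$pattern == p) / denom, numeric(1))
  donors <- setdiff(SAK_FAMILIES, fam)
  by_donor <- vapply(donors, function(f)
    sum(borrowed & rec$origin == f) / denom, numeric(1))
  bl <- rec[borrowed, c("origin", "resolution_level")]
  bl$resolution_level[is.na(bl$resolution_level)] <- "(unspecified)"
  by_level <- as.data.frame(table(donor = bl$origin, level = bl$resolution_level),
                            stringsAsFactors = FALSE)
  by_level <- by_level[by_level$Freq > 0, , drop = FALSE]
  by_level$fraction <- by_level$Freq / denom
  list(doculect = d, family = fam, n_present = n_present,
       denominator = denom,
       shared = sum(shared) / denom,
       borrowed = sum(borrowed) / denom,
       donated = sum(donated) / denom,
       unresolved_shared = sum(unresolved) / denom,
       unshared = sum(pres & rec$pattern == "NONE") / denom,
       by_pattern = by_pattern,
       borrowed_by_donor = by_donor,
       borrowed_by_donor_level = by_level)
}

#' Aggregate doculect fractions into a language-cluster profile
#'
#' Per-doculect fractions are computed for every member and averaged —
#' unweighted by default, mirroring percentages-per-doculect averaged
#' across the doculects forming a language cluster.
#'
#' @param m a [root_matrix].
#' @param records output of [detect_shared()].
#' @param cluster_id cluster id (matched against `m$doculects$cluster_id`),
#'   or a character vector of member doculect ids.
#' @param weighted if `TRUE`, weight member doculects by their attested
#'   root count instead of equally.
#' @param denominator passed to [doculect_fractions()].
#' @return named list mirroring [doculect_fractions()] plus `members`,
#'   `max_member_shared` and the per-member rows in `member_fractions`.
#' @export
cluster_profile <- function(m, records, cluster_id, weighted = FALSE,
                            denominator = "attested") {
  members <- if (all(cluster_id %in% colnames(m$state)) &&
                 !any(cluster_id %in% m$doculects$cluster_id)) cluster_id
  else m$doculects$id[!is.na(m$doculects$cluster_id) &
                        m$doculects$cluster_id %in% cluster_id]
  if (!length(members)) stop("cluster '", cluster_id, "' has no members")
  fr <- lapply(members, function(d)
    doculect_fractions(m, records, d, denominator = denominator))
  wts <- if (weighted) vapply(fr, `[[`, numeric(1), "n_present")
  else rep(1, length(fr))
  wts <- wts / sum(wts)
  avg <- function(field) sum(vapply(fr, `[[`, numeric(1), field) * wts)
  avg_vec <- function(field) {
    v <- vapply(fr, `[[`, numeric(length(fr[[1]][[field]])), field)
    if (is.null(dim(v))) v <- matrix(v, nrow = 1,
                                     dimnames = list(names(fr[[1]][[field]])))
    drop(v %*% wts)
  }
  fams <- unique(vapply(fr, `[[`, character(1), "family"))
  if (length(fams) != 1)
    stop("cluster members span more than one family")
  list(cluster_id = if (is.character(cluster_id) && length(cluster_id) == 1)
    cluster_id else paste(members, collapse = "+"),
    family = fams, members = members,
    shared = avg("shared"), borrowed = avg("borrowed"),
    donated = avg("donated"),
    unresolved_shared = avg("unresolved_shared"),
    unshared = avg("unshared"),
    by_pattern = avg_vec("by_pattern"),
    borrowed_by_donor = avg_vec("borrowed_by_donor"),
    max_member_shared = max(vapply(fr, `[[`, numeric(1), "shared")),
    member_fractions = fr)
}

#' Profiles for every language cluster in the metadata
#'
#' @param m a [root_matrix].
#' @param records output of [detect_shared()].
#' @param ... passed to [cluster_profile()].
#' @return data frame, one row per cluster, with the headline fractions and
#'   pattern/donor breakdown columns.
#' @export
all_cluster_profiles <- function(m, records, ...) {
  ids <- unique(m$doculects$cluster_id[!is.na(m$doculects$cluster_id)])
  profs <- lapply(ids, function(cl) cluster_profile(m, records, cl, ...))
  do.call(rbind, lapply(profs, function(p) {
    row <- data.frame(cluster_id = p$cluster_id, family = p$family,
                      n_members = length(p$members),
                      shared = p$shared, borrowed = p$borrowed,
                      donated = p$donated,
                      unresolved_shared = p$unresolved_shared,
                      unshared = p$unshared,
                      max_member_shared = p$max_member_shared,
                      stringsAsFactors = FALSE)
    for (nm in names(p$by_pattern)) row[[paste0("pat_", nm)]] <- p$by_pattern[[nm]]
    for (nm in SAK_FAMILIES)   # borrowing from one's own family is 0 by definition
      row[[paste0("from_", nm)]] <-
        if (nm %in% names(p$borrowed_by_donor)) p$borrowed_by_donor[[nm]] else 0
    row
  }))
}

#' Decompose loanwords by donor family and proto-level resolution
#'
#' Borrowings (shared roots with an identified origin) are grouped by donor
#' family and by the deepest proto-node within the donor family to which
#' the root reconstructs (e.g. Proto-Khoe vs Proto-Khoekhoe for Khoe-Kwadi
#' donors), optionally restricted to the loanwords attested in a recipient
#' scope.
#'
#' @param records output of [detect_shared()].
#' @param recipient_families optional character vector: only count roots as
#'   loanwords with respect to these recipient families (the donor family
#'   itself is always excluded as recipient).
#' @param level_inventory optional named list, family -> allowed proto-node
#'   labels; when given, a resolution level recorded under the wrong donor
#'   family raises an integrity error.
#' @return data frame with columns `donor`, `level`, `count`, `fraction`
#'   (fraction within the donor family's loanwords).
#' @export
resolution_decomposition <- function(records, recipient_families = NULL,
                                     level_inventory = NULL) {
  if (!is.null(level_inventory)) {
    ann <- records[records$origin %in% SAK_FAMILIES &
                     !is.na(records$resolution_level), , drop = FALSE]
    bad <- !mapply(function(lv, or) lv %in% level_inventory[[or]],
                   ann$resolution_level, ann$origin)
    if (any(bad))
      stop("resolution level inconsistent with donor family for root(s): ",
           paste(utils::head(ann$root_id[bad], 10), collapse = ", "))
  }
  shared <- records[records$pattern != "NONE" &
                      records$origin %in% SAK_FAMILIES, , drop = FALSE]
  if (!is.null(recipient_families)) {
    keep <- vapply(seq_len(nrow(shared)), function(i) {
      fams <- strsplit(shared$families[i], ",")[[1]]
      any(setdiff(fams, shared$origin[i]) %in% recipient_families)
    }, logical(1))
    shared <- shared[keep, , drop = FALSE]
  }
  if (!nrow(shared))
    return(data.frame(donor = character(0), level = character(0),
                      count = integer(0), fraction = numeric(0)))
  lvl <- shared$resolution_level
  lvl[is.na(lvl)] <- "(unspecified)"
  tab <- as.data.frame(table(donor = shared$origin, level = lvl),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  names(tab)[names(tab) == "Freq"] <- "count"
  per_donor <- tapply(tab$count, tab$donor, sum)
  tab$fraction <- tab$count / as.numeric(per_donor[tab$donor])
  rownames(tab) <- NULL
  tab[order(tab$donor, -tab$count), , drop = FALSE]
}
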