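## Classification of shared roots with unidentified origin into
## distant / areal / outlier sharing, from the geography of the attesting
## doculects.

#' Adjacency between doculects from coordinates or an explicit pair list
#'
#' Two doculects are adjacent when their great-circle distance is at most
#' `radius_km` (default 250 km). An explicit pair list overrides the
#' radius rule entirely, since "close geographic proximity" is ultimately
#' a qualitative judgement.
#'
#' @param doculects doculect metadata data frame (`id`, `latitude`,
#'   `longitude`).
#' @param pairs optional two-column matrix/data frame of doculect id pairs
#'   to treat as adjacent (symmetric closure is taken).
#' @param radius_km great-circle cutoff in kilometres.
#' @param planar if `TRUE`, coordinates are interpreted as x/y kilometres
#'   on a plane (used for synthetic data) instead of lon/lat degrees.
#' @return symmetric logical matrix with doculect ids as dimnames.
#' @export
doculect_adjacency <- function(doculects, pairs = NULL, radius_km = 250,
                               planar = FALSE) {
  ids <- doculects$id
  adj <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    for (k in seq_len(nrow(pairs))) {
      adj[pairs[k, 1], pairs[k, 2]] <- TRUE
      adj[pairs[k, 2], pairs[k, 1]] <- TRUE
    }
    return(adj)
  }
  if (any(is.na(doculects$latitude)) || any(is.na(doculects$longitude)))
    stop("doculect coordinates missing; supply an explicit adjacency pair list")
  if (planar) {
    dk <- as.matrix(stats::dist(cbind(doculects$longitude,
                                      doculects$latitude)))
  } else {
    dk <- geosphere::distm(cbind(doculects$longitude, doculects$latitude),
                           fun = geosphere::distHaversine) / 1000
  }
  adj[] <- dk <= radius_km
  diag(adj) <- FALSE
  adj
}

#' Classify unresolved shared roots as distant, areal or outlier sharing
#'
#' Applies only to shared roots whose origin is `UNIDENTIFIED`. For each,
#' the attesting doculects are examined under an adjacency relation:
#' \describe{
#'   \item{DISTANT}{the root reconstructs to proto-level in two or more
#'     families, or the attesting doculects fall into geographically
#'     unconnected units — evidence for inheritance from a distant common
#'     ancestor or ancient contact;}
#'   \item{AREAL}{the attesting doculects form a single connected
#'     neighbourhood under the adjacency relation — sharing between
#'     neighbours in close geographic proximity;}
#'   \item{OUTLIER}{the attestation is scattered as three or more
#'     mutually isolated single doculects across the area — an
#'     unresolvable setting.}
#' }
#'
#' @param records output of [detect_shared()].
#' @param doculects doculect metadata.
#' @param adjacency adjacency matrix from [doculect_adjacency()]; built
#'   from coordinates at `radius_km` if omitted.
#' @param radius_km,planar passed to [doculect_adjacency()] when
#'   `adjacency` is missing.
#' @param proto_families optional named integer vector (root id -> number
#'   of families in which the root reconstructs to proto-level); counts of
#'   2 or more force `DISTANT`.
#' @param patterns restrict to these sharing patterns (default: the
#'   Kx'a+Tuu-involving patterns, the unresolved roots of interest).
#' @return data frame with columns `root_id`, `category`, `n_components`.
#' @export
classify_unresolved <- function(records, doculects, adjacency = NULL,
                                radius_km = 250, planar = FALSE,
                                proto_families = NULL,
                                patterns = c("KXA_TUU", "KXA_TUU_KK")) {
  if (is.null(adjacency))
    adjacency <- doculect_adjacency(doculects, radius_km = radius_km,
                                    planar = planar)
  unres <- records[records$origin == "UNIDENTIFIED" &
                     records$pattern %in% patterns, , drop = FALSE]
  if (!nrow(unres))
    return(data.frame(root_id = character(0), category = character(0),
                      n_components = integer(0)))
  out <- lapply(seq_len(nrow(unres)), function(i) {
    docs <- unres$doculects[[i]]
    docs <- intersect(docs, rownames(adjacency))
    comp <- graph_components(adjacency[docs, docs, drop = FALSE])
    ncomp <- max(comp)
    proto_n <- if (!is.null(proto_families))
      proto_families[[unres$root_id[i]]] else 0L
    category <- if (!is.null(proto_n) && isTRUE(proto_n >= 2)) "DISTANT"
    else if (ncomp == 1L) "AREAL"
    else if (ncomp >= 3L && all(tabulate(comp) == 1L)) "OUTLIER"
    else "DISTANT"
    data.frame(root_id = unres$root_id[i], category = category,
               n_components = ncomp, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## connected components of an undirected adjacency matrix; returns integer
## component labels
graph_components <- function(adj) {
  n <- nrow(adj)
  if (n == 0) return(integer(0))
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Write the full set of sharing-analysis report tables
#'
#' Emits deterministic TSV tables (sharing records, pattern and origin
#' proportions, cluster profiles, resolution decomposition, unresolved
#' classification, per-cluster coordinates) plus a JSON summary of the
#' headline statistics.
#'
#' @param m a [root_matrix].
#' @param records output of [detect_shared()].
#' @param out_dir output directory (created if needed).
#' @param unresolved optional output of [classify_unresolved()].
#' @return invisibly, named character vector of files written.
#' @export
write_sharing_report <- function(m, records, out_dir, unresolved = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    paths[[name]] <<- p
    p
  }
  rec_flat <- records
  rec_flat$doculects <- vapply(records$doculects, paste, character(1),
                               collapse = ",")
  wt(rec_flat, "sharing_records.tsv")
  any_shared <- any(records$pattern != "NONE")
  none <- setNames(numeric(0), character(0))
  pp <- if (any_shared) pattern_proportions(records) else none
  wt(data.frame(pattern = names(pp), fraction = as.numeric(pp)),
     "pattern_proportions.tsv")
  op <- if (any_shared) origin_proportions(records) else none
  wt(data.frame(origin = names(op), fraction = as.numeric(op)),
     "origin_proportions.tsv")
  prof <- all_cluster_profiles(m, records)
  wt(prof, "cluster_profiles.tsv")
  wt(resolution_decomposition(records), "resolution_decomposition.tsv")
  if (!is.null(unresolved)) wt(unresolved, "unresolved_classification.tsv")
  coords <- m$doculects[, c("id", "family", "cluster_id", "latitude",
                            "longitude")]
  wt(coords, "doculect_coordinates.tsv")
  shared_n <- sum(records$pattern != "NONE")
  summary <- list(
    n_roots = nrow(m$state),
    n_doculects = ncol(m$state),
    n_shared = shared_n,
    shared_fraction = shared_n / nrow(m$state),
    pattern_proportions = as.list(pp),
    origin_proportions = as.list(op),
    n_unresolved = sum(records$pattern != "NONE" &
                         records$origin == "UNIDENTIFIED"),
    n_unresolved_kxa_tuu = sum(records$origin == "UNIDENTIFIED" &
                                 records$pattern %in% c("KXA_TUU", "KXA_TUU_KK")))
  if (!is.null(unresolved))
    summary$unresolved_categories <- as.list(table(unresolved$category))
  p <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths[["summary.json"]] <- p
  invisible(unlist(paths))
}
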