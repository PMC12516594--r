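#' @importFrom stats setNames rpois runif rbinom
#' @importFrom utils read.delim write.table
NULL

#' The three language families of the southern African "Khoisan" area
#'
#' Canonical family codes used throughout the package: `KXA` (Kx'a), `TUU`
#' (Tuu) and `KHOE_KWADI` (Khoe-Kwadi). Origin annotations may additionally
#' take the values `UNIDENTIFIED` (shared root whose donor family could not
#' be determined) and `UNANNOTATED` (no origin judgement recorded).
#'
#' @format Character vector of length 3.
#' @export
SAK_FAMILIES <- c("KXA", "TUU", "KHOE_KWADI")

#' @rdname SAK_FAMILIES
#' @export
ORIGIN_LEVELS <- c(SAK_FAMILIES, "UNIDENTIFIED", "UNANNOTATED")

## ---------------------------------------------------------------------------
## root_matrix class
## ---------------------------------------------------------------------------

#' Construct a root-by-doculect presence/absence matrix
#'
#' The `root_matrix` is the single source of truth for all downstream counts:
#' an integer matrix with one row per lexical root (cognate set) and one
#' column per doculect, with states coded `1` (present), `0` (absent) and
#' `NA` (no information, written `?` on disk). Synonymy is allowed — several
#' roots may be present for one meaning in one doculect — but each root
#' occurs only once in the data set, filed under its cross-linguistically
#' most widespread meaning.
#'
#' @param state integer or numeric matrix of 0/1/NA with rownames (root ids)
#'   and colnames (doculect ids).
#' @param doculects data frame with columns `id`, `family` and optionally
#'   `name`, `subgroup`, `cluster_id`, `latitude`, `longitude`,
#'   `subsistence`, `source`. Row per doculect; must cover every matrix
#'   column.
#' @param roots data frame with columns `id` and optionally
#'   `primary_meaning`, `polysemy_meanings` (comma-separated meaning ids),
#'   `bantu_flag`, `complex_flag`, `origin`, `resolution_level`. Missing
#'   annotation columns are filled with defaults (`origin = "UNANNOTATED"`).
#'   If `NULL`, a minimal registry is created from the matrix rownames.
#' @param meanings optional data frame with columns `id`, `gloss`,
#'   `swadesh200`.
#' @param require_present when `TRUE`, validation fails unless every root
#'   is present in at least one doculect (the invariant expected of a
#'   final analysis matrix); `FALSE` (default) admits intermediate
#'   matrices, e.g. freshly read files before filtering.
#'
#' @return An object of class `root_matrix`: a list with elements `state`,
#'   `doculects`, `roots`, `meanings`.
#' @export
root_matrix <- function(state, doculects, roots = NULL, meanings = NULL,
                        require_present = FALSE) {
  if (!is.matrix(state)) stop("'state' must be a matrix")
  storage.mode(state) <- "integer"
  if (is.null(rownames(state)) || is.null(colnames(state)))
    stop("'state' must have root ids as rownames and doculect ids as colnames")
  bad <- !(state %in% c(0L, 1L, NA_integer_))
  if (any(bad, na.rm = TRUE))
    stop("matrix states must be 0, 1 or NA ('?')")
  if (anyDuplicated(rownames(state)))
    stop("duplicate root id: ",
         paste(unique(rownames(state)[duplicated(rownames(state))]), collapse = ", "))
  if (anyDuplicated(colnames(state)))
    stop("duplicate doculect id in matrix header")

  doculects <- as.data.frame(doculects, stringsAsFactors = FALSE)
  if (!all(c("id", "family") %in% names(doculects)))
    stop("doculect metadata needs at least columns 'id' and 'family'")
  missing_doc <- setdiff(colnames(state), doculects$id)
  if (length(missing_doc))
    stop("doculect(s) in matrix absent from metadata: ",
         paste(missing_doc, collapse = ", "))
  doculects <- doculects[match(colnames(state), doculects$id), , drop = FALSE]
  rownames(doculects) <- NULL
  bad_fam <- setdiff(unique(doculects$family), SAK_FAMILIES)
  if (length(bad_fam))
    stop("unknown family code(s): ", paste(bad_fam, collapse = ", "),
         " (expected ", paste(SAK_FAMILIES, collapse = "/"), ")")
  for (col in c("name", "subgroup", "cluster_id", "subsistence", "source"))
    if (is.null(doculects[[col]])) doculects[[col]] <- NA_character_
  for (col in c("latitude", "longitude"))
    if (is.null(doculects[[col]])) doculects[[col]] <- NA_real_
  ok_lat <- is.na(doculects$latitude) |
    (doculects$latitude >= -90 & doculects$latitude <= 90)
  ok_lon <- is.na(doculects$longitude) |
    (doculects$longitude >= -180 & doculects$longitude <= 180)
  if (!all(ok_lat) || !all(ok_lon)) stop("invalid coordinates in metadata")

  if (is.null(roots)) {
    roots <- data.frame(id = rownames(state), stringsAsFactors = FALSE)
  } else {
    roots <- as.data.frame(roots, stringsAsFactors = FALSE)
    if (is.null(roots$id)) stop("root registry needs an 'id' column")
    if (anyDuplicated(roots$id)) stop("duplicate root id in registry")
    missing_r <- setdiff(rownames(state), roots$id)
    if (length(missing_r))
      stop("root(s) in matrix absent from registry: ",
           paste(utils::head(missing_r, 5), collapse = ", "))
    roots <- roots[match(rownames(state), roots$id), , drop = FALSE]
    rownames(roots) <- NULL
  }
  if (is.null(roots$primary_meaning)) roots$primary_meaning <- NA_character_
  if (is.null(roots$polysemy_meanings)) roots$polysemy_meanings <- NA_character_
  for (col in c("bantu_flag", "complex_flag"))
    if (is.null(roots[[col]])) roots[[col]] <- FALSE else
      roots[[col]] <- as.logical(roots[[col]])
  if (is.null(roots$origin)) roots$origin <- "UNANNOTATED"
  bad_or <- setdiff(unique(roots$origin), ORIGIN_LEVELS)
  if (length(bad_or))
    stop("unknown origin value(s): ", paste(bad_or, collapse = ", "))
  if (is.null(roots$resolution_level)) roots$resolution_level <- NA_character_

  if (require_present) {
    n_pres <- rowSums(state == 1L, na.rm = TRUE)
    if (any(n_pres == 0))
      stop("root(s) present in no doculect: ",
           paste(utils::head(rownames(state)[n_pres == 0], 5), collapse = ", "))
  }

  if (!is.null(meanings)) {
    meanings <- as.data.frame(meanings, stringsAsFactors = FALSE)
    if (anyDuplicated(meanings$gloss[!is.na(meanings$gloss)]))
      stop("meaning glosses must be unique")
  }

  structure(list(state = state, doculects = doculects, roots = roots,
                 meanings = meanings),
            class = "root_matrix")
}

#' @export
print.root_matrix <- function(x, ...) {
  fam <- table(x$doculects$family)
  cat(sprintf("root_matrix: %d roots x %d doculects\n",
              nrow(x$state), ncol(x$state)))
  cat("  families:", paste(sprintf("%s=%d", names(fam), fam), collapse = ", "), "\n")
  cat(sprintf("  states: %d present, %d absent, %d missing\n",
              sum(x$state == 1L, na.rm = TRUE),
              sum(x$state == 0L, na.rm = TRUE), sum(is.na(x$state))))
  invisible(x)
}

#' @export
dim.root_matrix <- function(x) dim(x$state)

#' Family of each doculect, as a named vector
#' @param m a [root_matrix].
#' @return named character vector, names = doculect ids.
#' @export
doculect_families <- function(m) {
  setNames(m$doculects$family, m$doculects$id)
}

## ---------------------------------------------------------------------------
## Readers / writers (TSV dialect: roots as rows, doculects as columns)
## ---------------------------------------------------------------------------

#' Read a root matrix and its metadata from tab-separated files
#'
#' The matrix file is tab-separated with roots as rows and doculects as
#' columns: the first column holds the root id, the header row the doculect
#' ids, and every cell one of `1` (present), `0` (absent) or `?` (no
#' information). The metadata file has one row per doculect (columns `id`,
#' `family`, and optionally `name`, `subgroup`, `cluster_id`, `latitude`,
#' `longitude`, `subsistence`, `source`). Optional sidecar tables give root
#' annotations and the meaning inventory. All files are UTF-8 (doculect
#' names contain the click letters ǀ ǁ ǂ !). Row and column order of the
#' input is preserved.
#'
#' @param matrix_path path to the state matrix TSV.
#' @param metadata_path path to the doculect metadata TSV.
#' @param roots_path optional path to the root annotation TSV.
#' @param meanings_path optional path to the meaning inventory TSV.
#' @return a [root_matrix].
#' @export
read_root_matrix <- function(matrix_path, metadata_path,
                             roots_path = NULL, meanings_path = NULL) {
  for (p in c(matrix_path, metadata_path, roots_path, meanings_path))
    if (!file.exists(p)) stop("file not found: ", p)
  raw <- read.delim(matrix_path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE,
                    fileEncoding = "UTF-8", quote = "")
  if (ncol(raw) < 2) stop("matrix file needs a root id column plus >=1 doculect")
  root_ids <- raw[[1]]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  ok <- cells %in% c("0", "1", "?")
  if (!all(ok)) {
    idx <- which(!ok)[1]
    rr <- (idx - 1) %% nrow(cells) + 1
    cc <- (idx - 1) %/% nrow(cells) + 1
    stop(sprintf("unknown state symbol '%s' at root '%s', doculect '%s'",
                 cells[rr, cc], root_ids[rr], colnames(cells)[cc]))
  }
  state <- matrix(NA_integer_, nrow(cells), ncol(cells),
                  dimnames = list(root_ids, colnames(cells)))
  state[cells == "1"] <- 1L
  state[cells == "0"] <- 0L

  meta <- read.delim(metadata_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                     quote = "")
  roots <- if (!is.null(roots_path))
    read.delim(roots_path, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE, fileEncoding = "UTF-8", quote = "")
  meanings <- if (!is.null(meanings_path))
    read.delim(meanings_path, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE, fileEncoding = "UTF-8", quote = "")
  root_matrix(state, meta, roots, meanings)
}

#' Write a root matrix (and registries) back to tab-separated files
#'
#' Inverse of [read_root_matrix()]; a read-write-read round trip reproduces
#' states exactly.
#'
#' @param m a [root_matrix].
#' @param matrix_path,metadata_path,roots_path output paths (`roots_path`
#'   optional).
#' @return invisibly, the paths written.
#' @export
write_root_matrix <- function(m, matrix_path, metadata_path, roots_path = NULL) {
  cells <- matrix("?", nrow(m$state), ncol(m$state),
                  dimnames = dimnames(m$state))
  cells[!is.na(m$state) & m$state == 1L] <- "1"
  cells[!is.na(m$state) & m$state == 0L] <- "0"
  df <- data.frame(root_id = rownames(cells), cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  write.table(m$doculects, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(roots_path))
    write.table(m$roots, roots_path, sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(matrix_path, metadata_path, roots_path))
}

## ---------------------------------------------------------------------------
## Coding / filtering operations
## ---------------------------------------------------------------------------

#' Lump several source doculects into a single doculect
#'
#' Used to pool multiple archival sources for one variety (in the study
#' data, the three ǂKhomani and five ǁXegwi sources each become one
#' doculect). The combined state is present if any member is present, absent
#' if at least one member is absent and none present, and missing only when
#' all members are missing.
#'
#' @param m a [root_matrix].
#' @param groups named list: new doculect id -> character vector of member
#'   doculect ids. Groups must be disjoint; unlisted doculects pass through
#'   unchanged. Metadata for the lumped doculect is taken from its first
#'   member.
#' @return a [root_matrix] with `length(unlist(groups)) - length(groups)`
#'   fewer doculects.
#' @export
lump_doculects <- function(m, groups) {
  members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(members))
    stop("lumping groups overlap: ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  unknown <- setdiff(members, colnames(m$state))
  if (length(unknown))
    stop("unknown doculect(s) in lumping groups: ", paste(unknown, collapse = ", "))
  fams <- doculect_families(m)
  state <- m$state
  keep <- setdiff(colnames(state), members)
  new_cols <- vapply(groups, function(g) {
    sub <- state[, g, drop = FALSE]
    out <- rep(NA_integer_, nrow(sub))
    any_pres <- rowSums(sub == 1L, na.rm = TRUE) > 0
    any_abs <- rowSums(sub == 0L, na.rm = TRUE) > 0
    out[any_abs] <- 0L
    out[any_pres] <- 1L
    out
  }, integer(nrow(state)))
  colnames(new_cols) <- names(groups)
  new_state <- cbind(state[, keep, drop = FALSE], new_cols)

  meta_keep <- m$doculects[m$doculects$id %in% keep, , drop = FALSE]
  meta_new <- do.call(rbind, lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    if (length(unique(fams[g])) != 1)
      stop("lumping group '", nm, "' mixes families")
    row <- m$doculects[m$doculects$id == g[1], , drop = FALSE]
    row$id <- nm
    row$source <- paste(m$doculects$source[m$doculects$id %in% g], collapse = "; ")
    row
  }))
  root_matrix(new_state, rbind(meta_keep, meta_new), m$roots, m$meanings,
              require_present = FALSE)
}

#' Remove flagged roots (Bantu borrowings, complex expressions)
#'
#' Roots flagged as Bantu loans or as complex expressions (e.g. 'chest bone'
#' for 'rib') are excluded from analysis. The doculect set is unchanged.
#'
#' @param m a [root_matrix].
#' @param drop_bantu,drop_complex which flag(s) to apply.
#' @return a filtered [root_matrix].
#' @export
filter_roots <- function(m, drop_bantu = TRUE, drop_complex = TRUE) {
  drop <- rep(FALSE, nrow(m$state))
  if (drop_bantu) drop <- drop | m$roots$bantu_flag
  if (drop_complex) drop <- drop | m$roots$complex_flag
  keep_ids <- m$roots$id[!drop]
  root_matrix(m$state[keep_ids, , drop = FALSE], m$doculects,
              m$roots[!drop, , drop = FALSE], m$meanings,
              require_present = FALSE)
}

#' Remove singleton roots
#'
#' A singleton is a root present in exactly one doculect (micro-variation
#' within a single doculect, as opposed to broader sharing patterns).
#' Idempotent.
#'
#' @param m a [root_matrix].
#' @return a [root_matrix] without singletons.
#' @export
remove_singletons <- function(m) {
  n_pres <- rowSums(m$state == 1L, na.rm = TRUE)
  keep <- n_pres != 1L
  root_matrix(m$state[keep, , drop = FALSE], m$doculects,
              m$roots[keep, , drop = FALSE], m$meanings,
              require_present = FALSE)
}
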