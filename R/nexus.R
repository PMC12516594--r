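## NEXUS interop: binary DATA block (BEAST/SplitsTree import) and
## TAXA/SPLITS blocks (SplitsTree dialect). Writers are deliberately
## canonical (fixed layout) so that export -> parse -> export is
## byte-identical.

nexus_quote <- function(x) {
  # quote labels containing NEXUS-unsafe characters; click letters are fine
  # inside single quotes
  needs <- grepl("[ \t'();,=]", x) | x == ""
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

nexus_unquote <- function(x) {
  q <- grepl("^'.*'$", x)
  x[q] <- gsub("''", "'", sub("^'", "", sub("'$", "", x[q])))
  x
}

#' Export a root matrix as a binary NEXUS DATA block
#'
#' Writes `datatype=standard`, `symbols="01"`, `missing=?`, taxa = doculects,
#' characters = roots — the format consumed by SplitsTree and by Bayesian
#' phylogenetics tools for ascertained binary data. Output is UTF-8.
#'
#' @param m a [root_matrix].
#' @param path output file.
#' @return invisibly, `path`.
#' @seealso [read_binary_nexus()]
#' @export
export_binary_nexus <- function(m, path) {
  rows <- apply(m$state, 2, function(col) {
    ch <- ifelse(is.na(col), "?", as.character(col))
    paste(ch, collapse = "")
  })
  labs <- nexus_quote(colnames(m$state))
  width <- max(nchar(labs))
  con <- file(path, open = "wb")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con, sep = "\n", useBytes = TRUE)
  w("#NEXUS")
  w("BEGIN DATA;")
  w(sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", ncol(m$state), nrow(m$state)))
  w("FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=- LABELS=LEFT;")
  w("MATRIX")
  for (i in seq_along(rows))
    w(sprintf("%-*s %s", width, labs[i], rows[i]))
  w(";")
  w("END;")
  invisible(path)
}

#' Read a binary NEXUS DATA block written by [export_binary_nexus()]
#'
#' Minimal reader for the package's own canonical dialect (one matrix row
#' per taxon, symbols 0/1/?); used for round-trip verification. For foreign
#' NEXUS files use `ape::read.nexus.data()`.
#'
#' @param path NEXUS file.
#' @return integer matrix taxa x characters with NA for `?`.
#' @export
read_binary_nexus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  dim_line <- grep("DIMENSIONS", lines, ignore.case = TRUE, value = TRUE)[1]
  ntax <- as.integer(sub(".*NTAX=([0-9]+).*", "\\1", dim_line, ignore.case = TRUE))
  nchar_ <- as.integer(sub(".*NCHAR=([0-9]+).*", "\\1", dim_line, ignore.case = TRUE))
  start <- grep("^MATRIX$", trimws(lines), ignore.case = TRUE)[1]
  taxa <- character(ntax)
  out <- matrix(NA_integer_, ntax, nchar_)
  for (i in seq_len(ntax)) {
    ln <- trimws(lines[start + i])
    if (startsWith(ln, "'")) {
      end <- regexpr("'(?!')", substring(ln, 2), perl = TRUE)
      lab <- substring(ln, 1, end + 1)
      rest <- trimws(substring(ln, end + 2))
    } else {
      sp <- regexpr("[ \t]", ln)
      lab <- substring(ln, 1, sp - 1)
      rest <- trimws(substring(ln, sp + 1))
    }
    taxa[i] <- nexus_unquote(lab)
    ch <- strsplit(rest, "")[[1]]
    if (length(ch) != nchar_)
      stop("row for taxon '", taxa[i], "' has ", length(ch),
           " characters, expected ", nchar_)
    known <- ch != "?"
    out[i, known] <- as.integer(ch[known])
  }
  rownames(out) <- taxa
  out
}

#' Export a circular split system as a SplitsTree NEXUS file
#'
#' Writes TAXA and SPLITS blocks (with the circular ordering as CYCLE and
#' weighted splits) readable by SplitsTree-compatible parsers such as
#' `phangorn::read.nexus.splits()`. Split sides are written as 1-based taxon
#' indices in the TAXA order; the side stored is the canonical one (the side
#' not containing taxon 1).
#'
#' @param s a `split_system` (see [circular_split_weights()]).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
export_splits_nexus <- function(s, path) {
  taxa <- s$taxa
  n <- length(taxa)
  con <- file(path, open = "wb")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con, sep = "\n", useBytes = TRUE)
  w("#NEXUS")
  w("BEGIN TAXA;")
  w(sprintf("DIMENSIONS NTAX=%d;", n))
  w("TAXLABELS")
  for (t in nexus_quote(taxa)) w(sprintf("  %s", t))
  w(";")
  w("END;")
  w("BEGIN SPLITS;")
  w(sprintf("DIMENSIONS NTAX=%d NSPLITS=%d;", n, length(s$splits)))
  w("FORMAT LABELS=LEFT WEIGHTS=YES;")
  cyc <- match(s$ordering, taxa)
  w(sprintf("CYCLE %s;", paste(cyc, collapse = " ")))
  w("MATRIX")
  if (length(s$splits)) {
    for (k in seq_along(s$splits)) {
      side <- sort(match(s$splits[[k]], taxa))
      w(sprintf("  %d\t%.10g\t%s,", k, s$weights[k],
                paste(side, collapse = " ")))
    }
  }
  w(";")
  w("END;")
  invisible(path)
}

#' Read a SplitsTree-dialect SPLITS NEXUS file
#'
#' Companion reader for [export_splits_nexus()]; recovers taxa, cycle,
#' split sides and weights.
#'
#' @param path NEXUS file.
#' @return a `split_system` object.
#' @export
read_splits_nexus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  tl <- grep("^TAXLABELS$", trimws(lines), ignore.case = TRUE)[1]
  taxa <- character(0)
  i <- tl + 1
  while (trimws(lines[i]) != ";") {
    taxa <- c(taxa, nexus_unquote(trimws(lines[i])))
    i <- i + 1
  }
  cyc_line <- grep("^CYCLE", trimws(lines), ignore.case = TRUE, value = TRUE)[1]
  cyc <- as.integer(strsplit(trimws(sub(";", "", sub("CYCLE", "", cyc_line,
                                                     ignore.case = TRUE))),
                             "[ \t]+")[[1]])
  start <- grep("^MATRIX$", trimws(lines), ignore.case = TRUE)
  start <- start[length(start)]
  splits <- list()
  weights <- numeric(0)
  i <- start + 1
  while (trimws(lines[i]) != ";") {
    ln <- trimws(lines[i])
    ln <- sub("\\[[^]]*\\]", "", ln)       # strip any comment
    ln <- sub(",$", "", trimws(ln))
    parts <- strsplit(ln, "[ \t]+")[[1]]   # label, weight, side indices
    weights <- c(weights, as.numeric(parts[2]))
    splits <- c(splits, list(taxa[as.integer(parts[-(1:2)])]))
    i <- i + 1
  }
  new_split_system(taxa = taxa, ordering = taxa[cyc], splits = splits,
                   weights = weights, fit = NA_real_)
}
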