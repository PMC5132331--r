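#' @importFrom stats rnorm rbinom rgeom sd t.test predict setNames
#' @importFrom utils read.delim write.table
NULL

# Canonical amino-acid alphabet used for all internal column/row orderings.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Column order printed by PSI-BLAST in ASCII profiles.
PSIBLAST_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased and returned in file order. Entries are not
#' filtered here; use [filter_proteins()] to apply the length and
#' alphabet criteria before feature encoding.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `sequence`, `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  ids <- unname(sub("\\s.*$", "", names(set)))
  seqs <- unname(toupper(as.character(set)))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("FASTA entry with empty sequence: ", ids[which(empty)[1L]])
  }
  if (any(!nzchar(ids))) {
    stop("FASTA entry with empty header at position ", which(!nzchar(ids))[1L])
  }
  data.frame(id = ids, sequence = unname(seqs), length = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins Data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(proteins$sequence)
  names(set) <- proteins$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the profile written by `psiblast -out_ascii_pssm`. The file
#' carries two 20-column blocks per position (log-odds scores, then
#' weighted observed percentages); the log-odds block is the default.
#' Columns are re-ordered internally to the alphabetical amino-acid
#' order `A, C, D, ..., Y` regardless of the order printed in the file
#' header, so profiles from different PSI-BLAST versions are comparable.
#'
#' @param path Path to the ASCII PSSM file.
#' @param sequence Optional protein sequence; when supplied, the residue
#'   column of the file is checked against it.
#' @param protein_id Identifier stored in the returned profile. Defaults
#'   to the file name without extension.
#' @param block Which score block to return: `"logodds"` (default) or
#'   `"percent"`.
#' @return An object of class `pssm_profile`: a list with elements
#'   `protein_id`, `scores` (an N x 20 integer matrix, columns in
#'   alphabetical amino-acid order) and `residues` (length-N character
#'   vector of query residues).
#' @export
parse_ascii_pssm <- function(path, sequence = NULL, protein_id = NULL,
                             block = c("logodds", "percent")) {
  block <- match.arg(block)
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path)

  header_idx <- NA_integer_
  header_order <- NULL
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(toks) >= 20L && all(toks %in% LETTERS) &&
        length(unique(toks[1:20])) == 20L) {
      header_idx <- i
      header_order <- toks[1:20]
      break
    }
  }
  if (is.na(header_idx)) {
    stop("no amino-acid header line found in PSSM file: ", path)
  }

  positions <- integer(0)
  residues <- character(0)
  rows <- list()
  for (i in seq((header_idx + 1L), length(lines))) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) break
    toks <- strsplit(ln, "\\s+")[[1L]]
    if (!grepl("^[0-9]+$", toks[1L])) break
    off <- if (block == "logodds") 2L else 22L
    if (length(toks) < off + 20L) {
      stop("PSSM row with fewer than 20 scores at line ", i, " of ", path)
    }
    vals <- suppressWarnings(as.numeric(toks[(off + 1L):(off + 20L)]))
    if (anyNA(vals)) {
      stop("non-numeric score field at line ", i, " of ", path)
    }
    positions <- c(positions, as.integer(toks[1L]))
    residues <- c(residues, toks[2L])
    rows[[length(rows) + 1L]] <- vals
  }
  if (length(rows) == 0L) stop("no profile rows found in ", path)

  scores <- do.call(rbind, rows)
  colnames(scores) <- header_order
  scores <- scores[, AA20, drop = FALSE]
  rownames(scores) <- NULL

  if (!is.null(sequence)) {
    expected <- strsplit(toupper(sequence), "")[[1L]]
    if (length(expected) != length(residues) ||
        !all(expected == residues)) {
      stop("PSSM residue column disagrees with the supplied sequence for ",
           path)
    }
  }
  if (is.null(protein_id)) {
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  }
  structure(list(protein_id = protein_id, scores = scores,
                 residues = residues),
            class = "pssm_profile")
}

#' Read a per-residue binding prediction track
#'
#' The track is a tab-separated table with columns `position`,
#' `residue`, `label` and `ri`: one row per residue, a binding or
#' non-binding call, and an integer reliability index between 0 (least
#' reliable) and 10 (most reliable). Rows are returned sorted by
#' position.
#'
#' @param path Path to the TSV file.
#' @param protein_id Identifier stored on the track; defaults to the
#'   file name without extension.
#' @return An object of class `binding_track`: a data frame with columns
#'   `position`, `residue`, `label`, `ri`.
#' @export
read_binding_track <- function(path, protein_id = NULL) {
  if (!file.exists(path)) stop("binding track file not found: ", path)
  x <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("position", "residue", "label", "ri")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("binding track is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (is.null(protein_id)) {
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  }
  binding_track(x$position, x$residue, x$label, x$ri, protein_id)
}

#' Construct a binding track from vectors
#'
#' @param position 1-based residue positions, a permutation of `1..N`.
#' @param residue One-letter residue codes.
#' @param label Per-residue call, `"binding"` or `"non-binding"`
#'   (case-insensitive).
#' @param ri Integer reliability indices in `0..10`.
#' @param protein_id Identifier stored on the track.
#' @return A `binding_track` data frame sorted by position.
#' @export
binding_track <- function(position, residue, label, ri, protein_id = NA) {
  n <- length(position)
  if (length(residue) != n || length(label) != n || length(ri) != n) {
    stop("position, residue, label and ri must have equal length")
  }
  position <- as.integer(position)
  ri <- as.numeric(ri)
  if (anyNA(ri) || any(ri < 0 | ri > 10) || any(ri != round(ri))) {
    stop("reliability index must be an integer in 0..10")
  }
  if (anyDuplicated(position) || !setequal(position, seq_len(n))) {
    stop("positions must cover 1..N exactly once for ", protein_id)
  }
  label <- tolower(label)
  if (!all(label %in% c("binding", "non-binding"))) {
    stop("labels must be 'binding' or 'non-binding'")
  }
  ord <- order(position)
  out <- data.frame(position = position[ord], residue = residue[ord],
                    label = label[ord], ri = as.integer(ri)[ord],
                    stringsAsFactors = FALSE)
  attr(out, "protein_id") <- protein_id
  class(out) <- c("binding_track", "data.frame")
  out
}

#' Write a binding track to a TSV file
#'
#' @param track A `binding_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_binding_track <- function(track, path) {
  write.table(as.data.frame(track)[, c("position", "residue", "label", "ri")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from a TSV file
#'
#' The table has a header row of feature names plus a terminal `label`
#' column with values `positive`/`negative`; row names hold protein ids.
#'
#' @param path Path to the TSV file.
#' @return A data frame of numeric feature columns plus a `label` column.
#' @export
read_feature_table <- function(path) {
  x <- read.delim(path, check.names = FALSE, row.names = 1L,
                  stringsAsFactors = FALSE)
  if (!"label" %in% names(x) || names(x)[ncol(x)] != "label") {
    stop("feature table must end with a 'label' column")
  }
  feat <- x[, -ncol(x), drop = FALSE]
  if (!all(vapply(feat, is.numeric, logical(1L)))) {
    stop("feature columns must be numeric")
  }
  if (anyNA(feat)) stop("feature table contains missing values")
  if (!all(x$label %in% c("positive", "negative"))) {
    stop("labels must be 'positive' or 'negative'")
  }
  x
}

#' Write a feature table to a TSV file
#'
#' @param table Data frame of numeric features plus a `label` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot("label" %in% names(table))
  table <- table[, c(setdiff(names(table), "label"), "label")]
  write.table(table, path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(path)
}

# Split a feature table into the numeric matrix and the label vector.
split_feature_table <- function(table) {
  stopifnot("label" %in% names(table))
  feats <- table[, setdiff(names(table), "label"), drop = FALSE]
  list(features = feats,
       labels = factor(table$label, levels = c("negative", "positive")))
}
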