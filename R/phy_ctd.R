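#' Built-in three-group amino-acid partitions
#'
#' Eight physicochemical properties, each dividing the 20 amino acids
#' into three disjoint, exhaustive groups, in the canonical order
#' hydrophobicity, polarity, polarizability, charge, surface tension,
#' secondary-structure propensity, solvent accessibility and normalised
#' van der Waals volume. The partitions are the groupings in common use
#' for composition/transition/distribution descriptors of protein
#' fold and function classes.
#'
#' @return Named list of 8 schemes; each scheme is a list of character
#'   vectors `g1`, `g2`, `g3`.
#' @export
default_ctd_schemes <- function() {
  s <- list(
    hydrophobicity = list(
      g1 = c("R", "K", "E", "D", "Q", "N"),                      # polar
      g2 = c("G", "A", "S", "T", "P", "H", "Y"),                 # neutral
      g3 = c("C", "L", "V", "I", "M", "F", "W")),                # hydrophobic
    polarity = list(
      g1 = c("L", "I", "F", "W", "C", "M", "V", "Y"),
      g2 = c("P", "A", "T", "G", "S"),
      g3 = c("H", "Q", "R", "K", "N", "E", "D")),
    polarizability = list(
      g1 = c("G", "A", "S", "D", "T"),
      g2 = c("C", "P", "N", "V", "E", "Q", "I", "L"),
      g3 = c("K", "M", "H", "F", "R", "Y", "W")),
    charge = list(
      g1 = c("K", "R"),                                          # positive
      g2 = c("A", "N", "C", "Q", "G", "H", "I", "L", "M", "F",
             "P", "S", "T", "W", "Y", "V"),                      # neutral
      g3 = c("D", "E")),                                         # negative
    surface_tension = list(
      g1 = c("G", "Q", "D", "N", "A", "H", "R"),
      g2 = c("K", "T", "S", "E", "C"),
      g3 = c("I", "L", "M", "F", "P", "W", "Y", "V")),
    secondary_structure = list(
      g1 = c("E", "A", "L", "M", "Q", "K", "R", "H"),            # helix
      g2 = c("V", "I", "Y", "C", "W", "F", "T"),                 # strand
      g3 = c("G", "N", "P", "S", "D")),                          # coil
    solvent_accessibility = list(
      g1 = c("A", "L", "F", "C", "G", "I", "V", "W"),            # buried
      g2 = c("R", "K", "Q", "E", "N", "D"),                      # exposed
      g3 = c("M", "P", "S", "T", "H", "Y")),                     # intermediate
    normalized_vdw_volume = list(
      g1 = c("G", "A", "S", "T", "P", "D", "C"),
      g2 = c("N", "V", "E", "Q", "I", "L"),
      g3 = c("M", "H", "K", "F", "R", "Y", "W"))
  )
  lapply(s, validate_ctd_scheme)
}

validate_ctd_scheme <- function(scheme) {
  stopifnot(all(c("g1", "g2", "g3") %in% names(scheme)))
  all_aa <- unlist(scheme[c("g1", "g2", "g3")])
  if (anyDuplicated(all_aa) || !setequal(all_aa, AA20)) {
    stop("groups must partition the 20 canonical amino acids")
  }
  scheme
}

#' Read grouping schemes from a TSV config file
#'
#' Format: columns `property`, `group1`, `group2`, `group3`, the group
#' columns holding comma-separated one-letter residue codes.
#'
#' @param path Path to the TSV file.
#' @return Named list of schemes as in [default_ctd_schemes()].
#' @export
read_ctd_schemes <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("property", "group1", "group2", "group3")
  if (!all(required %in% names(x))) {
    stop("grouping config needs columns: ", paste(required, collapse = ", "))
  }
  split_codes <- function(s) toupper(trimws(strsplit(s, ",")[[1L]]))
  out <- lapply(seq_len(nrow(x)), function(i) {
    validate_ctd_scheme(list(g1 = split_codes(x$group1[i]),
                             g2 = split_codes(x$group2[i]),
                             g3 = split_codes(x$group3[i])))
  })
  names(out) <- x$property
  out
}

#' Recode a sequence into group labels
#'
#' @param sequence Protein sequence over the 20 canonical codes.
#' @param scheme A grouping scheme (list `g1`, `g2`, `g3`).
#' @return String of the same length over the alphabet `{1, 2, 3}`.
#' @export
to_group_string <- function(sequence, scheme) {
  scheme <- validate_ctd_scheme(scheme)
  chars <- strsplit(toupper(sequence), "")[[1L]]
  if (length(chars) == 0L) stop("empty sequence")
  bad <- setdiff(chars, AA20)
  if (length(bad)) {
    stop("non-canonical residue(s): ", paste(bad, collapse = ", "))
  }
  map <- character(20L)
  names(map) <- AA20
  map[scheme$g1] <- "1"
  map[scheme$g2] <- "2"
  map[scheme$g3] <- "3"
  paste(map[chars], collapse = "")
}

#' Composition index
#'
#' Fraction of residues in each group; the three values sum to 1.
#'
#' @param group_string String over `{1, 2, 3}` from [to_group_string()].
#' @return Numeric vector `c(g1, g2, g3)`.
#' @export
composition_index <- function(group_string) {
  chars <- strsplit(group_string, "")[[1L]]
  if (length(chars) == 0L) stop("empty group string")
  out <- vapply(c("1", "2", "3"), function(g) mean(chars == g), numeric(1L))
  names(out) <- paste0("g", 1:3)
  out
}

#' Transition index
#'
#' For each unordered group pair, the number of adjacent residue pairs
#' whose labels form that pair (in either direction), divided by N - 1.
#'
#' @param group_string String over `{1, 2, 3}`, length >= 2.
#' @return Numeric vector `c(g1g2, g1g3, g2g3)`.
#' @export
transition_index <- function(group_string) {
  chars <- strsplit(group_string, "")[[1L]]
  n <- length(chars)
  if (n < 2L) stop("transition index needs at least 2 residues")
  a <- chars[-n]
  b <- chars[-1L]
  pair <- paste0(pmin(a, b), pmax(a, b))
  out <- vapply(c("12", "13", "23"), function(p) sum(pair == p) / (n - 1),
                numeric(1L))
  names(out) <- c("g1g2", "g1g3", "g2g3")
  out
}

#' Distribution index
#'
#' For each group, five landmarks: the sequence positions of the first
#' occurrence and of the occurrences at ranks `ceiling(0.25 c)`,
#' `ceiling(0.5 c)`, `ceiling(0.75 c)` and `c` (where `c` is the group's
#' occurrence count), each expressed as percent of the sequence length.
#' A group absent from the sequence yields five zeros.
#'
#' @param group_string String over `{1, 2, 3}`.
#' @return Numeric vector of length 15 (five landmarks per group), values
#'   in \[0, 100\].
#' @export
distribution_index <- function(group_string) {
  chars <- strsplit(group_string, "")[[1L]]
  n <- length(chars)
  if (n == 0L) stop("empty group string")
  landmarks <- c("first", "p25", "p50", "p75", "p100")
  out <- numeric(0)
  for (g in c("1", "2", "3")) {
    pos <- which(chars == g)
    cnt <- length(pos)
    if (cnt == 0L) {
      v <- rep(0, 5L)
    } else {
      ranks <- c(1L, ceiling(c(0.25, 0.5, 0.75) * cnt), cnt)
      v <- pos[ranks] / n * 100
    }
    names(v) <- paste0("g", g, ".", landmarks)
    out <- c(out, v)
  }
  out
}

#' 168-dimensional physicochemical CTD feature
#'
#' For each grouping scheme, the 21 descriptors composition (3),
#' transition (3) and distribution (15) are computed on the recoded
#' sequence and concatenated in the declared scheme order, giving
#' 8 x 21 = 168 values with the default schemes. Names follow
#' `PHY.<property>.<C|T|D>.<...>`.
#'
#' @param sequence Protein sequence over the 20 canonical codes,
#'   length >= 2.
#' @param schemes Named list of grouping schemes; defaults to
#'   [default_ctd_schemes()].
#' @param n_schemes Expected number of schemes (default 8). Set to `NA`
#'   to accept any number.
#' @return Named numeric vector of length `21 * n_schemes`.
#' @export
ctd_168 <- function(sequence, schemes = default_ctd_schemes(),
                    n_schemes = 8L) {
  if (!is.na(n_schemes) && length(schemes) != n_schemes) {
    stop("expected ", n_schemes, " grouping schemes, got ", length(schemes))
  }
  if (is.null(names(schemes)) || any(!nzchar(names(schemes)))) {
    stop("grouping schemes must be named")
  }
  out <- numeric(0)
  for (prop in names(schemes)) {
    gs <- to_group_string(sequence, schemes[[prop]])
    comp <- composition_index(gs)
    tran <- transition_index(gs)
    dist <- distribution_index(gs)
    block <- c(comp, tran, dist)
    names(block) <- paste0("PHY.", prop, ".",
                           c(paste0("C.", names(comp)),
                             paste0("T.", names(tran)),
                             paste0("D.", names(dist))))
    out <- c(out, block)
  }
  out
}
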