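#' Sigmoid scaling of profile scores
#'
#' Maps a raw log-odds profile score `x` to `1 / (1 + exp(-x))`, a value
#' strictly inside (0, 1). Applied element-wise to every profile cell
#' before residue-type pooling, so strongly conserved positions saturate
#' towards 1 and strongly disfavoured substitutions towards 0.
#'
#' @param x Numeric vector or matrix of profile scores.
#' @return Object of the same shape with values in (0, 1).
#' @export
sigmoid_scale <- function(x) {
  1 / (1 + exp(-x))
}

#' Built-in physicochemical property table
#'
#' Six per-amino-acid properties used by the profile-projection feature:
#' the pKa of the alpha-amino group, the pKa of the alpha-carboxyl group,
#' the electron-ion interaction potential (EIIP), the number of
#' side-chain lone electron pairs, the Wiener index of the molecular
#' graph, and the average molecular mass. pKa and mass values are the
#' standard free amino-acid reference values; the Wiener indices were
#' computed from the heavy-atom molecular graphs. Because every property
#' is min-max normalised before use, any positive affine rescaling of a
#' column (alternative unit conventions) yields identical features.
#'
#' @return A data frame with one row per amino acid (alphabetical
#'   one-letter order) and one column per property.
#' @export
default_property_table <- function() {
  tab <- data.frame(
    row.names    = AA20,
    pka_amino    = c(9.69, 10.28, 9.60, 9.67, 9.13, 9.60, 9.17, 9.60, 8.95,
                     9.60, 9.21, 8.80, 10.60, 9.13, 9.04, 9.15, 9.10, 9.62,
                     9.39, 9.11),
    pka_carboxyl = c(2.34, 1.96, 1.88, 2.19, 1.83, 2.34, 1.82, 2.36, 2.18,
                     2.36, 2.28, 2.02, 1.99, 2.17, 2.17, 2.21, 2.09, 2.32,
                     2.83, 2.20),
    eiip         = c(0.0373, 0.0829, 0.1263, 0.0058, 0.0946, 0.0050, 0.0242,
                     0.0000, 0.0371, 0.0000, 0.0823, 0.0036, 0.0198, 0.0761,
                     0.0959, 0.0829, 0.0941, 0.0057, 0.0548, 0.0516),
    lone_pairs   = c(0, 2, 4, 4, 0, 0, 2, 0, 1, 0, 2, 3, 0, 3, 2, 2, 2, 0,
                     0, 2),
    wiener       = c(29, 46, 96, 136, 212, 18, 165, 92, 143, 96, 102, 96,
                     62, 136, 247, 46, 65, 65, 369, 268),
    mass         = c(89.09, 121.16, 133.10, 147.13, 165.19, 75.07, 155.15,
                     131.17, 146.19, 131.17, 149.21, 132.12, 115.13, 146.15,
                     174.20, 105.09, 119.12, 117.15, 204.23, 181.19)
  )
  tab
}

#' Read a physicochemical property table from a TSV file
#'
#' Expects a column `amino_acid` of one-letter codes plus one numeric
#' column per property. All 20 canonical amino acids must be present and
#' no property may be constant.
#'
#' @param path Path to the TSV file.
#' @return A data frame with amino acids as row names, one column per
#'   property.
#' @export
read_property_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  if (!"amino_acid" %in% names(x)) {
    stop("property table needs an 'amino_acid' column")
  }
  validate_property_table(
    data.frame(x[setdiff(names(x), "amino_acid")],
               row.names = toupper(x$amino_acid)))
}

validate_property_table <- function(table) {
  if (!setequal(rownames(table), AA20)) {
    stop("property table must cover exactly the 20 canonical amino acids")
  }
  table <- table[AA20, , drop = FALSE]
  rng <- vapply(table, function(v) diff(range(v)), numeric(1L))
  if (any(rng == 0)) {
    stop("constant property column(s): ",
         paste(names(table)[rng == 0], collapse = ", "))
  }
  table
}

#' Min-max normalise one property over the 20 amino acids
#'
#' `NP(i) = (P(i) - min P) / (max P - min P)`, so the amino acid with the
#' smallest raw value maps to 0 and the largest to 1.
#'
#' @param table Property table as from [default_property_table()].
#' @param property Name of the property column.
#' @return Named numeric vector over the 20 amino acids, values in
#'   \[0, 1\].
#' @export
normalize_property <- function(table, property) {
  if (!property %in% names(table)) {
    stop("unknown property: ", property)
  }
  table <- validate_property_table(table)
  v <- table[[property]]
  out <- (v - min(v)) / (max(v) - min(v))
  names(out) <- rownames(table)
  out
}

#' Pool sigmoid-scaled profile rows by residue type
#'
#' Every profile row is sigmoid-scaled, then the rows belonging to each
#' of the 20 residue types in the query sequence are summed column-wise,
#' producing a 20 x 20 matrix: entry (k, i) is the summed scaled score
#' of profile column i over all sequence positions occupied by residue
#' type k. Residue types absent from the sequence give all-zero rows.
#' The result is invariant to permuting sequence positions.
#'
#' @param profile A `pssm_profile`.
#' @param sequence Optional protein sequence; defaults to the profile's
#'   own residue column. Must match the profile length.
#' @return Object of class `pooled_pssm`: list with `pooled` (20 x 20
#'   matrix, rows and columns in alphabetical amino-acid order) and
#'   `counts` (named occurrence counts A_k).
#' @export
pool_pssm <- function(profile, sequence = NULL) {
  scores <- profile$scores
  if (is.null(sequence)) {
    seq_chars <- profile$residues
  } else {
    seq_chars <- strsplit(toupper(sequence), "")[[1L]]
    if (length(seq_chars) != nrow(scores)) {
      stop("profile row count (", nrow(scores),
           ") does not match sequence length (", length(seq_chars), ")")
    }
  }
  if (!all(seq_chars %in% AA20)) {
    stop("sequence contains non-canonical residues: ",
         paste(unique(setdiff(seq_chars, AA20)), collapse = ", "))
  }
  scaled <- sigmoid_scale(scores)
  pooled <- matrix(0, nrow = 20L, ncol = 20L,
                   dimnames = list(AA20, AA20))
  counts <- setNames(integer(20L), AA20)
  for (k in AA20) {
    idx <- which(seq_chars == k)
    counts[k] <- length(idx)
    if (length(idx)) {
      pooled[k, ] <- colSums(scaled[idx, , drop = FALSE])
    }
  }
  structure(list(protein_id = profile$protein_id, pooled = pooled,
                 counts = counts),
            class = "pooled_pssm")
}

#' 400-dimensional pooled-profile feature
#'
#' Row-major flattening of the 20 x 20 pooled profile matrix: the 20
#' column sums for residue type A first, then C, and so on in
#' alphabetical order. Feature names follow `PSSM.<type>.<column>`.
#'
#' @param pooled A `pooled_pssm`.
#' @return Named numeric vector of length 400.
#' @export
pssm_400 <- function(pooled) {
  m <- pooled$pooled
  out <- as.vector(t(m))
  names(out) <- as.vector(t(outer(AA20, AA20,
                                  function(k, i) paste0("PSSM.", k, ".", i))))
  out
}

#' 120-dimensional profile-property projection feature
#'
#' Projects each residue type's pooled profile row onto each normalised
#' physicochemical property axis:
#' `S[a, k] = sum_i NP_a(i) * pooled[k, i]`,
#' where `NP_a` is the min-max normalised property `a` over the 20
#' amino-acid columns. With the six built-in properties the result has
#' length 6 x 20 = 120, ordered property-major then residue type;
#' names follow `PSSMPP.<property>.<type>`.
#'
#' @param pooled A `pooled_pssm`.
#' @param table Property table; defaults to [default_property_table()].
#' @param n_properties Expected number of properties (default 6). Set to
#'   `NA` to accept any number.
#' @return Named numeric vector of length `n_properties * 20`.
#' @export
pssm_pp_120 <- function(pooled, table = default_property_table(),
                        n_properties = 6L) {
  table <- validate_property_table(table)
  if (!is.na(n_properties) && ncol(table) != n_properties) {
    stop("expected ", n_properties, " properties, got ", ncol(table))
  }
  m <- pooled$pooled  # rows k, cols i, both alphabetical
  props <- names(table)
  out <- numeric(0)
  for (a in props) {
    np <- normalize_property(table, a)          # named by amino acid
    s_ak <- as.vector(m %*% np[colnames(m)])    # one value per residue type k
    names(s_ak) <- paste0("PSSMPP.", a, ".", rownames(m))
    out <- c(out, s_ak)
  }
  out
}
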