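#' Filter proteins by length and alphabet
#'
#' Keeps proteins with 50 to 6000 residues (inclusive) whose sequences
#' use only the 20 canonical one-letter codes. Shorter chains are
#' likely fragments, longer ones likely complexes, and ambiguity or
#' non-standard codes (X, Z, B, U, O, J, *) cannot be encoded by the
#' feature extractors. Each removal is attributed to the first matching
#' rule (short, then long, then irregular).
#'
#' @param proteins Data frame with columns `id`, `sequence` (as from
#'   [read_fasta()]).
#' @param min_length,max_length Inclusive length bounds.
#' @return List with `kept` (the retained rows) and `report` (counts
#'   `input_count`, `removed_short`, `removed_long`,
#'   `removed_irregular`, and the retained `kept_ids`).
#' @export
filter_proteins <- function(proteins, min_length = 50L,
                            max_length = 6000L) {
  n <- nchar(proteins$sequence)
  irregular <- grepl(paste0("[^", paste(AA20, collapse = ""), "]"),
                     toupper(proteins$sequence))
  short <- n < min_length
  long <- n > max_length
  removed_short <- short
  removed_long <- !short & long
  removed_irregular <- !short & !long & irregular
  keep <- !(removed_short | removed_long | removed_irregular)
  list(kept = proteins[keep, , drop = FALSE],
       report = list(input_count = nrow(proteins),
                     removed_short = sum(removed_short),
                     removed_long = sum(removed_long),
                     removed_irregular = sum(removed_irregular),
                     kept_ids = proteins$id[keep]))
}

#' Assemble the 292-dimensional feature vector for one protein
#'
#' Concatenates, in the package's canonical order: the 120 profile-
#' property projections, the four propensity measures BP1, BP2, NBP1,
#' NBP2, and the 168 composition/transition/distribution descriptors.
#' Feature names are stable across runs, so selection traces computed
#' on one table apply to any other. A track with no residues of a
#' target call yields 0 for the corresponding propensities.
#'
#' @param sequence Protein sequence (canonical alphabet).
#' @param profile A `pssm_profile` for the same protein.
#' @param track A `binding_track` for the same protein.
#' @param property_table Property table for the projection feature.
#' @param schemes Grouping schemes for the CTD feature.
#' @return Named numeric vector of length 292.
#' @export
assemble_features <- function(sequence, profile, track,
                              property_table = default_property_table(),
                              schemes = default_ctd_schemes()) {
  n <- nchar(sequence)
  if (nrow(profile$scores) != n) {
    stop("profile rows do not match sequence length for ",
         profile$protein_id)
  }
  if (nrow(track) != n) {
    stop("binding track does not match sequence length for ",
         attr(track, "protein_id"))
  }
  pooled <- pool_pssm(profile, sequence)
  pp <- pssm_pp_120(pooled, property_table)
  bp <- c(BP1 = bp1(track, "binding"),
          BP2 = bp2(track, "binding"),
          NBP1 = bp1(track, "non-binding"),
          NBP2 = bp2(track, "non-binding"))
  phy <- ctd_168(sequence, schemes)
  c(pp, bp, phy)
}

#' Assemble the feature table for a dataset
#'
#' Applies [assemble_features()] to every protein and binds the class
#' labels, producing the table consumed by selection and training.
#'
#' @param dataset List with `proteins`, `profiles`, `tracks`, `labels`
#'   (as from [gen_dataset()], or built from parsed files).
#' @param property_table,schemes Passed to [assemble_features()].
#' @return Data frame of 292 numeric feature columns plus a terminal
#'   `label` column; row names are protein ids.
#' @export
assemble_feature_table <- function(dataset,
                                   property_table = default_property_table(),
                                   schemes = default_ctd_schemes()) {
  ids <- dataset$proteins$id
  rows <- lapply(seq_along(ids), function(j) {
    id <- ids[j]
    if (is.null(dataset$profiles[[id]])) {
      stop("missing profile for protein ", id)
    }
    if (is.null(dataset$tracks[[id]])) {
      stop("missing binding track for protein ", id)
    }
    assemble_features(dataset$proteins$sequence[j],
                      dataset$profiles[[id]], dataset$tracks[[id]],
                      property_table, schemes)
  })
  tab <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  rownames(tab) <- ids
  tab$label <- unname(dataset$labels[ids])
  tab
}

#' Predict classes with a trained model
#'
#' Majority vote over the forest's trees; exact 50/50 ties go to the
#' positive class. The winning vote fraction is therefore always in
#' \[0.5, 1\].
#'
#' @param model A `dnabind_model` from [train_rf()].
#' @param features Numeric feature data frame with the model's training
#'   columns.
#' @return Data frame with columns `id` (row names of `features`),
#'   `class` and `vote_fraction`.
#' @export
predict_binding <- function(model, features) {
  stopifnot(inherits(model, "dnabind_model"))
  features <- as.data.frame(features)
  missing <- setdiff(model$feature_names, names(features))
  if (length(missing)) {
    stop("feature table lacks the model's column(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  features <- features[, model$feature_names, drop = FALSE]
  votes <- predict(model$forest, features, type = "vote", norm.votes = TRUE)
  pos <- votes[, "positive"]
  cls <- ifelse(pos >= 0.5, "positive", "negative")  # tie -> positive
  data.frame(id = rownames(features),
             class = unname(cls),
             vote_fraction = unname(pmax(pos, 1 - pos)),
             stringsAsFactors = FALSE)
}
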