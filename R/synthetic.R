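#' Configuration for the synthetic dataset generator
#'
#' Defines a two-class study condition: protein counts, a length range,
#' per-class per-residue binding-call probabilities, a reliability-index
#' concentration, and a per-class shift added to each position's
#' own-residue profile column for positive proteins. The default
#' condition (binding rates 0.15 vs 0.02, profile shift 2, reliability
#' concentrated near 10) gives two clearly separated classes; setting
#' both rates and the shift equal produces an exchangeable null.
#'
#' @param n_positive,n_negative Number of proteins per class.
#' @param length_range Integer `c(min, max)` residue counts, within
#'   \[50, 6000\].
#' @param binding_rate_pos,binding_rate_neg Per-residue probability of
#'   a binding call, by class.
#' @param ri_concentration Geometric decay parameter in (0, 1\]; the
#'   reliability index is `10 - G` with `G ~ Geometric(ri_concentration)`
#'   truncated at 0, so values concentrate at 10 as the parameter grows.
#' @param pssm_signal Integer added to the own-residue profile score at
#'   every position of positive-class proteins.
#' @param residue_freqs Optional named sampling weights over the 20
#'   amino acids; uniform by default.
#' @param seed Mandatory integer seed.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_positive = 100L, n_negative = 100L,
                         length_range = c(50L, 200L),
                         binding_rate_pos = 0.15,
                         binding_rate_neg = 0.02,
                         ri_concentration = 0.5,
                         pssm_signal = 2,
                         residue_freqs = NULL,
                         seed) {
  if (missing(seed) || length(seed) != 1L || !is.numeric(seed)) {
    stop("an integer seed is mandatory")
  }
  if (length(length_range) != 2L || length_range[1L] > length_range[2L]) {
    stop("length_range must be c(min, max) with min <= max")
  }
  if (length_range[1L] < 50L || length_range[2L] > 6000L) {
    stop("length_range must lie within [50, 6000]")
  }
  rates <- c(binding_rate_pos, binding_rate_neg)
  if (any(rates < 0 | rates > 1)) stop("binding rates must be in [0, 1]")
  if (ri_concentration <= 0 || ri_concentration > 1) {
    stop("ri_concentration must be in (0, 1]")
  }
  if (is.null(residue_freqs)) {
    residue_freqs <- setNames(rep(1 / 20, 20L), AA20)
  }
  if (!setequal(names(residue_freqs), AA20) || any(residue_freqs < 0)) {
    stop("residue_freqs must be non-negative weights over the 20 amino acids")
  }
  structure(list(n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 length_range = as.integer(length_range),
                 binding_rate_pos = binding_rate_pos,
                 binding_rate_neg = binding_rate_neg,
                 ri_concentration = ri_concentration,
                 pssm_signal = pssm_signal,
                 residue_freqs = residue_freqs[AA20],
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Reliability indices concentrated near 10: 10 minus a geometric
# variate, truncated at 0.
draw_ri <- function(n, concentration) {
  pmax(0L, 10L - rgeom(n, prob = concentration))
}

#' Generate a synthetic two-class dataset
#'
#' Emulates the three input streams of the predictor: protein sequences
#' (i.i.d. residues), per-protein profiles (integer scores from a
#' discretised normal clipped to \[-10, 13\], the typical PSI-BLAST
#' log-odds range, plus the configured own-residue shift for positive
#' proteins), and per-residue binding tracks (Bernoulli calls at the
#' class rate, with reliability indices concentrated near 10). Output
#' is fully deterministic given the config's seed.
#'
#' @param config A [synth_config()].
#' @return List with `proteins` (data frame `id`, `sequence`, `length`),
#'   `profiles` (named list of `pssm_profile`), `tracks` (named list of
#'   `binding_track`) and `labels` (named character vector,
#'   `"positive"`/`"negative"`).
#' @export
gen_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n_tot <- config$n_positive + config$n_negative
  labels <- c(rep("positive", config$n_positive),
              rep("negative", config$n_negative))
  ids <- sprintf("%s%04d", ifelse(labels == "positive", "POS", "NEG"),
                 seq_len(n_tot))
  names(labels) <- ids

  lengths <- sample(seq(config$length_range[1L], config$length_range[2L]),
                    n_tot, replace = TRUE)
  proteins <- data.frame(id = ids, sequence = NA_character_,
                         length = lengths, stringsAsFactors = FALSE)
  profiles <- vector("list", n_tot)
  tracks <- vector("list", n_tot)
  names(profiles) <- names(tracks) <- ids

  for (j in seq_len(n_tot)) {
    n <- lengths[j]
    seq_chars <- sample(AA20, n, replace = TRUE,
                        prob = config$residue_freqs)
    proteins$sequence[j] <- paste(seq_chars, collapse = "")

    scores <- matrix(pmin(13L, pmax(-10L, round(rnorm(n * 20L, 0, 2)))),
                     nrow = n, ncol = 20L, dimnames = list(NULL, AA20))
    if (labels[j] == "positive" && config$pssm_signal != 0) {
      scores[cbind(seq_len(n), match(seq_chars, AA20))] <-
        pmin(13L, scores[cbind(seq_len(n), match(seq_chars, AA20))] +
               round(config$pssm_signal))
    }
    profiles[[j]] <- structure(list(protein_id = ids[j], scores = scores,
                                    residues = seq_chars),
                               class = "pssm_profile")

    rate <- if (labels[j] == "positive") config$binding_rate_pos else
      config$binding_rate_neg
    is_binding <- rbinom(n, 1L, rate) == 1L
    tracks[[j]] <- binding_track(
      position = seq_len(n), residue = seq_chars,
      label = ifelse(is_binding, "binding", "non-binding"),
      ri = draw_ri(n, config$ri_concentration),
      protein_id = ids[j])
  }
  list(proteins = proteins, profiles = profiles, tracks = tracks,
       labels = labels)
}

#' Write a profile in the PSI-BLAST ASCII dialect
#'
#' Produces a file that [parse_ascii_pssm()] reads back bit-identically.
#' Columns are printed in the PSI-BLAST order (`A R N D C ...`) with
#' both score blocks (the second block is a zero placeholder) and the
#' trailing statistics lines of the format.
#'
#' @param profile A `pssm_profile` (scores in alphabetical column
#'   order, as produced by this package).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
gen_pssm_file <- function(profile, path) {
  scores <- profile$scores[, PSIBLAST_ORDER, drop = FALSE]
  n <- nrow(scores)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               paste("Last position-specific scoring matrix computed,",
                     "weighted observed percentages rounded down")), con)
  writeLines(paste0("           ",
                    paste(sprintf("%3s", rep(PSIBLAST_ORDER, 2L)),
                          collapse = "")), con)
  for (p in seq_len(n)) {
    writeLines(paste0(sprintf("%5d %s ", p, profile$residues[p]),
                      paste(sprintf("%4d", scores[p, ]), collapse = ""),
                      paste(sprintf("%4d", rep(0L, 20L)), collapse = "")),
               con)
  }
  writeLines(c("", "                      K         Lambda"), con)
  invisible(path)
}

#' Write a synthetic dataset to a directory
#'
#' Materialises every stream in its on-disk format: `proteins.fasta`,
#' one `<id>.pssm` per protein, one `<id>.track.tsv` per protein, and
#' `labels.tsv`.
#'
#' @param dataset Output of [gen_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$proteins, file.path(dir, "proteins.fasta"))
  for (id in dataset$proteins$id) {
    gen_pssm_file(dataset$profiles[[id]], file.path(dir, paste0(id, ".pssm")))
    write_binding_track(dataset$tracks[[id]],
                        file.path(dir, paste0(id, ".track.tsv")))
  }
  write.table(data.frame(id = names(dataset$labels),
                         label = unname(dataset$labels)),
              file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
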