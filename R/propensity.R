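#' First-order binding propensity
#'
#' The reliability-weighted fraction of residues carrying the target
#' call: the sum of reliability indices over residues labelled
#' `target_label`, divided by `10 * N` where N is the protein length.
#' Equals 0 when no residue carries the call and 1 when every residue
#' does with maximal reliability. The non-binding counterpart is the
#' same statistic with `target_label = "non-binding"`.
#'
#' @param track A `binding_track`.
#' @param target_label `"binding"` or `"non-binding"`.
#' @return A number in \[0, 1\].
#' @export
bp1 <- function(track, target_label = c("binding", "non-binding")) {
  target_label <- match.arg(target_label)
  n <- nrow(track)
  if (n < 1L) stop("empty binding track")
  sum(track$ri[track$label == target_label]) / (10 * n)
}

#' Pairwise distance counts of target-call residues
#'
#' Enumerates all unordered pairs of residues carrying the target call.
#' For each separation `i` (absolute position difference, 1..N-1) it
#' records the number of pairs `n(i)` and the summed per-pair
#' reliability `ri_sum(i)`. A pair's reliability is, by default, the
#' arithmetic mean of its two members' reliability indices; `"min"` and
#' `"product"` (of RI/10, rescaled back to the 0-10 scale) are
#' alternatives.
#'
#' @param track A `binding_track`.
#' @param target_label `"binding"` or `"non-binding"`.
#' @param pair_ri How a pair combines its members' reliabilities.
#' @return Data frame with columns `distance`, `n`, `ri_sum`, one row
#'   per separation that has at least one pair; attribute `N` holds the
#'   protein length.
#' @export
pair_distances <- function(track,
                           target_label = c("binding", "non-binding"),
                           pair_ri = c("mean", "min", "product")) {
  target_label <- match.arg(target_label)
  pair_ri <- match.arg(pair_ri)
  n_res <- nrow(track)
  hit <- track[track$label == target_label, , drop = FALSE]
  if (nrow(hit) < 2L) {
    out <- data.frame(distance = integer(), n = integer(),
                      ri_sum = numeric())
    attr(out, "N") <- n_res
    return(out)
  }
  pos <- hit$position
  ri <- hit$ri
  idx <- utils::combn(seq_along(pos), 2L)
  d <- abs(pos[idx[1L, ]] - pos[idx[2L, ]])
  w <- switch(pair_ri,
              mean = (ri[idx[1L, ]] + ri[idx[2L, ]]) / 2,
              min = pmin(ri[idx[1L, ]], ri[idx[2L, ]]),
              product = ri[idx[1L, ]] * ri[idx[2L, ]] / 10)
  agg_n <- tapply(rep(1L, length(d)), d, sum)
  agg_w <- tapply(w, d, sum)
  out <- data.frame(distance = as.integer(names(agg_n)),
                    n = as.integer(agg_n),
                    ri_sum = as.numeric(agg_w))
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "N") <- n_res
  out
}

# One summand per separation. p is ri_sum(i)/(10(N-i)), q the global
# reliability density; separations with p = 0 contribute exactly 0 in
# both forms, so callers may sum over observed separations only.
bp2_terms <- function(p, q, form = c("taylor", "exact")) {
  form <- match.arg(form)
  if (form == "taylor") {
    d <- p - q^2
    (d + d^2 / q^2) / log(2)
  } else {
    ifelse(p == 0, 0, p * log2(p / q^2))  # 0*log0 := 0
  }
}

#' Second-order (distance-correlation) binding propensity
#'
#' Measures how strongly target-call residues co-occur at each sequence
#' separation relative to what their overall density predicts. With
#' `q = sum(RI over target residues) / (10 N)` and, per separation `i`,
#' `p_i = ri_sum(i) / (10 (N - i))` (see [pair_distances()]), the
#' statistic is the sum over `i = 1..N-1` of relative-entropy-like
#' terms `p_i * log2(p_i / q^2)`. The default `"taylor"` form replaces
#' each term by its second-order expansion around `p_i = q^2`,
#' `(1/ln 2) * (d + d^2 / q^2)` with `d = p_i - q^2`, which is finite
#' when `p_i = 0`; the `"exact"` logarithmic form (with `0 log 0 := 0`)
#' is retained for comparison. Returns 0 when no residue carries the
#' target call.
#'
#' @param track A `binding_track` over at least 2 residues.
#' @param target_label `"binding"` or `"non-binding"`.
#' @param form `"taylor"` (default) or `"exact"`.
#' @param pair_ri Passed to [pair_distances()].
#' @return A real number; 0 for tracks without the target call.
#' @export
bp2 <- function(track, target_label = c("binding", "non-binding"),
                form = c("taylor", "exact"),
                pair_ri = c("mean", "min", "product")) {
  target_label <- match.arg(target_label)
  form <- match.arg(form)
  pair_ri <- match.arg(pair_ri)
  n_res <- nrow(track)
  if (n_res < 2L) stop("second-order propensity needs at least 2 residues")
  q <- sum(track$ri[track$label == target_label]) / (10 * n_res)
  if (q == 0) return(0)
  pd <- pair_distances(track, target_label, pair_ri)
  if (nrow(pd) == 0L) return(0)
  p <- pd$ri_sum / (10 * (n_res - pd$distance))
  sum(bp2_terms(p, q, form))
}
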