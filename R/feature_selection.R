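#' Discretise features for mutual-information estimation
#'
#' Default policy (`"mean-sigma"`): each feature is cut into three
#' states at its mean minus one standard deviation and mean plus one
#' standard deviation (below / within / above), the convention of the
#' classical minimum-redundancy maximum-relevance software. Constant
#' features collapse to a single state and are reported in a warning
#' and in the `constant_features` attribute.
#'
#' @param features Data frame or matrix of numeric feature columns.
#' @param bins Binning policy; only `"mean-sigma"` is provided.
#' @return Integer data frame of states in `{1, 2, 3}` with the same
#'   column names; attribute `constant_features` lists collapsed
#'   columns.
#' @export
discretize_features <- function(features, bins = "mean-sigma") {
  bins <- match.arg(bins, "mean-sigma")
  features <- as.data.frame(features)
  constant <- character(0)
  out <- lapply(names(features), function(nm) {
    v <- features[[nm]]
    s <- sd(v)
    if (is.na(s) || s == 0) {
      constant <<- c(constant, nm)
      return(rep(1L, length(v)))
    }
    m <- mean(v)
    findInterval(v, c(m - s, m + s), left.open = TRUE) + 1L
  })
  out <- as.data.frame(out, col.names = names(features),
                       check.names = FALSE)
  if (length(constant)) {
    warning("constant feature(s) collapsed to a single state: ",
            paste(constant, collapse = ", "))
  }
  attr(out, "constant_features") <- constant
  out
}

#' Mutual information between two discrete vectors
#'
#' Plug-in estimate from the empirical joint distribution, in bits.
#'
#' @param x,y Vectors of equal length, treated as categorical.
#' @return Non-negative mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) == 0L) stop("empty input")
  joint <- table(x, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  expected <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / expected[nz]))
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy forward selection on discretised features. The first pick
#' maximises relevance `I(f; class)`; each subsequent pick maximises
#' `I(f; class) - mean_{s in S} I(f; s)` (the difference, "MID",
#' criterion) or `I(f; class) / mean_{s in S} I(f; s)` ("MIQ") over the
#' already-selected set S. Ties are broken by original column order.
#'
#' @param features Discrete feature data frame (see
#'   [discretize_features()]).
#' @param labels Class labels, one per row.
#' @param criterion `"mid"` (default) or `"miq"`.
#' @return Character vector of feature names, best first.
#' @export
mrmr_rank <- function(features, labels, criterion = c("mid", "miq")) {
  criterion <- match.arg(criterion)
  features <- as.data.frame(features)
  p <- ncol(features)
  if (p < 1L) stop("need at least one feature")
  if (nrow(features) != length(labels)) {
    stop("labels must match the number of rows")
  }
  relevance <- vapply(features, mutual_information, numeric(1L), y = labels)

  selected <- integer(0)
  remaining <- seq_len(p)
  red_sum <- numeric(p)  # cumulative redundancy vs. selected set
  for (step in seq_len(p)) {
    if (step == 1L) {
      score <- relevance[remaining]
    } else {
      last <- selected[length(selected)]
      red_sum[remaining] <- red_sum[remaining] +
        vapply(remaining, function(j) {
          mutual_information(features[[j]], features[[last]])
        }, numeric(1L))
      mean_red <- red_sum[remaining] / length(selected)
      score <- if (criterion == "mid") {
        relevance[remaining] - mean_red
      } else {
        relevance[remaining] / pmax(mean_red, .Machine$double.eps)
      }
    }
    pick <- remaining[which.max(score)]  # which.max keeps original order
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  names(features)[selected]
}

#' Incremental feature selection over a ranked list
#'
#' Evaluates growing prefixes of the ranking: for each prefix size `k`
#' the classifier is trained and scored under cross-validation and the
#' four metrics are recorded; the optimal prefix is the smallest `k`
#' attaining the maximum Matthews correlation coefficient on the curve.
#' `stride` thins the evaluated prefix sizes (the full feature count is
#' always evaluated); an alternative `evaluator` function may replace
#' the default random-forest cross-validation.
#'
#' @param features Numeric feature data frame (undigested; the default
#'   evaluator trains on raw values).
#' @param labels Class labels (`"positive"`/`"negative"` or factor).
#' @param ranking Feature names in evaluation order, a permutation of
#'   `names(features)`.
#' @param folds Cross-validation folds for the default evaluator.
#' @param ntree,mtry Random-forest hyperparameters for the default
#'   evaluator.
#' @param stride Evaluate `k = 1, 1 + stride, 1 + 2*stride, ...` plus
#'   the full size.
#' @param seed Integer seed controlling fold assignment and forests.
#' @param evaluator Optional function `(features, labels, seed)`
#'   returning a list with elements `acc`, `se`, `sp`, `mcc`.
#' @return Object of class `selection_trace`: list with `ranking`,
#'   `curve` (data frame `k`, `acc`, `se`, `sp`, `mcc`), `optimal_k`
#'   and `optimal_features`.
#' @export
ifs_select <- function(features, labels, ranking, folds = 5L,
                       ntree = 1000L, mtry = NULL, stride = 1L,
                       seed = 1L, evaluator = NULL) {
  features <- as.data.frame(features)
  if (!setequal(ranking, names(features)) ||
      length(ranking) != ncol(features)) {
    stop("ranking must be a permutation of the feature names")
  }
  if (is.null(evaluator)) {
    evaluator <- function(f, l, s) {
      cross_validate(f, l, folds = folds, ntree = ntree, mtry = mtry,
                     seed = s)
    }
  }
  p <- length(ranking)
  ks <- unique(c(seq(1L, p, by = as.integer(stride)), p))
  rows <- lapply(ks, function(k) {
    rep_k <- evaluator(features[, ranking[seq_len(k)], drop = FALSE],
                       labels, seed)
    data.frame(k = k, acc = rep_k$acc, se = rep_k$se, sp = rep_k$sp,
               mcc = rep_k$mcc)
  })
  curve <- do.call(rbind, rows)
  best <- curve$k[which.max(curve$mcc)]  # smallest k at the max
  structure(list(ranking = ranking, curve = curve, optimal_k = best,
                 optimal_features = ranking[seq_len(best)]),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("mRMR-IFS selection trace\n")
  cat("  features ranked:", length(x$ranking), "\n")
  cat("  prefix sizes evaluated:", nrow(x$curve), "\n")
  cat(sprintf("  optimal k = %d (MCC = %.3f)\n", x$optimal_k,
              max(x$curve$mcc)))
  invisible(x)
}
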