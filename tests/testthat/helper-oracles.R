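# Independent brute-force transcriptions of the statistics, kept free of
# the package's own code paths so they can serve as oracles.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Triple-loop profile-property projection: positions x properties x columns.
oracle_pssm_pp <- function(scores, seq_chars, prop_table) {
  sig <- function(x) 1 / (1 + exp(-x))
  out <- numeric(0)
  for (a in names(prop_table)) {
    v <- prop_table[[a]]
    np <- (v - min(v)) / (max(v) - min(v))
    names(np) <- rownames(prop_table)
    for (k in AA) {
      s <- 0
      for (p in seq_along(seq_chars)) {
        if (seq_chars[p] == k) {
          for (i in seq_len(20L)) {
            s <- s + np[[AA[i]]] * sig(scores[p, i])
          }
        }
      }
      out <- c(out, s)
    }
  }
  out
}

# Exact logarithmic second-order propensity, summed over every distance
# 1..N-1 with 0*log0 := 0; pair reliability = mean of the two members.
oracle_bp2_exact <- function(position, label, ri, target) {
  n <- length(position)
  tgt <- which(label == target)
  q <- sum(ri[tgt]) / (10 * n)
  if (q == 0) return(0)
  total <- 0
  for (i in seq_len(n - 1L)) {
    ri_sum <- 0
    if (length(tgt) >= 2L) {
      for (a in seq_along(tgt)) {
        for (b in seq_along(tgt)) {
          if (a < b && abs(position[tgt[a]] - position[tgt[b]]) == i) {
            ri_sum <- ri_sum + (ri[tgt[a]] + ri[tgt[b]]) / 2
          }
        }
      }
    }
    p <- ri_sum / (10 * (n - i))
    if (p > 0) total <- total + p * log2(p / q^2)
  }
  total
}

# Same summation but with the Taylor bracket, for cross-checking bp2().
oracle_bp2_taylor <- function(position, label, ri, target) {
  n <- length(position)
  tgt <- which(label == target)
  q <- sum(ri[tgt]) / (10 * n)
  if (q == 0) return(0)
  total <- 0
  for (i in seq_len(n - 1L)) {
    ri_sum <- 0
    if (length(tgt) >= 2L) {
      for (a in seq_along(tgt)) {
        for (b in seq_along(tgt)) {
          if (a < b && abs(position[tgt[a]] - position[tgt[b]]) == i) {
            ri_sum <- ri_sum + (ri[tgt[a]] + ri[tgt[b]]) / 2
          }
        }
      }
    }
    p <- ri_sum / (10 * (n - i))
    d <- p - q^2
    total <- total + (d + d^2 / q^2) / log(2)
  }
  total
}

# Literal CTD block for one grouping scheme: C(3) + T(3) + D(15).
oracle_ctd_block <- function(seq_chars, scheme) {
  grp <- integer(length(seq_chars))
  grp[seq_chars %in% scheme$g1] <- 1L
  grp[seq_chars %in% scheme$g2] <- 2L
  grp[seq_chars %in% scheme$g3] <- 3L
  n <- length(grp)
  comp <- sapply(1:3, function(g) sum(grp == g) / n)
  tran <- c(sum((grp[-n] == 1 & grp[-1] == 2) | (grp[-n] == 2 & grp[-1] == 1)),
            sum((grp[-n] == 1 & grp[-1] == 3) | (grp[-n] == 3 & grp[-1] == 1)),
            sum((grp[-n] == 2 & grp[-1] == 3) | (grp[-n] == 3 & grp[-1] == 2))) /
    (n - 1)
  dist <- numeric(0)
  for (g in 1:3) {
    pos <- which(grp == g)
    cnt <- length(pos)
    if (cnt == 0L) {
      dist <- c(dist, rep(0, 5))
    } else {
      ranks <- c(1L, ceiling(0.25 * cnt), ceiling(0.5 * cnt),
                 ceiling(0.75 * cnt), cnt)
      dist <- c(dist, pos[ranks] / n * 100)
    }
  }
  c(comp, tran, dist)
}

# Metric formulas transcribed directly.
oracle_metrics <- function(tp, tn, fp, fn) {
  denom <- (tp + fp) * (tn + fn) * (tp + fn) * (tn + fp)
  list(acc = (tp + tn) / (tp + tn + fp + fn),
       se = tp / (tp + fn),
       sp = tn / (tn + fp),
       mcc = if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom))
}

# Mutual information via the entropy identity H(X) + H(Y) - H(X,Y).
oracle_mi <- function(x, y) {
  ent <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log2(p))
  }
  ent(x) + ent(y) - ent(paste(x, y))
}

# Feature table -> (features, labels) pair.
split_tab <- function(tab) {
  list(features = tab[, setdiff(names(tab), "label"), drop = FALSE],
       labels = tab$label)
}

# Random binding track over n residues.
random_track <- function(n, rate = 0.3, protein_id = "T") {
  lab <- ifelse(runif(n) < rate, "binding", "non-binding")
  binding_track(seq_len(n), sample(AA, n, TRUE), lab,
                sample(0:10, n, TRUE), protein_id)
}

# Random profile + sequence pair.
random_profile <- function(n, id = "P") {
  seq_chars <- sample(AA, n, TRUE)
  scores <- matrix(sample(-10:13, n * 20L, TRUE), nrow = n,
                   dimnames = list(NULL, AA))
  structure(list(protein_id = id, scores = scores, residues = seq_chars),
            class = "pssm_profile")
}
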