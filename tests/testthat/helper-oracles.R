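# Independent brute-force oracles used across the suite.

# BH step-up by its definition: adj_i = min over {j : p_j >= p_i} of m*p_j/rank_j
bf_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    min(1, min((m * p[p >= p[i]] / r[p >= p[i]])))
  }, numeric(1))
}

# two-sided Wilcoxon-Mann-Whitney p by full enumeration of group assignments
bf_wilcoxon_perm <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  us <- combn(length(pooled), n1, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# AUC by pair counting
bf_auc <- function(case, control) {
  s <- sum(outer(case, control, ">")) + 0.5 * sum(outer(case, control, "=="))
  s / (length(case) * length(control))
}

# Youden scan over a dense grid of candidate cutoffs (independent of the
# midpoint construction): every observed value +/- half the minimal gap
bf_youden_J <- function(case, control, dir) {
  v <- sort(unique(c(case, control)))
  gaps <- if (length(v) > 1) min(diff(v)) else 1
  cand <- sort(unique(c(v - gaps / 4, v + gaps / 4, -Inf, Inf)))
  best <- -Inf
  for (thr in cand) {
    if (dir == "case_higher") {
      J <- mean(case > thr) + mean(control <= thr) - 1
    } else {
      J <- mean(case < thr) + mean(control >= thr) - 1
    }
    best <- max(best, J)
  }
  best
}

# fast importance backend for tests where the invariant is backend-agnostic
fast_backend <- function() ranger_backend(num.trees = 100)

the_seven <- c("CAR 12:0", "CAR 10:0", "LPC 16:0", "LPC 18:0", "LPC 18:1",
               "LPC 18:2", "PC O-36:5")
the_depleted <- c("PC 34:1", "PC 26:0")
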