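# Independent oracles used to pin expected values. These deliberately avoid
# the package's own code paths: plain enumeration and first-principles
# arithmetic only.

# Exact expected confusion-cell rates for a finite collection of hypotheses
# with known truth labels: iterate hypotheses one by one and accumulate each
# one's expected contribution to every cell.
oracle_confusion <- function(truth, alpha, beta) {
  cells <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (t in truth) {
    p_pos <- if (t) 1 - beta else alpha
    if (t) {
      cells["tp"] <- cells["tp"] + p_pos
      cells["fn"] <- cells["fn"] + (1 - p_pos)
    } else {
      cells["fp"] <- cells["fp"] + p_pos
      cells["tn"] <- cells["tn"] + (1 - p_pos)
    }
  }
  rates <- cells / length(truth)
  s <- rates[["tp"]] + rates[["fp"]]
  list(tp = rates[["tp"]], fp = rates[["fp"]], fn = rates[["fn"]],
       tn = rates[["tn"]], s = s, tdr = rates[["tp"]] / s,
       fdr = rates[["fp"]] / s)
}

# Exhaustive hypergeometric pmf: enumerate every N-subset of a small frame
# whose first n_causal members are the causal ones.
oracle_hyper_pmf <- function(frame, n_causal, n_draw) {
  sets <- utils::combn(frame, n_draw)
  counts <- apply(sets, 2, function(s) sum(s <= n_causal))
  vapply(0:min(n_causal, n_draw),
         function(a) mean(counts == a), numeric(1))
}

# Exhaustive draw-test-advance success probability for a tiny frame:
# enumerate every portfolio and every vector of per-target test outcomes.
oracle_dev_success <- function(frame, n_causal, n_draw, alpha, beta) {
  sets <- utils::combn(frame, n_draw)
  outcomes <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n_draw)))
  total <- 0
  for (j in seq_len(ncol(sets))) {
    causal <- sets[, j] <= n_causal
    for (i in seq_len(nrow(outcomes))) {
      pos <- outcomes[i, ]
      p <- prod(ifelse(causal,
                       ifelse(pos, 1 - beta, beta),
                       ifelse(pos, alpha, 1 - alpha)))
      npos <- sum(pos)
      if (npos > 0) total <- total + p * sum(pos & causal) / npos
    }
  }
  total / ncol(sets)
}

# Tolerance equal to just over half a unit in the last printed decimal
# place, so computed values are compared at the precision a table prints.
printed_tol <- function(printed) {
  s <- tolower(printed)
  expo <- 0L
  if (grepl("e", s)) {
    parts <- strsplit(s, "e")[[1]]
    s <- parts[1]
    expo <- as.integer(parts[2])
  }
  d <- if (grepl("\\.", s)) nchar(strsplit(s, "\\.")[[1]][2]) else 0L
  0.551 * 10^(expo - d)
}

expect_printed <- function(x, printed) {
  expect_lt(abs(x - as.numeric(printed)), printed_tol(printed))
}
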