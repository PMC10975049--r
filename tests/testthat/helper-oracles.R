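# Independent oracles used to cross-check the implementation.

# Quartile membership by pair counting, no sorting: participant i is in Q1
# iff fewer than q participants strictly beat them (folded value higher,
# ties broken by id ascending), and in Q4 iff fewer than q are strictly
# worse.
oracle_quartile_membership <- function(folded, ids) {
  n <- length(folded)
  q <- n %/% 4L
  # beats[j, i]: participant j outranks participant i
  beats <- outer(folded, folded, ">") |
    (outer(folded, folded, "==") & outer(ids, ids, "<"))
  n_better <- colSums(beats)
  list(q1 = ids[n_better < q], q4 = ids[n_better >= n - q])
}

# AUC by exhaustive pair comparison.
oracle_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + (p > q) + 0.5 * (p == q)
  }
  s / (length(pos) * length(neg))
}

# Pearson chi-square by the definition sum((O - E)^2 / E).
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}
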