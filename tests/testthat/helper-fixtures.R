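# shared small fixtures, built in code at load time

small_words <- function(seed = 1, n_con = 12, n_abs = 18, k = 6) {
  gen_word_set(n_con, n_abs, k, seed = seed, silhouette_dim = c(16, 16))
}

# an rdm with hand-set lower triangle
rdm_from_lower <- function(vals, n, labels = NULL) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- vals
  m <- m + t(m)
  rdm(m, labels = labels)
}

# brute-force Spearman via explicit ranks (independent of package code)
oracle_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# partial correlation oracle: ranks + explicit normal equations
oracle_partial_spearman <- function(tv, mv, covs) {
  rt <- rank(tv); rm_ <- rank(mv)
  Z <- cbind(1, sapply(covs, rank))
  beta_t <- solve(t(Z) %*% Z, t(Z) %*% rt)
  beta_m <- solve(t(Z) %*% Z, t(Z) %*% rm_)
  et <- rt - Z %*% beta_t
  em <- rm_ - Z %*% beta_m
  sum(et * em) / sqrt(sum(et^2) * sum(em^2))
}
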