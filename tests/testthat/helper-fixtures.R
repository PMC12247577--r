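# Shared fixtures, built in code at test time.

# small balanced toy for RDM oracle checks: n_cond conditions, per_cond
# trials each, separable class patterns plus noise
toy_features <- function(n_cond = 4, per_cond = 16, p = 6, sep = 2,
                         seed = 1) {
  set.seed(seed)
  cond <- rep(seq_len(n_cond), each = per_cond)
  centers <- matrix(rnorm(n_cond * p), n_cond, p) * sep
  x <- centers[cond, ] + matrix(rnorm(length(cond) * p), ncol = p)
  list(x = x, cond = cond)
}

# brute-force cross-validated squared Euclidean RDM written as independent
# loops; shares the fold assignment with the implementation under test
bruteforce_cv_euclid_rdm <- function(x, cond, folds, k) {
  n_cond <- length(unique(cond))
  acc <- matrix(0, n_cond, n_cond)
  for (f in seq_len(k)) {
    m_tr <- matrix(0, n_cond, ncol(x))
    m_te <- matrix(0, n_cond, ncol(x))
    for (cc in seq_len(n_cond)) {
      tr <- which(cond == cc & folds != f)
      te <- which(cond == cc & folds == f)
      for (j in seq_len(ncol(x))) {
        m_tr[cc, j] <- mean(x[tr, j])
        m_te[cc, j] <- mean(x[te, j])
      }
    }
    for (a in seq_len(n_cond)) {
      for (b in seq_len(n_cond)) {
        d_tr <- m_tr[a, ] - m_tr[b, ]
        d_te <- m_te[a, ] - m_te[b, ]
        acc[a, b] <- acc[a, b] + sum(d_tr * d_te)
      }
    }
  }
  acc / k
}

# quick single-subject analysis of simulated impulse-2 data: observed betas
# plus label-permutation null betas
subject_betas_with_null <- function(sim, ck, n_reps = 1, n_perm = 0,
                                    k = 8) {
  prep <- wmrsa:::.prep_impulse2_models(ck$keys)
  rdm <- compute_rdm(sim$features, ck$id, k = k, n_reps = n_reps)
  obs <- wmrsa:::.fit_impulse2_fast(rdm$values, prep)
  nulls <- NULL
  if (n_perm > 0) {
    nulls <- t(vapply(seq_len(n_perm), function(i) {
      rn <- compute_rdm(sim$features, sample(ck$id), k = k, n_reps = 1)
      wmrsa:::.fit_impulse2_fast(rn$values, prep)
    }, obs))
  }
  list(obs = obs, nulls = nulls)
}
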