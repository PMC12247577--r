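test_that("stratified folds balance every condition across folds", {
  cond <- rep(1:2, c(16, 17))
  f <- stratified_folds(cond, k = 8, seed = 1)
  # 16 trials: exactly 2 per fold; 17 trials: seven folds of 2, one of 3
  expect_true(all(table(f[cond == 1]) == 2))
  expect_equal(sort(as.numeric(table(f[cond == 2]))), c(rep(2, 7), 3))

  # full design, against a brute-force tally
  d <- generate_design(1440, seed = 2)
  ck <- condition_keys(d, "impulse2")
  f2 <- stratified_folds(ck$id, k = 8, seed = 3)
  for (cc in unique(ck$id)) {
    counts <- tabulate(f2[ck$id == cc], 8)
    expect_lte(max(counts) - min(counts), 1)
    expect_equal(sum(counts), sum(ck$id == cc))
  }
  expect_identical(f2, stratified_folds(ck$id, k = 8, seed = 3))
  expect_error(stratified_folds(rep(1:2, c(4, 20)), k = 8), "fewer than k")
})

test_that("shrinkage covariance is consistent, PSD, and well-conditioned", {
  set.seed(4)
  # identity-covariance source, large n
  x <- matrix(rnorm(4000 * 8), 4000, 8)
  est <- shrinkage_covariance(x)
  expect_lt(max(abs(est$sigma - diag(8))), 0.15)

  # identity-covariance truth: the target IS the truth, so the estimated
  # intensity goes to 1 and the estimate is closer to I than the raw S
  s_raw <- crossprod(sweep(x, 2, colMeans(x))) / nrow(x)
  expect_lt(max(abs(est$sigma - diag(8))), max(abs(s_raw - diag(8))))

  # n = 2 mean-zero data: shrinkage engages and the estimate stays PSD
  x2 <- matrix(rnorm(2 * 10), 2, 10)
  est2 <- shrinkage_covariance(x2, center = FALSE)
  expect_gt(est2$shrinkage, 0)
  ev <- eigen(est2$sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  # centred n = 2 data are rank one: still PSD by construction
  est2c <- shrinkage_covariance(x2)
  evc <- eigen(est2c$sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(evc), -1e-10)
  expect_error(shrinkage_covariance(x2[1, , drop = FALSE]), "at least 2")
})

test_that("the pseudoinverse satisfies the Moore-Penrose identities", {
  set.seed(5)
  for (r in c(3, 6)) {
    a <- matrix(rnorm(8 * r), 8, r)
    sigma <- tcrossprod(a)  # rank-deficient PSD
    pinv <- psd_pinv(sigma)
    expect_equal(sigma %*% pinv %*% sigma, sigma, tolerance = 1e-9)
    expect_equal(pinv %*% sigma %*% pinv, pinv, tolerance = 1e-9)
    expect_equal(pinv, t(pinv), tolerance = 1e-12)
  }
  expect_equal(psd_pinv(diag(c(2, 4))), diag(c(0.5, 0.25)))
})

test_that("the LDC bilinear form reduces to known closed forms", {
  expect_equal(ldc_distance(c(3, 4), c(3, 4), diag(2)), 25)
  expect_equal(ldc_distance(c(1, 0), c(0, 1), diag(2)), 0)
  expect_equal(ldc_distance(c(0, 0), c(0, 0), diag(2)), 0)
  # symmetric under swapping the condition pair (both differences negate)
  set.seed(6)
  s <- crossprod(matrix(rnorm(9), 3))
  d1 <- rnorm(3); d2 <- rnorm(3)
  expect_equal(ldc_distance(d1, d2, s), ldc_distance(-d1, -d2, s))
  expect_error(ldc_distance(c(1, 2), c(1, 2, 3), diag(2)), "mismatch")
})

test_that("compute_rdm equals a brute-force CV Euclidean RDM under identity", {
  toy <- toy_features(n_cond = 4, per_cond = 16, p = 6, seed = 7)
  folds <- stratified_folds(toy$cond, k = 8, seed = 8)
  r <- compute_rdm(toy$x, toy$cond, k = 8, n_reps = 1, folds = folds,
                   cov = "identity")
  oracle <- bruteforce_cv_euclid_rdm(toy$x, toy$cond, folds, k = 8)
  expect_lt(max(abs(r$values - oracle)) / max(abs(oracle)), 1e-10)
  expect_equal(diag(r$values), rep(0, 4))
  expect_equal(r$values, t(r$values))
})

test_that("compiled and reference RDM engines agree given shared folds", {
  toy <- toy_features(n_cond = 4, per_cond = 16, p = 6, seed = 9)
  folds <- stratified_folds(toy$cond, k = 8, seed = 10)
  for (cv in c("identity", "shrinkage")) {
    a <- compute_rdm(toy$x, toy$cond, k = 8, n_reps = 1, folds = folds,
                     cov = cv, engine = "cpp")
    b <- compute_rdm(toy$x, toy$cond, k = 8, n_reps = 1, folds = folds,
                     cov = cv, engine = "r")
    expect_equal(unname(a$values), unname(b$values), tolerance = 1e-10)
  }
})

test_that("RDMs are invariant to trial order and recover true structure", {
  toy <- toy_features(n_cond = 4, per_cond = 16, p = 6, sep = 3, seed = 11)
  r1 <- compute_rdm(toy$x, toy$cond, k = 4, n_reps = 2, seed = 12)
  perm <- sample(length(toy$cond))
  r2 <- compute_rdm(toy$x[perm, ], toy$cond[perm], k = 4, n_reps = 2,
                    seed = 12)
  # same distribution of distances; same conditions recovered
  expect_equal(r1$n_conditions, r2$n_conditions)
  expect_gt(cor(r1$values[lower.tri(r1$values)],
                r2$values[lower.tri(r2$values)]), 0.95)
  # separable classes: all between-condition distances clearly positive
  expect_true(all(r1$values[lower.tri(r1$values)] > 0))
})

test_that("pure-noise features give RDMs centred on zero", {
  set.seed(13)
  vals <- replicate(12, {
    x <- matrix(rnorm(240 * 8), 240, 8)
    cond <- rep(1:6, each = 40)
    r <- compute_rdm(x, cond, k = 8, n_reps = 1)
    mean(r$values[lower.tri(r$values)])
  })
  tt <- mean(vals) / (sd(vals) / sqrt(length(vals)))
  expect_lt(abs(tt), 3)
})

test_that("RDM dimensions match the condition structure of each impulse", {
  d <- generate_design(1440, seed = 14)
  sim <- simulate_subject(scenario_spec("unique_scheme_both"), d, seed = 15)
  ck1 <- condition_keys(d, "impulse1")
  r1 <- compute_rdm(sim$features, ck1$id, k = 8, n_reps = 1, seed = 16)
  expect_equal(dim(r1$values), c(72, 72))
  ck2 <- condition_keys(d, "impulse2")
  r2 <- compute_rdm(sim$features, ck2$id, k = 8, n_reps = 1, seed = 17)
  expect_equal(dim(r2$values), c(60, 60))
})

test_that("model RDMs encode the hypothesised similarity structure", {
  d <- generate_design(1440, seed = 18)
  ck <- condition_keys(d, "impulse2")
  keys <- ck$keys

  m_cued <- model_rdm(keys, "cued")
  i15 <- which(keys$cued_ori == 15)[1]
  i165 <- which(keys$cued_ori == 165)[1]
  expect_equal(m_cued$values[i15, i165], 30)

  m_loc <- model_rdm(keys, "location")
  il <- which(keys$cue_side == "left")[1]
  ir <- which(keys$cue_side == "right")[1]
  expect_equal(m_loc$values[il, ir], 1)
  expect_equal(m_loc$values[il, il], 0)

  # rotation model: same-vs-different instruction, one level at a time
  m_rot <- model_rdm(keys, "rotation", level = -60)
  i60 <- which(keys$rotation == -60)[1:2]
  i30 <- which(keys$rotation == 30)[1]
  i0 <- which(keys$rotation == 0)[1]
  expect_equal(m_rot$values[i60[1], i60[2]], -1)
  expect_equal(m_rot$values[i60[1], i60[1]], -1)
  expect_equal(m_rot$values[i60[1], i30], 1)
  expect_equal(m_rot$values[i30, i0], 1)

  # down-weighting: across-side cells equal the pre-replacement average
  m_w <- model_rdm(keys, "cued", location_mode = "within")
  pre <- model_rdm(keys, "cued")
  same <- outer(keys$cue_side, keys$cue_side, `==`)
  expect_true(all(m_w$values[!same] == mean(pre$values)))
  expect_equal(m_w$values[same], pre$values[same])

  # generalisation model is symmetric
  m_g <- model_rdm(keys, "generalisation",
                   items = c("cued_ori", "rotated_ori"))
  expect_equal(m_g$values, t(m_g$values))
  expect_error(model_rdm(keys, "rotation"), "level")
})

test_that("model regression recovers planted coefficients", {
  d <- generate_design(1440, seed = 19)
  keys <- condition_keys(d, "impulse2")$keys
  m_cued <- model_rdm(keys, "cued")
  m_loc <- model_rdm(keys, "location")

  # data = one model exactly: beta equals 1 after z-scoring (= Pearson r)
  fake <- structure(list(values = 2 * m_cued$values, labels = NULL),
                    class = "rdm")
  fit <- regress_models(fake, list(cued = m_cued))
  expect_equal(unname(fit$beta["cued"]), 1, tolerance = 1e-10)

  # near-orthogonal models: each beta recovered independently
  v <- zscore(m_cued$values[lower.tri(m_cued$values)])
  w <- zscore(m_loc$values[lower.tri(m_loc$values)])
  expect_lt(abs(cor(v, w)), 0.05)
  comb <- matrix(0, 60, 60)
  comb[lower.tri(comb)] <- 1.5 * v + 0.5 * w
  comb <- comb + t(comb)
  fit2 <- regress_models(comb, list(cued = m_cued, location = m_loc))
  alone <- regress_models(comb, list(cued = m_cued))
  expect_equal(unname(fit2$beta["cued"]), unname(alone$beta["cued"]),
               tolerance = 0.02)

  # constant data vector: all betas zero
  fit3 <- regress_models(matrix(1, 60, 60), list(cued = m_cued))
  expect_equal(unname(fit3$beta["cued"]), 0)

  # collinear models are rejected with the pair named
  expect_error(regress_models(comb, list(a = m_cued, b = m_cued)),
               "collinear")
})

test_that("residual fitting removes only the targeted structure", {
  d <- generate_design(1440, seed = 20)
  keys <- condition_keys(d, "impulse2")$keys
  m_cued <- model_rdm(keys, "cued")
  m_loc <- model_rdm(keys, "location")
  v <- zscore(m_cued$values[lower.tri(m_cued$values)])
  w <- zscore(m_loc$values[lower.tri(m_loc$values)])
  # data built from the cued model only
  pure <- matrix(0, 60, 60)
  pure[lower.tri(pure)] <- v
  pure <- pure + t(pure)

  # removing a model (near-)orthogonal to the data leaves the test beta
  # essentially unchanged
  b_direct <- regress_models(pure, list(cued = m_cued))$beta["cued"]
  b_resid <- residual_fit(pure, m_loc, m_cued)
  expect_equal(unname(b_resid), unname(b_direct), tolerance = 0.01)

  # removing the model itself drives its residual fit to zero
  expect_lt(abs(residual_fit(pure, m_cued, m_cued)), 1e-10)
})

test_that("impulse-2 workflow betas match between fast and generic paths", {
  d <- generate_design(720, seed = 21)
  sim <- simulate_subject(scenario_spec("unique_scheme_both"), d, seed = 22)
  ck <- condition_keys(d, "impulse2", location = FALSE)
  r <- compute_rdm(sim$features, ck$id, k = 8, n_reps = 2, seed = 23)
  slow <- fit_impulse2_models(r, ck$keys)
  fast <- wmrsa:::.fit_impulse2_fast(r$values,
                                     wmrsa:::.prep_impulse2_models(ck$keys))
  expect_equal(slow, fast, tolerance = 1e-10)
})
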