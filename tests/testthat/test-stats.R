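test_that("fisher_z is the odd atanh transform with domain guards", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  rr <- seq(-0.9, 0.9, by = 0.15)
  expect_equal(fisher_z(-rr), -fisher_z(rr))
  expect_error(fisher_z(1), "< 1")
  expect_error(fisher_z(-1.2), "< 1")
})

test_that("permutation t-test handles extremes and respects its floor", {
  # no effect and no variance: p = 1 by convention
  expect_equal(perm_ttest(rep(0, 10))$p, 1)
  expect_error(perm_ttest(rep(2, 10)), "zero-variance")
  expect_error(perm_ttest(3), "at least 2")

  # overwhelming effect: p sits at the 1/(n_perm+1) floor
  set.seed(1)
  strong <- rnorm(20, mean = 5, sd = 0.5)
  pt <- perm_ttest(strong, n_perm = 199, seed = 2)
  expect_equal(pt$p, 1 / 200)

  # p is invariant to monotone rescaling of the statistic
  pt_scaled <- perm_ttest(strong * 3.7, n_perm = 199, seed = 2)
  expect_equal(pt$p, pt_scaled$p)

  # matrix null: matches the generator route
  null_mat <- matrix(rnorm(20 * 99), 20, 99)
  p1 <- perm_ttest(strong, null = null_mat)
  expect_equal(p1$p, 1 / 100)
})

test_that("permutation t-test type-I error matches its discrete nominal rate", {
  # label-shuffle null: per-subject statistic is a noise cross-product
  set.seed(3)
  n_sim <- 300; n_sub <- 12; n_tr <- 24; n_perm <- 99
  rejections <- 0
  for (i in seq_len(n_sim)) {
    xs <- matrix(rnorm(n_sub * n_tr), n_sub)
    ys <- matrix(rnorm(n_sub * n_tr), n_sub)
    vals <- rowMeans(xs * ys)
    null_mat <- vapply(seq_len(n_perm), function(j)
      rowMeans(xs * ys[, sample.int(n_tr)]), numeric(n_sub))
    p <- perm_ttest(vals, null = null_mat)$p
    if (p < 0.05) rejections <- rejections + 1
  }
  # nominal rate for n_perm = 99 and alpha 0.05 is 4/100
  nominal <- floor(0.05 * (n_perm + 1)) / (n_perm + 1)
  ci <- nominal + c(-1, 1) * 1.96 * sqrt(nominal * (1 - nominal) / n_sim)
  expect_gte(rejections / n_sim, ci[1])
  expect_lte(rejections / n_sim, ci[2])
})

test_that("cluster permutation finds planted effects and only those", {
  set.seed(4)
  n_sub <- 18; n_cen <- 40
  x <- matrix(rnorm(n_sub * n_cen), n_sub)
  x[, 10:20] <- x[, 10:20] + 1.2   # strong contiguous effect
  cp <- cluster_perm(x, n_perm = 499, seed = 5)
  sig <- which(cp$p < 0.05)
  expect_length(sig, 1)
  covered <- cp$clusters[[sig]]
  expect_true(all(covered >= 8 & covered <= 22))
  expect_gte(length(intersect(covered, 10:20)), 9)

  # constant huge effect: one cluster spanning everything, p at the floor
  xb <- matrix(rnorm(n_sub * n_cen, mean = 4), n_sub)
  cpb <- cluster_perm(xb, n_perm = 199, seed = 6)
  expect_length(cpb$clusters, 1)
  expect_equal(sort(cpb$clusters[[1]]), seq_len(n_cen))
  expect_equal(cpb$p, 1 / 200)
  expect_error(cluster_perm(x[1, , drop = FALSE]), ">= 2")
})

test_that("cluster permutation controls family-wise error on null data", {
  set.seed(7)
  n_sim <- 400
  rejections <- 0
  for (i in seq_len(n_sim)) {
    x <- matrix(rnorm(14 * 25), 14)
    cp <- cluster_perm(x, n_perm = 99)
    if (length(cp$p) && any(cp$p < 0.05)) rejections <- rejections + 1
  }
  rate <- rejections / n_sim
  # within a generous binomial window around the nominal 5%
  expect_gte(rate, 0.05 - 1.96 * sqrt(0.05 * 0.95 / n_sim) - 0.01)
  expect_lte(rate, 0.05 + 1.96 * sqrt(0.05 * 0.95 / n_sim) + 0.01)
})

test_that("behaviour regression is invariant to residualisation when
           regressors are orthogonal", {
  set.seed(8)
  # orthogonality must hold within each subject for residualisation to be
  # a per-subject no-op
  dat <- do.call(rbind, lapply(1:2, function(s) {
    n <- 150
    s_c <- rnorm(n)
    s_r <- lm(rnorm(n) ~ s_c)$residuals  # exactly orthogonal to s_c
    data.frame(subject = s, s_cued = s_c, s_rot = s_r,
               accuracy = rbinom(n, 1, plogis(0.8 + 0.5 * s_c)),
               rt = exp(-0.4 - 0.3 * s_r + rnorm(n, 0, 0.2)))
  }))
  bf <- behaviour_regression(dat, n_perm = 9, seed = 9)
  # compare against direct non-residualised fits per subject
  for (s in 1:2) {
    d <- dat[dat$subject == s, ]
    direct_rt <- coef(lm(log(rt) ~ s_cued + s_rot, data = d))[2:3]
    expect_equal(unname(bf$betas[s, c("rt_cued", "rt_rot")]),
                 unname(direct_rt), tolerance = 1e-6)
    direct_acc <- coef(glm(accuracy ~ s_cued + s_rot, data = d,
                           family = binomial()))[2:3]
    expect_equal(unname(bf$betas[s, c("acc_cued", "acc_rot")]),
                 unname(direct_acc), tolerance = 1e-6)
  }
})

test_that("behaviour regression recovers planted RT effects and flags
           degenerate accuracy", {
  set.seed(10)
  dat <- do.call(rbind, lapply(1:6, function(s) {
    n <- 300
    s_c <- rnorm(n, 0.04, 0.05)
    s_r <- rnorm(n, 0.04, 0.05)
    data.frame(subject = s, s_cued = s_c, s_rot = s_r,
               accuracy = if (s == 6) rep(1, n) else rbinom(n, 1, 0.85),
               rt = exp(-0.6 - 1 * s_r + rnorm(n, 0, 0.25)))
  }))
  bf <- behaviour_regression(dat, n_perm = 99, seed = 11)
  tests <- bf$tests
  expect_lt(tests$t[tests$term == "rt_rot"], 0)
  expect_lt(tests$p[tests$term == "rt_rot"], 0.05)
  # all-correct subject is excluded from the logistic aggregate only
  expect_true(6 %in% bf$excluded)
  expect_equal(tests$n[tests$term == "acc_cued"], 5)
  expect_equal(tests$n[tests$term == "rt_cued"], 6)
  expect_error(behaviour_regression(dat[, -3]), "missing columns")
})
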