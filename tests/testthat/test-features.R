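make_epochs <- function(n_trials = 4, srate = 500,
                        channels = posterior_channels(),
                        span = c(-0.15, 0.6), fill = NULL, seed = 1) {
  set.seed(seed)
  times <- seq(span[1], span[2], by = 1 / srate)
  arr <- array(rnorm(n_trials * length(channels) * length(times)),
               c(n_trials, length(channels), length(times)))
  if (!is.null(fill)) {
    for (tr in seq_len(n_trials)) for (ch in seq_along(channels)) {
      arr[tr, ch, ] <- fill(times, tr, ch)
    }
  }
  epochs(arr, channels, times, srate)
}

test_that("spatiotemporal extraction yields 510 zero-mean features", {
  ep <- make_epochs()
  fm <- extract_spatiotemporal(ep)
  expect_equal(ncol(fm$values), 510)  # 17 channels x 30 time points
  expect_equal(nrow(fm$feature_index), 510)
  # per trial and channel, window mean is zero
  for (ch in c("P7", "Oz")) {
    cols <- which(fm$feature_index$channel == ch)
    expect_lt(max(abs(rowMeans(fm$values[, cols]))), 1e-10)
  }
  expect_error(extract_spatiotemporal(ep, channels = c("P7", "XX")), "XX")
  expect_error(extract_spatiotemporal(ep, window = c(0.5, 0.9)),
               "outside")
})

test_that("constant or offset signals are annihilated by the relative baseline", {
  ep <- make_epochs(fill = function(t, tr, ch) rep(7 + tr + ch, length(t)))
  fm <- extract_spatiotemporal(ep)
  expect_lt(max(abs(fm$values)), 1e-10)

  # adding a per-(trial, channel) constant to noisy data changes nothing
  ep1 <- make_epochs(seed = 2)
  ep2 <- ep1
  for (tr in 1:4) for (ch in 1:17) {
    ep2$data[tr, ch, ] <- ep1$data[tr, ch, ] + 3 * tr - 5 * ch
  }
  expect_equal(extract_spatiotemporal(ep1)$values,
               extract_spatiotemporal(ep2)$values, tolerance = 1e-9)
})

test_that("drift confined outside the window leaves features unchanged", {
  ep1 <- make_epochs(seed = 3)
  ep2 <- ep1
  t0 <- 0.1
  ramp <- pmin(ep1$times, t0)  # rises before the window, flat inside
  for (tr in 1:4) for (ch in 1:17) {
    ep2$data[tr, ch, ] <- ep1$data[tr, ch, ] + (10 * tr + ch) * ramp
  }
  expect_equal(extract_spatiotemporal(ep1)$values,
               extract_spatiotemporal(ep2)$values, tolerance = 1e-9)
})

test_that("downsampling preserves a slow sinusoid at kept sample times", {
  freq <- 10
  ep <- make_epochs(n_trials = 2,
                    fill = function(t, tr, ch) sin(2 * pi * freq * t))
  fm <- extract_spatiotemporal(ep)
  tt <- ep$times[ep$times >= 0.1 - 1e-9 & ep$times < 0.4 - 1e-9]
  kept <- tt[seq(1, length(tt), by = 5)]
  expected <- sin(2 * pi * freq * kept)
  expected <- expected - mean(expected)
  expect_equal(unname(fm$values[1, 1:30]), expected, tolerance = 0.01)
})

test_that("extraction commutes with trial reordering", {
  ep <- make_epochs(n_trials = 6, seed = 4)
  perm <- c(4, 1, 6, 2, 5, 3)
  ep_perm <- ep
  ep_perm$data <- ep$data[perm, , , drop = FALSE]
  expect_equal(extract_spatiotemporal(ep_perm)$values,
               extract_spatiotemporal(ep)$values[perm, ])
})

test_that("time-course extraction gives 170 features per 61 centres", {
  ep <- make_epochs(n_trials = 2)
  tc <- extract_timecourse(ep)
  expect_length(tc, 61)
  expect_true(all(vapply(tc, function(f) ncol(f$values), numeric(1)) == 170))
  # constant signal: every window is all-zero
  epc <- make_epochs(n_trials = 2, fill = function(t, tr, ch) rep(5, length(t)))
  tcc <- extract_timecourse(epc, centers = c(0, 0.05))
  expect_lt(max(abs(tcc[[1]]$values)), 1e-10)
  expect_lt(max(abs(tcc[[2]]$values)), 1e-10)
})

test_that("searchlight groups match a brute-force nearest-neighbour sort", {
  # degenerate: 3 channels, every group is the full set
  lay3 <- data.frame(channel = c("a", "b", "c"), x = c(0, 1, 5), y = 0)
  g3 <- searchlight_groups(lay3)
  expect_true(all(vapply(g3, function(g)
    setequal(g, c("a", "b", "c")), logical(1))))

  # collinear equally spaced: group(B) = {B, A, C}
  lay4 <- data.frame(channel = c("A", "B", "C", "D"), x = 0:3, y = 0)
  expect_setequal(searchlight_groups(lay4)$B, c("B", "A", "C"))

  # random 62-channel layout against a full distance sort
  set.seed(5)
  lay <- data.frame(channel = sprintf("ch%02d", 1:62),
                    x = runif(62), y = runif(62))
  gr <- searchlight_groups(lay)
  d <- as.matrix(dist(cbind(lay$x, lay$y)))
  for (i in seq_len(62)) {
    nn <- lay$channel[setdiff(order(d[i, ]), i)[1:2]]
    expect_setequal(gr[[i]], c(lay$channel[i], nn))
  }
  expect_error(searchlight_groups(lay3[1:2, ]), "at least 3")
})

test_that("gaussian smoothing preserves constants and affine trends", {
  const <- rep(4.2, 61)
  expect_equal(smooth_timecourse(const), const)
  ramp <- seq(0, 6, length.out = 61)
  sm <- smooth_timecourse(ramp)
  interior <- 10:52
  expect_equal(sm[interior], ramp[interior], tolerance = 1e-6)
  # unit impulse spreads into the (renormalised) kernel shape
  imp <- rep(0, 61); imp[31] <- 1
  sm_imp <- smooth_timecourse(imp, sd = 0.016, spacing = 0.01)
  kern <- dnorm(seq(-7, 7) * 0.01, sd = 0.016)
  expect_equal(which.max(sm_imp), 31)
  expect_equal(sm_imp[31] / sm_imp[32], kern[8] / kern[9], tolerance = 1e-6)
  expect_error(smooth_timecourse(ramp, sd = 0), "positive")
})

test_that("epochs round-trip through the binary container", {
  ep <- make_epochs(n_trials = 3, seed = 6)
  path <- tempfile(fileext = ".dat")
  write_epochs(ep, path)
  back <- read_epochs(path)
  expect_equal(back$data, ep$data)
  expect_equal(back$channel_names, ep$channel_names)
  expect_equal(back$times, ep$times)
  unlink(c(path, paste0(path, ".json")))
})
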