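# Synthetic spike trains, pseudo-targets, event streams and preprocessing.

test_that("Poisson trains have Bernoulli per-bin statistics and are seeded", {
  expect_true(all(poisson_spike_train(rep(0, 5), 100, 1, seed = 1) == 0))
  tr1 <- poisson_spike_train(rep(100, 20), 500, 1, seed = 2)
  tr2 <- poisson_spike_train(rep(100, 20), 500, 1, seed = 2)
  expect_identical(tr1, tr2)
  expect_true(all(tr1 %in% c(0, 1)))
  # per-unit counts: binomial n = 500, p = 0.1 -> mean 50, sd ~ 6.7
  counts <- colSums(tr1)
  expect_true(all(abs(counts - 50) < 4 * sqrt(500 * 0.1 * 0.9)))
  expect_error(poisson_spike_train(2000, 10, 1, seed = 1), "rate")
  # empirical rate converges to nominal at 3-sigma binomial tolerance
  long <- poisson_spike_train(40, 20000, 1, seed = 3)
  p <- 40 / 1000
  expect_lt(abs(mean(long) - p), 3 * sqrt(p * (1 - p) / 20000))
})

test_that("regression pseudo-targets span [0,1] with the stated shapes", {
  tg <- regression_targets(500, 1)
  expect_identical(colnames(tg), c("ramp", "sin_hi", "sin_lo"))
  expect_equal(tg[1, "ramp"], 0, ignore_attr = TRUE)
  expect_equal(tg[500, "ramp"], 1, ignore_attr = TRUE)
  expect_equal(tg[1, "sin_hi"], 0.5, ignore_attr = TRUE) # sin(0) = 0
  expect_true(all(tg >= 0 & tg <= 1))
  # 2 Hz over 500 ms is exactly one period
  t_sec <- (0:499) / 1000
  expect_equal(tg[, "sin_lo"], 0.5 * (1 + sin(2 * pi * 2 * t_sec)), ignore_attr = TRUE)
  expect_error(regression_targets(1), "T_steps")
})

test_that("a noiseless bar emits ON at the leading and OFF at the trailing edge", {
  ev <- moving_bar_events(1, width = 8, height = 4, duration = 8, bar_width = 2,
                          jitter = 0, noise_rate = 0, seed = 1)
  # event count: 2 * height per step
  expect_identical(nrow(ev), 2L * 4L * 8L)
  step0 <- ev[ev$t == 0, ]
  expect_setequal(step0$x[step0$p == "ON"], 0) # leading column at x = 0
  expect_setequal(step0$x[step0$p == "OFF"], (0 - 2) %% 8) # trailing, wrapped
  step3 <- ev[ev$t == 3, ]
  expect_setequal(step3$x[step3$p == "ON"], 3)
  expect_setequal(step3$x[step3$p == "OFF"], 1)
  expect_error(moving_bar_events(99), "class_id")
})

test_that("right-to-left streams mirror left-to-right streams", {
  lr <- moving_bar_events(1, width = 10, height = 5, duration = 20, seed = 4)
  rl <- moving_bar_events(2, width = 10, height = 5, duration = 20, seed = 4)
  mirrored <- lr
  mirrored$x <- 10L - 1L - lr$x
  key <- function(d) {
    d <- d[order(d$t, d$x, d$y, d$p), c("t", "x", "y", "p")]
    rownames(d) <- NULL
    d
  }
  expect_identical(key(as.data.frame(mirrored)), key(as.data.frame(rl)))
})

test_that("generators are pure functions of parameters and seed", {
  a <- moving_bar_events(3, jitter = 0.5, noise_rate = 1, seed = 9)
  b <- moving_bar_events(3, jitter = 0.5, noise_rate = 1, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, moving_bar_events(3, jitter = 0.5, noise_rate = 1, seed = 10)))
  expect_true(all(diff(a$t) >= 0))
  expect_true(all(a$x >= 0 & a$x < 16 & a$y >= 0 & a$y < 16))
})

test_that("event binning counts every event once and downsampling sums neighbourhoods", {
  ev <- data.frame(t = c(0.4, 0.7, 1.2), x = c(3, 3, 5), y = c(2, 2, 1),
                   p = c("ON", "ON", "OFF"))
  stream <- structure(ev, width = 8L, height = 8L, duration = 2,
                      class = c("decolle_event_stream", "data.frame"))
  fr <- bin_events(stream, bin_ms = 1)
  expect_identical(dim(fr), c(2L, 2L, 8L, 8L))
  expect_equal(fr[1, 1, 3, 4], 2) # two ON events in bin 1 at (x=3, y=2)
  expect_equal(fr[2, 2, 2, 6], 1)
  expect_equal(sum(fr), nrow(ev)) # conservation
  # noisy bar: total count still conserved
  bar <- moving_bar_events(2, jitter = 0.4, noise_rate = 2, seed = 5)
  fb <- bin_events(bar, bin_ms = 1)
  expect_equal(sum(fb), nrow(bar))
  expect_error(bin_events(bar, spatial_factor = 3), "divisible")
})

test_that("spatial downsampling by 2 twice equals downsampling by 4 once", {
  bar <- moving_bar_events(4, width = 16, height = 16, jitter = 0.3,
                           noise_rate = 1, seed = 6)
  once <- bin_events(bar, 1, spatial_factor = 4)
  twice_a <- bin_events(bar, 1, spatial_factor = 2)
  # fold the factor-2 tensor once more by summing 2x2 neighbourhoods
  d <- dim(twice_a)
  twice <- array(0L, c(d[1], d[2], d[3] / 2, d[4] / 2))
  for (yy in seq_len(d[3] / 2)) for (xx in seq_len(d[4] / 2)) {
    twice[, , yy, xx] <- twice_a[, , 2 * yy - 1, 2 * xx - 1] +
      twice_a[, , 2 * yy, 2 * xx - 1] + twice_a[, , 2 * yy - 1, 2 * xx] +
      twice_a[, , 2 * yy, 2 * xx]
  }
  expect_equal(as.vector(once), as.vector(twice))
  expect_equal(sum(once), nrow(bar))
})

test_that("random slices are valid, seeded and cover the allowed starts", {
  bar <- moving_bar_events(1, duration = 100, seed = 7)
  fr <- bin_events(bar, 1)
  full <- slice_sequence(fr, 100, seed = 1)
  expect_equal(as.vector(full), as.vector(fr)) # full-length slice is the identity
  s1 <- slice_sequence(fr, 40, seed = 2)
  expect_identical(slice_sequence(fr, 40, seed = 2), s1)
  expect_identical(dim(s1)[1], 40L)
  starts <- vapply(1:100, function(s) attr(slice_sequence(fr, 40, seed = s), "start_ms"),
                   numeric(1))
  expect_true(all(starts >= 0 & starts <= 60))
  expect_gt(length(unique(starts)), 10)
  expect_error(slice_sequence(fr, 200, seed = 1), "shorter")
})

test_that("event streams round-trip through the tabular text format", {
  ev <- moving_bar_events(2, jitter = 0.2, noise_rate = 1, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(attr(back, "width"), attr(ev, "width"))
  expect_equal(attr(back, "duration"), attr(ev, "duration"))
  expect_equal(back$t, ev$t, tolerance = 1e-12)
  expect_identical(back$x, ev$x)
  expect_identical(back$p, ev$p)
  expect_error(read_events(withr::local_tempfile(lines = "t,x,y,p")), "geometry")
})

test_that("noise-free class templates separate noisy samples at the pixel level", {
  # sanity precondition for the classification experiment: the noiseless
  # spatiotemporal class tensors are distinct, and a nearest-centroid
  # (linear) classifier on flattened tensors labels noisy samples
  # perfectly
  templates <- lapply(1:4, function(cls) {
    as.vector(bin_events(moving_bar_events(cls, jitter = 0, noise_rate = 0, seed = 1), 1))
  })
  for (a in 1:3) for (b in (a + 1):4) {
    expect_gt(sum(abs(templates[[a]] - templates[[b]])), 100)
  }
  hits <- 0L
  for (cls in 1:4) for (s in 1:3) {
    noisy <- as.vector(bin_events(
      moving_bar_events(cls, jitter = 0.5, noise_rate = 2, seed = 40 + 10 * cls + s), 1
    ))
    d <- vapply(templates, function(tp) sum((noisy - tp)^2), numeric(1))
    hits <- hits + (which.min(d) == cls)
  }
  expect_identical(hits, 12L)
})
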