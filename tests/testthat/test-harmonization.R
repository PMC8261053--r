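test_that("dataset stats take the extremes over all recordings", {
  r1 <- raw_recording(matrix(-3:3, 1), 10, "Cz")
  r2 <- raw_recording(matrix(c(-1, 2, 5), 1), 10, "Cz")
  st <- compute_dataset_stats(list(r1, r2))
  expect_equal(st$global_min, -3)
  expect_equal(st$global_max, 5)
  expect_error(compute_dataset_stats(list()), "no recordings")
  flat <- raw_recording(matrix(rep(2, 8), 1), 10, "Cz")
  expect_error(compute_dataset_stats(list(flat)), "degenerate")
})

test_that("sequence scaling maps extremes to [-1, 1] and is idempotent", {
  sc <- scale_sequence(c(0, 2, 4))
  expect_equal(sc$scaled, c(-1, 0, 1))
  expect_false(sc$degenerate)
  expect_equal(scale_sequence(c(-1, 1))$scaled, c(-1, 1))
  flat <- scale_sequence(c(5, 5, 5))
  expect_equal(flat$scaled, c(0, 0, 0))
  expect_true(flat$degenerate)
  # idempotence on random multichannel input
  set.seed(1)
  for (i in 1:5) {
    x <- matrix(rnorm(60, sd = 10 * i), 4, 15)
    once <- scale_sequence(x)$scaled
    twice <- scale_sequence(once)$scaled
    expect_equal(twice, once, tolerance = 1e-12)
    expect_equal(max(once), 1)
    expect_equal(min(once), -1)
  }
})

test_that("relative amplitude is the ratio of trial to dataset range", {
  st <- structure(list(global_min = -400, global_max = 600),
                  class = "dataset_stats")
  expect_equal(amplitude_value(-50, 150, st), 0.2)
  expect_equal(amplitude_value(-400, 600, st), 1.0)
  expect_equal(amplitude_value(3, 3, st), 0)
  expect_warning(v <- amplitude_value(-500, 700, st), "clamped")
  expect_equal(v, 1)
})

test_that("whole-multiple resampling picks the nearest intermediate rate", {
  # 2048 Hz -> exact integer decimation by 8; oracle: direct decimation
  x <- matrix(sin(2 * pi * 5 * (0:4095) / 2048), 1)
  r <- raw_recording(x, 2048, "Cz")
  out <- resample_to_target(r, 256)
  expect_equal(out$sfreq, 256)
  expect_equal(ncol(out$data), 512)
  expect_equal(out$data[1, ], x[1, seq(1, 4096, by = 8)])
  # 160 Hz: oracle enumerates whole multiples; 320 is nearest to 256
  mults <- 160 * (1:6)
  expect_equal(mults[which.min(abs(mults - 256))], 320)
  r160 <- raw_recording(matrix(rnorm(480), 1), 160, "Cz")
  out160 <- resample_to_target(r160, 256)
  expect_equal(out160$sfreq, 256)
  # 3 s at 160 Hz -> 768 samples at 256 Hz via the 320 Hz intermediate
  expect_equal(ncol(out160$data), 768)
  # identity at target
  r256 <- raw_recording(matrix(rnorm(512), 1), 256, "Cz")
  expect_identical(resample_to_target(r256, 256)$data, r256$data)
})

test_that("resampling preserves duration within one output sample", {
  for (fs in c(100, 160, 200, 250, 256, 2048)) {
    n <- round(3 * fs)
    r <- raw_recording(matrix(rnorm(n), 1), fs, "Cz")
    out <- resample_to_target(r, 256)
    expect_equal(out$sfreq, 256)
    expect_lt(abs(recording_duration(out) - 3), 1 / 256 + 1e-12)
  }
})

test_that("anti-alias filter passes the band and kills aliases", {
  fs <- 2048
  tt <- (0:(8 * fs - 1)) / fs
  x <- rbind(sin(2 * pi * 10 * tt), sin(2 * pi * 500 * tt))
  r <- raw_recording(x, fs, c("C3", "C4"))
  out <- apply_antialias(r, 120)
  expect_equal(dim(out$data), dim(x))
  p10 <- band_power(out$data[1, ], fs, 8, 12) /
    band_power(x[1, ], fs, 8, 12)
  expect_gt(p10, 0.99)
  atten_db <- 10 * log10(band_power(x[2, ], fs, 490, 510) /
                           band_power(out$data[2, ], fs, 490, 510))
  expect_gt(atten_db, 40)
  # cutoff at/above Nyquist is a no-op with warning
  r2 <- raw_recording(matrix(rnorm(512), 1), 256, "Cz")
  expect_warning(out2 <- apply_antialias(r2, 200), "Nyquist")
  expect_identical(out2$data, r2$data)
})

test_that("harmonization yields 20 rows with canonical placement", {
  st <- structure(list(global_min = -100, global_max = 100),
                  class = "dataset_stats")
  # superset montage: surplus channels ignored
  chans <- c(canonical_channels(), paste0("X", 1:45))
  set.seed(2)
  r <- raw_recording(matrix(rnorm(64 * 512, sd = 20), 64, 512), 256, chans)
  h <- harmonize_recording(r, stats = st)
  expect_equal(nrow(h$data), 20L)
  expect_true(all(h$present))
  expect_equal(max(h$data[1:19, ]), 1, tolerance = 1e-6)
  expect_equal(min(h$data[1:19, ]), -1, tolerance = 1e-6)
  expect_equal(length(unique(h$data[20, ])), 1L)
  # sleep-style two bipolar channels -> 2 populated + 17 zero rows
  r2 <- raw_recording(matrix(rnorm(2 * 512, sd = 10), 2, 512), 256,
                      c("FPz-Cz", "Pz-Oz"))
  h2 <- harmonize_recording(r2, stats = st)
  expect_equal(sum(h2$present), 2L)
  canon <- canonical_channels()
  pop <- which(h2$present)
  expect_setequal(canon[pop], c("Fp1", "Pz"))
  zero_rows <- setdiff(1:19, pop)
  expect_true(all(h2$data[zero_rows, ] == 0))
  # case-insensitive + legacy names
  r3 <- raw_recording(matrix(rnorm(2 * 256), 2, 256), 256, c("t3", "FZ"))
  h3 <- harmonize_recording(r3, stats = st)
  expect_setequal(canon[which(h3$present)], c("T7", "Fz"))
  # no canonical channels at all
  r4 <- raw_recording(matrix(rnorm(256), 1, 256), 256, "EMG")
  expect_error(harmonize_recording(r4, stats = st), "unmappable")
  # wrong rate rejected
  r5 <- raw_recording(matrix(rnorm(200), 1, 200), 100, "Cz")
  expect_error(harmonize_recording(r5, stats = st), "256")
})

test_that("pre-training windows tile the sequence without overlap", {
  st <- structure(list(global_min = -50, global_max = 50),
                  class = "dataset_stats")
  mk <- function(secs) {
    r <- raw_recording(matrix(rnorm(19 * secs * 256, sd = 10), 19,
                              secs * 256), 256, canonical_channels())
    harmonize_recording(r, stats = st)
  }
  w130 <- window_pretrain(mk(130), 60)
  expect_length(w130, 2L)
  expect_true(all(vapply(w130, function(w) ncol(w$data), 0) == 15360))
  expect_length(window_pretrain(mk(59), 60), 0L)
  h <- mk(120)
  w <- window_pretrain(h, 60)
  expect_identical(w[[1]]$data, h$data[, 1:15360])
  expect_identical(w[[2]]$data, h$data[, 15361:30720])
})

test_that("trial extraction uses floored onset arithmetic and drops overruns", {
  st <- structure(list(global_min = -50, global_max = 50),
                  class = "dataset_stats")
  r <- raw_recording(matrix(rnorm(19 * 50 * 256, sd = 10), 19, 50 * 256),
                     256, canonical_channels())
  h <- harmonize_recording(r, stats = st)
  ev <- data.frame(onset = 10, duration = 0, label = "x")
  tr <- extract_trials(h, ev, start_s = -0.7, length_s = 2)
  expect_length(tr$trials, 1L)
  s0 <- floor(9.3 * 256)   # 0-based
  expect_equal(dim(tr$trials[[1]]), c(20L, 512L))
  expect_identical(tr$trials[[1]], h$data[, (s0 + 1):(s0 + 512)])
  # pre-recording window dropped
  ev2 <- data.frame(onset = c(0.5, 10), duration = 0, label = c("a", "b"))
  expect_message(tr2 <- extract_trials(h, ev2, start_s = -2, length_s = 2),
                 "dropped 1")
  expect_equal(tr2$labels, "b")
  # 30-s sleep segment
  tr3 <- extract_trials(h, data.frame(onset = 10, duration = 0, label = "W"),
                        start_s = 0, length_s = 30)
  expect_equal(ncol(tr3$trials[[1]]), 7680L)
})
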