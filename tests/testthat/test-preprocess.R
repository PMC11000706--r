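# digital squared magnitude of the order-2 band-pass design at 60 Hz /
# fs 173.61, cutoffs 0.5-50 Hz; frozen from an independent filter-design
# oracle (scipy.signal.butter + freqz)
GAIN2_60HZ <- 0.16613841583753078
GAIN2_10HZ <- 0.9999186023337082

central <- function(x, drop_frac = 0.1) {
  n <- length(x)
  k <- max(1L, floor(n * drop_frac))
  x[(k + 1):(n - k)]
}

tone <- function(freq, n = 4097L, fs = BONN_FS) {
  eeg_record(sin(2 * pi * freq * (seq_len(n) - 1) / fs), fs = fs,
             set_id = "A", source_id = sprintf("tone%g", freq))
}

test_that("stopband tones are attenuated per the squared Butterworth response", {
  x <- tone(60)
  y <- bandpass_filter(x)
  ratio <- sqrt(mean(central(y$samples)^2)) / sqrt(mean(central(x$samples)^2))
  expect_equal(ratio, GAIN2_60HZ, tolerance = 0.02)
  expect_equal(bandpass_gain(60), GAIN2_60HZ, tolerance = 1e-9)
})

test_that("passband tones keep their amplitude and acquire no delay", {
  x <- tone(10)
  y <- bandpass_filter(x)
  ratio <- sqrt(mean(central(y$samples)^2)) / sqrt(mean(central(x$samples)^2))
  expect_equal(ratio, 1, tolerance = 0.05)
  expect_equal(bandpass_gain(10), GAIN2_10HZ, tolerance = 1e-9)
  cc <- stats::ccf(y$samples, x$samples, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("the filter is linear and maps zero to zero", {
  set.seed(5)
  a <- eeg_record(rnorm(1000), set_id = "A")
  b <- eeg_record(rnorm(1000), set_id = "A")
  ab <- eeg_record(a$samples + b$samples, set_id = "A")
  lhs <- bandpass_filter(ab)$samples
  rhs <- bandpass_filter(a)$samples + bandpass_filter(b)$samples
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-8)

  z <- bandpass_filter(eeg_record(rep(0, 500), set_id = "A"))
  expect_equal(z$samples, rep(0, 500))
})

test_that("filter validates cutoffs and signal length", {
  short <- eeg_record(rnorm(8), set_id = "A")
  expect_error(bandpass_filter(short), "too short")
  lowfs <- eeg_record(rnorm(500), fs = 80, set_id = "A")
  expect_error(bandpass_filter(lowfs), "Nyquist")
})

test_that("segmentation returns floor(n/seg_len) windows anchored at zero", {
  rec <- eeg_record(seq_len(4097), set_id = "A")
  m <- segment_signal(rec, 2048L)
  expect_equal(dim(m), c(2L, 2048L))
  expect_equal(m[1, ], as.numeric(1:2048))
  expect_equal(m[2, ], as.numeric(2049:4096))  # sample 4097 discarded

  expect_equal(nrow(segment_signal(rec, 178L)), 23L)  # floor(4097/178)
  one <- segment_signal(eeg_record(1:100, set_id = "A"), 100L)
  expect_equal(dim(one), c(1L, 100L))
  expect_warning(empty <- segment_signal(eeg_record(1:50, set_id = "A"), 100L),
                 "shorter")
  expect_equal(nrow(empty), 0L)
})

test_that("segment counts and content are conserved", {
  set.seed(8)
  for (n in c(97L, 356L, 1000L)) {
    rec <- eeg_record(rnorm(n), set_id = "C")
    for (sl in c(7L, 50L, 178L)) {
      if (n < sl) next
      m <- segment_signal(rec, sl)
      k <- nrow(m)
      expect_true(sl * k <= n && n < sl * (k + 1))
      expect_equal(as.numeric(t(m)), rec$samples[seq_len(k * sl)])
    }
  }
})

test_that("study datasets apply the study's filtering and segment length", {
  recs <- tiny_records(n_per_class = 2L, n_points = 4097L, seed = 3L)
  lab <- make_task(recs, "AB-CD-E")

  ds3 <- build_study_dataset(lab, 3)
  expect_s3_class(ds3, "segmented_dataset")
  expect_equal(ds3$seg_len, 2048L)
  expect_equal(nrow(ds3$segments), 2L * length(lab$records))
  expect_equal(length(ds3$labels), nrow(ds3$segments))

  # odd studies never alter sample values
  expect_equal(ds3$segments[1, ], lab$records[[1]]$samples[1:2048])

  # studies 1/2: identity segmentation at full length
  ds1 <- build_study_dataset(lab, 1)
  expect_equal(ds1$seg_len, 4097L)
  expect_equal(nrow(ds1$segments), length(lab$records))

  # even studies filter first, so values differ from the raw signal
  ds4 <- build_study_dataset(lab, 4)
  expect_equal(ds4$seg_len, 2048L)
  expect_false(isTRUE(all.equal(ds4$segments[1, ], ds3$segments[1, ])))

  # 1 s study: 23 segments per record, sharing the record's group id
  one <- list(task = lab$task, records = lab$records[1],
              labels = lab$labels[1])
  ds5 <- build_study_dataset(one, 5)
  expect_equal(nrow(ds5$segments), 23L)
  expect_equal(unique(ds5$group_ids), lab$records[[1]]$source_id)
  expect_equal(unique(ds5$labels), lab$labels[1])

  expect_error(build_study_dataset(lab, 7), "1..6")
})

test_that("per-segment z-scoring is available but separate from the pipeline", {
  recs <- tiny_records(n_per_class = 1L, n_points = 600L)
  lab <- make_task(recs, "A-E")
  ds <- build_study_dataset(lab, 5)
  z <- zscore_segments(ds)
  expect_equal(unname(rowMeans(z$segments)), rep(0, nrow(z$segments)),
               tolerance = 1e-12)
  expect_equal(unname(apply(z$segments, 1, sd)), rep(1, nrow(z$segments)),
               tolerance = 1e-12)
})
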