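test_that("moving averages honor truncated edges, identity and constants", {
  expect_equal(moving_average(c(0, 3, 6), 3), c(1.5, 3, 4.5))
  x <- rnorm(50)
  expect_equal(moving_average(x, 1), x)
  expect_equal(moving_average(rep(2.5, 40), 7), rep(2.5, 40))
  expect_error(moving_average(x, 0), "width")

  # oracle check: direct window means at every position, odd and even widths
  for (w in c(3, 4, 10)) {
    got <- moving_average(x, w)
    left <- w %/% 2; right <- w - 1 - left
    want <- vapply(seq_along(x), function(i)
      mean(x[max(1, i - left):min(length(x), i + right)]), 0)
    expect_equal(got, want)
  }
})

test_that("baseline removal kills constants and suppresses slow drift", {
  expect_equal(remove_baseline(rep(3, 100), 10), rep(0, 100))
  expect_equal(remove_baseline(numeric(100), 10), numeric(100))

  # drift with period 20x the window: residual power under 10% of input power
  width <- 100
  t <- seq_len(5 * 20 * width)
  drift <- sin(2 * pi * t / (20 * width))
  resid <- remove_baseline(drift, width)
  expect_lt(mean(resid^2), 0.1 * mean(drift^2))
})

test_that("smoothing shrinks white-noise variance and keeps constants", {
  set.seed(1)
  x <- rnorm(2000)
  expect_lt(var(smooth_signal(x, 10)), var(x))
  expect_equal(smooth_signal(rep(1, 30), 10), rep(1, 30))
  expect_equal(smooth_signal(x, 1), x)
})

test_that("R-peak detection finds maxima, enforces refractory and tie rules", {
  # single Gaussian pulse: exactly one peak at the argmax
  x <- exp(-((seq_len(201) - 101)^2) / 50)
  expect_equal(detect_r_peaks(x, fs = 100), 101)

  # clean 10-beat record: peaks at the planted positions within 1 sample
  tpl <- make_subject_template(4, rr_jitter_sd = 0)
  rec <- synthesize_record(tpl, 10 * tpl$base_rr, 360,
                           noise_spec(0, 0, 0, 0, 0), seed = 2)
  y <- smooth_signal(remove_baseline(rec$samples[, 1], 500), 10)
  pk <- detect_r_peaks(y, 360)
  expect_length(pk, 10)
  expect_true(all(abs(pk - rec$r_peaks) <= 1))

  # two equal maxima inside one refractory window: earlier index wins
  z <- numeric(100); z[c(40, 50)] <- 1
  expect_equal(detect_r_peaks(z, fs = 100, refractory = 0.3), 40)
  # ... and outside the window both survive
  expect_equal(detect_r_peaks(z, fs = 100, refractory = 0.05), c(40, 50))

  expect_error(detect_r_peaks(rep(1, 100), fs = 100), "constant")
})

test_that("beat averaging reduces to single segments and respects boundaries", {
  set.seed(3)
  beat <- dnorm(seq(-3, 3, length.out = 100))
  x <- rep(beat, 5)
  peaks <- which.max(beat) + (0:4) * 100
  avg <- average_beat(x, peaks, window = 80)
  seg <- x[(peaks[1] - 39):(peaks[1] + 40)]
  expect_length(avg, 80)
  expect_equal(avg, seg)   # identical beats: mean equals any one segment

  # lone usable peak: the average IS that segment
  expect_equal(average_beat(x, peaks[3], window = 80), seg)
  # peaks whose windows cross the boundary are dropped
  expect_equal(average_beat(x, c(1, peaks[2]), window = 80), seg)
  expect_error(average_beat(x, c(1, 2), window = 80), "usable")
})

test_that("averaging n noisy beats attenuates noise like 1/sqrt(n)", {
  set.seed(42)
  n_beats <- 50
  beat <- numeric(500); beat[251] <- 1
  clean <- dnorm(seq(-3, 3, length.out = 101))
  beat[201:301] <- clean
  x <- rep(beat, n_beats) + rnorm(500 * n_beats, 0, 0.1)
  peaks <- 251 + (seq_len(n_beats) - 1) * 500
  avg <- average_beat(x, peaks, window = 100)
  ref <- average_beat(rep(beat, n_beats), peaks, window = 100)

  mad_avg <- mean(abs(avg - ref))
  mad_single <- mean(vapply(peaks, function(p)
    mean(abs(x[(p - 49):(p + 50)] - ref)), 0))
  ratio <- mad_single / mad_avg
  expect_gt(ratio, sqrt(n_beats) * 0.7)
  expect_lt(ratio, sqrt(n_beats) * 1.3)
})

test_that("beat vectors hit the length contract for one and two leads", {
  tpl <- make_subject_template(8, rr_jitter_sd = 0)
  rec1 <- synthesize_record(tpl, 10, 500, noise_spec(0, 0, 0, 0, 0), seed = 1)
  v1 <- build_beat_vector(rec1, 784)
  expect_length(v1, 784)
  expect_equal(mean(v1), 0, tolerance = 1e-12)
  expect_equal(max(abs(v1)), 1)

  rec2 <- synthesize_record(tpl, 10, 360, noise_spec(0, 0, 0, 0, 0),
                            seed = 1, n_leads = 2)
  v2 <- build_beat_vector(rec2, 1600)
  expect_length(v2, 1600)

  # determinism: same record, same vector
  expect_identical(v1, build_beat_vector(rec1, 784))
})

test_that("beat images are row-major reshapes that round-trip exactly", {
  v <- rnorm(784)
  img <- beat_image(v, 28, 28)
  expect_equal(dim(img), c(28, 28))
  expect_equal(as.vector(t(img)), v)
  img2 <- beat_image(seq_len(1600), 40, 40)
  expect_equal(dim(img2), c(40, 40))
  expect_error(beat_image(v, 27, 27), "784")
})

test_that("within-subject beat vectors correlate more than between-subject", {
  noise <- noise_spec(0.05, 0.3, 0.08, 0, 0)  # white sd ~10% of typical R amp
  within <- c(); between <- c()
  for (seed in 1:2) {
    co <- generate_cohort(6, 4, duration = 10, fs = 500, noise = noise,
                          seed = seed)
    pp <- preprocess_cohort(co, 784)
    b <- do.call(rbind, pp$beat)
    cc <- cor(t(b))
    same <- outer(pp$subject_id, pp$subject_id, `==`)
    ut <- upper.tri(cc)
    within <- c(within, cc[ut & same])
    between <- c(between, cc[ut & !same])
  }
  expect_gt(mean(within), mean(between))
})
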