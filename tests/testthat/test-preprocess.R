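test_that("walkway trimming keeps only the between-cone span", {
  tr <- generate_trial(seed = 11, heading_deg = 30)
  trimmed <- trim_to_walkway(tr)
  u <- trimmed$cone_end - trimmed$cone_start
  u <- u / sqrt(sum(u^2))
  s <- sweep(kinectome:::pelvis_xy(trimmed), 2, trimmed$cone_start) %*% u
  expect_true(all(s >= 0 & s <= 5000))
  expect_lt(dim(trimmed$positions)[1], dim(tr$positions)[1])
  # already-trimmed trial is unchanged
  again <- trim_to_walkway(trimmed)
  expect_identical(dim(again$positions), dim(trimmed$positions))
  # cones outside the recorded range
  far <- tr
  far$cone_start <- c(1e6, 0); far$cone_end <- c(2e6, 0)
  expect_error(trim_to_walkway(far), class = "kin_trim_error")
})

test_that("heel strikes land on the generator's ground truth", {
  seg <- kin_segments()
  coord <- coordination_spec(segments = seg, cycle_variability_sd = 0)
  tr <- generate_trial(segments = seg, coord = coord, seed = 12,
                       measurement_noise_sd = 0)
  trimmed <- trim_to_walkway(tr)
  ev <- detect_heel_strikes(trimmed)
  # constant stride period: inter-event intervals within +/- 2 samples of truth
  period <- 200 / 1.05
  for (s in unique(ev$side)) {
    gaps <- diff(ev$sample[ev$side == s])
    expect_true(all(abs(gaps - period) <= 2))
  }
  # detected left strikes sit on the true stride-phase origin
  left <- ev$sample[ev$side == "l"]
  truth <- trimmed$truth$left_hs
  match_err <- vapply(left, function(x) min(abs(truth - x)), numeric(1))
  expect_true(all(match_err <= 3))
  # constant heels carry no gait signal
  flat <- trimmed
  flat$aux[] <- 1
  expect_error(detect_heel_strikes(flat), class = "kin_insufficient_data")
})

test_that("event detection is equivariant to a uniform time shift", {
  pp <- fixture_preprocessed()
  trimmed <- trim_to_walkway(pp$trial)
  ev <- detect_heel_strikes(trimmed)
  shift <- 40L
  shifted <- trimmed
  n <- dim(trimmed$positions)[1]
  shifted$positions <- trimmed$positions[(shift + 1):n, , , drop = FALSE]
  shifted$aux <- trimmed$aux[(shift + 1):n, , , drop = FALSE]
  ev2 <- detect_heel_strikes(shifted)
  for (s in unique(ev$side)) {
    a <- ev$sample[ev$side == s] - shift
    b <- ev2$sample[ev2$side == s]
    a <- a[a >= 1]
    keep <- seq_len(min(length(a), length(b)))
    expect_true(all(abs(utils::tail(a, length(keep)) -
                        utils::tail(b, length(keep))) <= 1))
  }
})

test_that("acquisition windows match a hand-enumerated oracle", {
  fake_events <- function(a, b) {
    dplyr::bind_rows(tibble::tibble(side = "l", sample = a, type = "heel_strike"),
                     tibble::tibble(side = "r", sample = b, type = "heel_strike"))
  }
  # 6 interleaved strides per side -> windows from each left strike i while a
  # right strike beyond left strike i+1 exists: i = 1..5 minus the last
  a <- seq(100, 1100, by = 200)          # 6 left strikes
  b <- seq(200, 1200, by = 200)          # 6 right strikes
  w <- cut_gait_acquisitions(list(), fake_events(a, b))
  expect_gte(nrow(w), 4)
  expect_equal(w$start, a[seq_len(nrow(w))])
  expect_equal(w$end[1], b[b > a[2]][1])
  # minimum case: exactly 2 strikes per side -> 1 window
  w2 <- cut_gait_acquisitions(list(), fake_events(c(100, 300), c(200, 400)))
  expect_identical(nrow(w2), 1L)
  expect_equal(unlist(w2), c(start = 100, end = 400))
  # one side only
  expect_error(cut_gait_acquisitions(list(), tibble::tibble(
    side = "l", sample = c(100, 300, 500), type = "heel_strike")),
    class = "kin_insufficient_data")
})

test_that("gap filling is linear with a strict 271-sample threshold", {
  x <- c(1, NA, NA, 4, 5)
  out <- fill_missing(x)
  expect_equal(out$series, c(1, 2, 3, 4, 5))
  expect_identical(out$gaps$filled, TRUE)
  # 271 filled, 272 not
  long <- c(0, rep(NA, 271), 272, 273)
  expect_false(anyNA(fill_missing(long, 271)$series))
  longer <- c(0, rep(NA, 272), 273, 274)
  res <- fill_missing(longer, 271)
  expect_identical(sum(is.na(res$series)), 272L)
  expect_identical(res$gaps$reason, "over_threshold")
  # boundary gap cannot be interpolated
  res_b <- fill_missing(c(NA, NA, 3, 4, 5))
  expect_identical(res_b$gaps$reason, "boundary")
  expect_true(anyNA(res_b$series))
  # no gaps: identity
  expect_identical(fill_missing(1:10 / 2)$series, 1:10 / 2)
})

test_that("low-pass filter has unit DC gain and the designed roll-off", {
  t <- seq(0, 10, by = 1 / 200)
  expect_equal(lowpass_filter(rep(2.5, 500)), rep(2.5, 500), tolerance = 1e-9)
  # 50 Hz: forward-backward 2nd-order Butterworth gain 1/(1+(50/6)^4) < 1%
  hi <- sin(2 * pi * 50 * t)
  y <- lowpass_filter(hi)
  expect_lt(max(abs(y[500:1500])), 0.01)
  # 0.5 Hz: gain 1/(1+(0.5/6)^4) within 1% of unity
  lo <- sin(2 * pi * 0.5 * t)
  y2 <- lowpass_filter(lo)
  expect_equal(max(abs(y2[500:1500])), 1, tolerance = 0.01)
  # double filtering changes gait-band content by < 5%
  gait <- sin(2 * pi * 2.1 * t)
  once <- lowpass_filter(gait)
  twice <- lowpass_filter(once)
  expect_lt(max(abs(once[500:1500] - twice[500:1500])) /
            max(abs(once[500:1500])), 0.05)
  expect_error(lowpass_filter(c(1, NA, 3)), class = "kin_data_error")
  expect_error(lowpass_filter(1:5), class = "kin_data_error")
})

test_that("heading alignment recovers the walking direction", {
  pp <- fixture_preprocessed()  # generated at heading 30
  expect_equal(pp$pp$heading_estimate_deg, 30, tolerance = 0.5)
  aligned <- align_to_walking_direction(trim_to_walkway(pp$trial))
  pel <- kinectome:::pelvis_xy(aligned)
  disp <- pel[nrow(pel), ] - pel[1, ]
  expect_gt(disp[1], 0)
  expect_lt(abs(atan2(disp[2], disp[1])) * 180 / pi, 0.5)
  # an already-aligned trial rotates by ~ nothing
  again <- align_to_walking_direction(aligned)
  expect_lt(abs(attr(again, "heading_estimate_deg")), 0.5)
})

test_that("double differentiation is exact for polynomials and sinusoids", {
  rate <- 200
  t <- seq_len(400) / rate
  a_true <- 3.2
  quad <- 0.5 * a_true * t^2
  expect_equal(differentiate_to_acceleration(quad, rate),
               rep(a_true, 398), tolerance = 1e-8)
  expect_equal(differentiate_to_acceleration(5 + 2 * t, rate), rep(0, 398),
               tolerance = 1e-8)
  omega <- 2 * pi * 6
  sine <- 10 * sin(omega * t)
  acc <- differentiate_to_acceleration(sine, rate)
  expect_equal(max(abs(acc)), 10 * omega^2, tolerance = 0.01)
  expect_error(differentiate_to_acceleration(c(1, 2), rate),
               class = "kin_data_error")
})

test_that("time normalisation hits 500 samples and preserves endpoints", {
  x <- sin(seq(0, 3, length.out = 321))
  y <- time_normalize(x)
  expect_length(y, 500)
  expect_equal(y[c(1, 500)], x[c(1, 321)])
  expect_equal(time_normalize(x[1:500]), x[1:500], tolerance = 1e-12)
  ramp <- time_normalize(seq(2, 7, length.out = 100))
  expect_equal(ramp, seq(2, 7, length.out = 500))
  expect_error(time_normalize(1), class = "kin_data_error")
})

test_that("the preprocessing chain is deterministic and correctly shaped", {
  pp <- fixture_preprocessed()
  res1 <- pp$pp
  res2 <- preprocess_trial(pp$trial)
  expect_identical(res1$acquisitions, res2$acquisitions)
  expect_gte(length(res1$acquisitions), 3)
  for (a in res1$acquisitions) {
    for (d in c("AP", "ML", "V")) {
      expect_identical(dim(a$acc[[d]]), c(500L, 22L))
    }
  }
})

test_that("over-threshold gaps exclude overlapping acquisitions with a report", {
  pp <- fixture_preprocessed()
  n <- dim(pp$trial$positions)[1]
  tr <- inject_missing_samples(pp$trial,
                               data.frame(marker = "head",
                                          start = round(n / 2), length = 300))
  res <- preprocess_trial(tr)
  expect_gt(nrow(res$exclusions), 0)
  expect_true(all(res$exclusions$reason == "unfillable_gap"))
  expect_lt(length(res$acquisitions), length(pp$pp$acquisitions))
})
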