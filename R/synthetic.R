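#' Built-in walking speed conditions
#'
#' Stride frequency (strides/s) and progression speed (mm/s) for the three
#' walking instructions, representative of an older clinical cohort
#' (stride length = speed / frequency, about 0.75-1.1 m). These stride
#' lengths give at least three full gait acquisitions within a 5 m
#' walkway, matching the acquisition availability the analysis assumes.
#'
#' @return named list of conditions, each `list(name, stride_frequency, speed)`
#' @export
speed_conditions <- function() {
  list(
    preferred = list(name = "preferred", stride_frequency = 1.05, speed = 1100),
    fast      = list(name = "fast",      stride_frequency = 1.30, speed = 1450),
    slow      = list(name = "slow",      stride_frequency = 0.85, speed = 650)
  )
}

resolve_speed <- function(speed) {
  if (is.character(speed)) {
    if (!speed %in% kin_speeds) {
      kin_stop(sprintf("unknown speed condition '%s'", speed), "kin_parameter_error")
    }
    return(speed_conditions()[[speed]])
  }
  stopifnot(is.list(speed), all(c("name", "stride_frequency", "speed") %in% names(speed)))
  speed
}

#' Generate one synthetic walking trial
#'
#' Simulates a straight overground walk through a cone-bounded walkway
#' recorded by optical motion capture at 200 Hz. Segment accelerations are
#' constructed to realize the target coupling matrix exactly (at zero
#' cycle variability): an orthonormal basis of stride-clock quadrature
#' harmonics plus band-limited noise is mixed with the eigenfactor square
#' root of the coupling matrix, per-stride phase/amplitude jitter is
#' applied, and the result is double-integrated to marker positions. The
#' walk starts 2 m before the start cone and ends 2 m past the end cone.
#' All random draws happen in the body frame; the heading rotation is
#' applied last, so two trials differing only in heading are exact
#' rotations of one another.
#'
#' @param segments segment model tibble ([kin_segments()])
#' @param coord target coordination structure ([coordination_spec()]);
#'   defaults to the structure implied by `segments`
#' @param speed `"preferred"`, `"fast"`, `"slow"`, or a condition list
#' @param heading_deg walking direction relative to the lab X axis,
#'   degrees in (-180, 180]
#' @param duration trial length in seconds; default covers the walkway
#'   plus lead-in/out. Must allow at least 5 strides.
#' @param seed integer seed; identical inputs give bit-identical trials
#' @param subject_id,group trial metadata
#' @param walkway along-track cone positions, mm (start, end)
#' @param measurement_noise_sd marker measurement noise, mm
#' @param raw_layout if `TRUE`, emit the full 47-marker layout
#'   ([kin_raw_layout()]) instead of the reduced 22-segment layout
#' @param gaps optional missing-data windows, see [inject_missing_samples()]
#' @return a `marker_trial`: positions array (samples x markers x xyz, mm,
#'   lab frame), auxiliary heel channels, cone coordinates, and a `truth`
#'   element with the gait clock, heel-strike samples and coupling used
#' @export
#' @examples
#' trial <- generate_trial(seed = 1)
#' dim(trial$positions)
generate_trial <- function(segments = kin_segments(),
                           coord = coordination_spec(segments = segments),
                           speed = "preferred", heading_deg = 0,
                           duration = NULL, seed = 1,
                           subject_id = "sub-01", group = "control",
                           walkway = c(0, 5000),
                           measurement_noise_sd = 0.3,
                           raw_layout = FALSE, gaps = NULL) {
  spd <- resolve_speed(speed)
  if (!is.numeric(heading_deg) || length(heading_deg) != 1L ||
      heading_deg <= -180 || heading_deg > 180) {
    kin_stop("`heading_deg` must lie in (-180, 180]", "kin_parameter_error")
  }
  rate <- 200
  lead <- 2000 # mm before the start cone / past the end cone
  if (is.null(duration)) {
    duration <- (diff(walkway) + 2 * lead) / spd$speed + 0.5
  }
  if (!is.numeric(duration) || duration <= 0) {
    kin_stop("`duration` must be positive", "kin_parameter_error")
  }
  if (duration * spd$stride_frequency < 5) {
    kin_stop("`duration` must allow at least 5 strides", "kin_parameter_error")
  }
  n <- round(duration * rate)
  t <- seq_len(n) / rate
  labels <- segments$label
  n_seg <- length(labels)
  cv <- coord$cycle_variability_sd

  out <- with_kin_seed(seed, {
    clock <- stride_clock(n, rate, spd$stride_frequency, cv)
    basis <- acceleration_basis(clock$theta, n_seg, rate)
    acc <- lapply(stats::setNames(kin_directions, kin_directions), function(d) {
      mix_direction(basis, coord$coupling[[d]], segments, d,
                    spd$stride_frequency, clock, cv)
    })
    stride_len <- spd$speed / spd$stride_frequency
    x_prog <- stride_len * clock$theta / (2 * pi) + walkway[1] - lead

    pos <- array(NA_real_, dim = c(n, n_seg, 3),
                 dimnames = list(NULL, labels, c("x", "y", "z")))
    for (i in seq_len(n_seg)) {
      pos[, i, 1] <- x_prog + segments$base_x[i] + integrate_twice(acc$AP[, i], rate)
      pos[, i, 2] <- segments$base_y[i] + integrate_twice(acc$ML[, i], rate)
      pos[, i, 3] <- segments$base_z[i] + integrate_twice(acc$V[, i], rate)
    }

    heel <- heel_trajectories(clock$theta, x_prog, stride_len)
    if (measurement_noise_sd > 0) {
      pos <- pos + stats::rnorm(length(pos), sd = measurement_noise_sd)
      heel <- heel + stats::rnorm(length(heel), sd = measurement_noise_sd)
    }
    list(pos = pos, heel = heel, clock = clock)
  })

  # rotate the horizontal plane into the lab frame
  ang <- heading_deg * pi / 180
  pos <- out$pos
  heel <- out$heel
  if (heading_deg != 0) {
    for (i in seq_len(dim(pos)[2])) pos[, i, 1:2] <- rotate_xy(pos[, i, 1:2], ang)
    for (i in 1:2) heel[, i, 1:2] <- rotate_xy(heel[, i, 1:2], ang)
  }
  cone_start <- as.numeric(rotate_xy(matrix(c(walkway[1], 0), 1), ang))
  cone_end <- as.numeric(rotate_xy(matrix(c(walkway[2], 0), 1), ang))

  trial <- structure(list(
    subject_id = subject_id, group = group, speed = spd$name,
    sampling_rate = rate, positions = pos, aux = heel,
    cone_start = cone_start, cone_end = cone_end,
    heading_deg = heading_deg, layout = "segment",
    truth = list(theta = out$clock$theta,
                 left_hs = out$clock$left_hs, right_hs = out$clock$right_hs,
                 stride_frequency = spd$stride_frequency,
                 coupling = coord$coupling)
  ), class = "marker_trial")

  if (raw_layout) trial <- expand_raw_layout(trial, segments, ang)
  if (!is.null(gaps) && length(gaps)) trial <- inject_missing_samples(trial, gaps)
  trial
}

#' Gait clock with per-stride frequency jitter
#'
#' Per-stride frequencies are drawn once and interpolated linearly between
#' stride midpoints, so the clock rate (and with it the progression
#' velocity) is continuous: no spurious acceleration spikes appear at
#' stride boundaries under double differentiation.
#' @noRd
stride_clock <- function(n, rate, f0, cv) {
  n_strides <- ceiling(n / rate * f0) + 3L
  f <- f0 * pmax(0.5, 1 + cv * stats::rnorm(n_strides))
  bounds_nom <- cumsum(c(0, 1 / f))
  mids <- (utils::head(bounds_nom, -1) + utils::tail(bounds_nom, -1)) / 2
  t <- seq_len(n) / rate
  f_t <- stats::approx(mids, f, xout = t, rule = 2)$y
  theta <- cumsum(2 * pi * f_t) / rate
  # ground-truth phase crossings: first sample at/after each target phase
  crossings <- function(target) {
    idx <- vapply(2 * pi * (0:(n_strides - 1)) + target, function(th) {
      i <- which(theta >= th)
      if (length(i)) i[1] else NA_integer_
    }, integer(1))
    idx[!is.na(idx)]
  }
  list(theta = theta, f = f,
       stride_starts = crossings(0),
       left_hs = crossings(0), right_hs = crossings(pi))
}

#' Orthonormal acceleration basis: quadrature harmonics + band-limited noise
#'
#' Returns a samples x n_seg matrix of exactly orthonormal, zero-mean,
#' unit-variance columns. Columns 1-4 span the stride-clock harmonics 1
#' and 2; the rest are 0.5-5 Hz filtered noise orthogonalised against them.
#' @noRd
acceleration_basis <- function(theta, n_seg, rate) {
  n <- length(theta)
  q <- cbind(sin(theta), cos(theta), sin(2 * theta), cos(2 * theta))
  n_noise <- max(0L, n_seg - 4L)
  if (n_noise > 0L) {
    noise <- matrix(stats::rnorm(n * n_noise), n)
    bp <- signal::butter(2, c(0.5, 5) / (rate / 2), type = "pass")
    noise <- apply(noise, 2, function(x) signal::filtfilt(bp, x))
    B <- cbind(q, noise)
  } else {
    B <- q
  }
  B <- scale(B, center = TRUE, scale = FALSE)
  qr_dec <- qr(B)
  Q <- qr.Q(qr_dec)
  # fix column signs so the harmonic columns keep their orientation
  signs <- sign(diag(qr.R(qr_dec)))
  signs[signs == 0] <- 1
  Q <- sweep(Q, 2, signs, `*`)
  Q <- Q * sqrt(n - 1)
  Q[, seq_len(n_seg), drop = FALSE]
}

#' Mix the basis into per-segment accelerations for one direction
#' @noRd
mix_direction <- function(basis, C, segments, direction, f0, clock, cv) {
  C <- nearest_psd_correlation(C)
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  M <- e$vectors %*% diag(sqrt(lam)) # 22 x 22; column k loads basis column k
  A <- basis %*% t(M)
  if (cv > 0) {
    A <- apply_stride_jitter(A, basis[, 1:4, drop = FALSE],
                             M[, 1:4, drop = FALSE], clock, cv)
  }
  amp <- segments[[paste0("amp_", direction)]] * (2 * pi * f0)^2
  sweep(A, 2, amp, `*`)
}

#' Per-stride, per-segment phase/amplitude jitter
#'
#' Within each stride, every segment's harmonic component is rotated by an
#' independent Gaussian phase offset (sd = cv radians) and the segment's
#' whole signal is scaled by an independent amplitude factor 1 + N(0, cv).
#' @noRd
apply_stride_jitter <- function(A, H, M4, clock, cv) {
  n <- nrow(A)
  n_seg <- ncol(A)
  bounds_idx <- unique(c(1L, clock$stride_starts, n + 1L))
  for (m in seq_len(length(bounds_idx) - 1L)) {
    i0 <- bounds_idx[m]; i1 <- bounds_idx[m + 1L] - 1L
    if (i0 > n || i1 < i0) next
    g <- pmax(0.1, 1 + cv * stats::rnorm(n_seg))
    d <- cv * stats::rnorm(n_seg)
    c1 <- cos(d) * M4[, 1] - sin(d) * M4[, 2]
    c2 <- sin(d) * M4[, 1] + cos(d) * M4[, 2]
    c3 <- cos(2 * d) * M4[, 3] - sin(2 * d) * M4[, 4]
    c4 <- sin(2 * d) * M4[, 3] + cos(2 * d) * M4[, 4]
    rot <- H[i0:i1, , drop = FALSE] %*% (t(cbind(c1, c2, c3, c4)) - t(M4))
    A[i0:i1, ] <- (A[i0:i1, , drop = FALSE] + rot) *
      rep(g, each = i1 - i0 + 1L)
  }
  A
}

#' Double integration with drift removal (acceleration -> position, mm)
#' @noRd
integrate_twice <- function(a, rate) {
  dt <- 1 / rate
  v <- pracma::cumtrapz(a)[, 1] * dt
  p <- pracma::cumtrapz(v)[, 1] * dt
  # remove integration-constant drift; oscillatory content is untouched
  t <- seq_along(p)
  fit <- stats::lm.fit(cbind(1, t, t^2), p)
  fit$residuals
}

#' Heel marker trajectories (auxiliary channels, body frame)
#'
#' Left heel strike occurs at stride phase 0 (foremost heel excursion),
#' right heel strike at phase pi.
#' @noRd
heel_trajectories <- function(theta, x_prog, stride_len) {
  n <- length(theta)
  heel <- array(NA_real_, dim = c(n, 2, 3),
                dimnames = list(NULL, c("heel_l", "heel_r"), c("x", "y", "z")))
  a_h <- 0.25 * stride_len
  heel[, 1, 1] <- x_prog + a_h * cos(theta)
  heel[, 2, 1] <- x_prog + a_h * cos(theta - pi)
  heel[, 1, 2] <- 120 + 15 * sin(theta + 0.4)
  heel[, 2, 2] <- -120 + 15 * sin(theta - pi + 0.4)
  heel[, 1, 3] <- 60 + 25 * pmax(0, sin(theta - pi / 2))^2 * 4
  heel[, 2, 3] <- 60 + 25 * pmax(0, sin(theta - 3 * pi / 2))^2 * 4
  heel
}

#' Expand a segment-layout trial into the raw 47-marker layout
#' @noRd
expand_raw_layout <- function(trial, segments, ang) {
  layout <- kin_raw_layout()
  n <- dim(trial$positions)[1]
  pos <- array(NA_real_, dim = c(n, nrow(layout), 3),
               dimnames = list(NULL, layout$marker, c("x", "y", "z")))
  off <- as.matrix(layout[, c("off_x", "off_y", "off_z")])
  off[, 1:2] <- rotate_xy(off[, 1:2, drop = FALSE], ang)
  for (k in seq_len(nrow(layout))) {
    src <- layout$source[k]
    base <- if (src %in% c("heel_l", "heel_r")) {
      trial$aux[, src, ]
    } else {
      trial$positions[, src, ]
    }
    pos[, k, ] <- sweep(base, 2, off[k, ], `+`)
  }
  trial$positions <- pos
  trial$aux <- NULL
  trial$layout <- "raw"
  trial
}

#' Inject missing samples into a trial
#'
#' Flags the listed sample windows of a marker as missing (`NA`); all
#' other samples are untouched. Gap windows on the same marker must not
#' overlap and must lie within the trial.
#'
#' @param trial a `marker_trial`
#' @param gaps data frame (or list coercible to one) with columns
#'   `marker`, `start` (1-based first missing sample), `length`
#' @return the trial with `NA` runs in the affected marker channels
#' @export
inject_missing_samples <- function(trial, gaps) {
  stopifnot(inherits(trial, "marker_trial"))
  gaps <- dplyr::bind_rows(gaps)
  if (nrow(gaps) == 0L) return(trial)
  stopifnot(all(c("marker", "start", "length") %in% names(gaps)))
  n <- dim(trial$positions)[1]
  for (mk in unique(gaps$marker)) {
    g <- gaps[gaps$marker == mk, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (any(g$start < 1 | g$start + g$length - 1 > n)) {
      kin_stop(sprintf("gap out of bounds for marker '%s'", mk),
               "kin_parameter_error")
    }
    ends <- g$start + g$length - 1
    if (nrow(g) > 1L && any(g$start[-1] <= ends[-nrow(g)])) {
      kin_stop(sprintf("overlapping gaps on marker '%s'", mk),
               "kin_parameter_error")
    }
    if (!mk %in% dimnames(trial$positions)[[2]]) {
      kin_stop(sprintf("marker '%s' not present in trial", mk),
               "kin_parameter_error")
    }
    for (r in seq_len(nrow(g))) {
      idx <- g$start[r]:(g$start[r] + g$length[r] - 1L)
      trial$positions[idx, mk, ] <- NA_real_
    }
  }
  trial
}

#' @export
print.marker_trial <- function(x, ...) {
  cat(sprintf("<marker_trial> %s | %s | %s speed | %d samples x %d markers (%s layout)\n",
              x$subject_id, x$group, x$speed, dim(x$positions)[1],
              dim(x$positions)[2], x$layout))
  invisible(x)
}
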