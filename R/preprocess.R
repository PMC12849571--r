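#' Preprocessing parameters
#'
#' All thresholds default to the values used throughout the package:
#' linear interpolation of gaps up to 271 samples (1.355 s at 200 Hz),
#' zero-phase 2nd-order Butterworth low-pass at 6 Hz, 500-sample time
#' normalisation, and at least 3 gait acquisitions per trial.
#'
#' @param max_gap largest interpolatable gap, samples
#' @param filter_order Butterworth design order
#' @param cutoff_hz low-pass cut-off frequency, Hz
#' @param target_samples normalised acquisition length
#' @param min_acquisitions minimum usable acquisitions per trial
#' @param min_stride_s minimum stride period assumed by event detection, s
#' @return list of parameters
#' @export
preproc_params <- function(max_gap = 271, filter_order = 2, cutoff_hz = 6,
                           target_samples = 500, min_acquisitions = 3,
                           min_stride_s = 0.4) {
  list(max_gap = max_gap, filter_order = filter_order, cutoff_hz = cutoff_hz,
       target_samples = target_samples, min_acquisitions = min_acquisitions,
       min_stride_s = min_stride_s)
}

pelvis_labels <- function(labels) grep("^(asis|psis)_", labels, value = TRUE)

pelvis_xy <- function(trial) {
  labs <- pelvis_labels(dimnames(trial$positions)[[2]])
  if (length(labs) == 0L) kin_stop("no pelvis (asis/psis) channels found",
                                   "kin_data_error")
  cbind(rowMeans(trial$positions[, labs, 1, drop = FALSE], na.rm = TRUE),
        rowMeans(trial$positions[, labs, 2, drop = FALSE], na.rm = TRUE))
}

#' Trim a trial to the cone-bounded walkway
#'
#' Retains the samples where the pelvis centroid's along-track coordinate
#' (projection onto the start-to-end cone line) lies between the cones.
#'
#' @param trial a `marker_trial` with cone metadata
#' @return the trimmed trial (with `trim_offset` attribute, samples)
#' @export
trim_to_walkway <- function(trial) {
  stopifnot(inherits(trial, "marker_trial"))
  if (is.null(trial$cone_start) || is.null(trial$cone_end) ||
      any(is.na(c(trial$cone_start, trial$cone_end)))) {
    kin_stop("cone coordinates missing from trial metadata", "kin_data_error")
  }
  u <- trial$cone_end - trial$cone_start
  len <- sqrt(sum(u^2))
  u <- u / len
  s <- sweep(pelvis_xy(trial), 2, trial$cone_start) %*% u
  keep <- which(s >= 0 & s <= len)
  if (length(keep) == 0L) {
    kin_stop("subject never enters the walkway between the cones",
             "kin_trim_error")
  }
  idx <- keep[1]:keep[length(keep)]
  trial$positions <- trial$positions[idx, , , drop = FALSE]
  if (!is.null(trial$aux)) trial$aux <- trial$aux[idx, , , drop = FALSE]
  if (!is.null(trial$truth$theta)) {
    off <- idx[1] - 1L
    trial$truth$theta <- trial$truth$theta[idx]
    for (f in c("left_hs", "right_hs")) {
      hs <- trial$truth[[f]] - off
      trial$truth[[f]] <- hs[hs >= 1 & hs <= length(idx)]
    }
  }
  attr(trial, "trim_offset") <- idx[1] - 1L
  trial
}

#' Detect heel strikes from heel trajectories
#'
#' Coordinate-based detection: a heel strike is a local maximum of the
#' heel's along-track position relative to the pelvis centroid (the heel
#' is foremost relative to the body at initial contact). The along-track
#' axis is the direction of net pelvis displacement.
#'
#' @param trial a trimmed `marker_trial` with heel auxiliary channels
#' @param params see [preproc_params()]
#' @return tibble of gait events: `side`, `sample` (1-based), `type`
#' @export
detect_heel_strikes <- function(trial, params = preproc_params()) {
  stopifnot(inherits(trial, "marker_trial"))
  if (is.null(trial$aux)) {
    kin_stop("trial has no heel auxiliary channels", "kin_data_error")
  }
  pel <- pelvis_xy(trial)
  disp <- pel[nrow(pel), ] - pel[1, ]
  nrm <- sqrt(sum(disp^2))
  if (!is.finite(nrm) || nrm < 100) {
    kin_stop("no forward progression; cannot orient event detection",
             "kin_data_error")
  }
  u <- disp / nrm
  pel_s <- pel %*% u
  events <- list()
  for (lab in dimnames(trial$aux)[[2]]) {
    rel <- as.vector(trial$aux[, lab, 1:2] %*% u) - pel_s
    if (!all(is.finite(rel)) || stats::sd(rel) < 1e-6) {
      kin_stop(sprintf("heel channel '%s' carries no gait signal", lab),
               "kin_insufficient_data")
    }
    pk <- pracma::findpeaks(as.vector(rel),
                            minpeakheight = stats::quantile(rel, 0.6),
                            minpeakdistance = round(params$min_stride_s *
                                                    trial$sampling_rate))
    if (is.null(pk) || nrow(pk) < 2L) {
      kin_stop(sprintf("fewer than 2 strides detected on '%s'", lab),
               "kin_insufficient_data")
    }
    events[[lab]] <- tibble::tibble(side = sub("^heel_", "", lab),
                                    sample = sort(pk[, 2]),
                                    type = "heel_strike")
  }
  dplyr::arrange(dplyr::bind_rows(events), .data$sample)
}

#' Cut gait acquisitions from heel-strike events
#'
#' Each acquisition spans one full gait cycle of each side: from an
#' anchor-side heel strike i to the first opposite-side heel strike after
#' anchor strike i + 1. The anchor is the side with the earliest event.
#' Consecutive acquisitions advance by one anchor stride.
#'
#' @param trial a trimmed `marker_trial` (used only for bounds)
#' @param events event tibble from [detect_heel_strikes()]
#' @return tibble of windows: `start`, `end` (1-based, inclusive)
#' @export
cut_gait_acquisitions <- function(trial, events) {
  sides <- unique(events$side)
  if (length(sides) < 2L) {
    kin_stop("heel-strike events from both sides are required",
             "kin_insufficient_data")
  }
  firsts <- vapply(sides, function(s) min(events$sample[events$side == s]),
                   numeric(1))
  anchor <- sides[which.min(firsts)]
  other <- setdiff(sides, anchor)[1]
  a <- sort(events$sample[events$side == anchor])
  b <- sort(events$sample[events$side == other])
  if (length(a) < 2L || length(b) < 2L) {
    kin_stop("need at least 2 heel strikes per side", "kin_insufficient_data")
  }
  wins <- list()
  for (i in seq_len(length(a) - 1L)) {
    nxt <- b[b > a[i + 1L]]
    if (length(nxt) == 0L) break
    wins[[length(wins) + 1L]] <- tibble::tibble(start = a[i], end = nxt[1])
  }
  if (length(wins) == 0L) {
    kin_stop("no window containing one full cycle per side",
             "kin_insufficient_data")
  }
  dplyr::bind_rows(wins)
}

#' Linear interpolation of missing samples up to a threshold
#'
#' Interior gaps of at most `max_gap` samples are filled linearly between
#' the flanking valid samples; longer gaps and gaps touching a series
#' boundary are left missing and reported so the affected acquisitions
#' can be excluded.
#'
#' @param x numeric series with `NA` gaps
#' @param max_gap largest fillable gap, samples
#' @return list: `series` (filled), `gaps` tibble
#'   (`start`, `length`, `filled`, `reason`)
#' @export
fill_missing <- function(x, max_gap = 271) {
  n <- length(x)
  miss <- is.na(x)
  if (!any(miss)) {
    return(list(series = x, gaps = tibble::tibble(start = integer(),
                                                  length = integer(),
                                                  filled = logical(),
                                                  reason = character())))
  }
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gaps <- list()
  for (k in which(r$values)) {
    g_start <- starts[k]; g_len <- r$lengths[k]; g_end <- ends[k]
    at_boundary <- g_start == 1L || g_end == n
    if (!at_boundary && g_len <= max_gap) {
      x0 <- x[g_start - 1L]; x1 <- x[g_end + 1L]
      w <- seq_len(g_len) / (g_len + 1)
      x[g_start:g_end] <- x0 + w * (x1 - x0)
      gaps[[length(gaps) + 1L]] <- tibble::tibble(
        start = g_start, length = g_len, filled = TRUE, reason = "")
    } else {
      gaps[[length(gaps) + 1L]] <- tibble::tibble(
        start = g_start, length = g_len, filled = FALSE,
        reason = if (at_boundary) "boundary" else "over_threshold")
    }
  }
  list(series = x, gaps = dplyr::bind_rows(gaps))
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward application of the 2nd-order design (DC gain 1, no
#' phase distortion). The series is reflection-padded at both ends before
#' filtering to suppress edge transients.
#'
#' @param x numeric series without missing values
#' @param order design order
#' @param cutoff cut-off frequency, Hz
#' @param rate sampling rate, Hz
#' @return filtered series, same length
#' @export
lowpass_filter <- function(x, order = 2, cutoff = 6, rate = 200) {
  if (anyNA(x)) kin_stop("series still contains missing values", "kin_data_error")
  n <- length(x)
  if (n < 10 * order) {
    kin_stop("series shorter than the filter warm-up", "kin_data_error")
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  pad <- min(n - 1L, 200L)
  xp <- c(2 * x[1] - rev(x[2:(pad + 1L)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1L)]))
  y <- signal::filtfilt(bf, xp)
  y[(pad + 1L):(pad + n)]
}

#' Align a trial with its walking direction
#'
#' Estimates the heading as the first principal component of the pooled,
#' per-marker-centred horizontal displacements and rotates the horizontal
#' plane (a pure rotation about the vertical axis) so that the
#' anteroposterior axis becomes +X, with the sign fixed by the net pelvis
#' displacement. The vertical axis is untouched.
#'
#' @param trial a trimmed `marker_trial`
#' @return the rotated trial; attribute `heading_estimate_deg` holds the
#'   removed heading
#' @export
align_to_walking_direction <- function(trial) {
  stopifnot(inherits(trial, "marker_trial"))
  labels <- dimnames(trial$positions)[[2]]
  xs <- ys <- list()
  for (lab in labels) {
    xy <- trial$positions[, lab, 1:2]
    ok <- stats::complete.cases(xy)
    if (sum(ok) < 2L) next
    xs[[lab]] <- xy[ok, 1] - mean(xy[ok, 1])
    ys[[lab]] <- xy[ok, 2] - mean(xy[ok, 2])
  }
  X <- unlist(xs); Y <- unlist(ys)
  cxx <- mean(X^2); cyy <- mean(Y^2); cxy <- mean(X * Y)
  pel <- pelvis_xy(trial)
  disp <- pel[nrow(pel), ] - pel[1, ]
  if (sqrt(sum(disp^2)) < 100) {
    kin_stop("degenerate horizontal motion: no progression to align to",
             "kin_data_error")
  }
  ang <- 0.5 * atan2(2 * cxy, cxx - cyy) # principal-axis angle
  # sign: net pelvis displacement must map onto +X
  if (disp[1] * cos(ang) + disp[2] * sin(ang) < 0) ang <- ang + pi
  rot <- -ang
  for (i in seq_len(dim(trial$positions)[2])) {
    trial$positions[, i, 1:2] <- rotate_xy(trial$positions[, i, 1:2], rot)
  }
  if (!is.null(trial$aux)) {
    for (i in seq_len(dim(trial$aux)[2])) {
      trial$aux[, i, 1:2] <- rotate_xy(trial$aux[, i, 1:2], rot)
    }
  }
  trial$cone_start <- as.numeric(rotate_xy(matrix(trial$cone_start, 1), rot))
  trial$cone_end <- as.numeric(rotate_xy(matrix(trial$cone_end, 1), rot))
  attr(trial, "heading_estimate_deg") <- ang * 180 / pi
  trial
}

#' Second central difference: position to acceleration
#'
#' `a[t] = (p[t+1] - 2 p[t] + p[t-1]) * rate^2`; exact for quadratics.
#' The first and last samples are dropped, so output element `t`
#' corresponds to input sample `t + 1`.
#'
#' @param p position series (filtered, gap-free)
#' @param rate sampling rate, Hz
#' @return acceleration series of length `length(p) - 2`
#' @export
differentiate_to_acceleration <- function(p, rate) {
  n <- length(p)
  if (n < 3L) kin_stop("need at least 3 samples to differentiate twice",
                       "kin_data_error")
  (p[3:n] - 2 * p[2:(n - 1L)] + p[1:(n - 2L)]) * rate^2
}

#' Normalise a series to a fixed number of samples
#'
#' Linear interpolation onto a uniform grid spanning the original series;
#' endpoints are preserved exactly.
#'
#' @param x numeric series, length >= 2
#' @param target output length
#' @return series of length `target`
#' @export
time_normalize <- function(x, target = 500) {
  n <- length(x)
  if (n < 2L) kin_stop("need at least 2 samples to normalise", "kin_data_error")
  stats::approx(seq_len(n), x, xout = seq(1, n, length.out = target))$y
}

#' Preprocess one trial into normalised gait-acquisition accelerations
#'
#' Runs the full chain: walkway trimming, heel-strike detection,
#' acquisition cutting, gap interpolation (271-sample threshold),
#' zero-phase 6 Hz low-pass, PCA heading alignment, double
#' differentiation, and 500-sample time normalisation per direction.
#' Acquisitions overlapping unfillable gaps or the series boundary are
#' excluded with a reason.
#'
#' @param trial a `marker_trial` in the segment layout
#' @param params see [preproc_params()]
#' @return list: `acquisitions` (each with `window` and `acc`, a list of
#'   500 x 22 matrices for AP/ML/V), `events`, `exclusions` tibble,
#'   `sufficient` (at least `min_acquisitions` usable), `heading_estimate_deg`
#' @export
preprocess_trial <- function(trial, params = preproc_params()) {
  stopifnot(inherits(trial, "marker_trial"))
  if (!identical(trial$layout, "segment")) {
    kin_stop("preprocessing expects the reduced segment layout; run reduce_markers()",
             "kin_parameter_error")
  }
  trial <- trim_to_walkway(trial)
  events <- detect_heel_strikes(trial, params)
  windows <- cut_gait_acquisitions(trial, events)

  labels <- dimnames(trial$positions)[[2]]
  n <- dim(trial$positions)[1]
  rate <- trial$sampling_rate
  bad_ranges <- list() # sample ranges that cannot enter any acquisition
  for (lab in labels) {
    for (k in 1:3) {
      filled <- fill_missing(trial$positions[, lab, k], params$max_gap)
      x <- filled$series
      unfilled <- filled$gaps[!filled$gaps$filled, , drop = FALSE]
      if (nrow(unfilled) > 0L) {
        bad_ranges <- c(bad_ranges,
                        lapply(seq_len(nrow(unfilled)), function(r) {
                          c(unfilled$start[r],
                            unfilled$start[r] + unfilled$length[r] - 1L)
                        }))
        # bridge for filtering only; these ranges are excluded downstream
        x <- stats::approx(which(!is.na(x)), x[!is.na(x)], xout = seq_len(n),
                           rule = 2)$y
      }
      trial$positions[, lab, k] <- lowpass_filter(x, params$filter_order,
                                                  params$cutoff_hz, rate)
    }
  }
  trial <- align_to_walking_direction(trial)

  acc <- array(NA_real_, dim = c(n - 2L, length(labels), 3),
               dimnames = list(NULL, labels, kin_directions))
  for (i in seq_along(labels)) {
    for (k in 1:3) {
      acc[, i, k] <- differentiate_to_acceleration(trial$positions[, i, k], rate)
    }
  }

  acquisitions <- list()
  exclusions <- list()
  for (w in seq_len(nrow(windows))) {
    s <- windows$start[w]; e <- windows$end[w]
    overlaps_bad <- any(vapply(bad_ranges, function(r) s <= r[2] && e >= r[1],
                               logical(1)))
    if (overlaps_bad) {
      exclusions[[length(exclusions) + 1L]] <- tibble::tibble(
        window = w, start = s, end = e, reason = "unfillable_gap")
      next
    }
    if (s < 2L || e > n - 1L) {
      exclusions[[length(exclusions) + 1L]] <- tibble::tibble(
        window = w, start = s, end = e, reason = "boundary")
      next
    }
    rows <- (s - 1L):(e - 1L) # acceleration row t maps to position sample t+1
    dirs <- lapply(stats::setNames(1:3, kin_directions), function(k) {
      apply(acc[rows, , k, drop = FALSE], 2, time_normalize,
            target = params$target_samples)
    })
    acquisitions[[length(acquisitions) + 1L]] <-
      list(window = c(start = s, end = e), acc = dirs)
  }
  list(acquisitions = acquisitions, events = events,
       exclusions = dplyr::bind_rows(exclusions),
       sufficient = length(acquisitions) >= params$min_acquisitions,
       heading_estimate_deg = attr(trial, "heading_estimate_deg"))
}
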