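#' Default 22-segment body model
#'
#' The kinectome operates on 22 body segments, each represented by one
#' marker trajectory: head, sternum, and left/right shoulder, elbow, wrist,
#' hand, ASIS, PSIS, thigh, shank, ankle and toe. For each movement
#' direction (AP anteroposterior, ML mediolateral, V vertical) a segment
#' carries a position oscillation amplitude (mm), a phase within the stride
#' cycle (radians), and a split between the stride-frequency and
#' step-frequency harmonics. Contralateral limb segments are phase-shifted
#' by pi, reproducing the anti-phase limb swing of human gait; vertical
#' motion is dominated by the step-frequency (second) harmonic, which
#' repeats identically for left and right steps.
#'
#' `noise_sd` (mm) is segment-specific motor noise: oscillation energy that
#' is not shared with any other segment. It sets the communality
#' amp^2 / (amp^2 + noise_sd^2) used when deriving the default coupling
#' matrix, so `noise_sd = 0` makes equal-phase segments perfectly
#' correlated and anti-phase segments perfectly anti-correlated.
#'
#' @param noise_sd segment-specific motor noise, mm (scalar or length-22)
#' @return tibble with one row per segment: `label`, `side`, `level`,
#'   base position (`base_x`, `base_y`, `base_z`, mm), and per-direction
#'   `amp_*`, `phase_*`, `w1_*` (fraction of shared energy on the
#'   stride-frequency harmonic) plus `noise_sd`
#' @export
#' @examples
#' seg <- kin_segments()
#' nrow(seg) # 22
kin_segments <- function(noise_sd = 10) {
  pair <- function(base) c(paste0(base, "_l"), paste0(base, "_r"))
  labels <- c("head", "sternum", pair("shoulder"), pair("elbow"), pair("wrist"),
              pair("hand"), pair("asis"), pair("psis"), pair("thigh"),
              pair("shank"), pair("ankle"), pair("toe"))
  side <- c("center", "center", rep(c("left", "right"), 10))
  level <- c("axial", "axial", rep("upper", 8), rep("lower", 12))

  base_z <- c(1700, 1400, rep(1500, 2), rep(1200, 2), rep(950, 2), rep(850, 2),
              rep(1000, 2), rep(1000, 2), rep(800, 2), rep(450, 2),
              rep(100, 2), rep(50, 2))
  half_y <- c(0, 0, rep(c(200, 230, 250, 260, 120, 60, 120, 120, 120, 140),
                        each = 2))
  base_y <- ifelse(side == "left", half_y, -half_y)
  base_y[side == "center"] <- 0
  base_x <- c(0, 30, rep(0, 8), rep(c(40, -120), each = 2), rep(0, 8))

  # small deterministic per-segment phase perturbations: break exact ties
  # in the implied coupling so greedy extraction never depends on label
  # order for the default body (real bodies are not perfectly symmetric
  # either)
  eps <- 0.05 * (((seq_along(labels) * 37L) %% 11L) - 5L) / 5

  lower_lag <- c(thigh = 0, shank = 0.25, ankle = 0.45, toe = 0.6)
  upper_lag <- c(shoulder = 0, elbow = 0.2, wrist = 0.35, hand = 0.45)
  seg_base <- sub("_(l|r)$", "", labels)
  lag <- rep(0, length(labels))
  lag[seg_base %in% names(lower_lag)] <- lower_lag[seg_base[seg_base %in% names(lower_lag)]]
  lag[seg_base %in% names(upper_lag)] <- upper_lag[seg_base[seg_base %in% names(upper_lag)]]

  is_left <- side == "left"
  is_right <- side == "right"
  is_lower_limb <- seg_base %in% c("thigh", "shank", "ankle", "toe")
  is_upper_limb <- level == "upper"
  is_pelvis <- seg_base %in% c("asis", "psis")

  # AP: legs anti-phase between sides, arms anti-phase with ipsilateral leg
  phase_AP <- numeric(length(labels)) + eps
  phase_AP[is_lower_limb & is_left] <- 0 + lag[is_lower_limb & is_left] + eps[is_lower_limb & is_left]
  phase_AP[is_lower_limb & is_right] <- pi + lag[is_lower_limb & is_right] + eps[is_lower_limb & is_right]
  phase_AP[is_upper_limb & is_left] <- pi + lag[is_upper_limb & is_left] + eps[is_upper_limb & is_left]
  phase_AP[is_upper_limb & is_right] <- 0 + lag[is_upper_limb & is_right] + eps[is_upper_limb & is_right]
  phase_AP[is_pelvis & is_left] <- 0.1 + eps[is_pelvis & is_left]
  phase_AP[is_pelvis & is_right] <- pi + 0.1 + eps[is_pelvis & is_right]
  w1_AP <- ifelse(level == "axial", 0.2, ifelse(is_pelvis, 0.3, 0.85))

  # ML: whole-body sway at stride frequency; legs alternate sides
  phase_ML <- 0.3 * lag + eps
  phase_ML[is_lower_limb & is_right] <- pi + 0.3 * lag[is_lower_limb & is_right] + eps[is_lower_limb & is_right]
  phase_ML[is_upper_limb & is_left] <- 0.4 + eps[is_upper_limb & is_left]
  phase_ML[is_upper_limb & is_right] <- pi + 0.4 + eps[is_upper_limb & is_right]
  w1_ML <- ifelse(level == "axial" | is_pelvis, 0.8, 0.9)

  # V: step-frequency bounce shared by the whole body
  phase_V <- 0.5 * lag + eps
  phase_V[is_right] <- pi + 0.5 * lag[is_right] + eps[is_right]
  w1_V <- ifelse(is_lower_limb, 0.45, ifelse(is_upper_limb, 0.3, 0.15))

  amp_scale <- c(head = 15, sternum = 15, shoulder = 25, elbow = 45, wrist = 60,
                 hand = 65, asis = 20, psis = 18, thigh = 45, shank = 70,
                 ankle = 90, toe = 110)
  amp_AP <- unname(amp_scale[seg_base])
  amp_ML <- pmax(8, 0.3 * amp_AP)
  amp_V <- pmax(10, 0.4 * amp_AP)

  tibble::tibble(
    label = labels, side = side, level = level,
    base_x = base_x, base_y = base_y, base_z = base_z,
    amp_AP = amp_AP, amp_ML = amp_ML, amp_V = amp_V,
    phase_AP = phase_AP, phase_ML = phase_ML, phase_V = phase_V,
    w1_AP = w1_AP, w1_ML = w1_ML, w1_V = w1_V,
    noise_sd = rep_len(noise_sd, length(labels))
  )
}

#' Raw 47-marker layout and its reduction map
#'
#' The full marker set: four head markers, a three-marker sternum cluster,
#' four-marker clusters on each thigh and shank, single markers on
#' shoulders, elbows, wrists, hands, ASIS, PSIS, ankles and toes, plus
#' upper-arm and forearm markers (excluded from analysis) and heel markers
#' (kept only as auxiliary channels for gait-event detection).
#'
#' @return tibble: `marker`, `segment` (centroid target, `NA` = excluded),
#'   `role` (`cluster`, `single`, `excluded`, `heel`), and rigid body-frame
#'   offsets `off_x`, `off_y`, `off_z` (mm) from the segment point
#' @export
kin_raw_layout <- function() {
  rows <- list()
  add <- function(marker, segment, role, off, source = segment) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      marker = marker, segment = segment, role = role, source = source,
      off_x = off[1], off_y = off[2], off_z = off[3])
  }
  add("head_lf", "head", "cluster", c(60, 50, 20))
  add("head_rf", "head", "cluster", c(60, -50, 20))
  add("head_lb", "head", "cluster", c(-60, 50, -20))
  add("head_rb", "head", "cluster", c(-60, -50, -20))
  add("stern_up", "sternum", "cluster", c(10, 0, 80))
  add("stern_mid", "sternum", "cluster", c(20, 0, 0))
  add("stern_low", "sternum", "cluster", c(-30, 0, -80))
  for (s in c("l", "r")) {
    sg <- function(b) paste0(b, "_", s)
    for (k in 1:4) {
      off <- list(c(40, 25, 60), c(40, -25, -60), c(-40, 25, -60), c(-40, -25, 60))[[k]]
      add(paste0("thigh_", s, "_", k), sg("thigh"), "cluster", off)
      add(paste0("shank_", s, "_", k), sg("shank"), "cluster", off * 0.8)
    }
    for (b in c("shoulder", "elbow", "wrist", "hand", "asis", "psis",
                "ankle", "toe")) {
      add(sg(b), sg(b), "single", c(0, 0, 0))
    }
    add(paste0("upper_arm_", s, "_1"), NA_character_, "excluded", c(0, 0, -150),
        source = sg("shoulder"))
    add(paste0("upper_arm_", s, "_2"), NA_character_, "excluded", c(30, 0, -100),
        source = sg("shoulder"))
    add(paste0("forearm_", s), NA_character_, "excluded", c(0, 0, 120),
        source = sg("wrist"))
    add(paste0("heel_", s), NA_character_, "heel", c(0, 0, 0),
        source = paste0("heel_", s))
  }
  dplyr::bind_rows(rows)
}
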