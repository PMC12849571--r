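#' Cohort configuration for the synthetic generator
#'
#' Describes a two-group study: controls and a deficit ("PD-like") group,
#' each subject walking once per speed condition through the same 5 m
#' cone-bounded walkway. The deficit group can differ in stride-to-stride
#' variability and carry an attenuated coordination path.
#'
#' @param n_per_group subjects per group (>= 2)
#' @param speeds subset of `c("preferred", "fast", "slow")`
#' @param heading_deg walking direction vs the lab X axis, (-180, 180]
#' @param seed master integer seed
#' @param noise_sd segment motor noise, mm (see [kin_segments()])
#' @param cycle_variability_sd named vector `c(control = , pd = )`
#' @param attenuation optional planted deficit:
#'   `list(path = , direction = , factor = )` applied to the PD group
#' @param affected_side side carrying higher MDS-UPDRS III scores in the
#'   synthetic PD group (keeps mas/las relabelling consistent)
#' @param missing_gaps optional gap table applied to every trial
#'   (see [inject_missing_samples()])
#' @param measurement_noise_sd marker measurement noise, mm
#' @return a `cohort_config` list
#' @export
cohort_config <- function(n_per_group = 10,
                          speeds = kin_speeds,
                          heading_deg = 15,
                          seed = 1,
                          noise_sd = 10,
                          cycle_variability_sd = c(control = 0.02, pd = 0.08),
                          attenuation = NULL,
                          affected_side = "left",
                          missing_gaps = NULL,
                          measurement_noise_sd = 0.3) {
  if (!is.numeric(n_per_group) || n_per_group < 2) {
    kin_stop("`n_per_group` must be >= 2", "kin_parameter_error")
  }
  if (!all(speeds %in% kin_speeds)) {
    kin_stop("`speeds` must be a subset of preferred/fast/slow", "kin_parameter_error")
  }
  if (heading_deg <= -180 || heading_deg > 180) {
    kin_stop("`heading_deg` must lie in (-180, 180]", "kin_parameter_error")
  }
  stopifnot(all(c("control", "pd") %in% names(cycle_variability_sd)))
  if (!is.null(attenuation)) {
    stopifnot(all(c("path", "direction", "factor") %in% names(attenuation)))
  }
  structure(list(n_per_group = as.integer(n_per_group), speeds = speeds,
                 heading_deg = heading_deg, seed = as.integer(seed),
                 noise_sd = noise_sd,
                 cycle_variability_sd = cycle_variability_sd,
                 attenuation = attenuation, affected_side = affected_side,
                 missing_gaps = missing_gaps,
                 measurement_noise_sd = measurement_noise_sd),
            class = "cohort_config")
}

#' Generate a two-group synthetic cohort
#'
#' Deterministic for a fixed config: every subject gets one trial per
#' configured speed plus clinical metadata (group, MDS-UPDRS III items
#' 3.3-3.8 per side, handedness, possibly missing). PD subjects receive
#' higher item scores on the configured affected side and, if requested,
#' an attenuated coordination path and larger cycle variability.
#'
#' @param config a [cohort_config()]
#' @return a `gait_cohort`: `trials` (named list of `marker_trial`),
#'   `participants` (tibble of clinical metadata), `config`
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_per_group = 2, speeds = "preferred"))
#' length(cohort$trials) # 4
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_per_group
  groups <- rep(c("control", "pd"), each = n)
  ids <- sprintf("sub-%s%02d", ifelse(groups == "control", "c", "p"),
                 c(seq_len(n), seq_len(n)))

  meta <- with_kin_seed(config$seed, {
    synth_participants(ids, groups, config$affected_side)
  })
  subject_seeds <- with_kin_seed(config$seed + 1L,
                                 sample.int(.Machine$integer.max - 10L,
                                            length(ids)))

  trials <- list()
  for (k in seq_along(ids)) {
    grp <- groups[k]
    segments <- kin_segments(noise_sd = config$noise_sd)
    coord <- coordination_spec(
      segments = segments,
      cycle_variability_sd = unname(config$cycle_variability_sd[[grp]]))
    if (grp == "pd" && !is.null(config$attenuation)) {
      coord <- plant_coordination_deficit(coord, config$attenuation$path,
                                          config$attenuation$direction,
                                          config$attenuation$factor)
    }
    for (s in seq_along(config$speeds)) {
      spd <- config$speeds[s]
      trial <- generate_trial(
        segments = segments, coord = coord, speed = spd,
        heading_deg = config$heading_deg,
        seed = (as.numeric(subject_seeds[k]) + 131 * s) %% 2147483000,
        subject_id = ids[k], group = grp,
        measurement_noise_sd = config$measurement_noise_sd,
        gaps = config$missing_gaps)
      trials[[paste(ids[k], spd, sep = "_")]] <- trial
    }
  }
  structure(list(trials = trials, participants = meta, config = config),
            class = "gait_cohort")
}

#' Synthetic clinical metadata (MDS-UPDRS III items 3.3-3.8 per side)
#' @noRd
synth_participants <- function(ids, groups, affected_side) {
  n <- length(ids)
  hand <- sample(c("right", "left", NA_character_), n, replace = TRUE,
                 prob = c(0.8, 0.1, 0.1))
  items <- c("3_3", "3_4", "3_5", "3_6", "3_7", "3_8")
  score <- function(is_pd, is_affected) {
    base <- ifelse(is_pd, 1.4, 0.05)
    lambda <- base * ifelse(is_affected, 1.6, 0.7)
    pmin(4L, stats::rpois(n, lambda))
  }
  is_pd <- groups == "pd"
  left_affected <- affected_side == "left"
  out <- tibble::tibble(participant_id = ids, group = groups,
                        handedness = hand)
  for (it in items) {
    out[[paste0("updrs_", it, "_left")]] <- score(is_pd, left_affected)
    out[[paste0("updrs_", it, "_right")]] <- score(is_pd, !left_affected)
  }
  out
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d trials, %d participants (%s)\n",
              length(x$trials), nrow(x$participants),
              paste(x$config$speeds, collapse = "/")))
  invisible(x)
}
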