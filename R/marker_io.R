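#' Write / read marker trials in a BIDS-like tabular layout
#'
#' One trial becomes
#' `root/sub-<id>/motion/sub-<id>_task-walk<Speed>_tracksys-omc_motion.tsv`
#' (columns `time_s`, then `<label>_x`, `<label>_y`, `<label>_z` per
#' channel, missing samples encoded as `n/a`) plus a `.json` sidecar
#' carrying sampling rate, group, speed, cone coordinates, the channel
#' list and which channels are auxiliary (heels). Positions round-trip to
#' better than 1e-9 mm.
#'
#' @param trial a `marker_trial`
#' @param root cohort root directory
#' @return `write_trial`: invisibly, the paths written.
#'   `read_trial`: the reconstructed `marker_trial`.
#' @export
write_trial <- function(trial, root) {
  stopifnot(inherits(trial, "marker_trial"))
  dir_motion <- file.path(root, trial$subject_id, "motion")
  dir.create(dir_motion, recursive = TRUE, showWarnings = FALSE)
  stem <- trial_stem(trial$subject_id, trial$speed)
  tsv <- file.path(dir_motion, paste0(stem, "_motion.tsv"))
  json <- file.path(dir_motion, paste0(stem, "_motion.json"))

  n <- dim(trial$positions)[1]
  labels <- dimnames(trial$positions)[[2]]
  aux_labels <- if (!is.null(trial$aux)) dimnames(trial$aux)[[2]] else character()
  cols <- list(time_s = seq_len(n) / trial$sampling_rate)
  for (lab in labels) {
    for (k in 1:3) {
      cols[[paste0(lab, "_", c("x", "y", "z")[k])]] <- trial$positions[, lab, k]
    }
  }
  for (lab in aux_labels) {
    for (k in 1:3) {
      cols[[paste0(lab, "_", c("x", "y", "z")[k])]] <- trial$aux[, lab, k]
    }
  }
  df <- as.data.frame(cols, check.names = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "n/a")
  meta <- list(subject_id = trial$subject_id, group = trial$group,
               speed = trial$speed, sampling_rate = trial$sampling_rate,
               cone_start = trial$cone_start, cone_end = trial$cone_end,
               heading_deg = trial$heading_deg, layout = trial$layout,
               channels = labels, aux_channels = aux_labels)
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}

trial_stem <- function(subject_id, speed) {
  cap <- paste0(toupper(substr(speed, 1, 1)), substr(speed, 2, nchar(speed)))
  sprintf("%s_task-walk%s_tracksys-omc", subject_id, cap)
}

#' @rdname write_trial
#' @param subject,speed identify the trial under `root`
#' @export
read_trial <- function(root, subject, speed) {
  stem <- trial_stem(subject, speed)
  tsv <- file.path(root, subject, "motion", paste0(stem, "_motion.tsv"))
  json <- file.path(root, subject, "motion", paste0(stem, "_motion.json"))
  for (f in c(tsv, json)) {
    if (!file.exists(f)) {
      kin_stop(sprintf("trial file not found: %s", f), "kin_io_error")
    }
  }
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  df <- utils::read.delim(tsv, sep = "\t", check.names = FALSE,
                          na.strings = c("n/a", "NA"))
  expected <- c("time_s",
                as.vector(t(outer(c(meta$channels, meta$aux_channels),
                                  c("_x", "_y", "_z"), paste0))))
  unknown <- setdiff(names(df), expected)
  if (length(unknown) > 0L) {
    kin_stop(sprintf("%s: unknown column(s): %s", tsv,
                     paste(unknown, collapse = ", ")), "kin_format_error")
  }
  absent <- setdiff(expected, names(df))
  if (length(absent) > 0L) {
    kin_stop(sprintf("%s: missing channel column(s): %s", tsv,
                     paste(absent, collapse = ", ")), "kin_format_error")
  }
  build_array <- function(labels) {
    arr <- array(NA_real_, dim = c(nrow(df), length(labels), 3),
                 dimnames = list(NULL, labels, c("x", "y", "z")))
    for (lab in labels) {
      for (k in 1:3) {
        arr[, lab, k] <- df[[paste0(lab, "_", c("x", "y", "z")[k])]]
      }
    }
    arr
  }
  aux <- if (length(meta$aux_channels)) build_array(meta$aux_channels) else NULL
  structure(list(subject_id = meta$subject_id, group = meta$group,
                 speed = meta$speed,
                 sampling_rate = as.numeric(meta$sampling_rate),
                 positions = build_array(meta$channels), aux = aux,
                 cone_start = as.numeric(meta$cone_start),
                 cone_end = as.numeric(meta$cone_end),
                 heading_deg = meta$heading_deg %||% NA_real_,
                 layout = meta$layout %||% "segment", truth = NULL),
            class = "marker_trial")
}

#' Write / read a whole cohort (trials + participants.tsv)
#'
#' @param cohort a `gait_cohort`
#' @param root cohort root directory
#' @return `write_cohort`: invisibly, `root`. `read_cohort`: a
#'   `gait_cohort` (without generator ground truth).
#' @export
write_cohort <- function(cohort, root) {
  stopifnot(inherits(cohort, "gait_cohort"))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (trial in cohort$trials) write_trial(trial, root)
  utils::write.table(cohort$participants, file.path(root, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "n/a")
  invisible(root)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(root) {
  pfile <- file.path(root, "participants.tsv")
  if (!file.exists(pfile)) {
    kin_stop(sprintf("participants.tsv not found under %s", root), "kin_io_error")
  }
  participants <- tibble::as_tibble(
    utils::read.delim(pfile, sep = "\t", na.strings = c("n/a", "NA")))
  trials <- list()
  for (sub in participants$participant_id) {
    motion_dir <- file.path(root, sub, "motion")
    files <- list.files(motion_dir, pattern = "_motion\\.tsv$")
    for (f in files) {
      spd <- tolower(sub(".*task-walk([A-Za-z]+)_.*", "\\1", f))
      trials[[paste(sub, spd, sep = "_")]] <- read_trial(root, sub, spd)
    }
  }
  structure(list(trials = trials, participants = participants, config = NULL),
            class = "gait_cohort")
}

#' Reduce the raw 47-marker layout to the 22-segment layout
#'
#' Head (4 markers), sternum (3) and each thigh/shank cluster (4) collapse
#' to their centroids; upper-arm and forearm markers are dropped; heel
#' markers move to auxiliary channels used only for gait-event detection.
#' Already-reduced trials are returned unchanged with a warning.
#'
#' @param trial a `marker_trial` with `layout == "raw"`
#' @return a `marker_trial` with 22 segment channels + heel aux channels
#' @export
reduce_markers <- function(trial) {
  stopifnot(inherits(trial, "marker_trial"))
  if (identical(trial$layout, "segment")) {
    rlang::warn("trial already uses the reduced segment layout; nothing to do")
    return(trial)
  }
  layout <- kin_raw_layout()
  present <- dimnames(trial$positions)[[2]]
  segs <- kin_segments()$label
  n <- dim(trial$positions)[1]
  pos <- array(NA_real_, dim = c(n, length(segs), 3),
               dimnames = list(NULL, segs, c("x", "y", "z")))
  for (sg in segs) {
    members <- layout$marker[!is.na(layout$segment) & layout$segment == sg]
    missing <- setdiff(members, present)
    if (length(missing) > 0L) {
      kin_stop(sprintf("incomplete cluster for segment '%s': missing %s",
                       sg, paste(missing, collapse = ", ")),
               "kin_format_error")
    }
    block <- trial$positions[, members, , drop = FALSE]
    pos[, sg, ] <- apply(block, c(1, 3), mean)
  }
  heel_markers <- layout$marker[layout$role == "heel"]
  aux <- NULL
  if (all(heel_markers %in% present)) {
    aux <- trial$positions[, heel_markers, , drop = FALSE]
  }
  trial$positions <- pos
  trial$aux <- aux
  trial$layout <- "segment"
  trial
}

#' Per-side MDS-UPDRS III sub-scores from item-level metadata
#'
#' Upper-extremity sum: items 3.3 (rigidity) + 3.4 (finger tapping) +
#' 3.5 (hand movements) + 3.6 (pronation/supination). Lower-extremity
#' sum: 3.3 + 3.7 (toe tapping) + 3.8 (leg agility).
#'
#' @param participants tibble with `updrs_<item>_<side>` columns
#' @return tibble: `participant_id`, `group`, `handedness`,
#'   `updrs_upper_left/right`, `updrs_lower_left/right`
#' @export
clinical_records <- function(participants) {
  p <- participants
  sum_items <- function(items, side) {
    Reduce(`+`, lapply(items, function(it) p[[paste0("updrs_", it, "_", side)]]))
  }
  tibble::tibble(
    participant_id = p$participant_id, group = p$group,
    handedness = p$handedness,
    updrs_upper_left = sum_items(c("3_3", "3_4", "3_5", "3_6"), "left"),
    updrs_upper_right = sum_items(c("3_3", "3_4", "3_5", "3_6"), "right"),
    updrs_lower_left = sum_items(c("3_3", "3_7", "3_8"), "left"),
    updrs_lower_right = sum_items(c("3_3", "3_7", "3_8"), "right"))
}

#' Determine most and least affected sides
#'
#' Per limb level, the side with the higher MDS-UPDRS III sub-score is
#' most affected when the absolute difference is at least 1 point
#' (lateralized). When the scores are even, and always for the control
#' group, the non-dominant side is taken as most affected; missing
#' handedness defaults the non-dominant side to left.
#'
#' @param record one-row tibble or list with `updrs_upper_left/right`,
#'   `updrs_lower_left/right`, `handedness`, `group`
#' @return a `side_assignment`: most/least affected side per limb level
#'   and per-level `lateralized` flags
#' @export
determine_affected_side <- function(record) {
  r <- as.list(record)
  sums <- unlist(r[c("updrs_upper_left", "updrs_upper_right",
                     "updrs_lower_left", "updrs_lower_right")])
  if (any(is.na(sums)) || any(sums < 0)) {
    kin_stop("UPDRS side sums must be present and non-negative", "kin_data_error")
  }
  hand <- r$handedness
  non_dominant <- if (is.null(hand) || is.na(hand)) "left"
                  else if (hand == "right") "left" else "right"
  pick <- function(left, right) {
    if (!identical(r$group, "control") && abs(left - right) >= 1) {
      list(most = if (left > right) "left" else "right", lateralized = TRUE)
    } else {
      list(most = non_dominant, lateralized = FALSE)
    }
  }
  up <- pick(r$updrs_upper_left, r$updrs_upper_right)
  lo <- pick(r$updrs_lower_left, r$updrs_lower_right)
  structure(list(
    most_affected_upper = up$most,
    least_affected_upper = setdiff(c("left", "right"), up$most),
    most_affected_lower = lo$most,
    least_affected_lower = setdiff(c("left", "right"), lo$most),
    lateralized = c(upper = up$lateralized, lower = lo$lateralized)
  ), class = "side_assignment")
}

#' Label map from left/right to mas/las
#'
#' @param assignment a `side_assignment`
#' @param labels segment labels to map
#' @return named character vector: new label for each input label
#' @export
affectedness_map <- function(assignment, labels) {
  upper_bases <- c("shoulder", "elbow", "wrist", "hand")
  out <- labels
  for (k in seq_along(labels)) {
    m <- regmatches(labels[k], regexec("^(.*)_(l|r)$", labels[k]))[[1]]
    if (length(m) == 0L) next
    base <- m[2]
    side <- if (m[3] == "l") "left" else "right"
    most <- if (base %in% upper_bases) assignment$most_affected_upper
            else assignment$most_affected_lower
    out[k] <- paste0(base, "_", if (side == most) "mas" else "las")
  }
  stats::setNames(out, labels)
}

#' Relabel segments by affectedness (left/right to mas/las)
#'
#' @param trial a `marker_trial` in the segment layout
#' @param assignment a `side_assignment` from [determine_affected_side()]
#' @return the trial with mas/las segment labels (axial labels unchanged)
#' @export
relabel_segments_by_affectedness <- function(trial, assignment) {
  stopifnot(inherits(trial, "marker_trial"), inherits(assignment, "side_assignment"))
  labels <- dimnames(trial$positions)[[2]]
  if (any(grepl("_(mas|las)$", labels))) {
    kin_stop("trial segment labels are already relabelled to mas/las",
             "kin_parameter_error")
  }
  map <- affectedness_map(assignment, labels)
  if (anyDuplicated(unname(map))) {
    kin_stop("relabelling would not be a bijection", "kin_data_error")
  }
  dimnames(trial$positions)[[2]] <- unname(map[labels])
  # canonical channel order (mas before las within each pair) so that label
  # order is identical across subjects regardless of which side is affected
  canon <- unlist(lapply(labels, function(lab) {
    if (grepl("_l$", lab)) paste0(sub("_l$", "", lab), c("_mas", "_las"))
    else if (grepl("_r$", lab)) NULL
    else lab
  }))
  trial$positions <- trial$positions[, canon, , drop = FALSE]
  if (!is.null(trial$aux)) {
    heel_lab <- dimnames(trial$aux)[[2]]
    lower_most <- assignment$most_affected_lower
    heel_map <- vapply(heel_lab, function(h) {
      side <- if (grepl("_l$", h)) "left" else "right"
      paste0("heel_", if (side == lower_most) "mas" else "las")
    }, character(1))
    dimnames(trial$aux)[[2]] <- unname(heel_map)
  }
  if (!is.null(trial$truth$coupling)) {
    trial$truth$coupling <- lapply(trial$truth$coupling, function(C) {
      dimnames(C) <- list(unname(map[rownames(C)]), unname(map[colnames(C)]))
      C
    })
  }
  attr(trial, "side_assignment") <- assignment
  trial
}
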