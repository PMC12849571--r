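#' Build a kinectome from one gait acquisition
#'
#' A kinectome is the symmetric matrix of pairwise Pearson correlations
#' between the 500-sample normalised acceleration series of all body
#' segments in one movement direction over a single gait acquisition (one
#' full gait cycle of each side).
#'
#' @param acquisition one element of `preprocess_trial()$acquisitions`,
#'   or directly a samples x segments acceleration matrix
#' @param direction `"AP"`, `"ML"` or `"V"` (ignored when a matrix is
#'   supplied; recorded on the result either way)
#' @return a `kinectome`: correlation matrix with attributes `direction`
#'   and `role = "acquisition"`
#' @export
build_acquisition_kinectome <- function(acquisition, direction = "AP") {
  direction <- match.arg(direction, kin_directions)
  m <- if (is.matrix(acquisition)) acquisition else acquisition$acc[[direction]]
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- colnames(m)[sds == 0 | !is.finite(sds)]
    kin_stop(paste0("zero-variance acceleration series for segment(s): ",
                    paste(bad, collapse = ", ")), "kin_data_error")
  }
  K <- stats::cor(m)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  new_kinectome(K, direction = direction, role = "acquisition")
}

new_kinectome <- function(K, direction, role, speed = NA_character_,
                          subject = NA_character_, group = NA_character_) {
  structure(K, direction = direction, role = role, speed = speed,
            subject = subject, group = group,
            class = c("kinectome", class(K)))
}

#' @export
print.kinectome <- function(x, ...) {
  cat(sprintf("<kinectome> %s | role=%s | %d x %d\n", attr(x, "direction"),
              attr(x, "role"), nrow(x), ncol(x)))
  invisible(x)
}

#' Aggregate acquisition kinectomes into person mean / SD kinectomes
#'
#' Element-wise mean and element-wise sample standard deviation
#' (denominator n - 1) across all acquisition kinectomes of one subject,
#' one speed and one direction. With all three speeds and directions a
#' complete subject yields 9 mean and 9 SD kinectomes.
#'
#' @param kinectomes list of acquisition `kinectome`s (>= 3)
#' @return list with elements `mean` and `sd` (`kinectome`s with roles
#'   `person_mean` / `person_sd`)
#' @export
aggregate_person <- function(kinectomes) {
  if (length(kinectomes) < 3L) {
    kin_stop("need at least 3 acquisition kinectomes per person",
             "kin_insufficient_data")
  }
  check_same_shape(kinectomes)
  A <- simplify2array(kinectomes)
  m <- apply(A, c(1, 2), mean)
  s <- apply(A, c(1, 2), stats::sd)
  dimnames(m) <- dimnames(s) <- dimnames(kinectomes[[1]])
  dir <- attr(kinectomes[[1]], "direction")
  list(mean = new_kinectome((m + t(m)) / 2, dir, "person_mean"),
       sd = new_kinectome((s + t(s)) / 2, dir, "person_sd"))
}

#' Aggregate person kinectomes into a group kinectome
#'
#' Element-wise mean of person-mean kinectomes (role `group_mean`) or of
#' person-SD kinectomes (role `group_sd`) across the subjects of one
#' group, at one speed and direction.
#'
#' @param kinectomes list of person-level `kinectome`s (>= 2 subjects),
#'   all sharing one role and direction
#' @return a `kinectome` with role `group_mean` or `group_sd`
#' @export
aggregate_group <- function(kinectomes) {
  if (length(kinectomes) < 2L) {
    kin_stop("need at least 2 subjects to build a group kinectome",
             "kin_insufficient_data")
  }
  check_same_shape(kinectomes)
  dirs <- unique(vapply(kinectomes, attr, character(1), "direction"))
  roles <- unique(vapply(kinectomes, attr, character(1), "role"))
  if (length(dirs) != 1L || length(roles) != 1L) {
    kin_stop("cannot aggregate kinectomes with mixed directions or roles",
             "kin_parameter_error")
  }
  role_out <- switch(roles, person_mean = "group_mean", person_sd = "group_sd",
                     kin_stop("group aggregation expects person_mean or person_sd inputs",
                              "kin_parameter_error"))
  A <- simplify2array(kinectomes)
  m <- apply(A, c(1, 2), mean)
  dimnames(m) <- dimnames(kinectomes[[1]])
  new_kinectome((m + t(m)) / 2, dirs, role_out)
}

check_same_shape <- function(kinectomes) {
  d1 <- dim(kinectomes[[1]])
  l1 <- dimnames(kinectomes[[1]])[[1]]
  for (k in kinectomes[-1]) {
    if (!identical(dim(k), d1) || !identical(dimnames(k)[[1]], l1)) {
      kin_stop("kinectomes differ in shape or segment label order",
               "kin_parameter_error")
    }
  }
  invisible(TRUE)
}

#' Person-level kinectomes for a whole cohort
#'
#' Preprocesses every trial and aggregates acquisition kinectomes into
#' person mean/SD kinectomes per (subject, speed, direction). Trials with
#' fewer than the minimum number of acquisitions are excluded with a
#' reason.
#'
#' @param cohort a `gait_cohort`
#' @param params see [preproc_params()]
#' @param relabel map left/right segment labels to mas/las using the
#'   clinical metadata before building kinectomes
#' @return list: `person` tibble (subject, group, speed, direction,
#'   n_acquisitions, `mean`/`sd` list-columns of kinectomes),
#'   `exclusions` tibble, and `acquisitions` (per-trial window index)
#' @export
cohort_kinectomes <- function(cohort, params = preproc_params(),
                              relabel = TRUE) {
  stopifnot(inherits(cohort, "gait_cohort"))
  records <- clinical_records(cohort$participants)
  rows <- list()
  excl <- list()
  acq_rows <- list()
  for (trial in cohort$trials) {
    if (relabel) {
      rec <- records[records$participant_id == trial$subject_id, , drop = FALSE]
      trial <- relabel_segments_by_affectedness(trial,
                                                determine_affected_side(rec))
    }
    pp <- tryCatch(preprocess_trial(trial, params), kinectome_error = identity)
    if (inherits(pp, "condition")) {
      excl[[length(excl) + 1L]] <- tibble::tibble(
        subject = trial$subject_id, speed = trial$speed,
        reason = conditionMessage(pp))
      next
    }
    if (!pp$sufficient) {
      excl[[length(excl) + 1L]] <- tibble::tibble(
        subject = trial$subject_id, speed = trial$speed,
        reason = sprintf("only %d acquisitions (min %d)",
                         length(pp$acquisitions), params$min_acquisitions))
      next
    }
    acq_rows[[length(acq_rows) + 1L]] <- tibble::tibble(
      subject = trial$subject_id, speed = trial$speed,
      window = seq_along(pp$acquisitions),
      start = vapply(pp$acquisitions, function(a) a$window[["start"]],
                     numeric(1)),
      end = vapply(pp$acquisitions, function(a) a$window[["end"]], numeric(1)))
    for (d in kin_directions) {
      ks <- lapply(pp$acquisitions, build_acquisition_kinectome, direction = d)
      agg <- aggregate_person(ks)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = trial$subject_id, group = trial$group, speed = trial$speed,
        direction = d, n_acquisitions = length(ks),
        mean = list(agg$mean), sd = list(agg$sd))
    }
  }
  list(person = dplyr::bind_rows(rows), exclusions = dplyr::bind_rows(excl),
       acquisitions = dplyr::bind_rows(acq_rows))
}

#' Group mean / SD kinectomes from a person-kinectome table
#'
#' @param person the `person` tibble from [cohort_kinectomes()]
#' @return tibble: group, speed, direction, n_subjects, `mean` and `sd`
#'   list-columns of group kinectomes
#' @export
group_kinectomes <- function(person) {
  dplyr::group_by(person, .data$group, .data$speed, .data$direction) |>
    dplyr::summarise(
      n_subjects = dplyr::n(),
      mean = list(aggregate_group(.data$mean)),
      sd = list(aggregate_group(.data$sd)),
      .groups = "drop")
}

#' Write a kinectome as a labelled TSV matrix
#'
#' @param k a `kinectome`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_kinectome <- function(k, path) {
  df <- data.frame(segment = rownames(k), unclass(k), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinectome
#' @param direction,role attributes to attach on read
#' @export
read_kinectome <- function(path, direction = "AP", role = "acquisition") {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$segment
  new_kinectome(m, direction, role)
}
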