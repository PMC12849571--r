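#' Coordination specification: target acceleration correlation structure
#'
#' A `coordination_spec` holds, per movement direction, the symmetric
#' matrix of target pairwise acceleration correlations ("coupling") that
#' the synthetic generator realizes, plus the stride-to-stride variability
#' scale. When no coupling matrix is supplied it is derived from the
#' segment model: segment i loads on the two gait harmonics with phase
#' `phase_*` and communality amp^2 / (amp^2 + noise_sd^2), and the implied
#' correlation between two segments is the inner product of their loading
#' vectors. Equal-phase segments with zero motor noise therefore couple at
#' +1, anti-phase segments at -1.
#'
#' @param coupling `NULL` (derive from `segments`), a single symmetric
#'   matrix used for all three directions, or a named list with entries
#'   `AP`, `ML`, `V`
#' @param segments segment model tibble, see [kin_segments()]
#' @param cycle_variability_sd dimensionless scale of per-stride random
#'   phase/amplitude jitter (typical healthy gait ~0.02)
#' @return object of class `coordination_spec`: list with `coupling`
#'   (named list of 22 x 22 matrices), `cycle_variability_sd`, `labels`
#' @export
#' @examples
#' spec <- coordination_spec()
#' round(spec$coupling$AP[1:3, 1:3], 2)
coordination_spec <- function(coupling = NULL, segments = kin_segments(),
                              cycle_variability_sd = 0.02) {
  assert_scalar_number(cycle_variability_sd, "cycle_variability_sd", 0, 1)
  labels <- segments$label
  if (is.null(coupling)) {
    coupling <- lapply(stats::setNames(kin_directions, kin_directions),
                       function(d) implied_coupling(segments, d))
  } else if (is.matrix(coupling)) {
    coupling <- stats::setNames(rep(list(coupling), 3), kin_directions)
  }
  if (!is.list(coupling) || !all(kin_directions %in% names(coupling))) {
    kin_stop("`coupling` must be NULL, a matrix, or a list with AP/ML/V entries",
             "kin_parameter_error")
  }
  coupling <- lapply(coupling[kin_directions], function(C) {
    validate_coupling(C, labels)
    dimnames(C) <- list(labels, labels)
    C
  })
  structure(list(coupling = coupling,
                 cycle_variability_sd = cycle_variability_sd,
                 labels = labels),
            class = "coordination_spec")
}

validate_coupling <- function(C, labels) {
  if (!is.matrix(C) || nrow(C) != length(labels) || ncol(C) != length(labels)) {
    kin_stop("coupling matrix has wrong dimensions", "kin_parameter_error")
  }
  if (max(abs(C - t(C))) > 1e-8) {
    kin_stop("coupling matrix must be symmetric", "kin_parameter_error")
  }
  if (max(abs(diag(C) - 1)) > 1e-8) {
    kin_stop("coupling matrix must have unit diagonal", "kin_parameter_error")
  }
  if (any(abs(C) > 1 + 1e-8)) {
    kin_stop("coupling values must lie in [-1, 1]", "kin_parameter_error")
  }
  invisible(C)
}

#' Coupling matrix implied by the segment phase model
#' @noRd
implied_coupling <- function(segments, direction) {
  amp <- segments[[paste0("amp_", direction)]]
  phase <- segments[[paste0("phase_", direction)]]
  w1 <- segments[[paste0("w1_", direction)]]
  comm <- amp^2 / (amp^2 + segments$noise_sd^2)
  # loading of each segment on (sin, cos) of harmonics 1 and 2
  U <- sqrt(comm) * cbind(sqrt(w1) * cos(phase), sqrt(w1) * sin(phase),
                          sqrt(1 - w1) * cos(2 * phase),
                          sqrt(1 - w1) * sin(2 * phase))
  C <- U %*% t(U)
  diag(C) <- 1
  dimnames(C) <- list(segments$label, segments$label)
  C
}

#' Attenuate coordination along a path of segments
#'
#' Multiplies the coupling entries on consecutive edges of `path` in one
#' movement direction by `attenuation`, leaving every other entry
#' unchanged. Used to plant a known inter-segmental coordination deficit
#' in a synthetic group.
#'
#' @param coord a [coordination_spec()]
#' @param path ordered character vector of distinct segment labels
#' @param direction one of `"AP"`, `"ML"`, `"V"`
#' @param attenuation multiplicative factor in (0, 1]
#' @return a new `coordination_spec`
#' @export
plant_coordination_deficit <- function(coord, path, direction, attenuation) {
  stopifnot(inherits(coord, "coordination_spec"))
  direction <- match.arg(direction, kin_directions)
  if (!is.numeric(attenuation) || length(attenuation) != 1L ||
      attenuation <= 0 || attenuation > 1) {
    kin_stop("`attenuation` must lie in (0, 1]", "kin_parameter_error")
  }
  if (anyDuplicated(path) || length(path) < 2L) {
    kin_stop("`path` must hold at least two distinct segment labels",
             "kin_parameter_error")
  }
  missing_nodes <- setdiff(path, coord$labels)
  if (length(missing_nodes) > 0L) {
    kin_stop(paste0("path nodes not in coupling: ",
                    paste(missing_nodes, collapse = ", ")),
             "kin_parameter_error")
  }
  C <- coord$coupling[[direction]]
  for (k in seq_len(length(path) - 1L)) {
    i <- path[k]; j <- path[k + 1L]
    C[i, j] <- C[i, j] * attenuation
    C[j, i] <- C[i, j]
  }
  coord$coupling[[direction]] <- C
  coord
}

#' Project a symmetric matrix onto the nearest valid correlation matrix
#'
#' Clips negative eigenvalues at zero and rescales to a unit diagonal.
#' Planted deficits can push a coupling matrix slightly outside the
#' positive-semidefinite cone; generation always works on this projection.
#' @noRd
nearest_psd_correlation <- function(C) {
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) >= -1e-12) return(C)
  lam <- pmax(e$values, 0)
  C2 <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(pmax(diag(C2), .Machine$double.eps))
  C2 <- C2 / outer(d, d)
  diag(C2) <- 1
  dimnames(C2) <- dimnames(C)
  (C2 + t(C2)) / 2
}
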