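#' Represent a kinectome as a complete weighted coordination graph
#'
#' Body segments become nodes and the signed acceleration correlations
#' become edge weights of a complete undirected graph.
#'
#' @param kinectome a correlation-role `kinectome` (acquisition,
#'   person_mean or group_mean); SD-role kinectomes are refused
#' @return an undirected complete `igraph` graph with a `weight` edge
#'   attribute
#' @export
kinectome_to_graph <- function(kinectome) {
  role <- attr(kinectome, "role") %||% "acquisition"
  if (grepl("sd", role)) {
    kin_stop("SD-role kinectomes are not correlation graphs", "kin_parameter_error")
  }
  m <- unclass(kinectome)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  diag(m) <- 0
  igraph::graph_from_adjacency_matrix(m, mode = "undirected", weighted = TRUE,
                                      diag = FALSE)
}

as_weight_matrix <- function(graph) {
  if (igraph::is_igraph(graph)) {
    m <- as.matrix(igraph::as_adjacency_matrix(graph, attr = "weight",
                                               sparse = FALSE))
  } else {
    m <- unclass(graph)
    attributes(m) <- attributes(m)[c("dim", "dimnames")]
  }
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("n", seq_len(nrow(m)))
  }
  m
}

#' Greedy maximum-absolute-weight path from a start node
#'
#' Starting at `start`, iteratively appends the unvisited node whose
#' connecting edge has the highest absolute weight from the current node,
#' until the path holds `length` nodes. Only the path length is
#' constrained; there is no target node. Ties are broken by lexicographic
#' segment-label order, making the extraction deterministic.
#'
#' @param graph an `igraph` graph, a `kinectome`, or a symmetric weight
#'   matrix
#' @param start starting node label
#' @param length number of nodes in the path (2 to node count)
#' @return a `pattern_path`: ordered character vector of node labels with
#'   attributes `start` and `level`
#' @export
strongest_pattern <- function(graph, start, length) {
  w <- as_weight_matrix(graph)
  nodes <- rownames(w)
  if (!start %in% nodes) kin_stop(sprintf("start node '%s' not in graph", start),
                                  "kin_parameter_error")
  if (length < 2L || length > nrow(w)) {
    kin_stop("path length must lie between 2 and the node count",
             "kin_parameter_error")
  }
  path <- start
  current <- start
  for (step in seq_len(length - 1L)) {
    candidates <- setdiff(nodes, path)
    aw <- abs(w[current, candidates])
    best <- max(aw)
    chosen <- sort(candidates[aw == best])
    path <- c(path, chosen[1])
    current <- chosen[1]
  }
  new_pattern_path(path)
}

new_pattern_path <- function(nodes) {
  structure(nodes, start = nodes[1],
            level = classify_level(base::length(nodes)),
            class = "pattern_path")
}

#' @export
print.pattern_path <- function(x, ...) {
  cat(sprintf("<pattern_path> L=%d (%s): %s\n", base::length(x),
              attr(x, "level"), paste(unclass(x), collapse = " -> ")))
  invisible(x)
}

#' Pattern level taxonomy
#'
#' Local patterns span 2-6 body segments (simple coordination), multi-
#' segmental 7-14 (complex networks), whole-body 15 or more (global
#' coordination).
#'
#' @param L number of segments in the pattern, 2 to 22
#' @return `"local"`, `"multi_segmental"` or `"whole_body"`
#' @export
classify_level <- function(L) {
  if (!is.numeric(L) || L < 2 || L > 22) {
    kin_stop("pattern length must lie in [2, 22]", "kin_parameter_error")
  }
  if (L <= 6) "local" else if (L <= 14) "multi_segmental" else "whole_body"
}

#' Group reference pattern
#'
#' The group-specific strongest pattern for a start node and length.
#' Default strategy `"group_mean"`: greedy extraction on the element-wise
#' mean of the group's person-mean kinectomes. Alternative
#' `"majority_vote"`: extract each subject's strongest pattern and pick,
#' position by position, the most frequent unvisited node (ties by label
#' order).
#'
#' @param kinectomes list of the source group's person-mean kinectomes
#' @param start,length as in [strongest_pattern()]
#' @param strategy `"group_mean"` or `"majority_vote"`
#' @return a `pattern_path` with attribute `strategy`
#' @export
group_reference_pattern <- function(kinectomes, start, length,
                                    strategy = c("group_mean", "majority_vote")) {
  strategy <- match.arg(strategy)
  if (base::length(kinectomes) < 2L) {
    kin_stop("need at least 2 subjects for a group reference pattern",
             "kin_insufficient_data")
  }
  if (strategy == "group_mean") {
    A <- simplify2array(lapply(kinectomes, function(k) {
      m <- unclass(k); attributes(m) <- attributes(m)[c("dim", "dimnames")]; m
    }))
    m <- apply(A, c(1, 2), mean)
    dimnames(m) <- dimnames(kinectomes[[1]])
    out <- strongest_pattern(m, start, length)
  } else {
    paths <- lapply(kinectomes, strongest_pattern, start = start, length = length)
    path <- start
    for (pos in 2:length) {
      votes <- table(unlist(lapply(paths, function(p) {
        cand <- setdiff(unclass(p), path)
        if (base::length(cand) >= 1 && base::length(p) >= pos) p[[pos]] else NULL
      })))
      votes <- votes[!names(votes) %in% path]
      if (base::length(votes) == 0L) {
        # all subjects' nodes already used: fall back to remaining labels
        votes <- table(setdiff(rownames(kinectomes[[1]]), path))
      }
      best <- sort(names(votes)[votes == max(votes)])[1]
      path <- c(path, best)
    }
    out <- new_pattern_path(path)
  }
  attr(out, "strategy") <- strategy
  out
}

#' Value of a pattern in a kinectome
#'
#' Mean absolute edge weight over the path's consecutive edges (the
#' default; `method = "sum"` sums them instead). Higher values indicate
#' stronger correlation between the segments of the pattern; the mean
#' keeps values comparable across path lengths and bounded in [0, 1].
#'
#' @param kinectome a correlation-role `kinectome` (or weight matrix)
#' @param path a `pattern_path` or character vector of distinct labels
#' @param method `"mean"` or `"sum"` of absolute edge weights
#' @return scalar pattern value
#' @export
pattern_value <- function(kinectome, path, method = c("mean", "sum")) {
  method <- match.arg(method)
  path <- as.character(path)
  if (anyDuplicated(path)) kin_stop("path has repeated nodes", "kin_parameter_error")
  w <- as_weight_matrix(kinectome)
  idx <- cbind(path[-base::length(path)], path[-1])
  vals <- abs(w[idx])
  if (method == "mean") mean(vals) else sum(vals)
}

#' Jaccard overlap between the node sets of two patterns
#'
#' Patterns overlapping at 0.8 or more are treated as the same pattern.
#'
#' @param path1,path2 `pattern_path`s or character vectors
#' @return Jaccard index in [0, 1]
#' @export
jaccard_overlap <- function(path1, path2) {
  a <- unique(as.character(path1))
  b <- unique(as.character(path2))
  base::length(intersect(a, b)) / base::length(union(a, b))
}

#' Scan all pattern comparisons between two groups
#'
#' For every start node and every length in `lengths`, builds the source
#' group's reference pattern, reads that pattern's value off every
#' subject's person-mean kinectome in both groups, and compares the two
#' value samples (normality-gated t / Mann-Whitney U with outlier
#' removal). P-values are Bonferroni-adjusted across the start nodes
#' within each length (n = `bonferroni_n`).
#'
#' @param person person-kinectome tibble from [cohort_kinectomes()],
#'   filtered rows are selected by `speed` and `direction`
#' @param speed,direction condition to scan
#' @param source_group group whose reference patterns are extracted
#'   (`"control"` or `"pd"`)
#' @param lengths path lengths to scan (default 2:20)
#' @param bonferroni_n multiplicity for the per-length adjustment
#' @param value_method see [pattern_value()]
#' @param strategy see [group_reference_pattern()]
#' @return tibble with one row per (start, length): reference path,
#'   per-group ns, test, p_raw, p_bonferroni, Cohen's d, d label,
#'   direction of difference (`pd_weaker` / `pd_stronger`)
#' @export
scan_patterns <- function(person, speed, direction, source_group = "control",
                          lengths = 2:20, bonferroni_n = 22,
                          value_method = "mean", strategy = "group_mean") {
  sub <- person[person$speed == speed & person$direction == direction, ,
                drop = FALSE]
  groups <- unique(sub$group)
  if (!all(c("control", "pd") %in% groups)) {
    kin_stop("both groups (control, pd) must be present", "kin_parameter_error")
  }
  k_control <- sub$mean[sub$group == "control"]
  k_pd <- sub$mean[sub$group == "pd"]
  if (base::length(k_control) < 2L || base::length(k_pd) < 2L) {
    kin_stop("need at least 2 subjects per group", "kin_insufficient_data")
  }
  k_source <- if (source_group == "control") k_control else k_pd
  starts <- rownames(k_control[[1]])

  rows <- list()
  for (L in lengths) {
    for (st in starts) {
      ref <- group_reference_pattern(k_source, st, L, strategy = strategy)
      v_control <- vapply(k_control, pattern_value, numeric(1),
                          path = ref, method = value_method)
      v_pd <- vapply(k_pd, pattern_value, numeric(1),
                     path = ref, method = value_method)
      cmp <- compare_groups(v_control, v_pd)
      rows[[base::length(rows) + 1L]] <- tibble::tibble(
        speed = speed, direction = direction, source = source_group,
        start = st, length = L, level = attr(ref, "level"),
        path = list(unclass(ref)),
        n_control = cmp$n1, n_pd = cmp$n2, test = cmp$test,
        p_raw = cmp$p, cohens_d = cmp$cohens_d, d_label = cmp$d_label,
        direction_of_difference = if (mean(v_pd) < mean(v_control))
          "pd_weaker" else "pd_stronger")
    }
  }
  out <- dplyr::bind_rows(rows)
  dplyr::group_by(out, .data$length) |>
    dplyr::mutate(p_bonferroni = bonferroni_adjust(.data$p_raw, bonferroni_n)) |>
    dplyr::ungroup() |>
    dplyr::relocate("p_bonferroni", .after = "p_raw")
}

#' Deduplicate pattern comparisons between two scan sources
#'
#' Two references (one control-derived, one PD-derived) with node-set
#' Jaccard overlap >= `threshold` at the same speed, direction and length
#' are the same pattern; the PD-derived duplicate is flagged.
#'
#' @param scan_control,scan_pd outputs of [scan_patterns()] for the two
#'   source groups
#' @param threshold Jaccard threshold (default 0.8)
#' @return combined tibble with a logical `duplicate` column
#' @export
deduplicate_patterns <- function(scan_control, scan_pd, threshold = 0.8) {
  scan_control$duplicate <- FALSE
  dup <- logical(nrow(scan_pd))
  for (r in seq_len(nrow(scan_pd))) {
    same <- scan_control$length == scan_pd$length[r] &
      scan_control$speed == scan_pd$speed[r] &
      scan_control$direction == scan_pd$direction[r]
    if (!any(same)) next
    js <- vapply(scan_control$path[same], jaccard_overlap, numeric(1),
                 path2 = scan_pd$path[[r]])
    dup[r] <- any(js >= threshold)
  }
  scan_pd$duplicate <- dup
  dplyr::bind_rows(scan_control, scan_pd)
}
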