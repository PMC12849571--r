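#' Study configuration
#'
#' Bundles every tunable of an end-to-end run with its default: cohort
#' source (a [cohort_config()] or an on-disk root), preprocessing
#' thresholds, pattern-scan options and statistics options. Round-trips
#' losslessly through YAML ([write_study_config()] /
#' [read_study_config()]).
#'
#' @param cohort a `cohort_config`, or a path to a cohort root directory
#' @param preprocessing see [preproc_params()]
#' @param patterns list: `lengths`, `bonferroni_n`, `jaccard_threshold`,
#'   `value_method`, `strategy`, `sources`
#' @param stats list: `n_perm`, `bootstrap` (`enabled`, `fractions`,
#'   `n_boot`), `seed`
#' @param relabel map segment labels to mas/las from clinical metadata
#' @return a `study_config`
#' @export
study_config <- function(cohort = cohort_config(),
                         preprocessing = preproc_params(),
                         patterns = list(lengths = 2:20, bonferroni_n = 22,
                                         jaccard_threshold = 0.8,
                                         value_method = "mean",
                                         strategy = "group_mean",
                                         sources = c("control", "pd")),
                         stats = list(n_perm = 5000,
                                      bootstrap = list(enabled = FALSE,
                                                       fractions = seq(0.1, 0.9, 0.1),
                                                       n_boot = 5000),
                                      seed = 1),
                         relabel = TRUE) {
  structure(list(cohort = cohort, preprocessing = preprocessing,
                 patterns = patterns, stats = stats, relabel = relabel),
            class = "study_config")
}

#' @rdname study_config
#' @param config a `study_config`
#' @param path YAML file path
#' @export
write_study_config <- function(config, path) {
  x <- rapply(unclass(config), function(v) v, how = "replace")
  x$cohort <- if (is.character(config$cohort)) config$cohort
              else unclass(config$cohort)
  if (!is.character(x$cohort)) {
    # keep the group names through YAML (named vectors serialise unnamed)
    x$cohort$cycle_variability_sd <- as.list(x$cohort$cycle_variability_sd)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname study_config
#' @export
read_study_config <- function(path) {
  x <- yaml::read_yaml(path)
  cohort <- x$cohort
  if (!is.character(cohort)) {
    cv <- unlist(cohort$cycle_variability_sd)
    cohort <- cohort_config(
      n_per_group = cohort$n_per_group,
      speeds = unlist(cohort$speeds),
      heading_deg = cohort$heading_deg,
      seed = cohort$seed,
      noise_sd = cohort$noise_sd,
      cycle_variability_sd = cv,
      attenuation = if (!is.null(cohort$attenuation))
        list(path = unlist(cohort$attenuation$path),
             direction = cohort$attenuation$direction,
             factor = cohort$attenuation$factor),
      affected_side = cohort$affected_side,
      missing_gaps = cohort$missing_gaps,
      measurement_noise_sd = cohort$measurement_noise_sd)
  }
  study_config(cohort = cohort,
               preprocessing = utils::modifyList(preproc_params(),
                                                 x$preprocessing %||% list()),
               patterns = utils::modifyList(study_config()$patterns,
                                            x$patterns %||% list()),
               stats = utils::modifyList(study_config()$stats,
                                         x$stats %||% list()),
               relabel = x$relabel %||% TRUE)
}

config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' Run the full kinectome analysis
#'
#' Generates (or reads) the cohort, preprocesses every trial, builds
#' person and group kinectomes, runs the permutation comparison of group
#' mean and SD kinectomes, the optional bootstrap stability analysis, and
#' the pattern scans with Bonferroni adjustment and Jaccard
#' deduplication. Deterministic for a fixed configuration.
#'
#' @param config a [study_config()]
#' @param out_dir optional output directory for TSV tables, kinectome
#'   matrices and a JSON run manifest
#' @return list: `person`, `groups` (kinectome tibbles), `permutation`,
#'   `bootstrap`, `patterns` tibbles, `exclusions`, `manifest`
#' @export
run_pipeline <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  cohort <- if (is.character(config$cohort)) read_cohort(config$cohort)
            else generate_cohort(config$cohort)
  if (length(cohort$trials) == 0L) {
    kin_stop("cohort holds no trials", "kin_data_error")
  }
  ck <- cohort_kinectomes(cohort, params = config$preprocessing,
                          relabel = config$relabel)
  person <- ck$person
  if (nrow(person) == 0L) kin_stop("no usable trials after preprocessing",
                                   "kin_data_error")
  groups <- group_kinectomes(person)

  seed <- config$stats$seed
  conditions <- dplyr::distinct(person, .data$speed, .data$direction)
  perm_rows <- list()
  for (r in seq_len(nrow(conditions))) {
    spd <- conditions$speed[r]; d <- conditions$direction[r]
    gc <- groups[groups$speed == spd & groups$direction == d, ]
    if (!all(c("control", "pd") %in% gc$group)) next
    for (role in c("mean", "sd")) {
      res <- permutation_test_kinectomes(
        gc[[role]][gc$group == "control"][[1]],
        gc[[role]][gc$group == "pd"][[1]],
        n_perm = config$stats$n_perm,
        seed = seed + r * 13L + (role == "sd"))
      perm_rows[[length(perm_rows) + 1L]] <- tibble::tibble(
        speed = spd, direction = d, role = paste0("group_", role),
        rho = res$rho_observed, p = res$p, n_perm = res$n_perm)
    }
  }
  permutation <- dplyr::bind_rows(perm_rows)

  bootstrap <- NULL
  if (isTRUE(config$stats$bootstrap$enabled)) {
    boot_rows <- list()
    for (r in seq_len(nrow(conditions))) {
      spd <- conditions$speed[r]; d <- conditions$direction[r]
      sub <- person[person$speed == spd & person$direction == d, ]
      if (!all(c("control", "pd") %in% sub$group)) next
      bt <- bootstrap_stability(
        sub$mean[sub$group == "control"], sub$mean[sub$group == "pd"],
        fractions = config$stats$bootstrap$fractions,
        n_boot = config$stats$bootstrap$n_boot,
        seed = seed + 1000L + r)
      bt$speed <- spd; bt$direction <- d
      boot_rows[[length(boot_rows) + 1L]] <- bt
    }
    bootstrap <- dplyr::bind_rows(boot_rows)
  }

  pat_rows <- list()
  for (r in seq_len(nrow(conditions))) {
    spd <- conditions$speed[r]; d <- conditions$direction[r]
    sub <- person[person$speed == spd & person$direction == d, ]
    if (!all(c("control", "pd") %in% sub$group)) next
    scans <- lapply(config$patterns$sources, function(src) {
      scan_patterns(person, spd, d, source_group = src,
                    lengths = config$patterns$lengths,
                    bonferroni_n = config$patterns$bonferroni_n,
                    value_method = config$patterns$value_method,
                    strategy = config$patterns$strategy)
    })
    combined <- if (length(scans) == 2L) {
      deduplicate_patterns(scans[[1]], scans[[2]],
                           threshold = config$patterns$jaccard_threshold)
    } else {
      scans[[1]]$duplicate <- FALSE
      scans[[1]]
    }
    pat_rows[[length(pat_rows) + 1L]] <- combined
  }
  patterns <- dplyr::bind_rows(pat_rows)

  manifest <- list(config_hash = config_hash(config), seed = seed,
                   n_trials = length(cohort$trials),
                   n_subjects = nrow(cohort$participants),
                   package_version = as.character(utils::packageVersion("kinectome")),
                   timestamp = format(Sys.time(), tz = "UTC"))

  result <- list(person = person, groups = groups, permutation = permutation,
                 bootstrap = bootstrap, patterns = patterns,
                 exclusions = ck$exclusions, acquisitions = ck$acquisitions,
                 manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- result$manifest$config_hash
  write_tsv_plain <- function(df, name) {
    df$config_hash <- hash
    utils::write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  pat <- result$patterns
  if (!is.null(pat) && nrow(pat)) {
    pat$path <- vapply(pat$path, paste, character(1), collapse = ",")
    write_tsv_plain(pat, "pattern_comparisons.tsv")
    summary <- dplyr::count(result$patterns, .data$speed, .data$direction,
                            .data$source, .data$level,
                            significant = .data$p_bonferroni < 0.05)
    write_tsv_plain(summary, "pattern_summary.tsv")
  }
  if (nrow(result$permutation)) write_tsv_plain(result$permutation,
                                                "permutation_tests.tsv")
  if (!is.null(result$bootstrap) && nrow(result$bootstrap)) {
    bt <- result$bootstrap
    bt$rhos <- NULL
    write_tsv_plain(bt, "bootstrap_stability.tsv")
  }
  if (nrow(result$exclusions)) write_tsv_plain(result$exclusions,
                                               "exclusions.tsv")
  if (!is.null(result$acquisitions) && nrow(result$acquisitions)) {
    write_tsv_plain(result$acquisitions, "acquisition_index.tsv")
  }
  g <- result$groups
  for (r in seq_len(nrow(g))) {
    for (role in c("mean", "sd")) {
      write_kinectome(g[[role]][[r]], file.path(out_dir,
        sprintf("kinectome_%s_%s_%s_group_%s.tsv", g$group[r], g$speed[r],
                g$direction[r], role)))
    }
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
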