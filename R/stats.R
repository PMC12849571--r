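#' Remove outliers from a sample
#'
#' Normally distributed samples lose values more than three standard
#' deviations from the mean (Z-score method); non-normal samples lose
#' values beyond 1.5 interquartile ranges outside the quartiles
#' (quartiles by linear interpolation, type 7).
#'
#' @param values numeric sample (>= 3 values)
#' @param normal logical normality flag for the sample
#' @return list: `values` (kept), `removed`
#' @export
remove_outliers <- function(values, normal) {
  if (length(values) < 3L) {
    kin_stop("need at least 3 values for outlier screening", "kin_parameter_error")
  }
  if (isTRUE(normal)) {
    s <- stats::sd(values)
    keep <- if (s == 0) rep(TRUE, length(values))
            else abs(values - mean(values)) / s <= 3
  } else {
    q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    keep <- values >= q[1] - 1.5 * iqr & values <= q[2] + 1.5 * iqr
  }
  if (!any(keep)) kin_stop("outlier screening removed every value", "kin_data_error")
  list(values = values[keep], removed = values[!keep])
}

#' Cohen's d with pooled standard deviation
#'
#' Sign convention: (mean of group 1 - mean of group 2) / pooled SD.
#' Labels: |d| < 0.2 negligible, < 0.5 small, < 0.8 medium, >= 0.8 large.
#'
#' @param x,y the two samples
#' @return list: `d`, `label`
#' @export
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  diff <- mean(x) - mean(y)
  if (sp2 <= 0) {
    # degenerate zero-variance samples: keep d finite by convention
    d <- if (diff == 0) 0 else diff / (1e-12 * max(abs(c(x, y)), 1))
  } else {
    d <- diff / sqrt(sp2)
  }
  a <- abs(d)
  label <- if (a < 0.2) "negligible" else if (a < 0.5) "small"
           else if (a < 0.8) "medium" else "large"
  list(d = d, label = label)
}

shapiro_normal <- function(x, alpha = 0.05) {
  if (length(unique(x)) < 3L || stats::sd(x) == 0) return(FALSE)
  p <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  p > alpha
}

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk (alpha = 0.05) decides normality per group on the
#' original values; outliers are then removed per group using each
#' group's flag ([remove_outliers()]); a two-sample Student t-test
#' (pooled variance) is used when both groups are normal, otherwise the
#' Mann-Whitney U test. Cohen's d (group 1 - group 2, pooled SD) is
#' computed on the screened values. Two constant, equal samples return
#' p = 1 by convention.
#'
#' @param values1,values2 the two samples (>= 3 each)
#' @param var_equal use the pooled-variance t-test (Welch if `FALSE`)
#' @param screen_outliers apply outlier removal before testing
#' @return list: `test`, `statistic`, `p`, `n1`, `n2`,
#'   `removed_outliers` (per group), `cohens_d`, `d_label`, `normal`
#' @export
compare_groups <- function(values1, values2, var_equal = TRUE,
                           screen_outliers = TRUE) {
  if (length(values1) < 3L || length(values2) < 3L) {
    kin_stop("need at least 3 values per group", "kin_parameter_error")
  }
  norm1 <- shapiro_normal(values1)
  norm2 <- shapiro_normal(values2)
  removed <- list(group1 = numeric(), group2 = numeric())
  if (screen_outliers) {
    o1 <- remove_outliers(values1, norm1)
    o2 <- remove_outliers(values2, norm2)
    values1 <- o1$values; values2 <- o2$values
    removed <- list(group1 = o1$removed, group2 = o2$removed)
  }
  if (length(values1) < 2L || length(values2) < 2L) {
    kin_stop("fewer than 2 values per group after outlier removal",
             "kin_data_error")
  }
  both_normal <- norm1 && norm2
  degenerate <- stats::sd(values1) == 0 && stats::sd(values2) == 0
  if (degenerate && mean(values1) == mean(values2)) {
    test <- "t_test"; statistic <- 0; p <- 1
  } else if (both_normal) {
    tt <- stats::t.test(values1, values2, var.equal = var_equal)
    test <- "t_test"; statistic <- unname(tt$statistic); p <- tt$p.value
  } else {
    wt <- suppressWarnings(stats::wilcox.test(values1, values2, exact = FALSE,
                                              correct = TRUE))
    test <- "mann_whitney_u"; statistic <- unname(wt$statistic); p <- wt$p.value
  }
  es <- cohens_d(values1, values2)
  list(test = test, statistic = statistic, p = p,
       n1 = length(values1), n2 = length(values2),
       removed_outliers = removed, cohens_d = es$d, d_label = es$label,
       normal = c(norm1, norm2))
}

#' Permutation test between two group kinectomes
#'
#' The observed statistic is the Spearman correlation of the vectorised
#' strictly-upper-triangle entries of the two matrices. The null
#' distribution shuffles the control-group vector `n_perm` times; the
#' one-sided exceedance p-value uses +1 smoothing:
#' p = (1 + #\{null >= observed\}) / (n_perm + 1).
#'
#' @param control_kinectome,pd_kinectome matching group kinectomes
#' @param n_perm number of shuffles (default 5000)
#' @param seed integer seed
#' @return list: `rho_observed`, `null_rhos`, `p`, `n_perm`, `seed`
#' @export
permutation_test_kinectomes <- function(control_kinectome, pd_kinectome,
                                        n_perm = 5000, seed = 1) {
  if (!identical(dim(control_kinectome), dim(pd_kinectome)) ||
      !identical(rownames(control_kinectome), rownames(pd_kinectome))) {
    kin_stop("kinectomes differ in shape or label order", "kin_parameter_error")
  }
  x <- upper_tri_vec(control_kinectome)
  y <- upper_tri_vec(pd_kinectome)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    kin_stop("constant kinectome vector; Spearman correlation undefined",
             "kin_data_error")
  }
  rho <- stats::cor(x, y, method = "spearman")
  null_rhos <- with_kin_seed(seed, {
    vapply(seq_len(n_perm),
           function(b) stats::cor(sample(x), y, method = "spearman"),
           numeric(1))
  })
  p <- (1 + sum(null_rhos >= rho)) / (n_perm + 1)
  list(rho_observed = rho, null_rhos = null_rhos, p = p,
       n_perm = n_perm, seed = seed)
}

#' Bootstrap stability of the group-kinectome correlation
#'
#' For each subsample fraction, both groups are independently resampled
#' with replacement to `ceiling(fraction * n)` subjects, group-mean
#' kinectomes are rebuilt from the resampled subjects, and the Spearman
#' correlation between the two resampled group matrices is recorded.
#'
#' @param control_kinectomes,pd_kinectomes lists of person-level
#'   kinectomes (one role: all person_mean or all person_sd)
#' @param fractions subsample fractions (default 0.1 to 0.9 by 0.1)
#' @param n_boot iterations per fraction
#' @param seed integer seed
#' @return tibble: `fraction`, `n_boot`, `mean_rho`, `sd_rho`, `rhos`
#'   (list-column); fractions yielding fewer than 2 subjects are skipped
#'   with a warning
#' @export
bootstrap_stability <- function(control_kinectomes, pd_kinectomes,
                                fractions = seq(0.1, 0.9, by = 0.1),
                                n_boot = 5000, seed = 1) {
  if (length(control_kinectomes) < 5L || length(pd_kinectomes) < 5L) {
    kin_stop("need at least 5 subjects per group for bootstrapping",
             "kin_insufficient_data")
  }
  A1 <- simplify2array(lapply(control_kinectomes, unclass))
  A2 <- simplify2array(lapply(pd_kinectomes, unclass))
  ut <- upper.tri(A1[, , 1])
  v1 <- apply(A1, 3, function(m) m[ut]) # entries x subjects
  v2 <- apply(A2, 3, function(m) m[ut])
  n1 <- ncol(v1); n2 <- ncol(v2)
  rows <- with_kin_seed(seed, {
    out <- list()
    for (f in fractions) {
      k1 <- ceiling(f * n1); k2 <- ceiling(f * n2)
      if (k1 < 2L || k2 < 2L) {
        rlang::warn(sprintf("fraction %.2f yields fewer than 2 subjects; skipped", f))
        next
      }
      rhos <- vapply(seq_len(n_boot), function(b) {
        m1 <- rowMeans(v1[, sample.int(n1, k1, replace = TRUE), drop = FALSE])
        m2 <- rowMeans(v2[, sample.int(n2, k2, replace = TRUE), drop = FALSE])
        stats::cor(m1, m2, method = "spearman")
      }, numeric(1))
      out[[length(out) + 1L]] <- tibble::tibble(
        fraction = f, n_boot = n_boot, mean_rho = mean(rhos),
        sd_rho = stats::sd(rhos), rhos = list(rhos))
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, p * n)` with a fixed multiplicity `n` (default 22, the
#' number of start nodes compared within each pattern length).
#'
#' @param p vector of p-values in [0, 1]
#' @param n multiplicity
#' @return adjusted p-values, order preserved
#' @export
bonferroni_adjust <- function(p, n = 22) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    kin_stop("p-values must lie in [0, 1]", "kin_parameter_error")
  }
  pmin(1, p * n)
}
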