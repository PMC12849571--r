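# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# A preprocessed default trial (heading 30 deg, default coupling)
fixture_preprocessed <- function() {
  cached("pp30", {
    trial <- generate_trial(seed = 11, heading_deg = 30)
    list(trial = trial, pp = preprocess_trial(trial))
  })
}

# Minimal two-segment model for analytic correlation checks
two_segment_model <- function(phase2 = 0, noise_sd = 0) {
  seg <- kin_segments(noise_sd = noise_sd)[1:2, ]
  seg$label <- c("a", "b")
  seg$amp_AP <- c(40, 40); seg$amp_ML <- c(20, 20); seg$amp_V <- c(20, 20)
  seg$phase_AP <- c(0, phase2); seg$phase_ML <- c(0, phase2)
  seg$phase_V <- c(0, phase2)
  seg$w1_AP <- seg$w1_ML <- seg$w1_V <- c(1, 1)
  seg
}

# Brute-force acceleration correlations of a generated trial (independent
# of the preprocessing path: plain second differences, no filtering)
realized_correlations <- function(trial, direction = "AP") {
  k <- match(direction, c("AP", "ML", "V"))
  acc <- apply(trial$positions, c(2, 3), function(x) diff(diff(x))) *
    trial$sampling_rate^2
  stats::cor(acc[, , k])
}

# Random correlation-like symmetric weight matrix with n nodes
random_weight_matrix <- function(n, seed, labels = NULL) {
  withr::with_seed(seed, {
    m <- stats::cor(matrix(stats::rnorm(4 * n * n), ncol = n))
  })
  if (is.null(labels)) labels <- sprintf("n%02d", seq_len(n))
  dimnames(m) <- list(labels, labels)
  m
}

# Random person-kinectome table for pattern-scan tests (no gait involved)
fixture_person_table <- function(n_per_group = 6, seed = 7) {
  cached(sprintf("persontab_%d_%d", n_per_group, seed), {
    labels <- kin_segments()$label
    rows <- list()
    i <- 0
    for (grp in c("control", "pd")) {
      for (s in seq_len(n_per_group)) {
        i <- i + 1
        m <- random_weight_matrix(22, seed + i, labels)
        k <- kinectome:::new_kinectome(m, "AP", "person_mean")
        rows[[i]] <- tibble::tibble(
          subject = sprintf("s%02d", i), group = grp, speed = "preferred",
          direction = "AP", n_acquisitions = 4, mean = list(k), sd = list(k))
      }
    }
    dplyr::bind_rows(rows)
  })
}
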