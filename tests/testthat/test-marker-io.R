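test_that("trial round-trip preserves positions, masks and metadata", {
  tr <- generate_trial(seed = 5, heading_deg = 40,
                       gaps = data.frame(marker = "head", start = 100, length = 10))
  root <- withr::local_tempdir()
  write_trial(tr, root)
  tr2 <- read_trial(root, "sub-01", "preferred")
  expect_lt(max(abs(tr$positions - tr2$positions), na.rm = TRUE), 1e-9)
  expect_identical(is.na(tr$positions), is.na(tr2$positions))
  expect_lt(max(abs(tr$aux - tr2$aux)), 1e-9)
  expect_identical(tr2$group, tr$group)
  expect_identical(tr2$speed, tr$speed)
  expect_identical(tr2$sampling_rate, tr$sampling_rate)
  expect_equal(tr2$cone_start, tr$cone_start)
  expect_equal(tr2$cone_end, tr$cone_end)
})

test_that("malformed trial files raise format errors naming the problem", {
  tr <- generate_trial(seed = 5)
  root <- withr::local_tempdir()
  paths <- write_trial(tr, root)
  expect_error(read_trial(root, "sub-01", "fast"), class = "kin_io_error")
  df <- utils::read.delim(paths[["tsv"]], check.names = FALSE)
  df$rogue_x <- 1
  utils::write.table(df, paths[["tsv"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_trial(root, "sub-01", "preferred"),
               regexp = "rogue_x", class = "kin_format_error")
  df$rogue_x <- NULL
  df[["head_x"]] <- NULL
  utils::write.table(df, paths[["tsv"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_trial(root, "sub-01", "preferred"),
               regexp = "head_x", class = "kin_format_error")
})

test_that("cohort round-trip reproduces trials and participants", {
  co <- generate_cohort(cohort_config(n_per_group = 2, speeds = "preferred",
                                      seed = 1))
  root <- withr::local_tempdir()
  write_cohort(co, root)
  co2 <- read_cohort(root)
  expect_setequal(names(co2$trials), names(co$trials))
  nm <- names(co$trials)[1]
  expect_lt(max(abs(co$trials[[nm]]$positions - co2$trials[[nm]]$positions)),
            1e-9)
  expect_equal(as.data.frame(co$participants), as.data.frame(co2$participants))
})

test_that("47-marker layout reduces to 22 segments with exact centroids", {
  raw <- generate_trial(seed = 5, raw_layout = TRUE)
  expect_identical(dim(raw$positions)[2], 47L)
  red <- reduce_markers(raw)
  expect_identical(dim(red$positions)[2], 22L)
  expect_identical(dimnames(red$positions)[[2]], kin_segments()$label)
  expect_identical(dimnames(red$aux)[[2]], c("heel_l", "heel_r"))
  head_centroid <- apply(raw$positions[, c("head_lf", "head_rf", "head_lb",
                                           "head_rb"), ], c(1, 3), mean)
  expect_lt(max(abs(head_centroid - red$positions[, "head", ])), 1e-9)
  stern <- apply(raw$positions[, c("stern_up", "stern_mid", "stern_low"), ],
                 c(1, 3), mean)
  expect_lt(max(abs(stern - red$positions[, "sternum", ])), 1e-9)
  expect_false(any(grepl("upper_arm|forearm", dimnames(red$positions)[[2]])))
})

test_that("marker reduction is idempotent and strict about clusters", {
  tr <- generate_trial(seed = 5)
  expect_warning(again <- reduce_markers(tr), "already")
  expect_identical(again$positions, tr$positions)
  raw <- generate_trial(seed = 5, raw_layout = TRUE)
  keep <- setdiff(dimnames(raw$positions)[[2]], "thigh_l_2")
  raw$positions <- raw$positions[, keep, ]
  expect_error(reduce_markers(raw), regexp = "thigh_l",
               class = "kin_format_error")
})

test_that("affected-side rules match a brute-force truth table", {
  # independent oracle, written straight from the clinical rules
  oracle <- function(diff, hand, group) {
    nd <- if (is.na(hand)) "left" else if (hand == "right") "left" else "right"
    if (group != "control" && abs(diff) >= 1) {
      if (diff > 0) "left" else "right"
    } else nd
  }
  for (diff in -2:2) {
    for (hand in c("left", "right", NA)) {
      for (group in c("control", "pd")) {
        rec <- list(updrs_upper_left = 5 + diff, updrs_upper_right = 5,
                    updrs_lower_left = 3 + diff, updrs_lower_right = 3,
                    handedness = hand, group = group)
        a <- determine_affected_side(rec)
        expected <- oracle(diff, hand, group)
        expect_identical(a$most_affected_upper, expected)
        expect_identical(a$most_affected_lower, expected)
        expect_false(a$most_affected_upper == a$least_affected_upper)
        expect_identical(unname(a$lateralized["upper"]),
                         group != "control" && abs(diff) >= 1)
      }
    }
  }
  expect_error(determine_affected_side(list(
    updrs_upper_left = -1, updrs_upper_right = 0,
    updrs_lower_left = 0, updrs_lower_right = 0,
    handedness = "right", group = "pd")), class = "kin_data_error")
})

test_that("mas/las relabelling is a bijection with canonical order", {
  tr <- generate_trial(seed = 6)
  assign_left <- determine_affected_side(list(
    updrs_upper_left = 5, updrs_upper_right = 2,
    updrs_lower_left = 4, updrs_lower_right = 1,
    handedness = "right", group = "pd"))
  rel <- relabel_segments_by_affectedness(tr, assign_left)
  labs <- dimnames(rel$positions)[[2]]
  expect_true("thigh_mas" %in% labs)
  expect_lt(max(abs(rel$positions[, "thigh_mas", ] - tr$positions[, "thigh_l", ])),
            1e-12)
  expect_error(relabel_segments_by_affectedness(rel, assign_left),
               class = "kin_parameter_error")
  # inverting the map recovers the original labels
  map <- affectedness_map(assign_left, dimnames(tr$positions)[[2]])
  inv <- stats::setNames(names(map), unname(map))
  expect_setequal(unname(inv[labs]), dimnames(tr$positions)[[2]])
  # opposite assignment sends thigh_r to mas, but label order stays canonical
  assign_right <- determine_affected_side(list(
    updrs_upper_left = 1, updrs_upper_right = 5,
    updrs_lower_left = 1, updrs_lower_right = 5,
    handedness = "right", group = "pd"))
  rel2 <- relabel_segments_by_affectedness(tr, assign_right)
  expect_identical(dimnames(rel2$positions)[[2]], labs)
  expect_lt(max(abs(rel2$positions[, "thigh_mas", ] - tr$positions[, "thigh_r", ])),
            1e-12)
})
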