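test_that("a kinectome maps to a complete undirected weighted graph", {
  m <- random_weight_matrix(22, 1, kin_segments()$label)
  k <- kinectome:::new_kinectome(m, "AP", "person_mean")
  g <- kinectome_to_graph(k)
  expect_equal(igraph::vcount(g), 22)
  expect_equal(igraph::ecount(g), 231) # 22 * 21 / 2
  expect_false(igraph::is_directed(g))
  w <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  off <- upper.tri(m)
  expect_equal(unname(w[off]), unname(m[off]))
  sdk <- kinectome:::new_kinectome(abs(m), "AP", "person_sd")
  expect_error(kinectome_to_graph(sdk), class = "kin_parameter_error")
})

test_that("greedy extraction follows the highest absolute weight", {
  lab <- c("A", "B", "C")
  w <- matrix(0, 3, 3, dimnames = list(lab, lab))
  w["A", "B"] <- w["B", "A"] <- 0.9
  w["A", "C"] <- w["C", "A"] <- 0.5
  w["B", "C"] <- w["C", "B"] <- 0.1
  expect_identical(as.character(strongest_pattern(w, "A", 2)), c("A", "B"))
  # absolute value governs: a strong negative edge wins
  w["A", "B"] <- w["B", "A"] <- -0.9
  expect_identical(as.character(strongest_pattern(w, "A", 2)), c("A", "B"))
  expect_error(strongest_pattern(w, "A", 4), class = "kin_parameter_error")
  expect_error(strongest_pattern(w, "Z", 2), class = "kin_parameter_error")
})

test_that("every greedy step is locally maximal on random graphs", {
  # exhaustive per-step oracle over random graphs up to 10 nodes
  for (s in 1:25) {
    n <- 4 + (s %% 7)
    w <- random_weight_matrix(n, 400 + s)
    for (start in rownames(w)) {
      for (L in 2:n) {
        p <- unclass(strongest_pattern(w, start, L))
        expect_length(p, L)
        expect_identical(anyDuplicated(p), 0L)
        for (step in seq_len(L - 1)) {
          visited <- p[seq_len(step)]
          cand <- setdiff(rownames(w), visited)
          expect_equal(abs(w[p[step], p[step + 1]]),
                       max(abs(w[p[step], cand])))
        }
      }
    }
  }
})

test_that("ties break deterministically by label order", {
  lab <- c("a", "b", "c", "d")
  w <- matrix(0.5, 4, 4, dimnames = list(lab, lab)); diag(w) <- 0
  expect_identical(as.character(strongest_pattern(w, "c", 4)), c("c", "a", "b", "d"))
  expect_identical(as.character(strongest_pattern(w, "c", 4)),
                   as.character(strongest_pattern(w, "c", 4)))
})

test_that("pattern levels follow the 2-6 / 7-14 / 15+ taxonomy", {
  expect_identical(classify_level(2), "local")
  expect_identical(classify_level(6), "local")
  expect_identical(classify_level(7), "multi_segmental")
  expect_identical(classify_level(14), "multi_segmental")
  expect_identical(classify_level(15), "whole_body")
  expect_identical(classify_level(22), "whole_body")
  expect_error(classify_level(1), class = "kin_parameter_error")
  expect_error(classify_level(23), class = "kin_parameter_error")
})

test_that("group reference patterns agree with hand-built oracles", {
  lab <- kin_segments()$label
  mk <- function(seed) kinectome:::new_kinectome(
    random_weight_matrix(22, seed, lab), "AP", "person_mean")
  same <- replicate(4, mk(50), simplify = FALSE)
  ref_mean <- group_reference_pattern(same, "head", 5)
  ref_vote <- group_reference_pattern(same, "head", 5, strategy = "majority_vote")
  indiv <- strongest_pattern(same[[1]], "head", 5)
  expect_identical(as.character(ref_mean), as.character(indiv))
  expect_identical(as.character(ref_vote), as.character(indiv))
  # 5 distinct subjects: default strategy equals greedy on the mean matrix
  ks <- lapply(51:55, mk)
  hand_mean <- Reduce(`+`, lapply(ks, unclass)) / 5
  expect_identical(as.character(group_reference_pattern(ks, "toe_l", 7)),
                   as.character(strongest_pattern(hand_mean, "toe_l", 7)))
  expect_error(group_reference_pattern(ks[1], "head", 3),
               class = "kin_insufficient_data")
})

test_that("pattern values average absolute edge weights", {
  lab <- c("A", "B", "C")
  w <- matrix(0, 3, 3, dimnames = list(lab, lab))
  w["A", "B"] <- w["B", "A"] <- 0.7
  expect_equal(pattern_value(w, c("A", "B")), 0.7)
  w["A", "B"] <- w["B", "A"] <- 0.8
  w["B", "C"] <- w["C", "B"] <- -0.6
  expect_equal(pattern_value(w, c("A", "B", "C")), 0.7) # (0.8 + 0.6) / 2
  expect_equal(pattern_value(w, c("A", "B", "C"), method = "sum"), 1.4)
  ones <- matrix(1, 3, 3, dimnames = list(lab, lab))
  expect_equal(pattern_value(ones, c("C", "A", "B")), 1)
  # invariant to traversal reversal
  m <- random_weight_matrix(8, 3)
  p <- unclass(strongest_pattern(m, "n01", 5))
  expect_equal(pattern_value(m, p), pattern_value(m, rev(p)))
  expect_error(pattern_value(w, c("A", "B", "A")), class = "kin_parameter_error")
})

test_that("jaccard overlap satisfies identity, symmetry and the 0.8 rule", {
  expect_equal(jaccard_overlap(letters[1:5], letters[1:5]), 1)
  expect_equal(jaccard_overlap(letters[1:5], letters[6:10]), 0)
  a <- sprintf("s%02d", 1:10)
  b <- c(a[1:8], "x", "y") # 8 shared of 12 distinct
  expect_equal(jaccard_overlap(a, b), 8 / 12)
  expect_lt(jaccard_overlap(a, b), 0.8)
  expect_equal(jaccard_overlap(a, b), jaccard_overlap(b, a))
})

test_that("pattern scans enumerate all starts and lengths with valid stats", {
  person <- fixture_person_table()
  scan <- scan_patterns(person, "preferred", "AP", lengths = 2:4)
  expect_identical(nrow(scan), 22L * 3L)
  expect_true(all(scan$p_raw >= 0 & scan$p_raw <= 1))
  expect_true(all(scan$p_bonferroni >= scan$p_raw))
  expect_true(all(scan$p_bonferroni <= 1))
  expect_true(all(scan$p_bonferroni < 0.05 | scan$p_raw >= 0.05 / 22 - 1e-12))
  expect_true(all(vapply(scan$path, length, integer(1)) == scan$length))
  expect_true(all(is.finite(scan$cohens_d)))
  expect_setequal(unique(scan$level), "local")
  # per-length Bonferroni with n = 22
  expect_equal(scan$p_bonferroni, pmin(1, scan$p_raw * 22))
})

test_that("deduplication flags same-pattern references across sources", {
  person <- fixture_person_table()
  s1 <- scan_patterns(person, "preferred", "AP", source_group = "control",
                      lengths = 2:3)
  s2 <- scan_patterns(person, "preferred", "AP", source_group = "pd",
                      lengths = 2:3)
  both <- deduplicate_patterns(s1, s2)
  expect_identical(nrow(both), nrow(s1) + nrow(s2))
  expect_false(any(both$duplicate[both$source == "control"]))
  # a PD-derived reference identical to a control-derived one is a duplicate
  ident <- vapply(seq_len(nrow(s2)), function(r) {
    any(vapply(s1$path[s1$length == s2$length[r]],
               jaccard_overlap, numeric(1), path2 = s2$path[[r]]) >= 0.8)
  }, logical(1))
  expect_identical(both$duplicate[both$source == "pd"], ident)
})
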