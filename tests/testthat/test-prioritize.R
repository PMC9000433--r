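test_that("the greedy rule picks uncovered-count maxima with lexicographic ties", {
  fm <- fm_from_sets(list(A = c(1, 2, 3), B = c(3, 4), C = c(5)))
  sel <- prioritize_group(c("A", "B", "C"), fm, threshold = 0.75,
                          group_id = 1L)
  expect_equal(sel$universe_size, 5L)
  expect_equal(sel$selected, c("A", "B"))       # B beats C on the tie
  expect_equal(sel$cumulative_captured, c(3L, 4L))
  expect_equal(sel$captured_fraction, 0.8)

  # single member: forced, full coverage
  sel <- prioritize_group("A", fm_from_sets(list(A = c(1, 2))),
                          threshold = 0.1)
  expect_equal(sel$selected, "A")
  expect_equal(sel$captured_fraction, 1.0)

  # members adding nothing new are never selected, even at threshold 1
  fm <- fm_from_sets(list(A = 1, B = 2, C = 1))
  sel <- prioritize_group(c("A", "B", "C"), fm, threshold = 1.0)
  expect_equal(sel$selected, c("A", "B"))
  expect_equal(sel$captured_fraction, 1.0)
})

test_that("degenerate groups and bad inputs are handled per contract", {
  fm <- fm_from_sets(list(A = integer(0), B = integer(0)))
  sel <- prioritize_group(c("A", "B"), fm, threshold = 0.75)
  expect_equal(sel$universe_size, 0L)
  expect_equal(sel$selected, character(0))
  expect_equal(sel$captured_fraction, 1.0)
  # optional representative for empty-universe groups
  sel1 <- prioritize_group(c("B", "A"), fm, threshold = 0.75,
                           min_select = 1L)
  expect_equal(sel1$selected, "A")

  expect_error(prioritize_group(character(0), fm, 0.75), "empty group")
  expect_error(prioritize_group("A", fm, 0), "threshold")
  expect_error(prioritize_group("A", fm, 1.2), "threshold")
  expect_error(prioritize_group("Z", fm, 0.5), "Z")
})

test_that("greedy selection agrees with the brute-force oracle on small instances", {
  set.seed(41)
  for (i in 1:60) {
    sets <- random_sets(sample(2:6, 1), sample(2:8, 1), runif(1, 0.2, 0.7))
    for (th in c(0.3, 0.75, 1.0)) {
      got <- run_greedy(sets, th)
      want <- greedy_oracle(sets, th)
      expect_equal(got$selected, want$selected)
      expect_equal(got$cumulative_captured, want$cumulative)
      expect_equal(got$captured_fraction, want$fraction)
      expect_equal(got$captured_index, want$captured)
    }
  }
})

test_that("collection-level prioritization aggregates per-group results", {
  sets <- list(A = c(1, 2, 3), B = c(3, 4), C = c(5), D = c(6, 7),
               E = c(7))
  fm <- fm_from_sets(sets)

  # everything in one group equals a single prioritize_group call
  asg1 <- group_assignment(stats::setNames(rep(1L, 5), names(sets)))
  lib1 <- prioritize_all(asg1, fm, threshold = 0.75)
  expect_length(lib1$per_group, 1L)
  expect_equal(lib1$per_group[[1]]$selected,
               prioritize_group(names(sets), fm, 0.75)$selected)

  # singleton groups: every isolate selected
  asgN <- group_assignment(stats::setNames(1:5, names(sets)))
  libN <- prioritize_all(asgN, fm, threshold = 0.75)
  expect_equal(libN$n_selected_total, 5L)
  expect_equal(libN$n_features_captured, libN$n_features_total)

  # two groups: totals are sums/unions over groups
  asg2 <- group_assignment(c(A = 1L, B = 1L, C = 1L, D = 2L, E = 2L))
  lib2 <- prioritize_all(asg2, fm, threshold = 0.75)
  expect_equal(lib2$n_isolates_total, 5L)
  expect_equal(lib2$n_selected_total,
               sum(vapply(lib2$per_group,
                          function(g) length(g$selected), 1L)))
  expect_equal(lib2$n_features_total, 7L)
  union_cap <- sort(unique(unlist(lapply(lib2$per_group,
                                         `[[`, "captured_features"))))
  expect_equal(lib2$n_features_captured, length(union_cap))
  # determinism: identical inputs, identical outputs
  expect_identical(lib2, prioritize_all(asg2, fm, threshold = 0.75))
})

test_that("reported percentages use half-up integer rounding", {
  expect_identical(percent_reduction(100, 100), 0L)
  expect_identical(percent_reduction(200, 150), 25L)
  expect_identical(percent_reduction(8, 7), 13L)   # 12.5 rounds half up
  expect_error(percent_reduction(0, 0), "positive")
  expect_error(percent_reduction(10, 11), "n_selected")

  expect_identical(percent_captured(0, 10), 0L)
  expect_identical(percent_captured(10, 10), 100L)
  expect_identical(percent_captured(1, 8), 13L)
  expect_error(percent_captured(1, 0), "positive")
})

test_that("three-way comparison reports all Venn regions and isolate differences", {
  mk <- function(iso, cap) list(isolates = iso, captured = cap)
  s <- mk(sprintf("i%d", 1:5), 1:100)
  cmp <- compare_selections(s, s, s)
  expect_equal(unname(cmp$venn["abc"]), 100)
  expect_equal(sum(cmp$venn), 100)

  cmp <- compare_selections(mk("a", 1), mk("b", 2), mk("c", 3))
  expect_equal(unname(cmp$venn[c("a_only", "b_only", "c_only")]),
               c(1, 1, 1))
  expect_equal(sum(cmp$venn), 3)

  cmp <- compare_selections(mk(letters[1:2], c(1, 2, 3)),
                            mk(letters[1:3], c(2, 3, 4)),
                            mk(letters[1:5], c(3, 4, 5)),
                            labels = c("A", "B", "C"))
  expect_equal(unname(cmp$venn["abc"]), 1)      # {3}
  expect_equal(unname(cmp$venn["ab_only"]), 1)  # {2}
  expect_equal(unname(cmp$venn["bc_only"]), 1)  # {4}
  expect_equal(unname(cmp$venn["ac_only"]), 0)
  expect_equal(unname(cmp$venn[c("a_only", "b_only", "c_only")]),
               c(1, 0, 1))
  expect_equal(unname(cmp$isolate_diffs), c(-1, -3, -2))
  expect_equal(names(cmp$isolate_diffs), c("A-B", "A-C", "B-C"))

  # a library_selection is accepted directly
  fm <- fm_from_sets(list(A = 1:3, B = 2:4))
  asg <- group_assignment(c(A = 1L, B = 1L))
  lib <- prioritize_all(asg, fm, 1.0)
  cmp <- compare_selections(lib, lib, lib)
  expect_equal(unname(cmp$venn["abc"]), 4)
})
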