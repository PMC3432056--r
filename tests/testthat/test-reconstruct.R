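test_that("score_all enumerates every tuple, target and hypothesis once", {
  tr <- add_noise(simulate(e3(), 60, seed = 15), 0.05)
  sc <- score_all(tr, 3, 2)
  expect_equal(nrow(sc), 3 * 3 * 8)
  expect_equal(anyDuplicated(sc[, c("target", "inputs", "cell")]), 0L)
  # consistent with the single-table scorer
  one <- p_score_table(tr, 1, c(1, 3))
  rows <- sc[sc$target == 1 & sc$inputs == "1,3", ]
  expect_equal(rows$score[order(rows$cell)], unname(one))
  # deterministic given the samples
  expect_equal(score_all(tr, 3, 2), sc)
})

test_that("conflicts are detected for over-supported, constant and
           contradictory combinations", {
  # two prerequisites jointly implicating three genes for one target
  over <- make_scored(list(1, "1,3", 1, 0.01), list(1, "2,3", 5, 0.02))
  expect_true(has_conflict(over, K = 2))
  expect_match(attr(has_conflict(over, 2), "diagnosis")$reason, "exceeds K")

  # every left cell of one tuple: conjunction collapses to constant 0
  const <- make_scored(list(1, "1,2", 1, 0.01), list(1, "1,2", 3, 0.01),
                       list(1, "1,2", 5, 0.01), list(1, "1,2", 7, 0.01))
  expect_true(has_conflict(const, K = 2))

  # L and R forbidding the same pattern force the target to 0 and 1 at once
  contra <- make_scored(list(1, "1,2", 1, 0.01), list(1, "1,2", 0, 0.01))
  expect_true(has_conflict(contra, K = 2))

  # dual-equivalent L/R sets are a similarity, not a conflict
  sim <- make_scored(list(3, "1,2", 1, 0.01), list(3, "1,2", 2, 0.01),
                     list(3, "1,2", 5, 0.01), list(3, "1,2", 6, 0.01))
  expect_false(has_conflict(sim, K = 2))

  # the complete truthful selection for the example network is conflict-free
  truth <- e3_true_cells()
  truth$score <- 0.01
  truth$label <- "q"
  truth$side <- ifelse(truth$cell %% 2 == 1, "L", "R")
  expect_false(has_conflict(truth, K = 2))

  expect_false(has_conflict(truth[0, ], K = 2))
})

test_that("the threshold is the largest candidate whose strict selection is
           conflict-free", {
  # conflict first arises when admitting 0.3, and persists above
  sc <- make_scored(list(1, "1,3", 1, 0.1), list(1, "2,3", 5, 0.3),
                    list(2, "1,2", 1, 0.45))
  th <- max_compatibility_threshold(sc, K = 2)
  expect_equal(th$threshold, 0.3)
  expect_equal(th$selected$score, 0.1)
  expect_false(has_conflict(th$selected, 2))
  expect_equal(th$conflict_score, 0.3)

  # all-compatible scores: the cap is the threshold and everything enters
  ok <- make_scored(list(1, "1,3", 1, 0.1), list(2, "1,3", 1, 0.2))
  th2 <- max_compatibility_threshold(ok, K = 2)
  expect_equal(th2$threshold, 0.5)
  expect_equal(nrow(th2$selected), 2)
  expect_true(is.na(th2$conflict_score))

  # equal scores at the conflict point are excluded all-or-none
  tie <- make_scored(list(1, "1,3", 1, 0.3), list(1, "2,3", 5, 0.3),
                    list(2, "1,2", 1, 0.45))
  th3 <- max_compatibility_threshold(tie, K = 2)
  expect_equal(th3$threshold, 0.3)
  expect_equal(nrow(th3$selected), 0)

  # transient conflicts between marginal shadows of one relation must not
  # stop the sweep: the full shadow set collapses back to two genes
  shadows <- make_scored(
    list(2, "2,3", 5, 0.017), list(2, "1,3", 5, 0.038),
    list(2, "1,3", 1, 0.039), list(2, "2,3", 1, 0.052),
    list(2, "1,3", 3, 0.069),
    list(1, "1,3", 1, 0.016), list(1, "2,3", 5, 0.138))
  th4 <- max_compatibility_threshold(shadows, K = 2)
  expect_equal(th4$threshold, 0.138)
  expect_equal(nrow(th4$selected), 6)
})

test_that("the reference score multiset yields the known threshold and
           network", {
  sc <- e3_reference_scores()
  th <- max_compatibility_threshold(sc, K = 2)
  expect_equal(th$threshold, 0.138)
  expect_equal(nrow(th$selected), 16)
  net <- assemble_network(th$selected, 3, 2)
  expect_true(tdbn_equivalent(net, e3()))
  # the conflicting admission implicates three genes for gene 1
  expect_equal(th$conflict_score, 0.138)
})

test_that("assembly reproduces relations from selections", {
  truth <- e3_true_cells()
  truth$score <- 0.01
  truth$label <- "q"
  truth$side <- ifelse(truth$cell %% 2 == 1, "L", "R")
  net <- assemble_network(truth, 3, 2)
  expect_true(tdbn_equivalent(net, e3()))

  expect_length(assemble_network(truth[0, ], 3, 2)$relations, 0)

  sim <- make_scored(list(3, "1,2", 1, 0.01), list(3, "1,2", 2, 0.01),
                     list(3, "1,2", 5, 0.01), list(3, "1,2", 6, 0.01))
  rel <- tdbnet:::tdbn_relation_for(assemble_network(sim, 3, 2), 3)
  expect_equal(rel$rtype, "similar")
  expect_identical(rel$func, boolfun(2, c(0, 1)))

  over <- make_scored(list(1, "1,3", 1, 0.01), list(1, "2,3", 5, 0.02))
  expect_error(assemble_network(over, 3, 2), "conflict")
})

test_that("must-include seeding lower-bounds the threshold", {
  sc <- make_scored(list(1, "1,3", 1, 0.1), list(1, "2,3", 5, 0.3),
                    list(2, "1,2", 1, 0.45))
  # force the 0.3 hypothesis in: the sweep may not stop at or below 0.3
  th <- suppressWarnings(
    max_compatibility_threshold(sc, K = 2,
                                must_include = data.frame(
                                  target = 1, inputs = "2,3", cell = 5)))
  expect_gt(th$threshold, 0.3)
  expect_true(0.3 %in% th$selected$score)
})

test_that("noise-free identification probability rises with sample size", {
  net <- e3()
  lo <- identification_probability(net, m = 25, p = 0, trials = 20, seed = 5)
  hi <- identification_probability(net, m = 300, p = 0, trials = 20, seed = 5)
  expect_gte(hi, lo)
  expect_gte(hi, 0.9)
  # one sample can never pin down a nontrivial network
  one <- identification_probability(net, m = 1, p = 0, trials = 10, seed = 6)
  expect_lt(one, 0.2)
})
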