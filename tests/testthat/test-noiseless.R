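test_that("basic relations map forbidden cells to OR-form functions", {
  b <- basic_relation(c(1, 2), 1)  # cell 001: pattern 00, output 1
  expect_equal(b$side, "L")
  expect_equal(b$func$table, c(0L, 1L, 1L, 1L))  # v1 OR v2
  b2 <- basic_relation(c(1, 2), 3)  # pattern 01, output 1
  expect_equal(b2$func$table, c(1L, 0L, 1L, 1L))  # v1 OR !v2
  b3 <- basic_relation(c(1, 2), 4)  # pattern 10, output 0
  expect_equal(b3$side, "R")
  expect_equal(b3$func$table, c(1L, 1L, 0L, 1L))  # !v1 OR v2
  # the function always vanishes exactly at its forbidden pattern
  for (cell in 0:7) {
    bb <- basic_relation(c(2, 5), cell)
    expect_equal(sum(bb$func$table == 0L), 1L)
    expect_equal(which(bb$func$table == 0L) - 1L, cell %/% 2L)
  }
})

test_that("consistency scan returns one basic relation per zero cell", {
  mk <- function(counts) {
    structure(list(target = 1L, inputs = c(1L, 2L),
                   counts = as.integer(counts), N = sum(counts)),
              class = "count_table")
  }
  one <- consistent_basic_relations(mk(c(30, 0, 12, 10, 5, 9, 15, 17)))
  expect_length(one, 1)
  expect_equal(one[[1]]$cell, 1L)
  expect_equal(one[[1]]$side, "L")
  expect_equal(one[[1]]$func$table, c(0L, 1L, 1L, 1L))

  expect_length(consistent_basic_relations(mk(rep(5, 8))), 0)

  # the similarity footprint: zeros at cells 001, 101 (L) and 010, 110 (R)
  sim <- consistent_basic_relations(mk(c(9, 0, 0, 8, 7, 0, 0, 6)))
  expect_length(sim, 4)
  expect_equal(sort(vapply(sim, `[[`, integer(1), "cell")), c(1L, 2L, 5L, 6L))
  expect_equal(sort(vapply(sim, `[[`, character(1), "side")), c("L", "L", "R", "R"))

  expect_error(consistent_basic_relations(mk(integer(8))), "empty")
})

test_that("combining basics reproduces AND, similarity, and refusals", {
  # three left basics with forbidden inputs 00, 01, 10 conjoin to AND
  ands <- lapply(c(1, 3, 5), function(c0) basic_relation(c(1, 2), c0))
  rel <- combine_basics(ands, target = 3)
  expect_equal(rel$rtype, "prereq_target")
  expect_identical(bf_reduce(rel$func), boolfun(c(1, 2), c(0, 0, 0, 1)))

  # the four similarity cells give f_L = v2, f_R = !v2, hence similar
  sim <- lapply(c(1, 2, 5, 6), function(c0) basic_relation(c(1, 2), c0))
  rel2 <- combine_basics(sim, target = 3)
  expect_equal(rel2$rtype, "similar")
  expect_identical(rel2$func, boolfun(2, c(0, 1)))

  # both sides present but not dual-equivalent: no relation
  both <- list(basic_relation(c(1, 2), 1), basic_relation(c(1, 2), 2))
  # cell 1 -> L (v1|v2); cell 2 -> R with pattern 01... use a non-dual pair
  both <- list(basic_relation(c(1, 2), 1), basic_relation(c(1, 2), 4))
  expect_null(combine_basics(both, 3))

  # a conjunction collapsing to constant 0 is vacuous
  allL <- lapply(c(1, 3, 5, 7), function(c0) basic_relation(c(1, 2), c0))
  expect_null(combine_basics(allL, 3))

  expect_null(combine_basics(list(), 3))
})

test_that("exhaustive noise-free samples identify the example network exactly", {
  net <- e3()
  fit <- infer_tdbn_noiseless(exhaustive_transitions(net), 3, 2)
  expect_true(tdbn_equivalent(fit, net))
})

test_that("unregulated genes are left alone and gaps are not guessed", {
  # single free gene: all four transitions observed, no relation
  tr1 <- as_transitions(matrix(c(0, 0, 1, 1), 4, 1),
                        matrix(c(0, 1, 0, 1), 4, 1))
  fit1 <- infer_tdbn_noiseless(tr1, 1, 1)
  expect_length(fit1$relations, 0)

  # only inputs with v1 = 1: gene 1's relation is not determined, and the
  # algorithm must not invent one from one-sided evidence
  net <- e3()
  tr <- exhaustive_transitions(net)
  tm <- tdbnet:::transition_matrices(tr)
  sub <- tr[tm$X[, 1] == 1, ]
  fit <- suppressWarnings(infer_tdbn_noiseless(sub, 3, 2))
  r1 <- tdbnet:::tdbn_relation_for(fit, 1)
  if (!is.null(r1)) {
    expect_false(bf_equivalent(r1$func, boolfun(c(1, 3), c(0, 1, 1, 1))) &&
                   r1$rtype == "prereq_target")
  } else {
    succeed()
  }
})

test_that("random networks are recovered exactly from exhaustive enumeration", {
  set.seed(41)
  for (i in 1:40) {
    n <- sample(3:6, 1)
    net <- random_tdbn(n, 2, relation_prob = 0.8)
    fit <- suppressWarnings(infer_tdbn_noiseless(exhaustive_transitions(net), n, 2))
    expect_true(tdbn_equivalent(fit, net))
  }
})
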