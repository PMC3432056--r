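test_that("network construction enforces the indegree bound and uniqueness", {
  f3 <- boolfun(c(1, 2, 3), rep(c(0L, 1L), 4))
  expect_error(tdbn(3, list(tdbn_relation(1, f3)), K = 2), "indegree")
  r1 <- tdbn_relation(1, boolfun(2, c(0, 1)), "similar")
  expect_error(tdbn(3, list(r1, r1), K = 2), "one relation")
  expect_error(tdbn(2, list(tdbn_relation(3, boolfun(1, c(0, 1)))), K = 1),
               "out of range")
})

test_that("per-gene possibility sets follow the relation semantics", {
  net <- e3()
  # (v1 OR v3) off forces gene 1 off
  expect_equal(possible_outputs_gene(net, c(0, 1, 0), 1), 0L)
  # (v1 AND v3) on leaves gene 2 free
  expect_equal(sort(possible_outputs_gene(net, c(1, 0, 1), 2)), c(0L, 1L))
  # similarity pins gene 3 to v2
  expect_equal(possible_outputs_gene(net, c(1, 0, 1), 3), 0L)
  expect_equal(possible_outputs_gene(net, c(1, 1, 1), 3), 1L)
  # a prerequisite-to-dual relation forces the target ON when the function
  # is off
  netd <- tdbn(2, list(tdbn_relation(2, boolfun(1, c(0, 1)), "prereq_dual")))
  expect_equal(possible_outputs_gene(netd, c(0, 0), 2), 1L)
  expect_equal(sort(possible_outputs_gene(netd, c(1, 0), 2)), c(0L, 1L))
})

test_that("possible output sets are Cartesian products of per-gene sets", {
  net <- e3()
  out1 <- possible_outputs(net, c(0, 1, 0))
  expect_equal(nrow(out1), 1L)
  expect_equal(as.integer(out1[1, ]), c(0L, 0L, 1L))

  out2 <- possible_outputs(net, c(1, 0, 1))
  expect_equal(nrow(out2), 4L)
  expect_true(all(out2[, 3] == 0L))
  expect_equal(sort(out2[, 1] * 2 + out2[, 2]), 0:3)

  free <- tdbn(3, list())
  expect_equal(nrow(possible_outputs(free, c(1, 1, 0))), 8L)

  # sizes are always powers of two between 1 and 2^n
  set.seed(7)
  for (i in 1:10) {
    rnet <- random_tdbn(4, 2)
    x <- sample(0:1, 4, replace = TRUE)
    sz <- nrow(possible_outputs(rnet, x))
    expect_equal(sz, 2^round(log2(sz)))
    expect_true(sz >= 1 && sz <= 16)
  }
})

test_that("similarity-only networks are deterministic on regulated genes", {
  set.seed(19)
  for (i in 1:5) {
    rels <- lapply(1:4, function(t) {
      tdbn_relation(t, random_boolfun(4, 2), "similar")
    })
    net <- tdbn(4, rels, K = 2)
    for (j in 1:8) {
      x <- sample(0:1, 4, replace = TRUE)
      expect_equal(nrow(possible_outputs(net, x)), 1L)
    }
  }
})

test_that("network equivalence is semantic", {
  net <- e3()
  # same relation written over reordered inputs
  alt <- tdbn(3, list(
    tdbn_relation(1, boolfun(c(3, 1), c(0, 1, 1, 1)), "prereq_target"),
    tdbn_relation(2, boolfun(c(1, 3), c(0, 0, 0, 1)), "prereq_target"),
    tdbn_relation(3, boolfun(2, c(0, 1)), "similar")), K = 2)
  expect_true(tdbn_equivalent(net, alt))

  # a dummy input does not matter
  pad <- tdbn(3, list(
    tdbn_relation(1, boolfun(c(1, 3), c(0, 1, 1, 1)), "prereq_target"),
    tdbn_relation(2, boolfun(c(1, 3), c(0, 0, 0, 1)), "prereq_target"),
    tdbn_relation(3, boolfun(c(1, 2), c(0, 1, 0, 1)), "similar")), K = 2)
  expect_true(tdbn_equivalent(net, pad))

  # changing one relation breaks equivalence
  altf <- tdbn(3, list(
    tdbn_relation(1, boolfun(c(1, 3), c(0, 0, 0, 1)), "prereq_target"),
    tdbn_relation(2, boolfun(c(1, 3), c(0, 0, 0, 1)), "prereq_target"),
    tdbn_relation(3, boolfun(2, c(0, 1)), "similar")), K = 2)
  expect_false(tdbn_equivalent(net, altf))
  # dropping a relation breaks equivalence
  expect_false(tdbn_equivalent(net, tdbn(3, net$relations[1:2], K = 2)))
  expect_false(tdbn_equivalent(net, tdbn(3, list(), K = 2)))
})

test_that("networks round-trip through JSON", {
  set.seed(31)
  for (i in 1:5) {
    net <- random_tdbn(5, 2, relation_prob = 0.7)
    path <- withr::local_tempfile(fileext = ".json")
    write_tdbn(net, path)
    back <- read_tdbn(path)
    expect_equal(back$n, net$n)
    expect_equal(back$K, net$K)
    expect_true(tdbn_equivalent(net, back))
  }
})

test_that("exhaustive enumeration pairs every input with every possible output", {
  net <- e3()
  tr <- exhaustive_transitions(net)
  # per-input counts equal the size of the possible-output set
  tm <- tdbnet:::transition_matrices(tr)
  for (i in seq_len(nrow(tm$X))) {
    P <- possible_outputs(net, tm$X[i, ])
    hits <- apply(P, 1, function(y) all(y == tm$Y[i, ]))
    expect_equal(sum(hits), 1L)
  }
  sizes <- vapply(0:7, function(v) {
    x <- as.integer(intToBits(v))[3:1]
    nrow(possible_outputs(net, rev(as.integer(intToBits(v))[1:3])))
  }, numeric(1))
  expect_equal(nrow(tr), sum(sizes))
})
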