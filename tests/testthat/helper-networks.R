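# Shared fixtures: the three-gene example network and hand-derived facts
# about it, plus a frozen score multiset for threshold-rule tests.

e3 <- function() tdbn_example3()

# The 16 truly forbidden (zero-probability) cells of the three-gene example,
# derived by hand from the relation semantics: a cell (pattern, out) is
# forbidden when the relation forces the opposite output for every completion
# of the pattern.
e3_true_cells <- function() {
  rbind(
    data.frame(target = 1, inputs = "1,3", cell = 1),
    data.frame(target = 2, inputs = "1,2", cell = c(1, 3)),
    data.frame(target = 2, inputs = "1,3", cell = c(1, 3, 5)),
    data.frame(target = 2, inputs = "2,3", cell = c(1, 5)),
    data.frame(target = 3, inputs = "1,2", cell = c(1, 2, 5, 6)),
    data.frame(target = 3, inputs = "2,3", cell = c(1, 3, 4, 6)))
}

# Build a scored-hypothesis frame (the score_all layout) from a list of
# (target, inputs, cell, score) rows.
make_scored <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(target = r[[1]], inputs = r[[2]], cell = r[[3]],
               label = paste0("q", paste(rev((r[[3]] %/% 2^(0:2)) %% 2),
                                         collapse = "")),
               side = if (r[[3]] %% 2 == 1) "L" else "R",
               score = r[[4]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# One full 72-score multiset for the three-gene example (a reference run of
# the noisy pipeline at m = 100, p = 0.05), frozen so that threshold
# selection and assembly can be unit-tested deterministically. Column order
# within each row: hypotheses q000, q010, q100, q110, q001, q011, q101, q111
# (output-0 cells first), i.e. 0-based cells 0, 2, 4, 6, 1, 3, 5, 7.
e3_reference_scores <- function() {
  rows <- list(
    list(1, "1,2", c(0.493, 0.418, 0.273, 0.379, 0.148, 0.178, 0.372, 0.343)),
    list(1, "1,3", c(0.438, 0.147, 0.248, 0.222, 0.016, 0.245, 0.182, 0.241)),
    list(1, "2,3", c(0.318, 0.260, 0.571, 0.214, 0.189, 0.293, 0.138, 0.374)),
    list(2, "1,2", c(0.326, 0.300, 0.304, 0.297, 0.091, 0.092, 0.232, 0.209)),
    list(2, "1,3", c(0.338, 0.216, 0.349, 0.197, 0.039, 0.069, 0.038, 0.243)),
    list(2, "2,3", c(0.326, 0.253, 0.390, 0.174, 0.052, 0.141, 0.017, 0.169)),
    list(3, "1,2", c(0.211, 0.011, 0.355, 0.029, 0.040, 0.228, 0.011, 0.294)),
    list(3, "1,3", c(0.338, 0.290, 0.402, 0.734, 0.669, 0.291, 0.379, 0.360)),
    list(3, "2,3", c(0.247, 0.312, 0.030, 0.011, 0.039, 0.011, 0.283, 0.241)))
  cells <- c(0L, 2L, 4L, 6L, 1L, 3L, 5L, 7L)
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(target = r[[1]], inputs = r[[2]], cell = cells,
               label = sprintf("q%s", vapply(cells, function(cc)
                 paste(rev((cc %/% 2^(0:2)) %% 2), collapse = ""),
                 character(1))),
               side = ifelse(cells %% 2L == 1L, "L", "R"),
               score = r[[3]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Random Boolean function on up to k of the genes 1..n (fixed-seed callers).
random_boolfun <- function(n, k) {
  inputs <- sort(sample(seq_len(n), k))
  boolfun(inputs, sample(0:1, 2^k, replace = TRUE))
}
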