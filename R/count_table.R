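#' Transition count table for one target and one ordered input tuple
#'
#' Tabulates the `2^(k+1)` joint patterns of the k input bits and the target's
#' output bit over all samples. Cells are indexed by the concatenated bits
#' `(v_j, ..., v_l, v'_i)` with the first input as the most significant bit
#' and the output bit last, so for `k = 2` the cell labelled `001` is input
#' column `00`, output row 1.
#'
#' @param samples a transitions data frame.
#' @param target output gene index.
#' @param inputs ordered tuple of distinct input gene indices, length at most
#'   `k_max`.
#' @param k_max cap on the tuple length (default `getOption("tdbnet.kmax", 3)`),
#'   which keeps the `2^(k+1)`-cell tables and the tuple enumeration tractable
#'   under the bounded-indegree assumption.
#' @return an object of class `count_table` with fields `target`, `inputs`,
#'   `counts` (length `2^(k+1)`) and `N`.
#' @export
build_count_table <- function(samples, target, inputs,
                              k_max = getOption("tdbnet.kmax", 3L)) {
  tm <- transition_matrices(samples)
  inputs <- as.integer(inputs)
  target <- as.integer(target)
  k <- length(inputs)
  if (k < 1L) stop("need at least one input gene")
  if (k > k_max) stop("input tuple longer than k_max = ", k_max)
  if (anyDuplicated(inputs)) stop("duplicate input genes")
  if (any(inputs < 1L | inputs > tm$n) || target < 1L || target > tm$n) {
    stop("gene index out of range")
  }
  if (tm$n == 0L || nrow(samples) == 0L) {
    counts <- integer(2^(k + 1L))
  } else {
    cell <- as.integer(tm$X[, inputs, drop = FALSE] %*% 2^(k:1)) +
      as.integer(tm$Y[, target])
    counts <- tabulate(cell + 1L, nbins = 2^(k + 1L))
  }
  structure(list(target = target, inputs = inputs,
                 counts = as.integer(counts), N = nrow(samples)),
            class = "count_table")
}

#' Positivity pattern of a count table
#'
#' Marks each cell 1 when its count is positive and 0 otherwise; this is the
#' pattern matched against the eight basic relationships in the noiseless
#' identification algorithm.
#'
#' @param tab a [build_count_table()] result.
#' @return 0/1 integer vector of length `2^(k+1)`.
#' @export
positivity_pattern <- function(tab) {
  as.integer(tab$counts > 0L)
}

# "000", "001", ... labels for the cells of a table with b bits.
cell_labels <- function(b) {
  A <- bf_assignments(b)
  apply(A, 1L, paste, collapse = "")
}

#' @export
print.count_table <- function(x, ...) {
  k <- length(x$inputs)
  lab <- cell_labels(k + 1L)
  # counts are stored output-bit-last, so row 1 = output 0, row 2 = output 1
  m <- rbind(x$counts[seq(1L, length(x$counts), by = 2L)],
             x$counts[seq(2L, length(x$counts), by = 2L)])
  dimnames(m) <- list(c("out=0", "out=1"),
                      substr(lab[seq(1L, length(lab), by = 2L)], 1L, k))
  cat("Count table for target v", x$target, "' given (",
      paste0("v", x$inputs, collapse = ", "), "), N = ", x$N, "\n", sep = "")
  print(m)
  invisible(x)
}

#' Dump all count tables to a data frame
#'
#' One row per (target, canonical input tuple): the target, the tuple, and
#' the `2^(k+1)` cell counts. Intended for auditing a reconstruction run.
#'
#' @param samples a transitions data frame.
#' @param n number of genes (defaults to `ncol(samples)/2`).
#' @param K tuple size.
#' @return a data frame.
#' @export
count_table_dump <- function(samples, n = ncol(samples) %/% 2L, K = 2L) {
  combos <- utils::combn(n, K, simplify = FALSE)
  rows <- list()
  for (target in seq_len(n)) {
    for (combo in combos) {
      tab <- build_count_table(samples, target, combo)
      rows[[length(rows) + 1L]] <- c(list(target = target,
                                          inputs = paste(combo, collapse = ",")),
                                     as.list(tab$counts))
    }
  }
  out <- do.call(rbind.data.frame, rows)
  names(out) <- c("target", "inputs", paste0("m", cell_labels(K + 1L)))
  out
}
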