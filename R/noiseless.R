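#' Basic relationships of a count table
#'
#' For a table over k input genes there are `2^(k+1)` basic relationships,
#' one per cell: forbidding the cell with input pattern c and output bit 1
#' asserts that the OR-form function vanishing exactly at c is a prerequisite
#' for the target (`side = "L"`), while forbidding the cell with output bit 0
#' asserts the same function is a prerequisite for the dual of the target
#' (`side = "R"`). For pattern `00` the function is `v_j OR v_h`, for `01` it
#' is `v_j OR !v_h`, and so on: the literal for each input is complemented
#' exactly where the pattern bit is 1.
#'
#' @param inputs ordered input gene tuple of the table.
#' @param cell0 0-based cell index in `[0, 2^(k+1))`, output bit last.
#' @return a list with `cell`, `side` (`"L"` or `"R"`) and `func` (a
#'   [boolfun] that is 0 exactly at the forbidden input pattern).
#' @export
basic_relation <- function(inputs, cell0) {
  k <- length(inputs)
  if (cell0 < 0L || cell0 >= 2^(k + 1L)) stop("cell index out of range")
  pattern <- cell0 %/% 2L
  out <- cell0 %% 2L
  tab <- rep(1L, 2^k)
  tab[pattern + 1L] <- 0L
  list(cell = as.integer(cell0),
       side = if (out == 1L) "L" else "R",
       func = boolfun(inputs, tab))
}

#' Basic relationships consistent with a count table
#'
#' A basic relationship is consistent with the observed table when its single
#' forbidden cell has count zero. With noise-free data every true
#' relationship is consistent; spurious consistencies disappear as the sample
#' covers more input patterns.
#'
#' @param tab a [build_count_table()] result with `N > 0`.
#' @return list of [basic_relation()] entries, one per zero cell.
#' @export
consistent_basic_relations <- function(tab) {
  if (tab$N == 0L) stop("empty count table: no data to match against")
  zero <- which(tab$counts == 0L) - 1L
  lapply(zero, function(c0) basic_relation(tab$inputs, c0))
}

#' Combine basic relationships into a single relation
#'
#' All prerequisite-to-target functions (`side "L"`) are conjoined into one
#' function `f_L`, all prerequisite-to-dual functions (`side "R"`) into
#' `f_R`; the basics may come from different input tuples, in which case the
#' conjunction is taken over the union of inputs. Then:
#'
#' * only `f_L` present: `f_L` is a prerequisite for the target;
#' * only `f_R` present: `f_R` is a prerequisite for the dual of the target;
#' * both present and `dual(f_R)` equivalent to `f_L`: the two prerequisites
#'   pin the target to the function value — a similarity relation;
#' * both present but not dual-equivalent: not enough information to judge
#'   the true relationship — no relation is emitted;
#' * a conjunction that collapses to a constant is vacuous — no relation.
#'
#' @param basics list of [basic_relation()] entries.
#' @param target target gene index.
#' @return a [tdbn_relation] with reduced function, or `NULL`.
#' @export
combine_basics <- function(basics, target) {
  if (length(basics) == 0L) return(NULL)
  sides <- vapply(basics, function(b) b$side, character(1))
  fL <- fR <- NULL
  if (any(sides == "L")) {
    fL <- bf_reduce(Reduce(bf_conj, lapply(basics[sides == "L"], `[[`, "func")))
    if (length(fL$inputs) == 0L) return(NULL)  # constant conjunction: vacuous
  }
  if (any(sides == "R")) {
    fR <- bf_reduce(Reduce(bf_conj, lapply(basics[sides == "R"], `[[`, "func")))
    if (length(fR$inputs) == 0L) return(NULL)
  }
  if (is.null(fL) && is.null(fR)) return(NULL)
  if (!is.null(fL) && !is.null(fR)) {
    if (bf_equivalent(bf_dual(fR), fL)) {
      return(tdbn_relation(target, fL, "similar"))
    }
    return(NULL)
  }
  if (!is.null(fL)) tdbn_relation(target, fL, "prereq_target")
  else tdbn_relation(target, fR, "prereq_dual")
}

#' Noiseless network identification
#'
#' Exact reconstruction from noise-free transition samples. For every target
#' gene, the count tables of all canonical K-tuples of input genes are
#' matched against the basic relationships; every consistent basic relation
#' (from every tuple) is collected and combined with [combine_basics()] —
#' the per-tuple constraints are conjoined globally, so a low-order relation
#' detected through several marginal tables and a high-order relation seen
#' only in its own tuple reinforce rather than contradict each other. When
#' the sample contains every input assignment of every K-subset together
#' with all possible outputs, the reconstruction is unique and equals the
#' generating network.
#'
#' A target whose combined constraint needs more than `K` input genes
#' reflects conflicting marginal evidence from incomplete data; the target is
#' left unregulated with a warning rather than guessed.
#'
#' @param samples noise-free transitions data frame.
#' @param n number of genes (defaults to `ncol(samples)/2`).
#' @param K indegree bound / tuple size.
#' @return a [tdbn].
#' @export
infer_tdbn_noiseless <- function(samples, n = ncol(samples) %/% 2L, K = 2L) {
  n <- as.integer(n)
  K <- as.integer(K)
  if (n < K) stop("need n >= K")
  combos <- utils::combn(n, K, simplify = FALSE)
  rels <- list()
  for (target in seq_len(n)) {
    basics <- list()
    for (combo in combos) {
      tab <- build_count_table(samples, target, combo)
      basics <- c(basics, consistent_basic_relations(tab))
    }
    rel <- combine_basics(basics, target)
    if (!is.null(rel) && length(rel$func$inputs) > K) {
      warning("conflicting constraints for target v", target,
              "': combined relation needs ", length(rel$func$inputs),
              " inputs (K = ", K, "); leaving it unregulated")
      rel <- NULL
    }
    if (!is.null(rel)) rels[[length(rels) + 1L]] <- rel
  }
  tdbn(n, rels, K)
}
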