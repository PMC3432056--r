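#' Regulatory relation between a Boolean function and a target gene
#'
#' A time-delay Boolean network attaches at most one relation to each target
#' gene. Three relation types exist:
#'
#' * `"prereq_target"` — `f` is a prerequisite for the target: if `f(x) = 0`
#'   at time t the target is forced to 0 at time t+1; if `f(x) = 1` the target
#'   is free (the delayed activation may or may not have happened yet).
#' * `"prereq_dual"` — `f` is a prerequisite for the dual of the target:
#'   `f(x) = 0` forces the target to 1 at time t+1.
#' * `"similar"` — the target's next state equals `f(x)` (the classical
#'   deterministic Boolean update).
#'
#' Duals of functions are never stored as relations: a dual-function
#' prerequisite can always be rewritten as a prerequisite of another plain
#' function, so the three types above are a canonical set.
#'
#' @param target gene index of the regulated gene.
#' @param func a [boolfun] over the regulating genes.
#' @param rtype one of `"prereq_target"`, `"prereq_dual"`, `"similar"`.
#' @return an object of class `tdbn_relation`.
#' @export
tdbn_relation <- function(target, func,
                          rtype = c("prereq_target", "prereq_dual", "similar")) {
  rtype <- match.arg(rtype)
  target <- as.integer(target)
  if (length(target) != 1L || is.na(target) || target < 1L) {
    stop("target must be a single positive gene index")
  }
  if (!inherits(func, "boolfun")) stop("func must be a boolfun")
  structure(list(target = target, func = func, rtype = rtype),
            class = "tdbn_relation")
}

#' @export
format.tdbn_relation <- function(x, ...) {
  fs <- format(x$func)
  switch(x$rtype,
         prereq_target = paste0("(", fs, ") -> v", x$target, "'"),
         prereq_dual   = paste0("(", fs, ") -> dual(v", x$target, "')"),
         similar       = paste0("(", fs, ") ~ v", x$target, "'"))
}

#' @export
print.tdbn_relation <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Time-delay Boolean network
#'
#' A network of `n` binary genes in which each gene carries at most one
#' regulatory relation (see [tdbn_relation()]) with indegree bounded by `K`.
#' Genes without a relation are unregulated: their next state is free.
#' Because prerequisite relations constrain rather than determine their
#' target, one input state can have several possible output states; the
#' one-step semantics are exposed by [possible_outputs()].
#'
#' @param n number of genes.
#' @param relations list of [tdbn_relation] objects, at most one per target.
#' @param K indegree bound; every relation's function may use at most `K`
#'   input genes.
#' @return an object of class `tdbn`.
#' @examples
#' net <- tdbn_example3()
#' possible_outputs(net, c(0, 1, 0))
#' @export
tdbn <- function(n, relations = list(), K = 2L) {
  n <- as.integer(n)
  K <- as.integer(K)
  if (n < 1L) stop("n must be >= 1")
  if (K < 1L) stop("K must be >= 1")
  targets <- vapply(relations, function(r) r$target, integer(1))
  if (anyDuplicated(targets)) stop("at most one relation per target gene")
  for (r in relations) {
    if (!inherits(r, "tdbn_relation")) stop("relations must be tdbn_relation objects")
    if (r$target > n) stop("relation target out of range")
    if (any(r$func$inputs > n)) stop("relation input gene out of range")
    if (length(r$func$inputs) > K) {
      stop("relation for target ", r$target, " exceeds indegree bound K = ", K)
    }
  }
  structure(list(n = n, K = K, relations = relations), class = "tdbn")
}

# Relation attached to target i, or NULL.
tdbn_relation_for <- function(net, i) {
  for (r in net$relations) {
    if (r$target == i) return(r)
  }
  NULL
}

#' @export
print.tdbn <- function(x, ...) {
  cat("Time-delay Boolean network: ", x$n, " genes, indegree bound K = ",
      x$K, "\n", sep = "")
  if (length(x$relations) == 0L) {
    cat("  (no relations)\n")
  } else {
    for (r in x$relations) cat("  ", format(r), "\n", sep = "")
  }
  invisible(x)
}

#' Possible next-step values of one gene
#'
#' Applies the relation semantics: a `similar` relation determines the gene;
#' a prerequisite whose function is off forces the gene (to 0 for
#' `prereq_target`, to 1 for `prereq_dual`); in every other case — including
#' an unregulated gene — both values are possible.
#'
#' @param net a [tdbn].
#' @param x binary input state of length `net$n`.
#' @param i target gene index.
#' @return integer vector, either one value or `c(0, 1)`.
#' @export
possible_outputs_gene <- function(net, x, i) {
  if (length(x) != net$n) stop("state vector must have length n")
  if (i < 1L || i > net$n) stop("gene index out of range")
  rel <- tdbn_relation_for(net, i)
  if (is.null(rel)) return(c(0L, 1L))
  fx <- bf_eval(rel$func, x)
  switch(rel$rtype,
         similar       = fx,
         prereq_target = if (fx == 0L) 0L else c(0L, 1L),
         prereq_dual   = if (fx == 0L) 1L else c(0L, 1L))
}

#' All possible output states for one input state
#'
#' The Cartesian product of the per-gene possibility sets; the number of rows
#' is a power of two (2 raised to the number of free genes).
#'
#' @param net a [tdbn].
#' @param x binary input state of length `net$n`.
#' @return integer matrix with `net$n` columns, one row per possible output.
#' @export
possible_outputs <- function(net, x) {
  sets <- lapply(seq_len(net$n), function(i) possible_outputs_gene(net, x, i))
  grid <- do.call(expand.grid, c(sets, KEEP.OUT.ATTRS = FALSE))
  m <- as.matrix(grid)
  dimnames(m) <- list(NULL, paste0("v", seq_len(net$n)))
  storage.mode(m) <- "integer"
  m
}

#' Semantic equivalence of two networks
#'
#' Two networks are equivalent when every gene has the same set of possible
#' next-step values for every input assignment. The comparison is performed
#' per target over the assignments of the union of the two (reduced) input
#' supports, so it is insensitive to input ordering, dummy inputs, and any
#' syntactic difference between relations that impose identical constraints.
#'
#' @param a,b [tdbn] networks with equal `n`.
#' @return logical.
#' @export
tdbn_equivalent <- function(a, b) {
  if (!inherits(a, "tdbn") || !inherits(b, "tdbn")) stop("expected tdbn objects")
  if (a$n != b$n) return(FALSE)
  for (i in seq_len(a$n)) {
    ra <- tdbn_relation_for(a, i)
    rb <- tdbn_relation_for(b, i)
    if (is.null(ra) && is.null(rb)) next
    supp <- sort(unique(c(
      if (!is.null(ra)) bf_reduce(ra$func)$inputs,
      if (!is.null(rb)) bf_reduce(rb$func)$inputs)))
    A <- bf_assignments(length(supp))
    for (row in seq_len(nrow(A))) {
      x <- integer(a$n)
      x[supp] <- A[row, ]
      if (!identical(sort(possible_outputs_gene(a, x, i)),
                     sort(possible_outputs_gene(b, x, i)))) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' The three-gene example network
#'
#' The canonical worked example used throughout the package and its tests:
#' `(v1 OR v3)` is a prerequisite for `v1'`, `(v1 AND v3)` is a prerequisite
#' for `v2'`, and `v3'` is similar to `v2`.
#'
#' @return a [tdbn] with `n = 3`, `K = 2`.
#' @export
tdbn_example3 <- function() {
  tdbn(3L, list(
    tdbn_relation(1L, boolfun(c(1L, 3L), c(0L, 1L, 1L, 1L)), "prereq_target"),
    tdbn_relation(2L, boolfun(c(1L, 3L), c(0L, 0L, 0L, 1L)), "prereq_target"),
    tdbn_relation(3L, boolfun(2L, c(0L, 1L)), "similar")
  ), K = 2L)
}

#' Exhaustive transition enumeration
#'
#' Every input state in `{0,1}^n` paired with every one of its possible
#' output states. This is the completeness condition under which noiseless
#' identification is unique, and the natural fixture for exact-recovery
#' tests. The size grows as `2^n` times the number of free-output
#' combinations, so it is only intended for small `n`.
#'
#' @param net a [tdbn].
#' @return a transitions data frame (see [as_transitions()]).
#' @export
exhaustive_transitions <- function(net) {
  n <- net$n
  X <- bf_assignments(n)
  ins <- list()
  outs <- list()
  for (row in seq_len(nrow(X))) {
    P <- possible_outputs(net, X[row, ])
    ins[[row]] <- matrix(rep(X[row, ], each = nrow(P)), nrow(P), n)
    outs[[row]] <- P
  }
  as_transitions(do.call(rbind, ins), do.call(rbind, outs))
}
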