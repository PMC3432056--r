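#' Boolean functions as explicit truth tables
#'
#' A `boolfun` is a Boolean function over an ordered tuple of gene indices,
#' stored as its full truth table. The first listed input is the most
#' significant bit of the table index, so for inputs `(j, h)` the table is
#' ordered over assignments `00, 01, 10, 11` of `(v_j, v_h)` — the same
#' left-to-right column order used throughout the count tables.
#'
#' A function with zero inputs is a constant (table of length 1).
#'
#' @param inputs integer vector of distinct gene indices (possibly empty).
#' @param table 0/1 vector of length `2^length(inputs)`; entry `i` is the
#'   output for the assignment whose bits spell `i - 1` in binary.
#' @return an object of class `boolfun`.
#' @examples
#' f <- boolfun(c(1, 3), c(0, 1, 1, 1))  # v1 OR v3
#' bf_eval(f, c(1, 0, 0))
#' @export
boolfun <- function(inputs = integer(), table) {
  inputs <- as.integer(inputs)
  table <- as.integer(table)
  if (anyNA(inputs) || any(inputs < 1L)) {
    stop("input gene indices must be positive integers")
  }
  if (anyDuplicated(inputs)) {
    stop("duplicate input gene indices")
  }
  if (length(table) != 2^length(inputs)) {
    stop("table must have length 2^k for k = ", length(inputs), " inputs")
  }
  if (anyNA(table) || !all(table %in% c(0L, 1L))) {
    stop("table entries must be 0 or 1")
  }
  structure(list(inputs = inputs, table = table), class = "boolfun")
}

# All 2^k assignments of k bits, one row per table index, first input in the
# leftmost column (most significant bit).
bf_assignments <- function(k) {
  if (k == 0L) {
    return(matrix(integer(0), nrow = 1L, ncol = 0L))
  }
  idx <- 0:(2^k - 1)
  m <- matrix(0L, length(idx), k)
  for (j in seq_len(k)) {
    m[, j] <- as.integer((idx %/% 2^(k - j)) %% 2L)
  }
  m
}

#' Evaluate a Boolean function on a full state vector
#'
#' @param f a [boolfun].
#' @param x binary state vector long enough to index every input of `f`.
#' @return 0 or 1.
#' @export
bf_eval <- function(f, x) {
  k <- length(f$inputs)
  if (k == 0L) {
    return(f$table[1L])
  }
  bits <- as.integer(x[f$inputs])
  f$table[sum(bits * 2^((k - 1):0)) + 1L]
}

# Vectorised evaluation over rows of a state matrix (columns = genes).
bf_eval_states <- function(f, X) {
  k <- length(f$inputs)
  if (k == 0L) {
    return(rep(f$table[1L], nrow(X)))
  }
  idx <- as.integer(X[, f$inputs, drop = FALSE] %*% 2^((k - 1):0))
  f$table[idx + 1L]
}

# Evaluate f on an assignment matrix A whose columns correspond to the
# ordered gene tuple u (a superset of f's inputs).
bf_eval_assign <- function(f, A, u) {
  k <- length(f$inputs)
  if (k == 0L) {
    return(rep(f$table[1L], nrow(A)))
  }
  sub <- A[, match(f$inputs, u), drop = FALSE]
  idx <- as.integer(sub %*% 2^((k - 1):0))
  f$table[idx + 1L]
}

#' Dual (complement) of a Boolean function
#'
#' Flips every entry of the truth table; the dual of the dual is the original
#' function.
#'
#' @param f a [boolfun].
#' @return a [boolfun] over the same inputs.
#' @export
bf_dual <- function(f) {
  boolfun(f$inputs, 1L - f$table)
}

#' Conjunction of two Boolean functions
#'
#' The result is defined over the union of the two input sets (ordered by
#' gene index) and equals `f(x) AND g(x)` on every assignment.
#'
#' @param f,g [boolfun] objects; their input sets may differ.
#' @return a [boolfun] over the sorted union of inputs.
#' @export
bf_conj <- function(f, g) {
  u <- sort(unique(c(f$inputs, g$inputs)))
  A <- bf_assignments(length(u))
  boolfun(u, as.integer(bf_eval_assign(f, A, u) & bf_eval_assign(g, A, u)))
}

#' Disjunction of two Boolean functions
#'
#' Obtained by De Morgan duality from [bf_conj()].
#'
#' @param f,g [boolfun] objects.
#' @return a [boolfun] over the sorted union of inputs.
#' @export
bf_disj <- function(f, g) {
  bf_dual(bf_conj(bf_dual(f), bf_dual(g)))
}

#' Reduce a Boolean function to its essential inputs
#'
#' Removes every dummy input (a gene whose value never changes the output)
#' and reorders the surviving inputs into ascending gene index, permuting the
#' truth table accordingly. Constant functions reduce to zero inputs. Two
#' functions are equal as Boolean functions exactly when their reductions are
#' structurally identical, which is what [bf_equivalent()] checks.
#'
#' @param f a [boolfun].
#' @return the canonical reduced [boolfun].
#' @export
bf_reduce <- function(f) {
  repeat {
    k <- length(f$inputs)
    if (k == 0L) break
    A <- bf_assignments(k)
    dropped <- FALSE
    for (j in seq_len(k)) {
      lo <- which(A[, j] == 0L)
      hi <- lo + 2^(k - j)
      if (all(f$table[lo] == f$table[hi])) {
        f <- boolfun(f$inputs[-j], f$table[lo])
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  k <- length(f$inputs)
  if (k > 1L && is.unsorted(f$inputs)) {
    u <- sort(f$inputs)
    A <- bf_assignments(k)
    f <- boolfun(u, bf_eval_assign(f, A, u))
  }
  f
}

#' Test two Boolean functions for equivalence
#'
#' True when the two functions have identical reductions, i.e. the same
#' essential inputs and the same truth table over them. Dummy inputs are
#' ignored, so the constant-1 function on `(v1)` is equivalent to the
#' constant-1 function on `(v5)`.
#'
#' @param f,g [boolfun] objects.
#' @return logical.
#' @export
bf_equivalent <- function(f, g) {
  rf <- bf_reduce(f)
  rg <- bf_reduce(g)
  identical(rf$inputs, rg$inputs) && identical(rf$table, rg$table)
}

#' @export
bf_is_constant <- function(f) {
  length(bf_reduce(f)$inputs) == 0L
}

#' @export
format.boolfun <- function(x, ...) {
  k <- length(x$inputs)
  if (k == 0L) {
    return(as.character(x$table[1L]))
  }
  ones <- which(x$table == 1L)
  if (length(ones) == 0L) return("0")
  if (length(ones) == 2^k) return("1")
  A <- bf_assignments(k)
  if (length(ones) == 2^k - 1L) {
    # single zero: OR of literals complementing the forbidden pattern
    row <- which(x$table == 0L)
    lits <- ifelse(A[row, ] == 0L,
                   paste0("v", x$inputs),
                   paste0("!v", x$inputs))
    return(paste(lits, collapse = " | "))
  }
  term <- function(row) {
    lits <- ifelse(A[row, ] == 1L,
                   paste0("v", x$inputs),
                   paste0("!v", x$inputs))
    paste(lits, collapse = " & ")
  }
  terms <- vapply(ones, term, character(1))
  if (length(terms) == 1L) terms else paste0("(", terms, ")", collapse = " | ")
}

#' @export
print.boolfun <- function(x, ...) {
  k <- length(x$inputs)
  cat("Boolean function on (",
      paste0("v", x$inputs, collapse = ", "),
      "): ", format(x), "\n", sep = "")
  invisible(x)
}

# JSON-friendly representation (plain list) and its inverse.
bf_to_list <- function(f) {
  list(inputs = f$inputs, table = f$table)
}

bf_from_list <- function(x) {
  boolfun(unlist(x$inputs), unlist(x$table))
}
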