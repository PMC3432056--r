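#' Transition-sample container
#'
#' Transition samples are stored as a plain data frame with `2n` binary
#' columns: the input state `v1 ... vn` at time t followed by the output
#' state `v1_next ... vn_next` at time t+1, one row per sample.
#'
#' @param X integer matrix of input states (rows = samples).
#' @param Y integer matrix of output states, same dimensions.
#' @return a data frame of 0/1 integers.
#' @export
as_transitions <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y))) stop("input and output matrices must match in shape")
  n <- ncol(X)
  out <- as.data.frame(cbind(X, Y))
  names(out) <- c(paste0("v", seq_len(n)), paste0("v", seq_len(n), "_next"))
  for (j in seq_along(out)) out[[j]] <- as.integer(out[[j]])
  out
}

# Split a transitions data frame back into input/output matrices.
transition_matrices <- function(samples) {
  nc <- ncol(samples)
  if (nc %% 2L != 0L) stop("transitions must have 2n columns")
  n <- nc %/% 2L
  list(X = as.matrix(samples[, seq_len(n), drop = FALSE]),
       Y = as.matrix(samples[, n + seq_len(n), drop = FALSE]),
       n = n)
}

#' Simulate transition samples from a time-delay Boolean network
#'
#' Input states are drawn uniformly and independently from `{0,1}^n`. For
#' each gene the output is drawn uniformly from its possible next-step
#' values, independently across genes: a gene forced by its relation takes
#' the forced value, a free gene is on or off with equal probability.
#'
#' @param object a [tdbn].
#' @param nsim number of transition samples.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a transitions data frame with `nsim` rows.
#' @export
simulate.tdbn <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  nsim <- as.integer(nsim)
  if (is.na(nsim) || nsim < 0L) stop("nsim must be a non-negative integer")
  n <- object$n
  X <- matrix(sample(0:1, nsim * n, replace = TRUE), nsim, n)
  Y <- matrix(0L, nsim, n)
  for (i in seq_len(n)) {
    rel <- tdbn_relation_for(object, i)
    if (is.null(rel)) {
      Y[, i] <- sample(0:1, nsim, replace = TRUE)
    } else {
      fx <- bf_eval_states(rel$func, X)
      Y[, i] <- switch(rel$rtype,
        similar = fx,
        prereq_target = {
          y <- integer(nsim)
          free <- fx == 1L
          y[free] <- sample(0:1, sum(free), replace = TRUE)
          y
        },
        prereq_dual = {
          y <- rep(1L, nsim)
          free <- fx == 1L
          y[free] <- sample(0:1, sum(free), replace = TRUE)
          y
        })
    }
  }
  as_transitions(X, Y)
}

#' Corrupt transition samples with misclassification noise
#'
#' Every bit of every input and output vector is flipped independently with
#' probability `p`, emulating the measurement misclassification of binarized
#' expression arrays. The model is only identifiable for `p < 0.5`.
#'
#' @param samples a transitions data frame.
#' @param p flip probability in `[0, 0.5)`.
#' @param seed optional integer seed.
#' @return a transitions data frame of the same shape; the input is not
#'   modified.
#' @export
add_noise <- function(samples, p, seed = NULL) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p >= 0.5) {
    stop("p must lie in [0, 0.5)")
  }
  if (!is.null(seed)) set.seed(seed)
  M <- as.matrix(samples)
  if (p > 0 && length(M) > 0L) {
    flips <- matrix(stats::runif(length(M)) < p, nrow(M), ncol(M))
    M <- abs(M - flips)
  }
  out <- as.data.frame(M)
  names(out) <- names(samples)
  for (j in seq_along(out)) out[[j]] <- as.integer(out[[j]])
  rownames(out) <- NULL
  out
}

#' Sample a random time-delay Boolean network
#'
#' Each target gene independently receives a relation with probability
#' `relation_prob`. The indegree is uniform on `1..K`, the input genes are
#' sampled without replacement, the relation type is uniform over the three
#' types, and the truth table is uniform over non-constant tables.
#'
#' @param n number of genes.
#' @param K indegree bound.
#' @param relation_prob probability that a target is regulated.
#' @param seed optional integer seed.
#' @return a [tdbn].
#' @export
random_tdbn <- function(n, K, relation_prob = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  K <- as.integer(K)
  if (n < K || K < 1L) stop("need n >= K >= 1")
  rels <- list()
  for (i in seq_len(n)) {
    if (stats::runif(1) > relation_prob) next
    k <- if (K == 1L) 1L else sample(seq_len(K), 1L)
    inputs <- sort(sample(seq_len(n), k))
    repeat {
      tab <- sample(0:1, 2^k, replace = TRUE)
      if (any(tab == 0L) && any(tab == 1L)) break
    }
    rtype <- sample(c("prereq_target", "prereq_dual", "similar"), 1L)
    rels[[length(rels) + 1L]] <- tdbn_relation(i, boolfun(inputs, tab), rtype)
  }
  tdbn(n, rels, K)
}
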