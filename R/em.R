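#' EM estimation of the misclassification probability under a zero-cell
#' hypothesis
#'
#' The observed counts of a `2^(k+1)`-cell transition table are modelled as a
#' multinomial whose true cell probabilities `q` are distorted by independent
#' symmetric bit flips: the probability of observing cell `a` when the true
#' cell is `c` equals `p^d (1-p)^(b-d)` where `d` is the Hamming distance
#' between the two cell indices and `b = k + 1` is the number of bits. A
#' basic relationship corresponds to the hypothesis that one cell — the
#' forbidden cell — has true probability zero, so any observed count there
#' must be explained by flips.
#'
#' The complete data are the latent splitting counts (true cell, observed
#' cell); the EM alternates their conditional expectation
#' `m_hat[c,a] = n_a q_c p^d(c,a) (1-p)^(b-d(c,a)) / r_a`
#' with the closed-form M-step `q_c = sum_a m_hat[c,a] / N` and
#' `p = sum_{c,a} d(c,a) m_hat[c,a] / (b N)`, holding `q` at zero in the
#' forbidden cell. The observed-data log-likelihood `sum_a n_a log r_a` is
#' non-decreasing across iterations; `p` is constrained to `[0, 0.5)`, beyond
#' which the flip model is unidentifiable by symmetry.
#'
#' The maximised `p` is the p-score of the hypothesis: the smaller the flip
#' probability needed to reconcile the forbidden cell with the data, the more
#' plausible the relationship. When the forbidden cell's observed count is
#' already zero the hypothesis needs no noise at all and the score is exactly
#' 0 with `q = counts/N`.
#'
#' Two safeguards sharpen the plain EM without breaking its monotonicity.
#' EM converges linearly, so at the stopping point the `p`-updates form a
#' near-geometric sequence: the estimate is Aitken-extrapolated past the
#' stopping point, `q` is reconverged at the extrapolated `p` (a concave
#' subproblem), and the refinement is kept only when it improves the
#' likelihood. And because the joint likelihood can be multimodal — with a
#' spurious mode at the identifiability boundary — a fit landing at
#' `p >= 0.3` triggers a coarse profile-likelihood scan that restarts the
#' EM in a better interior basin when one exists.
#'
#' @param counts a [build_count_table()] result or a bare count vector of
#'   length `2^b`.
#' @param forbidden 1-based index of the cell constrained to zero.
#' @param init optional list with starting values `p` and `q`; by default
#'   `q` starts at the smoothed frequencies `(counts + 0.5)` renormalised
#'   after zeroing the forbidden cell, and `p` at 0.02 — a strictly interior
#'   start that keeps every observable cell probability positive. A
#'   degenerate user-supplied start (some observed cell given probability 0)
#'   is detected and replaced by the default with a warning.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @return an object of class `tdbn_em`: `p_hat`, `q_hat`, `loglik`,
#'   `loglik_trace`, `iterations`, `converged`, `forbidden`.
#' @export
em_fit <- function(counts, forbidden, init = NULL, tol = 1e-8,
                   max_iter = 2000L) {
  n_counts <- if (inherits(counts, "count_table")) counts$counts else as.numeric(counts)
  ncell <- length(n_counts)
  b <- as.integer(round(log2(ncell)))
  if (2^b != ncell) stop("counts length must be a power of two")
  if (any(n_counts < 0)) stop("negative counts")
  N <- sum(n_counts)
  if (N < 1) stop("empty table: the p-score is undefined for N = 0")
  forbidden <- as.integer(forbidden)
  if (forbidden < 1L || forbidden > ncell) stop("forbidden cell out of range")

  if (n_counts[forbidden] == 0) {
    q <- n_counts / N
    pos <- n_counts > 0
    ll <- sum(n_counts[pos] * log(q[pos]))
    return(structure(list(p_hat = 0, q_hat = q, loglik = ll,
                          loglik_trace = ll, iterations = 0L,
                          converged = TRUE, forbidden = forbidden),
                     class = "tdbn_em"))
  }

  D <- hamming_matrix(b)
  Didx <- D + 1L
  pos <- n_counts > 0
  default_init <- function() {
    q0 <- n_counts + 0.5
    q0[forbidden] <- 0
    list(p = 0.02, q = q0 / sum(q0))
  }

  zero <- n_counts == 0
  npos <- n_counts[pos]

  # one EM run from a given start; returns parameters and the ll trace
  run <- function(p, q, iters) {
    trace <- numeric(iters)
    ll_old <- -Inf
    converged <- FALSE
    it <- 0L
    degenerate <- FALSE
    p1 <- p2 <- NA_real_
    while (it < iters) {
      it <- it + 1L
      pow <- p^(0:b) * (1 - p)^(b:0)
      Kmat <- pow[Didx]                 # flip kernel, rows = true cells
      dim(Kmat) <- c(ncell, ncell)
      W <- q * Kmat                     # q recycles down rows
      r <- .colSums(W, ncell, ncell)
      if (any(r[pos] <= 0)) {
        degenerate <- TRUE
        break
      }
      ll <- sum(npos * log(r[pos]))
      trace[it] <- ll
      ratio <- n_counts / r             # expected-count weights per observed cell
      ratio[zero] <- 0
      p2 <- p1
      p1 <- p
      q <- as.vector(W %*% ratio) / N   # row sums of the split-count matrix
      q[forbidden] <- 0
      p <- sum((D * W) %*% ratio) / (b * N)
      p <- min(max(p, 1e-12), 0.5 - 1e-9)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    list(p = p, q = q, trace = trace[seq_len(it - degenerate)],
         iterations = it, converged = converged, degenerate = degenerate,
         p1 = p1, p2 = p2)
  }

  # reconverge q at fixed p (a concave subproblem) and report the profile
  # log-likelihood there
  inner_q <- function(p, q, iters = 300L) {
    pow <- p^(0:b) * (1 - p)^(b:0)
    Kmat <- pow[Didx]
    dim(Kmat) <- c(ncell, ncell)
    for (i in seq_len(iters)) {
      W <- q * Kmat
      r <- .colSums(W, ncell, ncell)
      ratio <- n_counts / r
      ratio[zero] <- 0
      qn <- as.vector(W %*% ratio) / N
      qn[forbidden] <- 0
      delta <- max(abs(qn - q))
      q <- qn
      if (delta < 1e-11) break
    }
    r <- .colSums(q * Kmat, ncell, ncell)
    ll <- if (any(r[pos] <= 0)) -Inf else sum(npos * log(r[pos]))
    list(q = q, ll = ll)
  }

  # profile scan: fixed-p maximisation over q is concave, so a coarse grid
  # of profile log-likelihoods locates the global basin reliably
  profile_scan <- function(grid) {
    q <- default_init()$q
    best <- list(ll = -Inf, p = NA_real_, q = NULL)
    for (p in grid) {
      fit <- inner_q(p, q, iters = 200L)
      q <- fit$q
      if (fit$ll > best$ll) best <- list(ll = fit$ll, p = p, q = q)
    }
    best
  }

  # continue a run from a better point, keeping the (monotone) trace whole
  continue_from <- function(res, p, q, ll_cur) {
    res2 <- run(p, q, max_iter)
    if (!res2$degenerate && length(res2$trace) &&
        res2$trace[length(res2$trace)] > ll_cur) {
      res2$trace <- c(res$trace, res2$trace)
      res2$iterations <- res$iterations + res2$iterations
      res2
    } else {
      res
    }
  }

  st <- if (is.null(init)) default_init() else init
  res <- run(st$p, st$q, max_iter)
  if (res$degenerate) {
    warning("degenerate starting values; restarting from the default")
    st <- default_init()
    res <- run(st$p, st$q, max_iter)
  }
  # EM converges linearly, so near the optimum the p-updates form a
  # geometric sequence: Aitken-extrapolate p past the stopping point,
  # reconverge q there, and keep the refinement when it improves the
  # likelihood
  if (res$converged && !is.na(res$p2)) {
    d1 <- res$p1 - res$p2
    d0 <- res$p - res$p1
    if (d1 != 0 && abs(d0) < abs(d1)) {
      rho <- d0 / d1
      p_ext <- min(max(res$p + d0 * rho / (1 - rho), 1e-12), 0.5 - 1e-9)
      fit <- inner_q(p_ext, res$q)
      ll_cur <- res$trace[length(res$trace)]
      if (is.finite(fit$ll) && fit$ll > ll_cur) {
        res <- continue_from(res, p_ext, fit$q, ll_cur)
      }
    }
  }
  # the joint likelihood can be multimodal, with a spurious mode at the
  # p -> 0.5 identifiability boundary; when the fit lands in that region,
  # check the profile likelihood for a better interior basin and restart
  # the EM there if one exists
  if (res$p >= 0.3) {
    sc <- profile_scan(seq(0.05, 0.475, by = 0.025))
    ll_cur <- res$trace[length(res$trace)]
    if (is.finite(sc$ll) && sc$ll > ll_cur + 1e-9) {
      res <- continue_from(res, sc$p, sc$q, ll_cur)
    }
  }
  structure(list(p_hat = res$p, q_hat = res$q,
                 loglik = res$trace[length(res$trace)],
                 loglik_trace = res$trace, iterations = res$iterations,
                 converged = res$converged, forbidden = forbidden),
            class = "tdbn_em")
}

# Pairwise Hamming distances between the 0-based indices of 2^b cells.
hamming_matrix <- function(b) {
  cache <- get0(".hamming_cache", envir = .tdbnet_env)
  key <- as.character(b)
  if (!is.null(cache[[key]])) return(cache[[key]])
  idx <- 0:(2^b - 1)
  X <- outer(idx, idx, bitwXor)
  D <- matrix(0L, length(idx), length(idx))
  for (s in 0:(b - 1L)) D <- D + bitwAnd(bitwShiftR(X, s), 1L)
  D <- matrix(as.integer(D), length(idx), length(idx))
  cache[[key]] <- D
  assign(".hamming_cache", cache, envir = .tdbnet_env)
  D
}

.tdbnet_env <- new.env(parent = emptyenv())
assign(".hamming_cache", list(), envir = .tdbnet_env)

#' @export
print.tdbn_em <- function(x, ...) {
  cat("EM fit under forbidden cell ", x$forbidden, ": p-score = ",
      signif(x$p_hat, 4), " (", x$iterations, " iterations, ",
      if (x$converged) "converged" else "not converged", ")\n", sep = "")
  invisible(x)
}

#' p-scores of all zero-cell hypotheses for one table
#'
#' Fits [em_fit()] once per cell of the count table for `target` given
#' `inputs` and returns the vector of estimated flip probabilities, one per
#' hypothesis, ordered by cell index (for `k = 2`: `q000, q001, ..., q111`).
#' The unconstrained model is never fitted — without a forbidden cell the
#' flip probability is unidentifiable (`p = 0`, `q` equal to the observed
#' frequencies is always a perfect fit).
#'
#' @param samples a transitions data frame.
#' @param target output gene index.
#' @param inputs ordered input tuple.
#' @param ... passed to [em_fit()].
#' @return named numeric vector of length `2^(k+1)`.
#' @export
p_score_table <- function(samples, target, inputs, ...) {
  tab <- build_count_table(samples, target, inputs)
  ncell <- length(tab$counts)
  scores <- vapply(seq_len(ncell),
                   function(cell) em_fit(tab, cell, ...)$p_hat,
                   numeric(1))
  names(scores) <- paste0("q", cell_labels(length(inputs) + 1L))
  scores
}
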