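# Independent profile-likelihood oracle for the misclassified-multinomial
# model: grid over the flip probability p, inner fixed-p maximisation over
# the constrained cell probabilities q (a concave subproblem), report the
# grid argmax at 1e-3 resolution. The search is two-stage — a coarse pass
# over [0, 0.499] followed by a fine pass around the coarse argmax — which
# is still an exhaustive profile grid at the stated resolution near the
# maximum. Written directly from the likelihood, independent of the
# package's joint EM update path; used to cross-check em_fit.

oracle_hamming <- function(b) {
  idx <- 0:(2^b - 1)
  outer(idx, idx, function(a, cc) {
    x <- bitwXor(a, cc)
    out <- 0L
    for (s in 0:(b - 1L)) out <- out + bitwAnd(bitwShiftR(x, s), 1L)
    out
  })
}

oracle_profile_ll <- function(p, counts, forbidden, q, D, b,
                              inner_iter = 2000L, inner_tol = 1e-12) {
  ncell <- length(counts)
  N <- sum(counts)
  pos <- counts > 0
  zero <- !pos
  Kmat <- (p^(0:b) * (1 - p)^(b:0))[D + 1L]
  dim(Kmat) <- c(ncell, ncell)
  for (i in seq_len(inner_iter)) {
    W <- q * Kmat
    r <- .colSums(W, ncell, ncell)
    if (any(r[pos] <= 0)) return(list(ll = -Inf, q = q))
    ratio <- counts / r
    ratio[zero] <- 0
    qn <- as.vector(W %*% ratio) / N
    qn[forbidden] <- 0
    delta <- max(abs(qn - q))
    q <- qn
    if (delta < inner_tol) break
  }
  r <- .colSums(q * Kmat, ncell, ncell)
  ll <- if (any(r[pos] <= 0)) -Inf else sum(counts[pos] * log(r[pos]))
  list(ll = ll, q = q)
}

oracle_profile_p <- function(counts, forbidden, step = 1e-3) {
  b <- as.integer(round(log2(length(counts))))
  D <- oracle_hamming(b)
  q0 <- counts + 0.5
  q0[forbidden] <- 0
  q0 <- q0 / sum(q0)

  scan <- function(grid, q) {
    best_ll <- -Inf
    best_p <- NA_real_
    for (p in grid) {
      fit <- oracle_profile_ll(p, counts, forbidden, q, D, b)
      q <- fit$q   # warm start along the grid
      if (fit$ll > best_ll) {
        best_ll <- fit$ll
        best_p <- p
      }
    }
    best_p
  }

  coarse <- scan(seq(0, 0.499, by = 5 * step), q0)
  fine <- seq(max(0, coarse - 5 * step), min(0.499, coarse + 5 * step),
              by = step)
  scan(fine, q0)
}
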