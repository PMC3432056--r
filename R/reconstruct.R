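#' Score every (input tuple, target, hypothesis) combination
#'
#' Runs [p_score_table()] for each target gene over every canonical K-subset
#' of input genes and stacks the results into one long data frame of scored
#' hypotheses: `C(n,K) * n * 2^(K+1)` rows with columns `target`, `inputs`
#' (comma-separated gene indices), `cell` (0-based forbidden cell), `label`
#' (e.g. `"q001"`), `side` (`"L"` for prerequisite-to-target hypotheses,
#' `"R"` for prerequisite-to-dual) and `score`.
#'
#' @param samples a transitions data frame.
#' @param n number of genes (defaults to `ncol(samples)/2`).
#' @param K input tuple size / indegree bound.
#' @param ... passed to [em_fit()].
#' @return a data frame of scored hypotheses.
#' @export
score_all <- function(samples, n = ncol(samples) %/% 2L, K = 2L, ...) {
  n <- as.integer(n)
  K <- as.integer(K)
  if (n < K) stop("need n >= K")
  combos <- utils::combn(n, K, simplify = FALSE)
  ncell <- 2^(K + 1L)
  labs <- paste0("q", cell_labels(K + 1L))
  blocks <- list()
  for (target in seq_len(n)) {
    for (combo in combos) {
      sc <- p_score_table(samples, target, combo, ...)
      blocks[[length(blocks) + 1L]] <- data.frame(
        target = target,
        inputs = paste(combo, collapse = ","),
        cell = 0:(ncell - 1L),
        label = labs,
        side = ifelse(0:(ncell - 1L) %% 2L == 1L, "L", "R"),
        score = as.numeric(sc),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

# Rebuild the basic relations implied by rows of a scored-hypothesis frame.
scored_to_basics <- function(rows) {
  lapply(seq_len(nrow(rows)), function(i) {
    inputs <- as.integer(strsplit(rows$inputs[i], ",", fixed = TRUE)[[1]])
    basic_relation(inputs, rows$cell[i])
  })
}

#' Conflict test for a set of selected hypotheses
#'
#' For each target, the selected basic relations are combined exactly as in
#' [combine_basics()]: the prerequisite-to-target functions are conjoined
#' into `f_L` and the prerequisite-to-dual functions into `f_R`, each over
#' the union of their input tuples, then reduced. The set conflicts when for
#' some target
#'
#' * the reduced support of `f_L` or `f_R` exceeds the indegree bound `K`
#'   (more genes implicated than the model allows),
#' * a conjunction collapses to a constant, or
#' * `f_L` and `f_R` coexist but are neither dual-equivalent (which would be
#'   a similarity) nor jointly satisfiable — some input would force the
#'   target to be 0 and 1 at once.
#'
#' @param selected data frame of scored hypotheses (rows of [score_all()]).
#' @param K indegree bound.
#' @return logical; attribute `"diagnosis"` holds a data frame of offending
#'   targets and reasons when conflicts exist.
#' @export
has_conflict <- function(selected, K) {
  diag <- list()
  if (nrow(selected) > 0L) {
    for (target in unique(selected$target)) {
      rows <- selected[selected$target == target, , drop = FALSE]
      basics <- scored_to_basics(rows)
      sides <- vapply(basics, `[[`, character(1), "side")
      fL <- fR <- NULL
      reason <- NULL
      if (any(sides == "L")) {
        fL <- bf_reduce(Reduce(bf_conj, lapply(basics[sides == "L"], `[[`, "func")))
      }
      if (any(sides == "R")) {
        fR <- bf_reduce(Reduce(bf_conj, lapply(basics[sides == "R"], `[[`, "func")))
      }
      for (f in list(fL, fR)) {
        if (is.null(reason) && !is.null(f)) {
          if (length(f$inputs) == 0L) reason <- "constant combined function"
          else if (length(f$inputs) > K) reason <- "combined support exceeds K"
        }
      }
      if (is.null(reason) && !is.null(fL) && !is.null(fR) &&
          !bf_equivalent(bf_dual(fR), fL)) {
        # jointly unsatisfiable when some x has f_L(x) = 0 and f_R(x) = 0
        both_off <- bf_conj(bf_dual(fL), bf_dual(fR))
        if (any(both_off$table == 1L)) reason <- "contradictory prerequisites"
      }
      if (!is.null(reason)) {
        diag[[length(diag) + 1L]] <- data.frame(target = target,
                                                reason = reason,
                                                stringsAsFactors = FALSE)
      }
    }
  }
  out <- length(diag) > 0L
  attr(out, "diagnosis") <- if (out) do.call(rbind, diag) else NULL
  out
}

#' Maximum-compatibility threshold selection
#'
#' Chooses the threshold that admits the maximum number of relationships
#' without conflicts. Candidate thresholds are the distinct p-scores
#' together with the absolute cap (default 0.5, the identifiability bound on
#' the flip probability); a candidate `t` is feasible when the selection
#' `{score < t}` is conflict-free (see [has_conflict()]), and the chosen
#' threshold is the largest feasible candidate. Selection is strict, so
#' equal scores at the threshold are excluded all-or-none.
#'
#' Feasibility is not monotone in `t`: a low-order relation casts marginal
#' shadows into several input tuples, and a partially admitted set of
#' shadows can transiently conjoin to a function on more than `K` genes that
#' collapses back once the remaining shadows (with slightly larger scores)
#' join. Maximising over all candidates, rather than stopping at the first
#' conflicting score, is therefore essential; the admitted count grows with
#' `t`, so the largest feasible candidate also admits the most
#' relationships.
#'
#' Known biology can seed the selection: hypotheses listed in `must_include`
#' (matched on `target`, `inputs`, `cell`) lower-bound the threshold, so
#' candidates not exceeding the largest of their scores are never chosen.
#'
#' @param scored data frame from [score_all()].
#' @param K indegree bound.
#' @param cap absolute threshold cap.
#' @param must_include optional data frame with columns `target`, `inputs`,
#'   `cell` naming hypotheses that must end up selected.
#' @return a list: `threshold`, `selected` (data frame), `conflict_score`
#'   (the smallest infeasible candidate above the threshold, `NA` when every
#'   candidate is feasible), `diagnosis` (conflict reasons at that
#'   candidate), and `sweep` (the feasibility trace over candidates).
#' @export
max_compatibility_threshold <- function(scored, K, cap = 0.5,
                                        must_include = NULL) {
  if (nrow(scored) == 0L) stop("no scored hypotheses to sweep")
  floor_t <- -Inf
  if (!is.null(must_include) && nrow(must_include) > 0L) {
    keys <- paste(scored$target, scored$inputs, scored$cell)
    want <- paste(must_include$target, must_include$inputs, must_include$cell)
    hit <- keys %in% want
    if (!any(hit)) stop("must_include does not match any scored hypothesis")
    floor_t <- max(scored$score[hit])
  }
  cand <- sort(unique(c(scored$score[scored$score <= cap], cap)))
  sweep_trace <- data.frame(threshold = cand, admitted = NA_integer_,
                            feasible = NA)
  feas <- rep(NA, length(cand))
  diags <- vector("list", length(cand))
  for (i in rev(seq_along(cand))) {
    t <- cand[i]
    sel <- scored[scored$score < t, , drop = FALSE]
    sweep_trace$admitted[i] <- nrow(sel)
    hc <- has_conflict(sel, K)
    feas[i] <- !as.logical(hc)
    dg <- attr(hc, "diagnosis")
    if (!is.null(dg)) diags[[i]] <- dg
    sweep_trace$feasible[i] <- feas[i]
    if (feas[i] && t > floor_t) break  # largest feasible candidate found
  }
  ok <- which(feas & cand > floor_t)
  if (length(ok) == 0L) {
    # every candidate above the must-include floor conflicts; honour the
    # seeding and take the smallest candidate above it
    warning("no conflict-free threshold above the must-include floor")
    idx <- which(cand > floor_t)
    idx <- if (length(idx)) min(idx) else length(cand)
  } else {
    idx <- max(ok)
  }
  threshold <- cand[idx]
  above <- which(!feas & cand > threshold)
  if (length(above)) {
    # the admission that creates the persistent conflict: the largest score
    # admitted by the smallest infeasible candidate above the threshold
    ci <- cand[min(above)]
    conflict_score <- max(scored$score[scored$score < ci])
    diagnosis <- diags[[min(above)]]
  } else {
    conflict_score <- NA_real_
    diagnosis <- NULL
  }
  sweep_trace <- sweep_trace[!is.na(sweep_trace$feasible), , drop = FALSE]
  list(threshold = threshold,
       selected = scored[scored$score < threshold, , drop = FALSE],
       conflict_score = conflict_score,
       diagnosis = diagnosis,
       sweep = sweep_trace)
}

#' Assemble a network from a conflict-free selection
#'
#' Combines the selected basic relations per target ([combine_basics()]
#' semantics: conjoin the prerequisite side(s), recognise dual-equivalent
#' pairs as similarity) and emits the resulting network. The selection must
#' be conflict-free; a conflicting selection is a programming error after
#' threshold selection and raises a hard error.
#'
#' @param selected data frame of selected hypotheses.
#' @param n number of genes.
#' @param K indegree bound.
#' @return a [tdbn].
#' @export
assemble_network <- function(selected, n, K = 2L) {
  hc <- has_conflict(selected, K)
  if (hc) {
    stop("selection contains conflicts: ",
         paste(attr(hc, "diagnosis")$reason, collapse = "; "))
  }
  rels <- list()
  if (nrow(selected) > 0L) {
    for (target in sort(unique(selected$target))) {
      rows <- selected[selected$target == target, , drop = FALSE]
      rel <- combine_basics(scored_to_basics(rows), target)
      if (!is.null(rel)) rels[[length(rels) + 1L]] <- rel
    }
  }
  tdbn(n, rels, K)
}

#' Fit a time-delay Boolean network to transition samples
#'
#' The main entry point of the package. For noisy data (the default) it runs
#' the full pipeline: score every zero-cell hypothesis for every (input
#' tuple, target) combination by EM ([score_all()]), choose the maximum-
#' compatibility threshold ([max_compatibility_threshold()]), and assemble
#' the selected relationships into a network ([assemble_network()]). With
#' `noiseless = TRUE` the exact pattern-matching algorithm
#' ([infer_tdbn_noiseless()]) is used instead and no scores are produced.
#'
#' @param samples a transitions data frame with `2n` binary columns.
#' @param n number of genes; defaults to `ncol(samples)/2`.
#' @param K indegree bound (input tuple size), default 2.
#' @param cap absolute threshold cap, default 0.5.
#' @param must_include optional data frame of hypotheses that must be
#'   selected (see [max_compatibility_threshold()]).
#' @param noiseless use the exact noise-free algorithm.
#' @param ... passed to [em_fit()].
#' @return an object of class `tdbn_fit` with components `network` (a
#'   [tdbn]), `scores`, `threshold`, `conflict_score`, `selected`, `sweep`,
#'   `n`, `K`, `noiseless` and `call`.
#' @examples
#' net <- tdbn_example3()
#' tr <- simulate(net, 100, seed = 1)
#' fit <- tdbn_infer(add_noise(tr, 0.05), K = 2)
#' fit
#' @export
tdbn_infer <- function(samples, n = ncol(samples) %/% 2L, K = 2L, cap = 0.5,
                       must_include = NULL, noiseless = FALSE, ...) {
  cl <- match.call()
  if (noiseless) {
    net <- infer_tdbn_noiseless(samples, n, K)
    res <- list(network = net, scores = NULL, threshold = NA_real_,
                conflict_score = NA_real_, selected = NULL, sweep = NULL,
                n = as.integer(n), K = as.integer(K), noiseless = TRUE,
                call = cl)
    return(structure(res, class = "tdbn_fit"))
  }
  scores <- score_all(samples, n, K, ...)
  thr <- max_compatibility_threshold(scores, K, cap = cap,
                                     must_include = must_include)
  net <- assemble_network(thr$selected, n, K)
  structure(list(network = net, scores = scores, threshold = thr$threshold,
                 conflict_score = thr$conflict_score,
                 selected = thr$selected, sweep = thr$sweep,
                 n = as.integer(n), K = as.integer(K), noiseless = FALSE,
                 call = cl),
            class = "tdbn_fit")
}

#' @export
print.tdbn_fit <- function(x, ...) {
  cat("Time-delay Boolean network reconstruction\n")
  if (x$noiseless) {
    cat("  method: exact (noise-free pattern matching)\n")
  } else {
    cat("  method: EM p-scores, maximum-compatibility threshold\n")
    cat("  scored hypotheses: ", nrow(x$scores),
        ";  threshold: ", signif(x$threshold, 4),
        if (is.na(x$conflict_score)) " (cap, no conflict found)" else "",
        ";  selected: ", nrow(x$selected), "\n", sep = "")
  }
  print(x$network)
  invisible(x)
}

#' @export
coef.tdbn_fit <- function(object, ...) {
  rels <- object$network$relations
  if (length(rels) == 0L) {
    return(data.frame(target = integer(0), rtype = character(0),
                      inputs = character(0), func = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    target = vapply(rels, `[[`, integer(1), "target"),
    rtype = vapply(rels, `[[`, character(1), "rtype"),
    inputs = vapply(rels, function(r) paste(r$func$inputs, collapse = ","),
                    character(1)),
    func = vapply(rels, function(r) format(r$func), character(1)),
    stringsAsFactors = FALSE)
}

#' Score matrix of a fit, one row per (input pair, target)
#'
#' Reshapes the long score frame into the familiar wide layout: rows are the
#' (input tuple, target) combinations, columns the zero-cell hypotheses.
#'
#' @param object a [tdbn_fit][tdbn_infer()].
#' @param ... unused.
#' @return an object of class `summary.tdbn_fit`.
#' @export
summary.tdbn_fit <- function(object, ...) {
  if (object$noiseless || is.null(object$scores)) {
    out <- list(table = NULL, fit = object)
  } else {
    sc <- object$scores
    labs <- unique(sc$label)
    keys <- unique(sc[, c("inputs", "target")])
    m <- matrix(NA_real_, nrow(keys), length(labs),
                dimnames = list(paste0("(", gsub(",", ",v", paste0("v", keys$inputs)),
                                       ") -> v", keys$target, "'"),
                                labs))
    for (i in seq_len(nrow(keys))) {
      rows <- sc[sc$inputs == keys$inputs[i] & sc$target == keys$target[i], ]
      m[i, rows$label] <- rows$score
    }
    out <- list(table = m, fit = object)
  }
  class(out) <- "summary.tdbn_fit"
  out
}

#' @export
print.summary.tdbn_fit <- function(x, digits = 3, ...) {
  print(x$fit)
  if (!is.null(x$table)) {
    cat("\np-scores by hypothesis:\n")
    print(round(x$table, digits))
  }
  invisible(x)
}

#' Plot a reconstructed network
#'
#' Draws the regulatory graph: solid directed arrows from inputs to target
#' for prerequisite relations (dashed when the prerequisite is to the dual),
#' undirected edges for similarity. Requires the igraph package.
#'
#' @param x a [tdbn] or [tdbn_fit][tdbn_infer()].
#' @param ... passed to `plot.igraph`.
#' @export
plot.tdbn <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("plotting requires the igraph package")
  }
  edges <- character(0)
  lty <- numeric(0)
  arrow <- character(0)
  for (r in x$relations) {
    for (j in bf_reduce(r$func)$inputs) {
      edges <- c(edges, paste0("v", j), paste0("v", r$target))
      lty <- c(lty, if (r$rtype == "prereq_dual") 2 else 1)
      arrow <- c(arrow, if (r$rtype == "similar") "-" else ">")
    }
  }
  g <- igraph::make_graph(edges, isolates = setdiff(paste0("v", seq_len(x$n)),
                                                    edges))
  igraph::plot.igraph(g, edge.lty = lty, edge.arrow.mode = arrow, ...)
  invisible(x)
}

#' @export
plot.tdbn_fit <- function(x, ...) {
  plot(x$network, ...)
}

#' Empirical identification probability
#'
#' Estimates the probability that the full pipeline recovers the generating
#' network from `m` transition samples: each trial simulates `m` samples
#' from `net`, optionally corrupts them with flip probability `p`, runs
#' [tdbn_infer()] (the exact noiseless path when `p = 0`) and checks
#' [tdbn_equivalent()] against the truth. Per-trial seeds are drawn from the
#' master seed, so calls with the same `seed` and `trials` but different `m`
#' are paired trial-by-trial — the natural design for studying how the
#' recovery probability grows with the sample size.
#'
#' @param net the generating [tdbn].
#' @param m samples per trial.
#' @param p misclassification probability.
#' @param trials number of replicates.
#' @param seed optional master seed.
#' @param K indegree bound used for inference (defaults to `net$K`).
#' @param ... passed to [tdbn_infer()].
#' @return fraction of trials with exact recovery.
#' @export
identification_probability <- function(net, m, p = 0, trials = 50,
                                       seed = NULL, K = net$K, ...) {
  if (trials < 1L) stop("trials must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  tseeds <- sample.int(.Machine$integer.max - 1L, trials)
  ok <- logical(trials)
  for (t in seq_len(trials)) {
    tr <- simulate(net, m, seed = tseeds[t])
    if (p > 0) tr <- add_noise(tr, p)
    fit <- suppressWarnings(tdbn_infer(tr, n = net$n, K = K,
                                       noiseless = (p == 0), ...))
    ok[t] <- tdbn_equivalent(fit$network, net)
  }
  mean(ok)
}
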