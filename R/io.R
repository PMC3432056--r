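#' Read and write transition samples as TSV
#'
#' The on-disk format is a tab-separated table with a header line and `2n`
#' binary columns — the time-t state `v1 ... vn` followed by the time-t+1
#' state `v1_next ... vn_next`. Reading and writing round-trip exactly.
#'
#' @param samples a transitions data frame.
#' @param file path.
#' @return `read_transitions` returns a transitions data frame;
#'   `write_transitions` returns `file` invisibly.
#' @export
write_transitions <- function(samples, file) {
  utils::write.table(samples, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_transitions
#' @export
read_transitions <- function(file) {
  out <- utils::read.table(file, header = TRUE, sep = "\t",
                           check.names = FALSE)
  if (ncol(out) %% 2L != 0L) stop("transitions file must have 2n columns")
  for (j in seq_along(out)) {
    v <- out[[j]]
    if (anyNA(v) || !all(v %in% c(0L, 1L))) {
      stop("non-binary entry in column ", names(out)[j])
    }
    out[[j]] <- as.integer(v)
  }
  out
}

#' Read and write networks as JSON
#'
#' Canonical serialization:
#' `{"n": 3, "K": 2, "relations": [{"target": 1, "rtype": "prereq_target",
#' "func": {"inputs": [1, 3], "table": [0, 1, 1, 1]}}, ...]}`.
#' A written network reads back [tdbn_equivalent()] (indeed structurally
#' identical) to the original.
#'
#' @param net a [tdbn].
#' @param file path.
#' @return `read_tdbn` returns a [tdbn]; `write_tdbn` returns `file`
#'   invisibly.
#' @export
write_tdbn <- function(net, file) {
  obj <- list(n = net$n, K = net$K,
              relations = lapply(net$relations, function(r) {
                list(target = r$target, rtype = r$rtype,
                     func = bf_to_list(r$func))
              }))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_tdbn
#' @export
read_tdbn <- function(file) {
  obj <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  rels <- lapply(obj$relations, function(r) {
    tdbn_relation(r$target, bf_from_list(r$func), r$rtype)
  })
  tdbn(obj$n, rels, obj$K)
}

#' Export a network in DOT format
#'
#' Prerequisite relations are drawn as directed arrows from each input gene
#' to the target (dashed when the prerequisite is to the dual of the
#' target); similarity relations as undirected lines (`dir=none`).
#'
#' @param net a [tdbn].
#' @param file path.
#' @return `file`, invisibly.
#' @export
write_dot <- function(net, file) {
  lines <- c("digraph tdbn {")
  for (i in seq_len(net$n)) lines <- c(lines, paste0("  v", i, ";"))
  for (r in net$relations) {
    for (j in bf_reduce(r$func)$inputs) {
      attrs <- switch(r$rtype,
                      prereq_target = "",
                      prereq_dual = " [style=dashed]",
                      similar = " [dir=none]")
      lines <- c(lines, paste0("  v", j, " -> v", r$target, attrs, ";"))
    }
  }
  lines <- c(lines, "}")
  writeLines(lines, file)
  invisible(file)
}

#' Export a network in SIF format
#'
#' One line per regulatory edge: `v<j> <relation> v<target>` with relation
#' keywords `prereq`, `prereq_dual` and `similar`.
#'
#' @param net a [tdbn].
#' @param file path.
#' @return `file`, invisibly.
#' @export
write_sif <- function(net, file) {
  lines <- character(0)
  kw <- c(prereq_target = "prereq", prereq_dual = "prereq_dual",
          similar = "similar")
  for (r in net$relations) {
    for (j in bf_reduce(r$func)$inputs) {
      lines <- c(lines, paste0("v", j, "\t", kw[[r$rtype]], "\tv", r$target))
    }
  }
  writeLines(lines, file)
  invisible(file)
}

#' Read a gene-expression matrix
#'
#' Tab-separated layout: first column gene identifiers, header row of
#' time-point labels, and optionally a second header row assigning each
#' column to an experiment (a multi-experiment time course). Columns with
#' missing values can be dropped on read, mirroring the usual filtering of
#' public expression compendia.
#'
#' @param file path.
#' @param experiment_row logical; is the second line an experiment-ID row?
#' @param drop_missing drop columns containing missing values.
#' @return a list with `values` (numeric matrix, genes x time points) and
#'   `experiments` (character vector, one entry per retained column).
#' @export
read_expression <- function(file, experiment_row = FALSE,
                            drop_missing = TRUE) {
  lines <- readLines(file)
  if (experiment_row) {
    exps <- strsplit(lines[2L], "\t", fixed = TRUE)[[1]][-1L]
    dat <- utils::read.delim(text = lines[-2L], header = TRUE,
                             row.names = 1L, check.names = FALSE)
  } else {
    dat <- utils::read.delim(text = lines, header = TRUE, row.names = 1L,
                             check.names = FALSE)
    exps <- rep("experiment1", ncol(dat))
  }
  mat <- as.matrix(dat)
  storage.mode(mat) <- "double"
  if (drop_missing) {
    keep <- colSums(is.na(mat)) == 0L
    mat <- mat[, keep, drop = FALSE]
    exps <- exps[keep]
  }
  list(values = mat, experiments = exps)
}

#' Binarize log-ratio expression values
#'
#' A gene is called on (1) at a time point when its expression log-ratio is
#' strictly positive, off (0) otherwise; an exact zero binarizes to 0.
#' Missing values are an error and are reported with their coordinates.
#'
#' @param mat numeric matrix of log-ratios, genes x time points.
#' @return integer 0/1 matrix of the same shape.
#' @export
binarize_log_ratio <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)
    stop("missing values at (row, col): ",
         paste(apply(bad, 1L, paste, collapse = ","), collapse = "; "))
  }
  out <- (mat > 0) + 0L
  storage.mode(out) <- "integer"
  out
}

#' Binarize a time course by its trend
#'
#' Each gene is called on (1) between consecutive time points when its value
#' increases, off (0) when it decreases or stays exactly constant. Trends
#' are computed within experiments only, so a course of T time points yields
#' T-1 trend columns per experiment and no bit ever spans an experiment
#' boundary. Every experiment needs at least two time points.
#'
#' @param mat numeric matrix, genes x time points.
#' @param experiments character vector assigning each column to an
#'   experiment; by default all columns belong to one experiment.
#' @return integer 0/1 matrix with one column per within-experiment
#'   transition; attribute `"experiments"` gives each column's experiment.
#' @export
binarize_trend <- function(mat, experiments = rep("experiment1", ncol(mat))) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing values; filter or impute before binarizing")
  if (length(experiments) != ncol(mat)) {
    stop("experiments must have one entry per column")
  }
  blocks <- list()
  exps_out <- character(0)
  for (e in unique(experiments)) {
    cols <- which(experiments == e)
    if (length(cols) < 2L) {
      stop("experiment ", e, " has fewer than 2 time points")
    }
    d <- mat[, cols[-1L], drop = FALSE] - mat[, cols[-length(cols)], drop = FALSE]
    blocks[[length(blocks) + 1L]] <- (d > 0) + 0L
    exps_out <- c(exps_out, rep(e, length(cols) - 1L))
  }
  out <- do.call(cbind, blocks)
  storage.mode(out) <- "integer"
  attr(out, "experiments") <- exps_out
  out
}

#' Transition samples from a binarized time course
#'
#' Pairs consecutive columns within each experiment: the state at time t is
#' the input, the state at time t+1 the output. Experiments of T1, T2, ...
#' time points yield (T1 - 1) + (T2 - 1) + ... samples and no sample ever
#' crosses an experiment boundary.
#'
#' @param bmat binary matrix, genes x time points.
#' @param experiments character vector per column; defaults to the
#'   `"experiments"` attribute of `bmat` when present, else one experiment.
#' @return a transitions data frame with `nrow(bmat)` genes.
#' @export
transitions_from_binary <- function(bmat, experiments = NULL) {
  bmat <- as.matrix(bmat)
  if (is.null(experiments)) {
    experiments <- attr(bmat, "experiments")
    if (is.null(experiments)) experiments <- rep("experiment1", ncol(bmat))
  }
  if (length(experiments) != ncol(bmat)) {
    stop("experiments must have one entry per column")
  }
  ins <- list()
  outs <- list()
  for (e in unique(experiments)) {
    cols <- which(experiments == e)
    if (length(cols) < 2L) next
    ins[[length(ins) + 1L]] <- t(bmat[, cols[-length(cols)], drop = FALSE])
    outs[[length(outs) + 1L]] <- t(bmat[, cols[-1L], drop = FALSE])
  }
  if (length(ins) == 0L) {
    return(as_transitions(matrix(integer(0), 0L, nrow(bmat)),
                          matrix(integer(0), 0L, nrow(bmat))))
  }
  as_transitions(do.call(rbind, ins), do.call(rbind, outs))
}
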