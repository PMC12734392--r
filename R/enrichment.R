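# Single-sample gene-set enrichment.
#
# Two scoring variants share a common random-walk core:
#   * kcdf-walk : per-gene kernel-CDF statistic across samples (Gaussian for
#     continuous data, Poisson for counts, or the raw ECDF), symmetric rank
#     statistic, and a tau-weighted Kolmogorov-Smirnov-like walk whose score
#     is bounded in [-1, 1].
#   * rank-walk : rank-weighted walk on raw within-sample expression ranks
#     (weight rank^alpha), optionally normalized by the global score range.

#' Enrichment parameters
#'
#' @param method `"kcdf-walk"` (kernel-CDF variant, bounded scores) or
#'   `"rank-walk"` (rank-weighted variant for sparse single-cell data).
#' @param kernel kernel for the per-gene CDF statistic: `"auto"` picks
#'   `"poisson"` when every value is a non-negative integer and
#'   `"gaussian"` otherwise; `"ecdf"` uses the raw empirical CDF.
#' @param tau weight exponent on the symmetric rank statistic (> 0).
#' @param score_mode `"maxdiff"` (sum of the most positive and most negative
#'   walk deviations) or `"absmax"` (signed deviation of largest magnitude).
#' @param alpha rank-weight exponent for the rank-walk variant (>= 0).
#' @param normalize rank-walk only: divide all scores by the global
#'   (max - min) so they are comparable across runs.
#' @return an `enrichment_params` object.
#' @export
enrichment_params <- function(method = c("kcdf-walk", "rank-walk"),
                              kernel = c("auto", "gaussian", "poisson", "ecdf"),
                              tau = 1, score_mode = c("maxdiff", "absmax"),
                              alpha = 0.25, normalize = TRUE) {
  method <- match.arg(method)
  kernel <- match.arg(kernel)
  score_mode <- match.arg(score_mode)
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) stop("`tau` must be > 0")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0) stop("`alpha` must be >= 0")
  structure(list(method = method, kernel = kernel, tau = tau,
                 score_mode = score_mode, alpha = alpha,
                 normalize = isTRUE(normalize)),
            class = "enrichment_params")
}

#' @export
print.enrichment_params <- function(x, ...) {
  cat("enrichment_params:", x$method)
  if (x$method == "kcdf-walk")
    cat(sprintf(" (kernel=%s, tau=%g, mode=%s)\n", x$kernel, x$tau, x$score_mode))
  else
    cat(sprintf(" (alpha=%g, normalize=%s)\n", x$alpha, x$normalize))
  invisible(x)
}

validate_expression <- function(expr) {
  if (inherits(expr, "sparseMatrix")) {
    vals_finite <- all(is.finite(expr@x))
  } else {
    expr <- as.matrix(expr)
    storage.mode(expr) <- "double"
    vals_finite <- all(is.finite(expr))
  }
  if (!vals_finite) stop("expression matrix contains missing or non-finite values")
  if (nrow(expr) < 2L || ncol(expr) < 1L)
    stop("expression matrix must have at least 2 genes and 1 sample")
  if (is.null(rownames(expr)) || anyDuplicated(rownames(expr)))
    stop("expression matrix needs unique, non-null gene identifiers (rownames)")
  if (is.null(colnames(expr)) || anyDuplicated(colnames(expr)))
    stop("expression matrix needs unique, non-null sample identifiers (colnames)")
  expr
}

is_count_matrix <- function(expr) {
  x <- if (inherits(expr, "sparseMatrix")) expr@x else expr
  all(x >= 0) && all(x == floor(x))
}

#' Kernel-CDF statistic per gene
#'
#' For gene i with values \eqn{x_{i1},\dots,x_{in}} across samples, computes
#' \eqn{z_{ij} = n^{-1}\sum_k K((x_{ij}-x_{ik})/h_i)} where K is the kernel
#' CDF.  The Gaussian kernel uses per-gene bandwidth \eqn{h_i = s_i/4}
#' (sample standard deviation over 4); a constant gene (\eqn{s_i = 0}) is
#' assigned the distribution-center value 0.5 for every sample.  The Poisson
#' kernel evaluates the Poisson CDF at \eqn{x_{ij}} with per-observation
#' rate \eqn{x_{ik} + 0.5} and requires non-negative integer input.  The
#' ECDF kernel is the plain empirical CDF with a `<=` comparison.
#'
#' @param expr genes x samples numeric matrix (dense or sparse; sparse input
#'   is densified row-block-wise).
#' @param kernel `"gaussian"`, `"poisson"`, `"ecdf"`, or `"auto"`.
#' @return genes x samples matrix of CDF statistics in (0, 1].
#' @export
kernel_cdf_transform <- function(expr, kernel = c("auto", "gaussian",
                                                  "poisson", "ecdf")) {
  kernel <- match.arg(kernel)
  expr <- validate_expression(expr)
  if (kernel == "auto")
    kernel <- if (is_count_matrix(expr)) "poisson" else "gaussian"
  n <- ncol(expr)
  if (kernel == "gaussian" && n < 2L)
    stop("gaussian kernel bandwidth is undefined for a single-sample matrix")
  if (kernel == "poisson" && !is_count_matrix(expr))
    stop("poisson kernel requires non-negative integer counts")
  out <- matrix(NA_real_, nrow(expr), n, dimnames = dimnames(expr))
  # row blocks keep memory bounded for sparse single-cell input
  block <- max(1L, floor(2e6 / max(n, 1L)))
  for (start in seq(1L, nrow(expr), by = block)) {
    idx <- start:min(start + block - 1L, nrow(expr))
    X <- as.matrix(expr[idx, , drop = FALSE])
    out[idx, ] <- switch(kernel,
      gaussian = t(apply(X, 1L, function(x) {
        h <- stats::sd(x) / 4
        if (h == 0) return(rep(0.5, n))
        colMeans(stats::pnorm(outer(-x, x, `+`) / h))
      })),
      poisson = t(apply(X, 1L, function(x) {
        colMeans(matrix(stats::ppois(rep(x, each = n), x + 0.5), n, n))
      })),
      ecdf = t(apply(X, 1L, function(x) {
        colMeans(outer(x, x, `<=`))
      }))
    )
  }
  out
}

#' Per-sample gene ordering and symmetric rank statistic
#'
#' Within each sample, genes are ordered by decreasing statistic; ties keep
#' input row order (stable).  With p genes and rank 1 assigned to the
#' largest statistic, the symmetric rank statistic is
#' \eqn{r_{ij} = |p/2 - \mathrm{rank}_{ij}|}, largest in the distribution
#' tails.
#'
#' @param stat genes x samples matrix of finite statistics.
#' @return list with `ordering` (p x n matrix of row indices, walk order)
#'   and `r` (p x n matrix of the symmetric rank statistic, input row order).
#' @export
sample_rank_statistic <- function(stat) {
  stat <- as.matrix(stat)
  if (!all(is.finite(stat))) stop("statistic matrix must be finite")
  p <- nrow(stat); n <- ncol(stat)
  ordering <- matrix(0L, p, n)
  r <- matrix(0, p, n)
  for (j in seq_len(n)) {
    o <- order(stat[, j], decreasing = TRUE)  # stable: ties by row order
    ordering[, j] <- o
    rk <- integer(p); rk[o] <- seq_len(p)
    r[, j] <- abs(p / 2 - rk)
  }
  dimnames(r) <- dimnames(stat)
  list(ordering = ordering, r = r)
}

#' Random-walk enrichment score for one sample and one set
#'
#' Walks the sample's genes in decreasing-statistic order.  At position l
#' the deviation is
#' \deqn{\nu(l) = \frac{\sum_{i \le l, i \in S} r_i^{\tau}}{\sum_{i \in S}
#'   r_i^{\tau}} - \frac{\#\{i \le l, i \notin S\}}{p - |S|}.}
#' `maxdiff` returns `max(nu, 0) + min(nu, 0)` (most positive plus most
#' negative deviation); `absmax` returns the signed deviation of largest
#' magnitude.  Either way the score lies in \[-1, 1\].
#'
#' @param ordering integer vector: gene row indices in walk order.
#' @param r numeric vector of rank statistics in input row order.
#' @param members logical vector in input row order flagging set membership.
#' @param tau weight exponent (> 0).
#' @param score_mode `"maxdiff"` or `"absmax"`.
#' @return scalar enrichment score.
#' @export
set_walk_score <- function(ordering, r, members, tau = 1,
                           score_mode = c("maxdiff", "absmax")) {
  score_mode <- match.arg(score_mode)
  p <- length(r)
  m <- sum(members)
  if (m == 0L) stop("empty gene set")
  if (m >= p) stop("gene set covers every gene; walk undefined")
  mem_walk <- members[ordering]
  r_walk <- r[ordering]^tau
  denom_in <- sum(r_walk[mem_walk])
  step_in <- if (denom_in > 0) cumsum(r_walk * mem_walk) / denom_in
             else cumsum(mem_walk) / m  # all-zero weights: uniform steps
  step_out <- cumsum(!mem_walk) / (p - m)
  nu <- step_in - step_out
  if (score_mode == "maxdiff") {
    max(nu, 0) + min(nu, 0)
  } else {
    nu[which.max(abs(nu))]
  }
}

rank_walk_scores <- function(expr, member_idx, alpha, normalize) {
  p <- nrow(expr); n <- ncol(expr)
  scores <- matrix(0, length(member_idx), n)
  for (j in seq_len(n)) {
    x <- as.numeric(expr[, j])
    o <- order(x, decreasing = TRUE)       # stable tie-break by row order
    w <- (p - seq_len(p) + 1)^alpha        # weight of the gene at walk pos l
    for (s in seq_along(member_idx)) {
      mem <- logical(p); mem[member_idx[[s]]] <- TRUE
      mem_walk <- mem[o]
      m <- sum(mem_walk)
      if (m >= p) stop("gene set covers every gene; walk undefined")
      step_in <- cumsum(w * mem_walk) / sum(w[mem_walk])
      step_out <- cumsum(!mem_walk) / (p - m)
      scores[s, j] <- sum(step_in - step_out)
    }
  }
  if (normalize) {
    rng <- range(scores)
    if (diff(rng) > 0) scores <- scores / diff(rng)
  }
  scores
}

#' Score gene-set activity per sample
#'
#' The main enrichment entry point: turns a genes x samples expression
#' matrix and a gene-set collection into a sets x samples activity matrix.
#' The collection is restricted to the matrix's genes first (a coverage
#' report is attached); scoring is independent across samples.
#'
#' @param expr genes x samples numeric matrix (dense, or a `Matrix` sparse
#'   matrix for single-cell counts) with unique rownames/colnames.
#' @param collection a [geneset_collection()].
#' @param params an [enrichment_params()] object.
#' @param min_size,max_size size filters applied during restriction.
#' @return sets x samples numeric matrix of class `activity_matrix` with
#'   attributes `params` (provenance) and `coverage` (restriction report).
#' @export
score_activity <- function(expr, collection, params = enrichment_params(),
                           min_size = 3L, max_size = Inf) {
  stopifnot(inherits(params, "enrichment_params"))
  expr <- validate_expression(expr)
  res <- restrict_to_matrix(collection, rownames(expr), min_size = min_size,
                            max_size = max_size)
  coll <- res$collection
  if (!length(coll)) stop("zero scorable sets")
  gene_index <- stats::setNames(seq_len(nrow(expr)), rownames(expr))
  member_idx <- lapply(coll$sets, function(g) unname(gene_index[g]))

  if (params$method == "kcdf-walk") {
    stat <- kernel_cdf_transform(expr, params$kernel)
    rs <- sample_rank_statistic(stat)
    n <- ncol(expr)
    scores <- matrix(0, length(member_idx), n)
    members <- lapply(member_idx, function(idx) {
      mem <- logical(nrow(expr)); mem[idx] <- TRUE; mem
    })
    for (j in seq_len(n)) {
      ordj <- rs$ordering[, j]; rj <- rs$r[, j]
      for (s in seq_along(members)) {
        scores[s, j] <- set_walk_score(ordj, rj, members[[s]],
                                       tau = params$tau,
                                       score_mode = params$score_mode)
      }
    }
  } else {
    scores <- rank_walk_scores(expr, member_idx, params$alpha, params$normalize)
  }
  dimnames(scores) <- list(names(coll$sets), colnames(expr))
  structure(scores, class = c("activity_matrix", class(scores)),
            params = params, coverage = res$report)
}

#' @export
print.activity_matrix <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("activity_matrix: %d sets x %d samples (%s)\n",
              nrow(x), ncol(x), if (!is.null(p)) p$method else "?"))
  y <- x; attributes(y) <- attributes(x)[c("dim", "dimnames")]
  print(utils::head(y, 6L))
  invisible(x)
}

#' Write an activity matrix as TSV
#'
#' Tab-separated, set names in the first column, values with 10 significant
#' digits so repeated runs diff cleanly.
#'
#' @param activity sets x samples matrix.
#' @param path output path.
#' @param long also write a long-format CSV (`set,sample,score`) next to
#'   `path` with extension `.long.csv`? Default FALSE.
#' @return `path`, invisibly.
#' @export
write_activity_tsv <- function(activity, path, long = FALSE) {
  df <- data.frame(set = rownames(activity),
                   signif(unclass(activity), 10),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (long) {
    lf <- data.frame(set = rep(rownames(activity), ncol(activity)),
                     sample = rep(colnames(activity), each = nrow(activity)),
                     score = signif(as.vector(activity), 10))
    utils::write.csv(lf, sub("\\.tsv$", ".long.csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' Read an activity matrix written by [write_activity_tsv()]
#' @param path TSV path with a `set` first column.
#' @return sets x samples numeric matrix.
#' @export
read_activity_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
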