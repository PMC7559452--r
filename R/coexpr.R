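#' Rank-transform one expression row
#'
#' Converts a feature's per-sample expression values to ascending ranks,
#' with tied values receiving their mean rank. Rows with fewer than three
#' samples are rejected (a rank correlation over one or two samples is
#' meaningless), as are non-finite values.
#'
#' @param values Numeric vector (one row of an expression matrix).
#' @return Numeric vector of ranks (mean rank for ties).
#' @export
rank_transform <- function(values) {
  if (length(values) < 3L) {
    stop("at least 3 samples are required for rank correlation (got ",
         length(values), ")")
  }
  if (any(!is.finite(values))) stop("non-finite expression values")
  rank(values, ties.method = "average")
}

#' Build a rank matrix (per-row ranks plus standardized embedding)
#'
#' Every row of the expression matrix is rank-transformed
#' ([rank_transform()]); the standardized embedding centers each rank row
#' and scales it to unit Euclidean norm, so that for two embedded rows
#' `a`, `b` the dot product `a . b` is exactly the Spearman correlation of
#' the original rows and the squared Euclidean distance is `2 * (1 - rho)`.
#' Rows whose values are all tied (zero rank variance) have no defined
#' correlation; they are excluded from the embedding and listed in
#' `$excluded`.
#'
#' @param expr Numeric matrix, features x samples, with rownames.
#' @return Object of class `rank_matrix`: list with `ranks` (all rows),
#'   `embedding` (rows with nonzero rank variance, centered unit-norm),
#'   `feature_ids` (rows of the embedding), `sample_ids`, `excluded`.
#' @export
rank_matrix <- function(expr) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (ncol(expr) < 3L) {
    stop("dataset rejected: fewer than 3 samples (", ncol(expr), ")")
  }
  ranks <- t(apply(expr, 1L, rank_transform))
  dimnames(ranks) <- dimnames(expr)
  centered <- ranks - rowMeans(ranks)
  norms <- sqrt(rowSums(centered^2))
  keep <- norms > 0
  emb <- centered[keep, , drop = FALSE] / norms[keep]
  structure(list(
    ranks = ranks,
    embedding = emb,
    feature_ids = rownames(expr)[keep],
    sample_ids = colnames(expr),
    excluded = rownames(expr)[!keep]
  ), class = "rank_matrix")
}

#' Correlation distance between two rank vectors
#'
#' `distance = 1 - cov(a, b) / (sd(a) * sd(b))`, i.e. one minus the Pearson
#' correlation of the rank vectors, which equals one minus the Spearman
#' correlation of the original values. Lies in [0, 2].
#'
#' @param rank_a,rank_b Rank vectors of equal length (from
#'   [rank_transform()]).
#' @return The correlation distance (scalar).
#' @export
correlation_distance <- function(rank_a, rank_b) {
  if (length(rank_a) != length(rank_b)) stop("rank vectors differ in length")
  ca <- rank_a - mean(rank_a)
  cb <- rank_b - mean(rank_b)
  na <- sqrt(sum(ca^2)); nb <- sqrt(sum(cb^2))
  if (na == 0 || nb == 0) {
    stop("correlation distance undefined: zero rank variance")
  }
  1 - sum(ca * cb) / (na * nb)
}

## ---- ball tree over the standardized rank embedding -----------------------

## Recursive construction: split on the projection onto the axis through the
## two mutually farthest points; deterministic given input row order.
.build_ball_node <- function(emb, idx, leaf_size) {
  pts <- emb[idx, , drop = FALSE]
  center <- colMeans(pts)
  d2c <- sqrt(rowSums((pts - rep(center, each = nrow(pts)))^2))
  node <- list(center = center, radius = max(d2c))
  if (length(idx) <= leaf_size) {
    node$idx <- idx
    return(node)
  }
  p1 <- which.max(d2c)
  d2p1 <- sqrt(rowSums((pts - rep(pts[p1, ], each = nrow(pts)))^2))
  p2 <- which.max(d2p1)
  axis <- pts[p2, ] - pts[p1, ]
  proj <- as.numeric(pts %*% axis)
  ord <- order(proj, idx)
  half <- ceiling(length(idx) / 2)
  node$left <- .build_ball_node(emb, idx[ord[seq_len(half)]], leaf_size)
  node$right <- .build_ball_node(emb, idx[ord[-seq_len(half)]], leaf_size)
  node
}

#' Build a ball-tree co-expression index over a rank matrix
#'
#' The index lives in the standardized rank embedding, where Euclidean
#' distance is a true metric and relates monotonically to correlation
#' distance (`d^2 = 2 * (1 - rho)`), so ball-tree pruning is exact: a
#' radius query at `d = sqrt(2 * (1 - rho_min))` returns precisely the
#' features with Spearman rho >= rho_min.
#'
#' @param ranks A `rank_matrix` (see [rank_matrix()]).
#' @param leaf_size Maximum number of features per leaf (default 5).
#' @return Object of class `coexpr_index`.
#' @export
build_coexpr_index <- function(ranks, leaf_size = 5L) {
  stopifnot(inherits(ranks, "rank_matrix"))
  n <- nrow(ranks$embedding)
  if (n < 1L) stop("no features with nonzero rank variance to index")
  root <- .build_ball_node(ranks$embedding, seq_len(n), as.integer(leaf_size))
  structure(list(
    root = root,
    embedding = ranks$embedding,
    feature_ids = ranks$feature_ids,
    sample_ids = ranks$sample_ids,
    excluded = ranks$excluded,
    leaf_size = as.integer(leaf_size)
  ), class = "coexpr_index")
}

## Exact radius search: all leaf indices whose ball can intersect the query
## ball; candidates are verified afterwards with exact dot products.
.ball_radius_search <- function(node, q, radius) {
  dist_center <- sqrt(sum((q - node$center)^2))
  if (dist_center - node$radius > radius) return(integer(0))
  if (!is.null(node$idx)) return(node$idx)
  c(.ball_radius_search(node$left, q, radius),
    .ball_radius_search(node$right, q, radius))
}

## Standardize a query rank vector into the embedding space.
.standardize_query <- function(smorf_ranks) {
  cq <- smorf_ranks - mean(smorf_ranks)
  nq <- sqrt(sum(cq^2))
  if (nq == 0) stop("query has zero rank variance; correlation undefined")
  cq / nq
}

## Shared post-processing: threshold, sort by rho descending then id
## ascending, truncate to k. Rho ties are detected at 1e-9 resolution:
## distinct Spearman values on <= ~100 samples are >= ~1e-6 apart, so this
## merges only floating-point noise and keeps the id tie-break reproducible
## across computation routes.
.hits_from_rho <- function(rho, ids, k, rho_min) {
  if (!(rho_min > -1 && rho_min <= 1)) stop("rho_min must lie in (-1, 1]")
  keep <- which(round(rho, 9) >= rho_min)
  ord <- keep[order(-round(rho[keep], 9), ids[keep])]
  ord <- utils::head(ord, k)
  data.frame(gene_id = ids[ord], rho = rho[ord], distance = 1 - rho[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Query the correlated genes of a smORF
#'
#' Returns the genes whose Spearman correlation with the query rank vector
#' is at least `rho_min`, at most `k` of them, sorted by rho descending with
#' ties (compared at 1e-9 resolution) broken by gene id ascending. The
#' tree prunes the search; surviving
#' candidates are scored by the exact dot product in the standardized
#' embedding, so results are identical to a brute-force scan.
#'
#' @param smorf_ranks Rank vector of the query smORF (same samples as the
#'   index), e.g. `rank_transform(expr_row)`.
#' @param index A `coexpr_index` from [build_coexpr_index()].
#' @param k Maximum number of hits (default 1000).
#' @param rho_min Minimum Spearman rho (default 0.5).
#' @return data.frame gene_id, rho, distance (= 1 - rho).
#' @export
query_correlated_genes <- function(smorf_ranks, index, k = 1000L,
                                   rho_min = 0.5) {
  stopifnot(inherits(index, "coexpr_index"))
  if (length(smorf_ranks) != length(index$sample_ids)) {
    stop("query length (", length(smorf_ranks),
         ") does not match the index sample count (",
         length(index$sample_ids), ")")
  }
  if (!(rho_min > -1 && rho_min <= 1)) stop("rho_min must lie in (-1, 1]")
  q <- .standardize_query(smorf_ranks)
  ## pad covers the 1e-9 rho rounding slack even as rho_min -> 1
  radius <- sqrt(max(0, 2 * (1 - rho_min)) + 1e-8) + 1e-7
  cand <- .ball_radius_search(index$root, q, radius)
  if (!length(cand)) {
    return(data.frame(gene_id = character(0), rho = numeric(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  }
  rho <- as.numeric(index$embedding[cand, , drop = FALSE] %*% q)
  .hits_from_rho(rho, index$feature_ids[cand], k, rho_min)
}

#' Correlated-gene search without the tree (pre-ranked brute force)
#'
#' Scores every indexed feature by the exact embedding dot product. Used as
#' the middle rung of the three equivalent search strategies (brute force on
#' raw values, pre-ranked brute force, pre-ranked tree).
#'
#' @param smorf_ranks Query rank vector.
#' @param ranks A `rank_matrix`.
#' @inheritParams query_correlated_genes
#' @return data.frame gene_id, rho, distance.
#' @export
correlated_genes_preranked <- function(smorf_ranks, ranks, k = 1000L,
                                       rho_min = 0.5) {
  stopifnot(inherits(ranks, "rank_matrix"))
  if (length(smorf_ranks) != length(ranks$sample_ids)) {
    stop("query length does not match the rank matrix sample count")
  }
  q <- .standardize_query(smorf_ranks)
  rho <- as.numeric(ranks$embedding %*% q)
  .hits_from_rho(rho, ranks$feature_ids, k, rho_min)
}

#' Correlated-gene search on raw values (rank-on-the-fly brute force)
#'
#' Ranks every expression row at query time and computes the Spearman
#' correlation directly via [correlation_distance()]; the slowest but most
#' transparent of the three strategies. Features with zero rank variance are
#' skipped (their correlation is undefined).
#'
#' @param smorf_values Raw (unranked) expression vector of the query.
#' @param expr Numeric matrix, features x samples.
#' @inheritParams query_correlated_genes
#' @return data.frame gene_id, rho, distance.
#' @export
correlated_genes_bruteforce <- function(smorf_values, expr, k = 1000L,
                                        rho_min = 0.5) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (length(smorf_values) != ncol(expr)) {
    stop("query length does not match the expression sample count")
  }
  qr <- rank_transform(smorf_values)
  if (length(unique(qr)) == 1L) {
    stop("query has zero rank variance; correlation undefined")
  }
  rho <- rep(NA_real_, nrow(expr))
  for (i in seq_len(nrow(expr))) {
    r <- rank_transform(expr[i, ])
    if (length(unique(r)) == 1L) next
    rho[i] <- 1 - correlation_distance(r, qr)
  }
  defined <- which(!is.na(rho))
  .hits_from_rho(rho[defined], rownames(expr)[defined], k, rho_min)
}

#' Dispatch over the three equivalent search strategies
#'
#' @param smorf_values Raw expression vector of the query smORF.
#' @param expr Expression matrix (features x samples) the search runs over.
#' @param method `"tree"` (default; pre-ranked ball tree), `"preranked"`
#'   (pre-ranked brute force) or `"bruteforce"` (rank on the fly).
#' @param index Optional prebuilt `coexpr_index` (only for
#'   `method = "tree"`; built on the fly otherwise).
#' @inheritParams query_correlated_genes
#' @param leaf_size Leaf size when an index is built on the fly.
#' @return data.frame gene_id, rho, distance.
#' @export
find_correlated_genes <- function(smorf_values, expr,
                                  method = c("tree", "preranked",
                                             "bruteforce"),
                                  k = 1000L, rho_min = 0.5, index = NULL,
                                  leaf_size = 5L) {
  method <- match.arg(method)
  if (method == "bruteforce") {
    return(correlated_genes_bruteforce(smorf_values, expr, k, rho_min))
  }
  qr <- rank_transform(smorf_values)
  if (method == "preranked") {
    return(correlated_genes_preranked(qr, rank_matrix(expr), k, rho_min))
  }
  if (is.null(index)) index <- build_coexpr_index(rank_matrix(expr), leaf_size)
  query_correlated_genes(qr, index, k, rho_min)
}
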