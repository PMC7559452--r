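#' Aggregate duplicate features by per-sample median
#'
#' Collapses rows of an expression matrix that map to the same canonical
#' identifier (e.g. several probe sets annotated to one Entrez gene) into a
#' single row holding the per-sample median. Output rows are sorted by
#' canonical id so the result is deterministic.
#'
#' @param mat Numeric matrix, features x samples, with rownames.
#' @param id_map Named character vector mapping every rowname of `mat` to
#'   its canonical feature id.
#' @return Numeric matrix with one row per canonical id.
#' @export
aggregate_duplicate_features <- function(mat, id_map) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) == 0L) return(mat)
  if (is.null(rownames(mat))) stop("matrix must have rownames")
  canonical <- id_map[rownames(mat)]
  if (anyNA(canonical)) {
    stop("id_map does not cover feature(s): ",
         paste(utils::head(rownames(mat)[is.na(canonical)], 5L),
               collapse = ", "))
  }
  ids <- sort(unique(canonical))
  out <- matrix(NA_real_, nrow = length(ids), ncol = ncol(mat),
                dimnames = list(ids, colnames(mat)))
  groups <- split(seq_len(nrow(mat)), canonical)
  for (id in ids) {
    rows <- groups[[id]]
    out[id, ] <- if (length(rows) == 1L) mat[rows, ] else
      apply(mat[rows, , drop = FALSE], 2L, stats::median)
  }
  out
}

#' Estimate smORF expression from probe-set signals and annotation weights
#'
#' A smORF annotated by probe sets with weights `w_1..w_n` and log2-scale
#' signals `RMA_1..RMA_n` gets, per sample,
#'
#'   `E = log2( f(w_1 * 2^RMA_1, ..., w_n * 2^RMA_n) )`
#'
#' where `f` is the chosen summary (median by default) and only annotations
#' with `w_i > weight_min` enter the summary. The exponentiation undoes the
#' log2 of RMA normalization so that weights scale linear signal; the result
#' is returned on the log2 scale. With an even number of surviving probe
#' sets the median interpolates (mean of the two middle values,
#' [stats::median()] convention). smORFs with no surviving annotation are
#' absent from the result and listed in `attr(, "unquantified")`.
#'
#' @param probe_signals Numeric matrix, probe sets x samples, log2 scale.
#' @param annotations data.frame with columns probe_set_id, smorf_id, weight
#'   (see [compute_weights()] / [read_annotation_tsv()]).
#' @param estimator Summary over weighted linear signals: "median"
#'   (default), "mean" or "max".
#' @param weight_min Annotations with weight <= weight_min are removed
#'   (default 0.1; the boundary weight 0.1 itself is removed).
#' @return Numeric matrix, smORFs x samples, log2 scale, rows sorted by
#'   smORF id; `attr(, "unquantified")` is a character vector of smORF ids
#'   present in `annotations` but excluded by the weight filter.
#' @export
estimate_smorf_expression <- function(probe_signals, annotations,
                                      estimator = c("median", "mean", "max"),
                                      weight_min = 0.1) {
  estimator <- match.arg(estimator)
  stopifnot(is.matrix(probe_signals), is.data.frame(annotations))
  if (any(annotations$weight < 0)) stop("negative annotation weight")
  if (any(annotations$weight > 1)) stop("annotation weight above 1")
  missing_ps <- setdiff(annotations$probe_set_id, rownames(probe_signals))
  if (length(missing_ps)) {
    stop("annotation references probe set(s) absent from the signal matrix: ",
         paste(utils::head(missing_ps, 5L), collapse = ", "))
  }
  surviving <- annotations[annotations$weight > weight_min, , drop = FALSE]
  all_smorfs <- sort(unique(annotations$smorf_id))
  kept_smorfs <- sort(unique(surviving$smorf_id))
  dropped <- setdiff(all_smorfs, kept_smorfs)
  if (length(dropped)) {
    warning(length(dropped), " smORF(s) have no annotation with weight > ",
            weight_min, " and are excluded: ",
            paste(utils::head(dropped, 5L), collapse = ", "))
  }
  summary_fun <- switch(estimator,
                        median = stats::median,
                        mean = mean,
                        max = max)
  out <- matrix(NA_real_, nrow = length(kept_smorfs),
                ncol = ncol(probe_signals),
                dimnames = list(kept_smorfs, colnames(probe_signals)))
  ann_by_smorf <- split(surviving, surviving$smorf_id)
  for (sid in kept_smorfs) {
    a <- ann_by_smorf[[sid]]
    linear <- a$weight * 2^probe_signals[a$probe_set_id, , drop = FALSE]
    out[sid, ] <- log2(apply(linear, 2L, summary_fun))
  }
  attr(out, "unquantified") <- dropped
  out
}
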