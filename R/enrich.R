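#' Background gene universe for enrichment
#'
#' The background is the intersection of the genes measurable in a dataset
#' (those annotated by its probe sets) with the union of all gene-set
#' members, so the hypergeometric urn only contains genes that could appear
#' both in the correlated list and in a term.
#'
#' @param dataset_genes Character vector of gene ids measurable in the
#'   dataset.
#' @param gene_sets Named list of character vectors (see [read_gmt()]).
#' @return Character vector: the background (size T).
#' @export
make_background <- function(dataset_genes, gene_sets) {
  if (!length(dataset_genes) || !length(gene_sets)) {
    stop("dataset genes and gene sets must both be non-empty")
  }
  bg <- intersect(dataset_genes, unique(unlist(gene_sets, use.names = FALSE)))
  if (!length(bg)) {
    stop("empty background: no dataset gene appears in any gene set")
  }
  bg
}

#' Upper hypergeometric tail for one dataset
#'
#' Probability of seeing at least `I` term members among `N` correlated
#' genes drawn without replacement from a background of `T` genes of which
#' `M` belong to the term:
#'
#'   `p = sum_{x = I..N} C(M, x) * C(T - M, N - x) / C(T, N)`
#'
#' Terms with `x > M` or `N - x > T - M` contribute zero. Evaluated through
#' [stats::phyper()] (log-gamma based, exact to full double precision).
#'
#' @param I Correlated genes inside the term.
#' @param M Term genes in the background.
#' @param N Correlated genes in the background.
#' @param T_ Background size.
#' @return The tail probability in (0, 1].
#' @export
hypergeom_tail <- function(I, M, N, T_) {
  vals <- c(I = I, M = M, N = N, T = T_)
  if (any(vals != round(vals)) || any(vals < 0)) {
    stop("hypergeometric counts must be non-negative integers")
  }
  if (I > min(M, N) || M > T_ || N > T_) {
    stop("invalid hypergeometric counts: need I <= min(M, N), M <= T, N <= T")
  }
  stats::phyper(I - 1, M, T_ - M, N, lower.tail = FALSE)
}

#' Pooled hypergeometric tail across datasets
#'
#' The multi-dataset p-value is the same upper tail evaluated on the
#' component-wise sums of the per-dataset counts: sum(I), sum(M), sum(N),
#' sum(T). With a single dataset it reduces to that dataset's p.
#'
#' @param counts data.frame with integer columns `I`, `M`, `N`, `T` (one row
#'   per dataset).
#' @return Pooled tail probability.
#' @export
pooled_p <- function(counts) {
  stopifnot(is.data.frame(counts))
  if (nrow(counts) == 0L) stop("pooled_p needs at least one dataset")
  need <- c("I", "M", "N", "T")
  if (!all(need %in% colnames(counts))) {
    stop("counts must have columns ", paste(need, collapse = ", "))
  }
  hypergeom_tail(sum(counts$I), sum(counts$M), sum(counts$N), sum(counts$T))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment: sort ascending, multiply by m/i, enforce
#' monotonicity from the largest p down, cap at 1, return in input order.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Infer the collection of MSigDB-style term ids
#'
#' Recognizes the GOBP_/GOCC_/GOMF_/KEGG_/REACTOME_ prefixes; anything else
#' is `custom`.
#'
#' @param term_ids Character vector.
#' @return Character vector of collection labels.
#' @export
gene_set_collections <- function(term_ids) {
  out <- rep("custom", length(term_ids))
  out[startsWith(term_ids, "GOBP_")] <- "GO-BP"
  out[startsWith(term_ids, "GOCC_")] <- "GO-CC"
  out[startsWith(term_ids, "GOMF_")] <- "GO-MF"
  out[startsWith(term_ids, "KEGG_")] <- "KEGG"
  out[startsWith(term_ids, "REACTOME_")] <- "REACTOME"
  out
}

#' Predict smORF functions by pooled co-expression enrichment
#'
#' For every dataset in which the smORF was quantified, the smORF's
#' correlated genes (Spearman rho >= `rho_min`, at most `k`) are intersected
#' with the dataset background, per-term hypergeometric tails are computed,
#' and the per-dataset counts are pooled by summation into a single tail
#' per term. FDR is controlled by Benjamini-Hochberg, by default within
#' each collection; terms with pooled `p <= p_max` and `FDR <= fdr_max` are
#' flagged as predicted functions.
#'
#' Terms with no member in a dataset's background are skipped for that
#' dataset (they contribute nothing to the pooled sums); datasets in which
#' the smORF is not quantified contribute nothing either.
#'
#' @param smorf_id Identifier of the query smORF.
#' @param datasets Named list; each element a list with `gene_expr` (genes x
#'   samples matrix), `smorf_expr` (smORFs x samples matrix), optional
#'   `background` (defaults to [make_background()] over the gene rows) and
#'   optional prebuilt `index` (a `coexpr_index` over `gene_expr`).
#' @param gene_sets Named list of member vectors (see [read_gmt()]).
#' @param k,rho_min Correlated-gene search parameters (defaults 1000, 0.5).
#' @param p_max,fdr_max Selection thresholds (defaults 0.05, 0.2).
#' @param fdr_family `"collection"` (default) adjusts within each
#'   collection; `"all"` adjusts across every tested term jointly.
#' @param method Search strategy passed to [find_correlated_genes()].
#' @param leaf_size Ball-tree leaf size when indexes are built on the fly.
#' @return data.frame term_id, collection, I_sum, M_sum, N_sum, T_sum, p,
#'   fdr, selected, sorted by pooled p; per-dataset counts in
#'   `attr(, "per_dataset")`, the datasets actually used in
#'   `attr(, "datasets_used")`, and `attr(, "status")` equal to `"ok"` or
#'   `"unquantifiable"` (smORF absent from every dataset; empty result).
#' @export
predict_functions <- function(smorf_id, datasets, gene_sets,
                              k = 1000L, rho_min = 0.5,
                              p_max = 0.05, fdr_max = 0.2,
                              fdr_family = c("collection", "all"),
                              method = c("tree", "preranked", "bruteforce"),
                              leaf_size = 5L) {
  fdr_family <- match.arg(fdr_family)
  method <- match.arg(method)
  stopifnot(is.list(datasets), length(datasets) > 0L,
            is.list(gene_sets), !is.null(names(gene_sets)))
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("dataset", seq_along(datasets))
  }

  detail <- list()
  used <- character(0)
  for (ds_id in names(datasets)) {
    ds <- datasets[[ds_id]]
    if (!smorf_id %in% rownames(ds$smorf_expr)) next
    used <- c(used, ds_id)
    background <- if (!is.null(ds$background)) ds$background else
      make_background(rownames(ds$gene_expr), gene_sets)
    hits <- find_correlated_genes(ds$smorf_expr[smorf_id, ], ds$gene_expr,
                                  method = method, k = k, rho_min = rho_min,
                                  index = ds$index, leaf_size = leaf_size)
    correlated <- intersect(hits$gene_id, background)
    N <- length(correlated)
    T_ <- length(background)
    for (term in names(gene_sets)) {
      members_bg <- intersect(gene_sets[[term]], background)
      M <- length(members_bg)
      if (M == 0L) next                      # term untestable in this dataset
      I <- length(intersect(correlated, members_bg))
      detail[[length(detail) + 1L]] <- data.frame(
        dataset_id = ds_id, term_id = term,
        I = I, M = M, N = N, T = T_,
        p = hypergeom_tail(I, M, N, T_),
        stringsAsFactors = FALSE
      )
    }
  }

  empty <- data.frame(term_id = character(0), collection = character(0),
                      I_sum = integer(0), M_sum = integer(0),
                      N_sum = integer(0), T_sum = integer(0),
                      p = numeric(0), fdr = numeric(0), selected = logical(0),
                      stringsAsFactors = FALSE)
  if (!length(used)) {
    attr(empty, "status") <- "unquantifiable"
    attr(empty, "datasets_used") <- character(0)
    return(empty)
  }
  if (!length(detail)) {
    attr(empty, "status") <- "ok"
    attr(empty, "datasets_used") <- used
    return(empty)
  }
  detail <- do.call(rbind, detail)

  terms <- sort(unique(detail$term_id))
  by_term <- split(detail, detail$term_id)
  res <- do.call(rbind, lapply(terms, function(tm) {
    d <- by_term[[tm]]
    data.frame(term_id = tm,
               collection = gene_set_collections(tm),
               I_sum = sum(d$I), M_sum = sum(d$M),
               N_sum = sum(d$N), T_sum = sum(d$T),
               p = pooled_p(d),
               stringsAsFactors = FALSE)
  }))
  res$fdr <- NA_real_
  if (fdr_family == "all") {
    res$fdr <- bh_fdr(res$p)
  } else {
    for (coll in unique(res$collection)) {
      sel <- res$collection == coll
      res$fdr[sel] <- bh_fdr(res$p[sel])
    }
  }
  res$selected <- res$p <= p_max & res$fdr <= fdr_max
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "per_dataset") <- detail
  attr(res, "datasets_used") <- used
  attr(res, "status") <- "ok"
  res
}
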