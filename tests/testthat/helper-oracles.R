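# Independent oracles used to cross-check the implementation.

# Naive O(genome x probe) sliding-window scan over both strands; the
# reference for exact probe matching. 0-based half-open coordinates.
naive_probe_scan <- function(sequence, genome_strings) {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  out <- list()
  # a self-complementary probe has one occurrence, reported on "+"
  strands <- if (revcomp(sequence) == sequence) "+" else c("+", "-")
  for (chrom in names(genome_strings)) {
    g <- genome_strings[[chrom]]
    L <- nchar(g); w <- nchar(sequence)
    if (w > L) next
    for (i in seq_len(L - w + 1L)) {
      window <- substr(g, i, i + w - 1L)
      for (strand in strands) {
        pat <- if (strand == "+") sequence else revcomp(sequence)
        if (window == pat) {
          out[[length(out) + 1L]] <- data.frame(
            chrom = chrom, start = i - 1L, end = i + w - 1L, strand = strand,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  m <- do.call(rbind, out)
  m[order(m$chrom, m$start, m$strand), , drop = FALSE]
}

# Exhaustive hypergeometric tail: enumerate every N-subset of a T-element
# urn whose first M elements are the term, count draws with >= I term
# members. Feasible for T <= 12.
enum_hyper_tail <- function(I, M, N, T_) {
  if (N == 0L) return(if (I == 0L) 1 else 0)
  draws <- utils::combn(T_, N)
  hits <- colSums(draws <= M)        # elements 1..M are the term
  mean(hits >= I)
}

# Hand step-up BH adjustment, independent of stats::p.adjust.
manual_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(ord)]
}

# Brute-force Spearman correlated-gene search through stats::cor, applying
# the package's documented threshold and tie-break. The oracle for every
# search strategy.
oracle_correlated <- function(smorf_values, expr, k = 1000L, rho_min = 0.5) {
  rho <- suppressWarnings(
    as.numeric(stats::cor(smorf_values, t(expr), method = "spearman")))
  ok <- which(!is.na(rho) & round(rho, 9) >= rho_min)
  ids <- rownames(expr)[ok]
  ord <- order(-round(rho[ok], 9), ids)   # the package's documented tie-break
  ord <- utils::head(ord, k)
  data.frame(gene_id = ids[ord], rho = rho[ok][ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

# Small labelled expression matrix with optional forced ties.
random_expr <- function(n_feat, n_samp, tie = FALSE) {
  m <- matrix(rnorm(n_feat * n_samp), n_feat, n_samp,
              dimnames = list(sprintf("g%04d", seq_len(n_feat)),
                              sprintf("s%03d", seq_len(n_samp))))
  if (tie) {
    idx <- sample(length(m), floor(0.3 * length(m)))
    m[idx] <- round(m[idx], 1)
  }
  m
}

# Write a tiny genome FASTA and return its path (in the session tempdir).
write_tiny_genome <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n),
                                                      seqs[[n]]))), path)
  path
}

# Minimal probe table data.frame.
probe_df <- function(sequences, set_id = "ps1") {
  data.frame(probe_set_id = set_id,
             probe_id = sprintf("%s_p%02d", set_id, seq_along(sequences)),
             sequence = sequences, stringsAsFactors = FALSE)
}

# GRanges of smORFs from 0-based half-open coordinates.
smorf_granges <- function(chrom, start0, end0, ids, strand = "+") {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1L,
                                                end = end0),
                               strand = strand)
  names(gr) <- ids
  gr$name <- ids
  gr
}

# Assemble predict_functions() input from a simulate_expression() result.
sim_to_datasets <- function(sim, estimator = "median", weight_min = 0.1) {
  id_map <- stats::setNames(sim$probeset_gene_map$gene_id,
                            sim$probeset_gene_map$probe_set_id)
  lapply(sim$datasets, function(m) {
    gene_rows <- intersect(rownames(m), names(id_map))
    ge <- aggregate_duplicate_features(m[gene_rows, , drop = FALSE],
                                       id_map[gene_rows])
    se <- suppressWarnings(
      estimate_smorf_expression(m, sim$annotations, estimator = estimator,
                                weight_min = weight_min))
    list(gene_expr = ge, smorf_expr = se)
  })
}
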