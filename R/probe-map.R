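#' Exactly match probe sequences against a reference genome
#'
#' Each probe sequence is matched with zero mismatches against both strands
#' of the genome: forward-strand hits are exact occurrences of the sequence
#' itself, minus-strand hits are exact occurrences of its reverse complement
#' (reported in forward-strand coordinates with strand `-`). A probe is
#' retained for downstream annotation iff it matched at least once and has
#' fewer than `max_hits` matches in total; a probe with `max_hits` or more
#' matches is treated as unmappable. Probes containing characters outside
#' A/C/G/T are rejected with a diagnostic and treated as unmatched.
#'
#' Coordinates are 0-based half-open (BED convention) throughout, so each
#' match interval has `end - start == nchar(sequence)`.
#'
#' @param probes data.frame with columns probe_set_id, probe_id, sequence
#'   (see [read_probe_table()]).
#' @param genome A [Biostrings::DNAStringSet] (see [read_genome_fasta()]).
#' @param max_hits Probes with at least this many matches are dropped
#'   (default 100, i.e. fewer than 100 matches are retained).
#' @return A list with:
#'   \describe{
#'     \item{matches}{data.frame probe_set_id, probe_id, chrom, start, end,
#'       strand for every match of every retained probe, ordered by probe
#'       then (chrom, start, strand).}
#'     \item{probes}{data.frame probe_set_id, probe_id, n_matches, retained,
#'       reason (empty string when retained).}
#'   }
#' @export
match_probes <- function(probes, genome, max_hits = 100L) {
  stopifnot(is.data.frame(probes),
            all(c("probe_set_id", "probe_id", "sequence") %in% colnames(probes)),
            methods::is(genome, "DNAStringSet"))
  n <- nrow(probes)
  per_probe <- data.frame(
    probe_set_id = probes$probe_set_id,
    probe_id = probes$probe_id,
    n_matches = integer(n),
    retained = logical(n),
    reason = character(n),
    stringsAsFactors = FALSE
  )
  match_list <- vector("list", n)
  chrom_names <- names(genome)
  for (i in seq_len(n)) {
    seq_i <- probes$sequence[i]
    if (grepl("[^ACGT]", seq_i)) {
      per_probe$reason[i] <- "non-ACGT characters"
      next
    }
    pat <- Biostrings::DNAString(seq_i)
    rc <- Biostrings::reverseComplement(pat)
    fwd <- Biostrings::vmatchPattern(pat, genome)
    ## a self-complementary probe has a single occurrence, not one per strand
    strands <- if (as.character(rc) == seq_i) "+" else c("+", "-")
    rows <- list()
    for (strand_sym in strands) {
      hits <- if (strand_sym == "+") fwd else
        Biostrings::vmatchPattern(rc, genome)
      counts <- S4Vectors::elementNROWS(hits)
      idx <- which(counts > 0L)
      for (ci in idx) {
        r <- hits[[ci]]
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom_names[ci],
          start = BiocGenerics::start(r) - 1L,   # to 0-based half-open
          end = BiocGenerics::end(r),
          strand = strand_sym,
          stringsAsFactors = FALSE
        )
      }
    }
    if (length(rows)) {
      m <- do.call(rbind, rows)
      m <- m[order(m$chrom, m$start, m$strand), , drop = FALSE]
      per_probe$n_matches[i] <- nrow(m)
      if (nrow(m) < max_hits) {
        per_probe$retained[i] <- TRUE
        match_list[[i]] <- data.frame(
          probe_set_id = probes$probe_set_id[i],
          probe_id = probes$probe_id[i],
          m, stringsAsFactors = FALSE
        )
      } else {
        per_probe$reason[i] <- sprintf(">=%d matches", max_hits)
      }
    } else {
      per_probe$reason[i] <- "no exact match"
    }
  }
  matches <- do.call(rbind, match_list[!vapply(match_list, is.null, TRUE)])
  if (is.null(matches)) {
    matches <- data.frame(probe_set_id = character(0), probe_id = character(0),
                          chrom = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          stringsAsFactors = FALSE)
  }
  rownames(matches) <- NULL
  list(matches = matches, probes = per_probe)
}

#' Intersect retained probe matches with smORF intervals
#'
#' A probe overlaps a smORF iff any of its genomic matches shares at least
#' one base with the smORF interval; the comparison ignores strand. A probe
#' with several matches inside the same smORF still counts once for that
#' smORF. Returns per (probe set, smORF) the number of distinct overlapping
#' probes.
#'
#' @param matches data.frame of retained probe matches as produced by
#'   [match_probes()] (`$matches`).
#' @param smorfs [GenomicRanges::GRanges] of smORF intervals with smORF ids
#'   as names (see [read_smorf_bed()]).
#' @return data.frame probe_set_id, smorf_id, n_overlapping (distinct probes).
#' @export
intersect_with_smorfs <- function(matches, smorfs) {
  empty <- data.frame(probe_set_id = character(0), smorf_id = character(0),
                      n_overlapping = integer(0), stringsAsFactors = FALSE)
  if (length(smorfs) == 0L || nrow(matches) == 0L) return(empty)
  probe_gr <- GenomicRanges::GRanges(
    seqnames = matches$chrom,
    ranges = IRanges::IRanges(start = matches$start + 1L, end = matches$end),
    strand = "*"
  )
  smorf_gr <- smorfs
  GenomicRanges::strand(smorf_gr) <- "*"
  ov <- suppressWarnings(GenomicRanges::findOverlaps(
    probe_gr, smorf_gr, minoverlap = 1L, ignore.strand = TRUE))
  if (length(ov) == 0L) return(empty)
  pairs <- unique(data.frame(
    probe_set_id = matches$probe_set_id[S4Vectors::queryHits(ov)],
    probe_id = matches$probe_id[S4Vectors::queryHits(ov)],
    smorf_id = names(smorfs)[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE
  ))
  agg <- stats::aggregate(probe_id ~ probe_set_id + smorf_id, data = pairs,
                          FUN = function(x) length(unique(x)))
  names(agg)[3L] <- "n_overlapping"
  agg <- agg[order(agg$probe_set_id, agg$smorf_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Compute probe-set to smORF annotation weights
#'
#' The weight of a (probe set, smORF) link is the fraction of the probe
#' set's retained probes whose matches overlap the smORF. Weights therefore
#' lie in (0, 1]. All links with a positive count are reported here,
#' including those at or below the downstream quantification threshold
#' (`weight_min`, default 0.1), which are flagged in `below_threshold` so
#' that the filter lives in a single place ([estimate_smorf_expression()]).
#'
#' @param counts data.frame from [intersect_with_smorfs()].
#' @param retained_per_set Named integer vector: retained probe count per
#'   probe set id (the weight denominator). With
#'   `denominator = "all"` pass total probe counts per set instead.
#' @param weight_min Threshold used to flag sub-threshold weights
#'   (annotations with weight <= weight_min are removed at quantification).
#' @return data.frame probe_set_id, smorf_id, weight, below_threshold,
#'   sorted by probe_set_id then smorf_id.
#' @export
compute_weights <- function(counts, retained_per_set, weight_min = 0.1) {
  if (nrow(counts) == 0L) {
    return(data.frame(probe_set_id = character(0), smorf_id = character(0),
                      weight = numeric(0), below_threshold = logical(0),
                      stringsAsFactors = FALSE))
  }
  denom <- retained_per_set[counts$probe_set_id]
  if (anyNA(denom) || any(denom <= 0L)) {
    stop("missing or non-positive retained-probe count for probe set(s): ",
         paste(unique(counts$probe_set_id[is.na(denom) | denom <= 0]),
               collapse = ", "))
  }
  if (any(counts$n_overlapping > denom)) {
    stop("internal consistency failure: overlap count exceeds probe count ",
         "for probe set ",
         counts$probe_set_id[which(counts$n_overlapping > denom)[1L]])
  }
  out <- data.frame(
    probe_set_id = counts$probe_set_id,
    smorf_id = counts$smorf_id,
    weight = as.numeric(counts$n_overlapping) / as.numeric(denom),
    stringsAsFactors = FALSE
  )
  out$below_threshold <- out$weight <= weight_min
  out <- out[order(out$probe_set_id, out$smorf_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate probe sets to smORFs (full reannotation stage)
#'
#' Convenience wrapper chaining [match_probes()], [intersect_with_smorfs()]
#' and [compute_weights()].
#'
#' @inheritParams match_probes
#' @inheritParams intersect_with_smorfs
#' @inheritParams compute_weights
#' @param denominator `"retained"` (default) divides by the probes of the
#'   set surviving the exact-match/<`max_hits` filter; `"all"` divides by
#'   all probes originally in the set.
#' @return The annotation data.frame of [compute_weights()], with the
#'   per-probe match report in `attr(, "probe_report")`.
#' @export
annotate_probesets <- function(probes, genome, smorfs, max_hits = 100L,
                               weight_min = 0.1,
                               denominator = c("retained", "all")) {
  denominator <- match.arg(denominator)
  aligned <- match_probes(probes, genome, max_hits = max_hits)
  counts <- intersect_with_smorfs(aligned$matches, smorfs)
  if (denominator == "retained") {
    per_set <- table(aligned$probes$probe_set_id[aligned$probes$retained])
  } else {
    per_set <- table(probes$probe_set_id)
  }
  denom <- stats::setNames(as.integer(per_set), names(per_set))
  ann <- compute_weights(counts, denom, weight_min = weight_min)
  attr(ann, "probe_report") <- aligned$probes
  ann
}
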