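#' Read a tab-separated expression matrix
#'
#' Expression matrices are stored as TSV with the feature identifier in the
#' first column and one column per sample. Values are log2-scale signals
#' (RMA-level for probe sets, estimated expression for smORFs).
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, features in rows (rownames), samples in columns
#'   (colnames).
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("expression TSV must have a feature-id column plus >=1 sample column: ",
         path)
  }
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate feature ids in ", path,
         "; aggregate duplicates before loading")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (any(!is.finite(m))) stop("non-finite values in expression matrix: ", path)
  m
}

#' Write an expression matrix as TSV
#'
#' @param mat Numeric matrix with rownames (features) and colnames (samples).
#' @param path Output path.
#' @param id_column Name used for the first (feature id) column.
#' @return Invisibly, `path`.
#' @export
write_expression_tsv <- function(mat, path, id_column = "feature_id") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe table
#'
#' Probe tables carry one row per probe with columns `probe_set_id`,
#' `probe_id` and `sequence` (DNA over A/C/G/T; lower case accepted and
#' normalized to upper case).
#'
#' @param path Path to the probe TSV.
#' @return data.frame with columns probe_set_id, probe_id, sequence.
#' @export
read_probe_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("probe_set_id", "probe_id", "sequence")
  if (!all(need %in% colnames(df))) {
    stop("probe table must have columns ", paste(need, collapse = ", "),
         ": ", path)
  }
  df <- df[, need]
  df$sequence <- toupper(df$sequence)
  if (anyDuplicated(df$probe_id)) stop("duplicate probe_id in ", path)
  if (any(!nzchar(df$sequence))) stop("empty probe sequence in ", path)
  df
}

#' Read smORF annotations from a BED6 file
#'
#' The BED file is the canonical coordinate entry point: 0-based half-open
#' intervals, columns chrom/start/end/name/score/strand, with `name` holding
#' the smORF identifier. smORFs longer than 303 nt (100 codons plus the stop)
#' are rejected, as are malformed lines.
#'
#' @param path Path to a BED6 file.
#' @param max_length_nt Maximum smORF length in nucleotides (default 303).
#' @return A [GenomicRanges::GRanges] with the smORF ids as names.
#' @export
read_smorf_bed <- function(path, max_length_nt = 303L) {
  lines <- readLines(path, warn = FALSE)
  body <- which(nzchar(lines) & !startsWith(lines, "track") &
                  !startsWith(lines, "#"))
  for (ln in body) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    ok <- length(f) >= 4L && !is.na(suppressWarnings(as.integer(f[2L]))) &&
      !is.na(suppressWarnings(as.integer(f[3L]))) &&
      as.integer(f[2L]) < as.integer(f[3L]) && as.integer(f[2L]) >= 0L
    if (!ok) {
      stop("malformed BED line ", ln, " in ", path, ": ", lines[ln],
           call. = FALSE)
    }
  }
  if (!length(body)) {
    warning("empty smORF BED: ", path)
    gr <- GenomicRanges::GRanges()
    names(gr) <- character(0)
    return(gr)
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) stop("malformed BED file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(gr$name) || anyNA(gr$name)) {
    stop("BED name column (smORF id) required: ", path)
  }
  if (anyDuplicated(gr$name)) stop("duplicate smORF ids in ", path)
  too_long <- GenomicRanges::width(gr) > max_length_nt
  if (any(too_long)) {
    stop(sum(too_long), " smORF(s) exceed ", max_length_nt,
         " nt (first: ", gr$name[which(too_long)[1L]], ")")
  }
  names(gr) <- gr$name
  gr
}

#' Read a reference genome from FASTA
#'
#' Multi-record, line-wrapped FASTA; sequence names are truncated at the
#' first whitespace, matching common chromosome-naming practice.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome))) stop("duplicate sequence names in ", path)
  genome
}

#' Read gene sets from a GMT file
#'
#' One term per line: term id, description, then member gene ids, all
#' tab-separated. Duplicate members within a term are dropped.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (members per term), with the
#'   descriptions in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad)) {
    stop("GMT line ", bad[1L], " has fewer than 3 fields: ", path)
  }
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate term ids in ", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(vapply(parts, `[[`, "", 2L), ids)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  desc <- if (is.null(descriptions)) rep("na", length(sets)) else
    descriptions[names(sets)]
  lines <- mapply(function(id, d, members) {
    paste(c(id, d, members), collapse = "\t")
  }, names(sets), desc, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write probe-set to smORF annotation tables
#'
#' Annotation TSVs carry columns `probe_set_id`, `smorf_id`, `weight`;
#' weights are printed with at least 6 significant digits.
#'
#' @param path File path.
#' @return `read_annotation_tsv`: data.frame with those three columns.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("probe_set_id", "smorf_id", "weight")
  if (!all(need %in% colnames(df))) {
    stop("annotation TSV must have columns ", paste(need, collapse = ", "))
  }
  df$weight <- as.numeric(df$weight)
  df[, need]
}

#' @rdname read_annotation_tsv
#' @param annotations data.frame as returned by [compute_weights()].
#' @export
write_annotation_tsv <- function(annotations, path) {
  out <- annotations[, c("probe_set_id", "smorf_id", "weight")]
  out$weight <- formatC(out$weight, format = "g", digits = 8)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flat key=value mapping file (sidecars, configs, dataset->model maps)
#'
#' Lines are `key=value`; blank lines and lines starting with `#` are
#' ignored.
#'
#' @param path File path.
#' @return Named character vector.
#' @export
read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(stats::setNames(character(0), character(0)))
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0L)) stop("line without '=' in key=value file: ", path)
  stats::setNames(trimws(substring(lines, eq + 1L)),
                  trimws(substring(lines, 1L, eq - 1L)))
}

#' @rdname read_keyvalue
#' @param x Named vector or list of scalar values.
#' @export
write_keyvalue <- function(x, path) {
  vals <- vapply(x, function(v) paste(as.character(v), collapse = ","), "")
  writeLines(paste0(names(x), "=", vals), path)
  invisible(path)
}
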