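## Condition helpers: data errors exit with code 2 from the CLI, usage
## errors with 1.
.data_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("smorfcoex_data_error", "error")))
}

#' Pipeline run configuration
#'
#' Collects file paths and parameters for the pipeline stages. Defaults are
#' the method's standard settings: weight_min 0.1, median estimator, ball
#' tree with leaf size 5, at most 1000 correlated genes at rho >= 0.5,
#' selection at p <= 0.05 and FDR <= 0.2 with per-collection BH adjustment.
#'
#' @param file Optional flat `key=value` config file read first (see
#'   [read_keyvalue()]); `...` overrides it.
#' @param ... Named overrides: paths `genome`, `probes`, `smorfs`,
#'   `expression` (comma-separated TSV paths or a directory of
#'   `dataset_*.tsv`), `gene_sets`, `annotations`, `probeset_gene_map`,
#'   `dataset_model_map`, `out_dir`; parameters `weight_min`, `estimator`,
#'   `leaf_size`, `k`, `rho_min`, `p_max`, `fdr_max`, `fdr_family`, `seed`.
#' @return List of class `run_config`.
#' @export
run_config <- function(..., file = NULL) {
  cfg <- list(genome = NULL, probes = NULL, smorfs = NULL, expression = NULL,
              gene_sets = NULL, annotations = NULL, probeset_gene_map = NULL,
              dataset_model_map = NULL, out_dir = ".",
              weight_min = 0.1, estimator = "median", leaf_size = 5L,
              k = 1000L, rho_min = 0.5, p_max = 0.05, fdr_max = 0.2,
              fdr_family = "collection", seed = 1L)
  numeric_keys <- c("weight_min", "leaf_size", "k", "rho_min", "p_max",
                    "fdr_max", "seed")
  apply_kv <- function(cfg, kv) {
    for (key in names(kv)) {
      if (!key %in% names(cfg)) stop("unknown config key: ", key)
      val <- kv[[key]]
      if (key %in% numeric_keys) val <- as.numeric(val)
      cfg[[key]] <- val
    }
    cfg
  }
  if (!is.null(file)) cfg <- apply_kv(cfg, as.list(read_keyvalue(file)))
  cfg <- apply_kv(cfg, list(...))
  cfg$leaf_size <- as.integer(cfg$leaf_size)
  cfg$k <- as.integer(cfg$k)
  cfg$seed <- as.integer(cfg$seed)
  if (!cfg$estimator %in% c("median", "mean", "max")) {
    stop("estimator must be median, mean or max")
  }
  if (!cfg$fdr_family %in% c("collection", "all")) {
    stop("fdr_family must be 'collection' or 'all'")
  }
  class(cfg) <- "run_config"
  cfg
}

.require_paths <- function(config, keys) {
  for (key in keys) {
    if (is.null(config[[key]])) stop("config is missing required path: ", key)
    if (!file.exists(config[[key]])) {
      .data_error("file not found for config key '", key, "': ", config[[key]])
    }
  }
}

.expression_paths <- function(config) {
  spec <- config$expression
  if (is.null(spec)) stop("config is missing required path: expression")
  paths <- if (length(spec) == 1L && dir.exists(spec)) {
    sort(list.files(spec, pattern = "^dataset_.*\\.tsv$", full.names = TRUE))
  } else {
    unlist(strsplit(spec, ",", fixed = TRUE))
  }
  if (!length(paths)) .data_error("no expression matrices found: ", spec)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) .data_error("expression TSV not found: ", missing[1L])
  stats::setNames(paths, sub("\\.tsv$", "", basename(paths)))
}

.write_sidecar <- function(config, stage, fields) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_keyvalue(fields, file.path(config$out_dir,
                                   paste0(stage, "_summary.txt")))
}

#' Pipeline stage: reannotate probes to smORFs
#'
#' Matches every probe against the genome, intersects retained matches with
#' the smORF BED and writes the annotation weights to
#' `out_dir/annotations.tsv`, plus a key-value run summary.
#'
#' @param config A [run_config()] with `genome`, `probes`, `smorfs`,
#'   `out_dir` set.
#' @return The annotation data.frame, invisibly.
#' @export
cmd_annotate_probes <- function(config) {
  .require_paths(config, c("genome", "probes", "smorfs"))
  genome <- read_genome_fasta(config$genome)
  probes <- read_probe_table(config$probes)
  smorfs <- read_smorf_bed(config$smorfs)
  if (length(smorfs) == 0L) {
    message("warning: empty smORF BED; writing empty annotation table")
  }
  ann <- annotate_probesets(probes, genome, smorfs,
                            weight_min = config$weight_min)
  report <- attr(ann, "probe_report")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_annotation_tsv(ann, file.path(config$out_dir, "annotations.tsv"))
  .write_sidecar(config, "annotate", list(
    probes_read = nrow(probes),
    probes_retained = sum(report$retained),
    probe_sets_annotated = length(unique(ann$probe_set_id)),
    smorfs_annotated = length(unique(ann$smorf_id)),
    annotations = nrow(ann)))
  message(sprintf("annotate-probes: %d/%d probes retained, %d annotations",
                  sum(report$retained), nrow(probes), nrow(ann)))
  invisible(ann)
}

#' Pipeline stage: estimate smORF expression per dataset
#'
#' Applies the weighted-median estimator to every dataset's probe-set
#' matrix; writes `out_dir/smorf_expr_<dataset>.tsv` per dataset and a
#' sidecar listing smORFs that could not be quantified (all weights at or
#' below `weight_min`).
#'
#' @param config A [run_config()] with `annotations`, `expression`,
#'   `out_dir` set.
#' @return Named list of smORF expression matrices, invisibly.
#' @export
cmd_quantify <- function(config) {
  .require_paths(config, "annotations")
  ann <- read_annotation_tsv(config$annotations)
  paths <- .expression_paths(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  unquantified <- character(0)
  for (ds in names(paths)) {
    signals <- read_expression_tsv(paths[[ds]])
    keep <- ann$probe_set_id %in% rownames(signals)
    expr <- withCallingHandlers(
      estimate_smorf_expression(signals, ann[keep, , drop = FALSE],
                                estimator = config$estimator,
                                weight_min = config$weight_min),
      warning = function(w) invokeRestart("muffleWarning"))
    unq <- attr(expr, "unquantified")
    if (length(unq)) unquantified <- union(unquantified, unq)
    write_expression_tsv(expr, file.path(config$out_dir,
                                         paste0("smorf_expr_", ds, ".tsv")),
                         id_column = "smorf_id")
    out[[ds]] <- expr
  }
  .write_sidecar(config, "quantify", list(
    datasets = length(paths),
    smorfs_quantified = length(unique(unlist(lapply(out, rownames)))),
    smorfs_unquantified = paste(unquantified, collapse = ",")))
  invisible(out)
}

## Assemble per-dataset gene/smORF matrices for correlation and prediction.
.load_prediction_datasets <- function(config) {
  .require_paths(config, c("annotations", "probeset_gene_map"))
  ann <- read_annotation_tsv(config$annotations)
  map_df <- utils::read.delim(config$probeset_gene_map,
                              colClasses = "character")
  if (!all(c("probe_set_id", "gene_id") %in% colnames(map_df))) {
    .data_error("probeset_gene_map needs columns probe_set_id, gene_id")
  }
  id_map <- stats::setNames(map_df$gene_id, map_df$probe_set_id)
  paths <- .expression_paths(config)
  datasets <- list()
  for (ds in names(paths)) {
    signals <- read_expression_tsv(paths[[ds]])
    gene_rows <- intersect(rownames(signals), names(id_map))
    if (!length(gene_rows)) {
      .data_error("no probe set of ", ds, " appears in probeset_gene_map")
    }
    gene_expr <- aggregate_duplicate_features(
      signals[gene_rows, , drop = FALSE], id_map[gene_rows])
    keep <- ann$probe_set_id %in% rownames(signals)
    smorf_expr <- withCallingHandlers(
      estimate_smorf_expression(signals, ann[keep, , drop = FALSE],
                                estimator = config$estimator,
                                weight_min = config$weight_min),
      warning = function(w) invokeRestart("muffleWarning"))
    datasets[[ds]] <- list(gene_expr = gene_expr, smorf_expr = smorf_expr)
  }
  datasets
}

#' Pipeline stage: correlated genes of one smORF
#'
#' Quantifies the smORF in every dataset, runs the ball-tree search and
#' writes per-dataset hit tables `out_dir/correlated_<dataset>.tsv`
#' (columns gene_id, rho, distance) plus a metadata sidecar recording
#' leaf_size, k, rho_min and features excluded for zero rank variance.
#'
#' @param config A [run_config()] with `annotations`, `probeset_gene_map`,
#'   `expression`, `out_dir` set.
#' @param smorf_id The query smORF id.
#' @return Named list of hit data.frames, invisibly.
#' @export
cmd_correlate <- function(config, smorf_id) {
  datasets <- .load_prediction_datasets(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hits <- list()
  excluded <- character(0)
  for (ds in names(datasets)) {
    d <- datasets[[ds]]
    if (!smorf_id %in% rownames(d$smorf_expr)) next
    rm_ <- rank_matrix(d$gene_expr)
    excluded <- union(excluded, rm_$excluded)
    index <- build_coexpr_index(rm_, leaf_size = config$leaf_size)
    h <- query_correlated_genes(rank_transform(d$smorf_expr[smorf_id, ]),
                                index, k = config$k,
                                rho_min = config$rho_min)
    utils::write.table(h, file.path(config$out_dir,
                                    paste0("correlated_", ds, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    hits[[ds]] <- h
  }
  if (!length(hits)) {
    .data_error("smORF ", smorf_id, " is unquantifiable in every dataset")
  }
  .write_sidecar(config, "correlate", list(
    smorf_id = smorf_id, leaf_size = config$leaf_size, k = config$k,
    rho_min = config$rho_min, datasets = length(hits),
    excluded_features = paste(excluded, collapse = ",")))
  invisible(hits)
}

## Extract each smORF's genomic sequence on its annotated strand.
.smorf_sequences <- function(genome, smorfs) {
  chrom <- as.character(GenomicRanges::seqnames(smorfs))
  missing <- setdiff(unique(chrom), names(genome))
  if (length(missing)) {
    .data_error("smORF chromosome(s) absent from the genome: ",
                paste(missing, collapse = ", "))
  }
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(smorfs), function(i) {
    s <- Biostrings::subseq(genome[[chrom[i]]],
                            BiocGenerics::start(smorfs)[i],
                            BiocGenerics::end(smorfs)[i])
    if (as.character(GenomicRanges::strand(smorfs))[i] == "-") {
      s <- Biostrings::reverseComplement(s)
    }
    as.character(s)
  }, ""))
  names(seqs) <- names(smorfs)
  seqs
}

#' Resolve a smORF query by id, exact sequence or genomic coordinate
#'
#' `by = "id"` matches the BED name column; `by = "sequence"` compares the
#' query (case-insensitive) with each smORF's genomic sequence on its
#' annotated strand and with the reverse complement; `by = "coordinate"`
#' parses `chrom:start-end` (1-based inclusive, the usual browser
#' convention) and returns the smORF(s) overlapping it by at least one
#' base.
#'
#' @param query Query string.
#' @param smorfs [GenomicRanges::GRanges] from [read_smorf_bed()].
#' @param by One of "id", "sequence", "coordinate".
#' @param genome [Biostrings::DNAStringSet]; required for `by =
#'   "sequence"`.
#' @return Character vector of matching smORF ids (error if none).
#' @export
resolve_smorf_query <- function(query, smorfs,
                                by = c("id", "sequence", "coordinate"),
                                genome = NULL) {
  by <- match.arg(by)
  if (by == "id") {
    if (!query %in% names(smorfs)) .data_error("smORF id not found: ", query)
    return(query)
  }
  if (by == "sequence") {
    if (is.null(genome)) stop("sequence queries need the genome")
    q <- toupper(query)
    seqs <- .smorf_sequences(genome, smorfs)    # strand-aware extraction
    rc <- Biostrings::reverseComplement(seqs)
    hit <- as.character(seqs) == q | as.character(rc) == q
    if (!any(hit)) .data_error("no smORF with that exact sequence")
    return(names(smorfs)[hit])
  }
  m <- regmatches(query, regexec("^([^:]+):([0-9]+)-([0-9]+)$", query))[[1L]]
  if (length(m) != 4L) {
    .data_error("coordinate query must look like chr1:100-200")
  }
  q_gr <- GenomicRanges::GRanges(m[2L],
                                 IRanges::IRanges(as.integer(m[3L]),
                                                  as.integer(m[4L])))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(q_gr, smorfs,
                                                     ignore.strand = TRUE))
  if (!length(ov)) {
    near <- suppressWarnings(GenomicRanges::distanceToNearest(
      q_gr, smorfs, ignore.strand = TRUE))
    hint <- if (length(near)) {
      paste0("; nearest smORF: ",
             names(smorfs)[S4Vectors::subjectHits(near)[1L]], " at distance ",
             S4Vectors::mcols(near)$distance[1L], " nt")
    } else ""
    .data_error("no smORF overlaps ", query, hint)
  }
  names(smorfs)[S4Vectors::subjectHits(ov)]
}

#' Pipeline stage: predict smORF functions
#'
#' Resolves the query to a smORF id, runs the full
#' correlate-enrich-pool-select pipeline over every dataset and writes
#' `out_dir/predictions_<smorf>.tsv` with a provenance header (parameters,
#' datasets, package version) plus a per-dataset detail table.
#'
#' @inheritParams cmd_correlate
#' @param query smORF id, exact sequence, or `chrom:start-end` coordinate.
#' @param by Query mode, as in [resolve_smorf_query()].
#' @return The [predict_functions()] result, invisibly.
#' @export
cmd_predict <- function(config, query, by = c("id", "sequence",
                                              "coordinate")) {
  by <- match.arg(by)
  .require_paths(config, c("smorfs", "gene_sets"))
  smorfs <- read_smorf_bed(config$smorfs)
  genome <- if (by == "sequence") {
    .require_paths(config, "genome")
    read_genome_fasta(config$genome)
  }
  smorf_id <- resolve_smorf_query(query, smorfs, by = by, genome = genome)
  if (length(smorf_id) > 1L) {
    message("query resolves to ", length(smorf_id),
            " smORFs; using the first: ", smorf_id[1L])
    smorf_id <- smorf_id[1L]
  }
  gene_sets <- read_gmt(config$gene_sets)
  datasets <- .load_prediction_datasets(config)
  res <- predict_functions(smorf_id, datasets, gene_sets,
                           k = config$k, rho_min = config$rho_min,
                           p_max = config$p_max, fdr_max = config$fdr_max,
                           fdr_family = config$fdr_family,
                           leaf_size = config$leaf_size)
  if (attr(res, "status") == "unquantifiable") {
    .data_error("smORF ", smorf_id, " is unquantifiable in every dataset")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out_path <- file.path(config$out_dir,
                        paste0("predictions_", smorf_id, ".tsv"))
  header <- c(
    paste0("# smorfcoex ", as.character(utils::packageVersion("smorfcoex"))),
    paste0("# smorf_id=", smorf_id),
    paste0("# datasets=", paste(attr(res, "datasets_used"), collapse = ",")),
    sprintf("# k=%d rho_min=%g p_max=%g fdr_max=%g fdr_family=%s leaf_size=%d",
            config$k, config$rho_min, config$p_max, config$fdr_max,
            config$fdr_family, config$leaf_size))
  con <- file(out_path, "w")
  writeLines(header, con)
  suppressWarnings(utils::write.table(res, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  close(con)
  detail <- attr(res, "per_dataset")
  if (!is.null(detail)) {
    utils::write.table(detail,
                       file.path(config$out_dir,
                                 paste0("predictions_", smorf_id,
                                        "_per_dataset.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(res)
}

#' Pipeline stage: write a complete synthetic fixture bundle
#'
#' Generates the genome/platform files and the planted expression matrices
#' for a [simulation_config()] and writes every format the pipeline
#' consumes: `genome.fa`, `probes.tsv`, `smorfs.bed`,
#' `annotation_truth.tsv`, `dataset_*.tsv`, `probeset_gene_map.tsv`,
#' `gene_sets.gmt`, `modules_truth.tsv` and a `simulation_config.txt`
#' key-value record.
#'
#' @param sim_config A [simulation_config()].
#' @param dir Output directory.
#' @return Invisible list with the generator outputs (`platform`,
#'   `expression`).
#' @export
cmd_simulate <- function(sim_config, dir) {
  stopifnot(inherits(sim_config, "simulation_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  platform <- simulate_genome_and_platform(sim_config, dir)
  sim <- simulate_expression(sim_config)
  for (ds in names(sim$datasets)) {
    write_expression_tsv(sim$datasets[[ds]],
                         file.path(dir, paste0(ds, ".tsv")),
                         id_column = "probe_set_id")
  }
  utils::write.table(sim$probeset_gene_map,
                     file.path(dir, "probeset_gene_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(sim$gene_sets, file.path(dir, "gene_sets.gmt"))
  modules <- data.frame(smorf_id = names(sim$truth$planted_modules),
                        gene_set = unname(sim$truth$planted_modules),
                        rho_star = sim_config$rho_star,
                        stringsAsFactors = FALSE)
  utils::write.table(modules, file.path(dir, "modules_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg_flat <- sim_config
  cfg_flat$smorf_weights <- paste(sim_config$smorf_weights, collapse = ",")
  write_keyvalue(unclass(cfg_flat), file.path(dir, "simulation_config.txt"))
  message("simulate: bundle written to ", dir)
  invisible(list(platform = platform, expression = sim))
}
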