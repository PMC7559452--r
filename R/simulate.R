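#' Configuration for the synthetic fixture generators
#'
#' Bundles and validates every knob of the synthetic genome/platform and
#' expression generators. The defaults describe the standard simulation
#' study: 2,000 background genes measured in 3 datasets of 60 samples, one
#' smORF whose 50-gene module is planted at Spearman rho 0.8, the smORF
#' signal split over two probe sets with weights 0.6 and 0.4 plus one
#' sub-threshold decoy annotation at weight 0.1.
#'
#' @param seed Integer master seed; every sub-generator derives its own
#'   child seed from it, so a config is fully reproducible.
#' @param n_genes Number of background genes per dataset.
#' @param n_smorfs Number of smORFs.
#' @param n_samples Samples per dataset.
#' @param n_datasets Number of datasets.
#' @param n_gene_sets,set_size Number and size of generated gene sets; the
#'   first `n_smorfs` sets are the planted modules.
#' @param rho_star Target Spearman correlation between each smORF and its
#'   planted module members, in [0, 1); 0 plants nothing.
#' @param noise_sd Standard deviation of additive measurement noise on top
#'   of the unit-variance signal; the latent-factor loading is calibrated
#'   so the target Spearman survives the noise (an unattainable
#'   combination aborts).
#' @param tie_fraction Fraction of matrix entries rounded to one decimal to
#'   force rank ties, in [0, 1).
#' @param probes_per_set Probes per probe set.
#' @param smorf_probe_sets Probe sets annotated to each smORF.
#' @param smorf_weights Intended annotation weights, length
#'   `smorf_probe_sets`; each times `probes_per_set` must be a whole number
#'   of probes.
#' @param n_decoy_sets Per smORF, probe sets overlapping by exactly one
#'   probe (weight `1/probes_per_set`, sub-threshold at the default filter).
#' @param n_extra_sets Probe sets with no smORF overlap.
#' @param n_duplicate_probesets Genes measured by two probe sets (exercises
#'   median aggregation of duplicate ids).
#' @param plant_multicopy_decoy Plant one probe occurring 100 times in the
#'   genome (exercises the <100-matches retention rule).
#' @param probe_length Probe length in nt (default 25, Affymetrix-style).
#' @param spacer Spacer between probe slots outside smORFs, nt.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 2000L, n_smorfs = 1L,
                              n_samples = 60L, n_datasets = 3L,
                              n_gene_sets = 40L, set_size = 50L,
                              rho_star = 0.8, noise_sd = 0.3,
                              tie_fraction = 0.1,
                              probes_per_set = 10L, smorf_probe_sets = 2L,
                              smorf_weights = c(0.6, 0.4),
                              n_decoy_sets = 1L, n_extra_sets = 2L,
                              n_duplicate_probesets = 10L,
                              plant_multicopy_decoy = TRUE,
                              probe_length = 25L, spacer = 10L) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_smorfs = as.integer(n_smorfs),
              n_samples = as.integer(n_samples),
              n_datasets = as.integer(n_datasets),
              n_gene_sets = as.integer(n_gene_sets),
              set_size = as.integer(set_size),
              rho_star = rho_star, noise_sd = noise_sd,
              tie_fraction = tie_fraction,
              probes_per_set = as.integer(probes_per_set),
              smorf_probe_sets = as.integer(smorf_probe_sets),
              smorf_weights = smorf_weights,
              n_decoy_sets = as.integer(n_decoy_sets),
              n_extra_sets = as.integer(n_extra_sets),
              n_duplicate_probesets = as.integer(n_duplicate_probesets),
              plant_multicopy_decoy = isTRUE(plant_multicopy_decoy),
              probe_length = as.integer(probe_length),
              spacer = as.integer(spacer))
  counts <- c(cfg$n_genes, cfg$n_smorfs, cfg$n_samples, cfg$n_datasets,
              cfg$n_gene_sets, cfg$set_size, cfg$probes_per_set,
              cfg$smorf_probe_sets)
  if (any(counts < 1L)) stop("all counts in the simulation config must be >= 1")
  if (cfg$n_samples < 3L) stop("n_samples must be >= 3 for rank correlation")
  if (!(rho_star >= 0 && rho_star < 1)) stop("rho_star must lie in [0, 1)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (!(tie_fraction >= 0 && tie_fraction < 1)) {
    stop("tie_fraction must lie in [0, 1)")
  }
  if (length(smorf_weights) != cfg$smorf_probe_sets) {
    stop("smorf_weights must have length smorf_probe_sets")
  }
  k <- smorf_weights * cfg$probes_per_set
  if (any(abs(k - round(k)) > 1e-9) || any(k < 1) || any(k > cfg$probes_per_set)) {
    stop("each smorf_weight times probes_per_set must be a whole number ",
         "of probes in [1, probes_per_set]")
  }
  if (cfg$n_gene_sets < cfg$n_smorfs) {
    stop("need at least one gene set per smORF (planted modules)")
  }
  if (cfg$set_size > cfg$n_genes) stop("set_size cannot exceed n_genes")
  ## calibration: Spearman rho_star under bivariate normality needs Pearson
  ## r = 2*sin(pi*rho_star/6); measurement noise attenuates by 1/(1+sd^2)
  r_base <- 2 * sin(pi * rho_star / 6) * (1 + noise_sd^2)
  if (r_base >= 1) {
    stop("rho_star = ", rho_star, " is not attainable with noise_sd = ",
         noise_sd, "; lower one of them (required latent loading ",
         signif(r_base, 4), " >= 1)")
  }
  cfg$r_base <- r_base
  class(cfg) <- "simulation_config"
  cfg
}

## Shared id conventions so genome/platform and expression fixtures cohere.
.sim_gene_ids <- function(cfg) sprintf("gene_%04d", seq_len(cfg$n_genes))
.sim_smorf_ids <- function(cfg) sprintf("smorf_%03d", seq_len(cfg$n_smorfs))
.sim_smorf_ps <- function(smorf_id, j) sprintf("ps_%s_%d", smorf_id, j)
.sim_decoy_ps <- function(smorf_id, d) sprintf("ps_%s_decoy%d", smorf_id, d)

.sim_child_seeds <- function(cfg, n) {
  set.seed(cfg$seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Draw unique probe sequences whose reverse complements are also distinct
## (so each planted probe matches the genome exactly once, on one strand).
.draw_probe_seqs <- function(n, len) {
  out <- character(n)
  seen <- character(0)
  i <- 0L
  while (i < n) {
    s <- .random_dna(len)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    if (s == rc || s %in% seen || rc %in% seen) next
    i <- i + 1L
    out[i] <- s
    seen <- c(seen, s, rc)
  }
  out
}

#' Intended probe-set annotations for a simulation config
#'
#' The ground-truth (probe set, smORF, weight) links both generators plant:
#' per smORF, `smorf_probe_sets` sets at the configured weights plus
#' `n_decoy_sets` sub-threshold links at weight `1/probes_per_set`.
#'
#' @param config A `simulation_config`.
#' @return data.frame probe_set_id, smorf_id, weight.
#' @export
simulated_annotation_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  rows <- list()
  for (sid in .sim_smorf_ids(config)) {
    for (j in seq_len(config$smorf_probe_sets)) {
      rows[[length(rows) + 1L]] <- data.frame(
        probe_set_id = .sim_smorf_ps(sid, j), smorf_id = sid,
        weight = config$smorf_weights[j], stringsAsFactors = FALSE)
    }
    for (d in seq_len(config$n_decoy_sets)) {
      rows[[length(rows) + 1L]] <- data.frame(
        probe_set_id = .sim_decoy_ps(sid, d), smorf_id = sid,
        weight = 1 / config$probes_per_set, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a genome, probe platform and smORF annotation with known truth
#'
#' Builds a single-chromosome genome in which every probe of the synthetic
#' platform occurs exactly once (except a planted 100-copy decoy probe, if
#' configured), and smORF intervals positioned so that each annotated probe
#' set overlaps the smORF with exactly the intended number of probes. Probes
#' are planted alternately on the forward and reverse strand. All
#' coordinates are BED convention (0-based half-open).
#'
#' @param config A `simulation_config`.
#' @param dir Output directory (created if needed); files `genome.fa`,
#'   `probes.tsv`, `smorfs.bed`, `annotation_truth.tsv` are written there.
#' @return Invisible list with the file `paths`, the `truth` annotation
#'   data.frame, the per-probe `probe_truth` (including the multicopy decoy
#'   flagged `expect_retained = FALSE`), and the smORF BED data.frame.
#' @export
simulate_genome_and_platform <- function(config, dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- .sim_child_seeds(config, config$n_datasets + 2L)
  set.seed(seeds[length(seeds)])

  plen <- config$probe_length
  smorf_ids <- .sim_smorf_ids(config)
  truth <- simulated_annotation_truth(config)

  ## probe inventory: probe set -> number of probes overlapping each smORF
  sets <- list()   # each: id, n_probes, smorf (or NA), k_overlap, multicopy
  for (sid in smorf_ids) {
    ann <- truth[truth$smorf_id == sid, ]
    for (i in seq_len(nrow(ann))) {
      sets[[length(sets) + 1L]] <- list(
        id = ann$probe_set_id[i], n = config$probes_per_set, smorf = sid,
        k = as.integer(round(ann$weight[i] * config$probes_per_set)))
    }
  }
  for (e in seq_len(config$n_extra_sets)) {
    sets[[length(sets) + 1L]] <- list(id = sprintf("ps_extra_%02d", e),
                                      n = config$probes_per_set,
                                      smorf = NA_character_, k = 0L)
  }
  if (config$plant_multicopy_decoy) {
    sets[[length(sets) + 1L]] <- list(id = "ps_multicopy",
                                      n = config$probes_per_set,
                                      smorf = NA_character_, k = 0L,
                                      multicopy = TRUE)
  }

  n_probes_total <- sum(vapply(sets, `[[`, 1L, "n"))
  seqs <- .draw_probe_seqs(n_probes_total, plen)
  seq_idx <- 0L
  next_seq <- function() {
    seq_idx <<- seq_idx + 1L
    seqs[seq_idx]
  }

  probes <- list()   # probe_set_id, probe_id, sequence, region, expect_retained
  for (s in sets) {
    multicopy <- isTRUE(s$multicopy)
    for (p in seq_len(s$n)) {
      probes[[length(probes) + 1L]] <- data.frame(
        probe_set_id = s$id,
        probe_id = sprintf("%s_p%02d", s$id, p),
        sequence = next_seq(),
        overlaps = p <= s$k,
        smorf_id = if (p <= s$k) s$smorf else NA_character_,
        multicopy = multicopy && p == s$n,
        stringsAsFactors = FALSE)
    }
  }
  probes <- do.call(rbind, probes)

  ## genome assembly: per smORF a tight run of its overlapping probe slots
  ## (pitch plen + 1 so the run fits the 303 nt smORF cap), then a loose
  ## region for everything else, then the 100-copy tandem repeat.
  pieces <- character(0)
  pos <- 0L                      # 0-based current genome length
  bed <- list()
  strand_toggle <- TRUE
  plant <- function(seq, minus) {
    if (minus) as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq))) else seq
  }
  for (sid in smorf_ids) {
    ov <- probes[probes$overlaps & probes$smorf_id == sid, , drop = FALSE]
    K <- nrow(ov)
    span <- (K - 1L) * (plen + 1L) + 1L
    if (span > 303L) {
      stop("infeasible placement: ", K, " overlapping probe slots span ",
           span, " nt, above the 303 nt smORF cap; reduce probes_per_set, ",
           "smorf_weights or n_decoy_sets")
    }
    run_start <- pos
    for (i in seq_len(K)) {
      minus <- (i %% 4L == 0L)
      pieces <- c(pieces, plant(ov$sequence[i], minus), .random_dna(1L))
      pos <- pos + plen + 1L
    }
    ## smORF covers slots 1..K-1 fully and exactly 1 base of slot K
    smorf_end <- run_start + (K - 1L) * (plen + 1L) + 1L
    bed[[length(bed) + 1L]] <- data.frame(
      chrom = "chr1", start = run_start, end = smorf_end, name = sid,
      score = 0L, strand = if (strand_toggle) "+" else "-",
      stringsAsFactors = FALSE)
    strand_toggle <- !strand_toggle
    pieces <- c(pieces, .random_dna(config$spacer))
    pos <- pos + config$spacer
  }
  away <- probes[!probes$overlaps & !probes$multicopy, , drop = FALSE]
  for (i in seq_len(nrow(away))) {
    minus <- (i %% 4L == 0L)
    pieces <- c(pieces, plant(away$sequence[i], minus),
                .random_dna(config$spacer))
    pos <- pos + plen + config$spacer
  }
  mc <- probes[probes$multicopy, , drop = FALSE]
  if (nrow(mc) == 1L) {
    pieces <- c(pieces, strrep(mc$sequence, 100L), .random_dna(config$spacer))
    pos <- pos + 100L * plen + config$spacer
  }
  genome_seq <- paste(pieces, collapse = "")

  probe_truth <- data.frame(
    probes[, c("probe_set_id", "probe_id", "sequence", "overlaps",
               "smorf_id")],
    expect_retained = !probes$multicopy,
    stringsAsFactors = FALSE)
  bed <- do.call(rbind, bed)

  paths <- list(genome = file.path(dir, "genome.fa"),
                probes = file.path(dir, "probes.tsv"),
                smorfs = file.path(dir, "smorfs.bed"),
                truth = file.path(dir, "annotation_truth.tsv"))
  writeLines(c(">chr1", gsub("(.{70})", "\\1\n", genome_seq)), paths$genome)
  utils::write.table(probes[, c("probe_set_id", "probe_id", "sequence")],
                     paths$probes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bed, paths$smorfs, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_annotation_tsv(truth, paths$truth)

  invisible(list(paths = paths, truth = truth, probe_truth = probe_truth,
                 smorf_bed = bed))
}

#' Simulate probe-set expression matrices with planted co-expression
#'
#' Generates `n_datasets` probe-set-level log2-scale matrices. Each smORF's
#' planted module (the members of its gene set) and its probe sets load on a
#' shared latent Gaussian factor whose loading is calibrated so that the
#' pairwise Spearman correlation between planted features is `rho_star` in
#' expectation after measurement noise; all other features are independent
#' noise. A configurable fraction of entries is rounded to one decimal to
#' force rank ties. Identical seeds give identical output.
#'
#' @param config A `simulation_config`.
#' @return List with:
#'   \describe{
#'     \item{datasets}{named list of matrices (probe sets x samples).}
#'     \item{probeset_gene_map}{data.frame probe_set_id, gene_id for the
#'       gene-level probe sets (duplicate probe sets map to the same gene).}
#'     \item{annotations}{intended probe-set/smORF annotation weights.}
#'     \item{gene_sets}{named list; element 1..n_smorfs are the planted
#'       modules (`GOBP_SET_001` is smORF 1's), the rest random draws over
#'       cycling collection prefixes.}
#'     \item{truth}{planted module membership and the config.}
#'   }
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  seeds <- .sim_child_seeds(config, config$n_datasets + 2L)
  gene_ids <- .sim_gene_ids(config)
  smorf_ids <- .sim_smorf_ids(config)

  ## gene sets (fixed across datasets): first n_smorfs are planted modules
  set.seed(seeds[config$n_datasets + 1L])
  prefixes <- c("GOBP_", "GOCC_", "KEGG_", "REACTOME_")
  set_names <- sprintf("%sSET_%03d",
                       prefixes[(seq_len(config$n_gene_sets) - 1L) %%
                                  length(prefixes) + 1L],
                       seq_len(config$n_gene_sets))
  gene_sets <- lapply(seq_len(config$n_gene_sets), function(i) {
    sort(sample(gene_ids, config$set_size))
  })
  names(gene_sets) <- set_names
  planted <- stats::setNames(set_names[seq_len(config$n_smorfs)], smorf_ids)

  annotations <- simulated_annotation_truth(config)
  dup_genes <- gene_ids[seq_len(min(config$n_duplicate_probesets,
                                    config$n_genes))]
  ps_map <- data.frame(
    probe_set_id = c(paste0("ps_", gene_ids),
                     if (length(dup_genes)) paste0("ps_", dup_genes, "_b")),
    gene_id = c(gene_ids, dup_genes),
    stringsAsFactors = FALSE)

  loading <- sqrt(config$r_base)
  resid <- sqrt(1 - config$r_base)
  sample_ids <- sprintf("s%03d", seq_len(config$n_samples))
  all_ps <- c(ps_map$probe_set_id, annotations$probe_set_id)

  datasets <- vector("list", config$n_datasets)
  names(datasets) <- sprintf("dataset_%02d", seq_len(config$n_datasets))
  for (d in seq_len(config$n_datasets)) {
    set.seed(seeds[d])
    mu <- stats::setNames(stats::runif(length(all_ps), 4, 10), all_ps)
    factors <- matrix(stats::rnorm(config$n_smorfs * config$n_samples),
                      nrow = config$n_smorfs)
    mat <- matrix(NA_real_, nrow = length(all_ps), ncol = config$n_samples,
                  dimnames = list(all_ps, sample_ids))
    member_of <- rep(NA_integer_, length(all_ps))
    names(member_of) <- all_ps
    if (config$rho_star > 0) {
      for (si in seq_len(config$n_smorfs)) {
        members <- gene_sets[[planted[si]]]
        member_ps <- ps_map$probe_set_id[ps_map$gene_id %in% members]
        smorf_ps <- c(.sim_smorf_ps(smorf_ids[si],
                                    seq_len(config$smorf_probe_sets)))
        member_of[c(member_ps, smorf_ps)] <- si
      }
    }
    for (i in seq_along(all_ps)) {
      signal <- if (!is.na(member_of[i])) {
        loading * factors[member_of[i], ] +
          resid * stats::rnorm(config$n_samples)
      } else {
        stats::rnorm(config$n_samples)
      }
      mat[i, ] <- mu[i] + signal + config$noise_sd *
        stats::rnorm(config$n_samples)
    }
    if (config$tie_fraction > 0) {
      n_tie <- floor(config$tie_fraction * length(mat))
      idx <- sample(length(mat), n_tie)
      mat[idx] <- round(mat[idx], 1L)
    }
    datasets[[d]] <- mat
  }

  list(datasets = datasets,
       probeset_gene_map = ps_map,
       annotations = annotations,
       gene_sets = gene_sets,
       truth = list(planted_modules = planted,
                    planted_genes = lapply(planted, function(s) gene_sets[[s]]),
                    config = config))
}
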