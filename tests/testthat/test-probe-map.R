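test_that("exact probe matching finds forward and reverse-complement hits", {
  genome <- read_genome_fasta(write_tiny_genome(list(chr1 = "ACGTACGTTT")))
  res <- match_probes(probe_df("ACGTACGT"), genome)
  expect_equal(nrow(res$matches), 1L)
  expect_equal(res$matches$chrom, "chr1")
  expect_equal(res$matches$start, 0L)
  expect_equal(res$matches$end, 8L)
  expect_equal(res$matches$strand, "+")
  expect_true(res$probes$retained)

  # reverse-complement occurrence reported on the minus strand
  genome2 <- read_genome_fasta(write_tiny_genome(list(chrA = "TTTTG")))
  res2 <- match_probes(probe_df("AAAA"), genome2)
  expect_equal(res2$matches$strand, "-")
  expect_equal(res2$matches$start, 0L)
  expect_equal(res2$matches$end, 4L)
  expect_true(res2$probes$retained)
})

test_that("probes with 100 or more matches are not retained, 99 are", {
  probe <- "ACGTTGCACGGTGCATCAAGGCATG"
  for (copies in c(99L, 100L)) {
    genome <- read_genome_fasta(write_tiny_genome(
      list(chr1 = strrep(probe, copies))))
    res <- match_probes(probe_df(probe), genome)
    expect_equal(res$probes$n_matches, copies)
    expect_equal(res$probes$retained, copies < 100L)
  }
})

test_that("non-ACGT probes are rejected with a diagnostic", {
  genome <- read_genome_fasta(write_tiny_genome(list(chr1 = "ACGTACGTTT")))
  res <- match_probes(probe_df(c("ACGTNCGT", "ACGTACGT")), genome)
  expect_false(res$probes$retained[1L])
  expect_match(res$probes$reason[1L], "non-ACGT")
  expect_true(res$probes$retained[2L])
})

test_that("matching agrees with a naive sliding-window scan", {
  set.seed(42)
  for (rep in 1:5) {
    bases <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
    g <- list(chr1 = paste(bases[1:250], collapse = ""),
              chr2 = paste(bases[251:400], collapse = ""))
    genome <- read_genome_fasta(write_tiny_genome(g))
    # short probes so multiple (possibly overlapping) hits occur
    probes <- probe_df(vapply(1:8, function(i) {
      paste(sample(c("A", "C", "G", "T"), 4, replace = TRUE), collapse = "")
    }, ""))
    res <- match_probes(probes, genome, max_hits = 1000L)
    for (pid in probes$probe_id) {
      got <- res$matches[res$matches$probe_id == pid,
                         c("chrom", "start", "end", "strand")]
      rownames(got) <- NULL
      want <- naive_probe_scan(probes$sequence[probes$probe_id == pid], g)
      rownames(want) <- NULL
      expect_equal(got, want, ignore_attr = TRUE)
    }
  }
})

test_that("probe/smORF intersection honours half-open 1-base boundaries", {
  smorfs <- smorf_granges("chr1", 34, 90, "sm1")
  one_base <- data.frame(probe_set_id = "ps1", probe_id = "p1",
                         chrom = "chr1", start = 10L, end = 35L,
                         strand = "+", stringsAsFactors = FALSE)
  touching <- transform(one_base, end = 34L)
  expect_equal(intersect_with_smorfs(one_base, smorfs)$n_overlapping, 1L)
  expect_equal(nrow(intersect_with_smorfs(touching, smorfs)), 0L)
})

test_that("a probe with several matches in one smORF counts once", {
  smorfs <- smorf_granges("chr1", 0, 100, "sm1")
  matches <- data.frame(
    probe_set_id = "ps1", probe_id = c("p1", "p1", "p2", "p3"),
    chrom = "chr1", start = c(5L, 40L, 50L, 200L),
    end = c(30L, 65L, 75L, 225L), strand = "+", stringsAsFactors = FALSE)
  counts <- intersect_with_smorfs(matches, smorfs)
  expect_equal(counts$n_overlapping, 2L)   # p1 once, p2 once; p3 outside
})

test_that("intersection of empty inputs yields an empty mapping", {
  empty_smorfs <- GenomicRanges::GRanges()
  names(empty_smorfs) <- character(0)
  matches <- data.frame(probe_set_id = "ps1", probe_id = "p1",
                        chrom = "chr1", start = 0L, end = 25L, strand = "+",
                        stringsAsFactors = FALSE)
  expect_equal(nrow(intersect_with_smorfs(matches, empty_smorfs)), 0L)
})

test_that("annotation weights are overlap fractions of retained probes", {
  counts <- data.frame(probe_set_id = c("ps1", "ps2", "ps3"),
                       smorf_id = "sm1",
                       n_overlapping = c(4L, 1L, 10L),
                       stringsAsFactors = FALSE)
  w <- compute_weights(counts, c(ps1 = 10L, ps2 = 10L, ps3 = 10L))
  expect_equal(w$weight, c(0.4, 0.1, 1.0))
  expect_equal(w$below_threshold, c(FALSE, TRUE, FALSE))
  expect_true(all(w$weight > 0 & w$weight <= 1))

  bad <- data.frame(probe_set_id = "ps1", smorf_id = "sm1",
                    n_overlapping = 11L, stringsAsFactors = FALSE)
  expect_error(compute_weights(bad, c(ps1 = 10L)), "consistency")
})

test_that("full reannotation recovers exhaustive pairwise overlap checks", {
  set.seed(7)
  # random intervals; compare findOverlaps-backed counting with an
  # all-pairs base-sharing check
  n_probe <- 40L
  starts <- sample(0:500, n_probe)
  matches <- data.frame(
    probe_set_id = paste0("ps", rep(1:4, each = 10)),
    probe_id = paste0("p", seq_len(n_probe)),
    chrom = "chr1", start = starts, end = starts + 25L,
    strand = sample(c("+", "-"), n_probe, TRUE), stringsAsFactors = FALSE)
  sm_start <- sample(0:500, 6)
  smorfs <- smorf_granges("chr1", sm_start, sm_start + 60L, paste0("sm", 1:6))
  got <- intersect_with_smorfs(matches, smorfs)
  for (si in seq_along(smorfs)) {
    s0 <- sm_start[si]; s1 <- s0 + 60L
    ov <- matches$start < s1 & matches$end > s0   # >= 1 shared base
    want <- table(matches$probe_set_id[ov])
    for (ps in names(want)) {
      expect_equal(
        got$n_overlapping[got$probe_set_id == ps &
                            got$smorf_id == paste0("sm", si)],
        as.integer(want[[ps]]))
    }
  }
})

test_that("denominator switch divides by all probes of the set", {
  # ps1 has 3 probes; one is unmappable, one overlaps the smORF
  genome <- read_genome_fasta(write_tiny_genome(
    list(chr1 = "CACACTTGAGAGTTTTTTTTTT")))
  probes <- probe_df(c("CACAC", "GAGAG", "NNNNN"))
  smorfs <- smorf_granges("chr1", 0, 5, "sm1")
  ann_ret <- annotate_probesets(probes, genome, smorfs)
  ann_all <- annotate_probesets(probes, genome, smorfs, denominator = "all")
  expect_equal(ann_ret$weight, 1 / 2)   # 2 retained probes
  expect_equal(ann_all$weight, 1 / 3)   # 3 probes in the set
})
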