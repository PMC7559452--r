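---
title: "Methods and design of smorfcoex"
author: "smorfcoex authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of smorfcoex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smorfcoex)
```

# The problem and the model

Small open reading frames (smORFs, under 100 codons) are mostly
unannotated, and their microproteins largely escape mass-spectrometric
detection. `smorfcoex` infers smORF function by guilt-by-association from
microarray data: a smORF whose estimated expression tracks the members of
a functional gene set across many samples is predicted to participate in
that function.

The chain of inference rests on three modeling assumptions:

1. **Shared probe signal.** A microarray probe set whose probes fall
   inside a smORF measures a mixture of the smORF's transcript and
   whatever else the probes hit. The fraction of the set's retained probes
   overlapping the smORF (the weight $w$) is used as the smORF's share.
2. **Stable proportions.** Within one dataset, the unknown true mixing
   proportions are assumed constant across samples. Under this assumption
   the weight enters the expression estimate only as a multiplicative
   constant on the linear scale, i.e. an additive constant on the log2
   scale, so the smORF's *rank* profile — and hence every Spearman
   correlation, every correlated-gene list, and every predicted term — is
   invariant to the actual value of $w$ (up to which annotations survive
   the $w > 0.1$ filter). This invariance is tested end to end.
3. **Guilt by association.** Enrichment of the smORF's correlated genes in
   a gene set is evidence for the smORF's participation in that set's
   function; pooling counts across datasets accumulates that evidence.

# Procedure

**Reannotation.** Probes are matched exactly (zero mismatches) against
both strands of the genome. A probe is retained iff it has at least one
and fewer than 100 matches; a probe with 100 or more matches is considered
unmappable, and a self-complementary probe counts its single genomic
occurrence once (on the forward strand), not once per strand. Matches are
intersected with smORF intervals strand-agnostically; one shared base
annotates. The weight of a (probe set, smORF) pair is overlapping
retained probes / retained probes of the set.

**Quantification.** Per sample, with surviving weights $w_i > 0.1$
(the boundary $w = 0.1$ is removed — the strict inequality of the
estimator's side condition):
$$E = \log_2 \mathrm{median}\left(w_1 2^{RMA_1}, \dots, w_n 2^{RMA_n}\right).$$
The exponentiation undoes RMA's log2 so weights scale linear signal. With
an even number of surviving probe sets the median interpolates
(`stats::median`). `mean` and `max` summaries are available as options;
`median` is the default. Probe sets mapping to the same gene are collapsed
by their per-sample median before any correlation step.

**Correlated-gene search.** Rows are rank-transformed (ties get their mean
rank), and the correlation distance $1 - \rho$ is used, which for ranked
rows equals one minus the Spearman correlation. $1 - \rho$ violates the
triangle inequality, so the search index is not built on it directly:
each rank vector is centered and scaled to unit norm, where the squared
Euclidean distance satisfies $d^2 = 2(1-\rho)$. This map is monotone, so a
ball tree under the (true) Euclidean metric with an exact radius query at
$d = \sqrt{2(1-\rho_{\min})}$ returns exactly the features with
$\rho \ge \rho_{\min}$ — no approximation is introduced by the tree. Three
equivalent strategies (rank-on-the-fly brute force, pre-ranked brute
force, pre-ranked tree) are exposed and tested for identical output. The
default query keeps at most $k = 1000$ genes at $\rho \ge 0.5$, leaf size
5; negative correlations are not used for prediction by default.

**Enrichment, pooling, selection.** Per dataset $S$: background $T_S$ =
measurable genes ∩ union of all gene-set members; $N_S$ correlated genes
in the background, of which $I_S$ fall in a term of $M_S$ background
members; $p_S$ is the hypergeometric upper tail at $I_S$ (evaluated via
`stats::phyper`, i.e. log-gamma, exact to double precision; validated
against exhaustive enumeration). Across datasets the pooled p is the same
tail at the summed counts $\sum I_S, \sum M_S, \sum N_S, \sum T_S$ — never
Fisher's method. BH FDR is applied across tested terms; terms with pooled
$p \le 0.05$ and $\mathrm{FDR} \le 0.2$ are selected.

# Parameters

| parameter | default | role |
|---|---|---|
| `max_hits` | 100 | probes with ≥ 100 genomic matches are unmappable |
| `weight_min` | 0.1 | annotations with $w \le 0.1$ excluded from quantification |
| `estimator` | median | summary over weighted linear signals |
| `leaf_size` | 5 | ball-tree leaf size (search exactness is unaffected) |
| `k` | 1000 | maximum correlated genes per dataset |
| `rho_min` | 0.5 | minimum Spearman correlation of a hit |
| `p_max` | 0.05 | pooled-p selection threshold |
| `fdr_max` | 0.2 | BH FDR selection threshold |
| `fdr_family` | collection | BH family: per collection, or `all` jointly |

# Numerical and design choices

- **Coordinates** are 0-based half-open (BED) everywhere internally; the
  BED reader is the single coordinate entry point. Interval intersection
  ignores strand (probes report the strand of their match, but a one-base
  overlap annotates regardless of orientation).
- **Weight denominator.** "Probes of the set" is read as the probes
  surviving the match filter; `annotate_probesets(denominator = "all")`
  divides by all probes originally in the set instead, for users whose
  platform tables include unmappable probes they wish to count.
- **Rho ties.** Sorting and the $\rho \ge \rho_{\min}$ threshold compare
  $\rho$ at $10^{-9}$ resolution, with residual ties broken by gene id
  ascending. Distinct Spearman values on at most a few hundred samples
  differ by far more than $10^{-9}$, so this merges only floating-point
  noise between computation routes and makes results reproducible across
  strategies and platforms.
- **Degenerate inputs.** Features whose values are all tied have no
  defined correlation; they are excluded from the index (and therefore
  from backgrounds built on indexed features) and listed in run metadata,
  never silently given $\rho = 0$. Datasets with fewer than three samples
  are rejected. Terms with no member in a dataset's background are skipped
  for that dataset rather than reported at $p = 1$, keeping the BH family
  meaningful; datasets where the smORF is unquantifiable contribute
  nothing to the pooled sums.
- **BH family.** Whether FDR should be controlled within each collection
  (GO-BP, GO-CC, GO-MF, KEGG, REACTOME panels) or jointly is a genuine
  modeling choice; per-collection is the default because predictions are
  naturally read per panel, and `fdr_family = "all"` switches to a joint
  family.
- **Dataset grouping** into models (tissue/disease) is user-supplied
  configuration (`dataset_model_map`); the statistical machinery is
  agnostic to it.

# The synthetic-fixture generator

`simulation_config()` fixes the study conditions; its defaults are one
smORF measured by two probe sets (weights 0.6/0.4, plus one decoy
annotation at exactly $w = 0.1$ and one probe planted in 100 genomic
copies), 2,000 background genes, 3 datasets of 60 samples, and a 50-gene
module co-expressed with the smORF at Spearman $\rho^* = 0.8$.

- **Genome/platform.** Probes are unique random 25-mers planted at known
  positions (alternately forward and reverse strand); smORF intervals are
  laid over probe slots so every intended overlap count — and hence every
  weight — is exact by construction, under the 303 nt smORF length cap
  (infeasible layouts abort with a sizing hint). Recovery of the truth
  table is therefore a sharp test of the whole reannotation stage.
- **Expression.** Planted co-expression uses a latent Gaussian factor:
  members and smORF probe sets load on the factor with Pearson loading
  calibrated through $r = 2\sin(\pi\rho^*/6)$ (the bivariate-normal
  Spearman–Pearson relation), corrected for attenuation by additive
  measurement noise (`noise_sd`, default 0.3; unattainable combinations
  abort). A `tie_fraction` (default 0.1) of entries is rounded to one
  decimal to exercise the mean-rank path. All randomness derives from the
  single config seed.

What the generator does **not** emulate: probe affinity effects, batch
effects, heavy-tailed or platform-specific noise, correlated background
structure among non-module genes, multi-exon smORFs, and real annotation
error. Passing the planted-truth tests therefore shows the machinery is
correct and sensitive under idealized conditions; it does not certify
recall or false-discovery behavior on real arrays.

# Problem sizes used by the test suite

Unit and property tests run on matrices up to 500 features × 100 samples
(search-oracle equivalence, 20 matrices), exhaustive hypergeometric
enumeration up to $T = 12$, and the planted-recovery study at the default
conditions (2,000 genes × 60 samples × 3 datasets) over 50 replicates per
arm — sizes chosen so the full suite and the acceptance script each finish
in minutes on a single CPU while still exercising every code path at
realistic dimensionality per dataset.

# Known limitations

- smORFs are modeled as single contiguous intervals; multi-exon smORFs
  are out of scope.
- Sequence queries are exact-match only; there is no fuzzy/BLAST search.
- The pipeline starts from RMA-level probe-set matrices; CEL-file
  processing and RNA-seq quantification are out of scope.
- Pooling by summed counts treats datasets as exchangeable draws from one
  urn; strongly heterogeneous datasets (very different backgrounds or
  sample sizes) are weighted implicitly by their counts.
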