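---
title: "Models and design choices in AREmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in AREmd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AREmd)
```

# The biological problem

AU-rich elements (AREs) are destabilizing cis-regulatory sequences in mRNA
3'UTRs, typically one or more AUUUA pentamers embedded in AU-rich context.
ARE-binding proteins of the TIS11/tristetraprolin family recognize these
elements and recruit deadenylation and decay machinery (ARE-mediated decay,
AMD). Under oxygen shifts this pathway shapes the transcriptome: transcripts
induced during hypoxia are disproportionately ARE-containing, and their
clearance upon reoxygenation depends on the TIS11-family protein whose own
level recovers with oxygen.

`AREmd` implements the computational side of this analysis as a reusable,
tested pipeline: ARE scoring of 3'UTRs, enrichment testing of regulated
transcript sets against randomized expressed-gene backgrounds, a genotype
contrast of reoxygenation repression, and mRNA half-life estimation from
transcription-shutoff time courses. A synthetic-data module generates every
input the pipeline consumes, so all stages are testable without sequencing
data.

# ARE scoring

## Model

For a normalized RNA sequence (upper-case, U-based; `normalizeAlphabet()`),
the score of a 3'UTR is assembled additively:

* one `pentamerWeight` (default 1) per AUUUA occurrence, overlapping
  occurrences each counted (AUUUAUUUA = 2 hits) — functional AREs typically
  consist of multiple close or overlapping pentamers, and a lone pentamer
  is the minimal unit;
* one `clusterBonus` (default 1.5) per consecutive pair of hits whose
  start-to-start distance is at most `clusterMaxGap` (default 10 nt).
  Counting consecutive pairs only (a run of k clustered pentamers yields
  k − 1 pairs, not all k(k−1)/2 pairs) keeps the score linear in pentamer
  count;
* one `auBlockBonus` (default 0.85) per AU-rich block lying within
  `auBlockMaxDist` (default 25 nt) of any hit. A block is a maximal
  interval obtained by merging every window of `auBlockMinLen` (default
  20 nt) whose A+U fraction is at least `auBlockMinFraction` (default
  0.9). Operationalizing "maximal AU-rich region" as the union of
  qualifying fixed-length windows makes the definition deterministic and
  order-independent; the merged interval may dilute slightly below the
  window threshold, which we accept as the natural closure of the window
  criterion.

The decomposition identity
`score = nPentamers·w + nClusterPairs·c + nAuBlocks·b` holds exactly for
every scored sequence, and `score == 0` iff no pentamer is present: AU
context alone never scores, because blocks only count near a pentamer.

The anchor of the default parameterization is that a single isolated AUUUA
in non-AU context scores exactly 1, and a score of 2 — reachable only
through clustering or AU context — marks the minimal functional ARE. The
classification threshold is boundary-inclusive (`score >= 2`). All weights
are exposed in `AREScoreParams()`, so recalibration against any external
scoring convention changes configuration, not code.

Coordinates: positions inside R objects are 1-based `IRanges` (the
Bioconductor convention); every tabular output and the `pentamerStarts()`
accessor use 0-based, half-open coordinates, which keep interval
arithmetic unambiguous in exported files.

Ambiguity letters (N, R, Y, ...) are preserved through normalization but
never match inside a pentamer and never count as A/U in block detection:
the scorer must not invent a motif. Only the forward strand is scanned, as
AREs act in the mRNA as written.

# Enrichment testing

The regulated sets are selected from upstream differential-expression
tables with strict cutoffs (|FC| > 1.5 on the linear scale and FDR below
the per-contrast threshold; boundary values excluded, matching the ">"/"<"
convention of the source analyses). Gene sets are expanded to all isoform
transcripts — enrichment is computed at transcript level, since isoforms of
one gene can differ in their 3'UTRs; a gene-level collapse (max isoform
score) is available in `joinGenotypes()` where a per-gene quantity is
needed.

Backgrounds are drawn uniformly without replacement from the expressed
universe (genes with at least `minReads = 10` in any sample of either
oxygen condition), 900 genes per draw by default, two independent draws
per run, each reproducible from its seed.

Two complementary comparisons are made:

* **ECDF/KS** — cumulative score distributions compared by the two-sided
  two-sample Kolmogorov–Smirnov test. The reported p-value is asymptotic
  (effective size n1·n2/(n1+n2)), appropriate at the sample sizes of this
  design; whether the original analyses were one- or two-sided is not
  stated anywhere we could verify, so the standard two-sided sup-distance
  is used and recorded in the output provenance. An exact-permutation
  option (full enumeration of label assignments) exists for small samples
  and is cross-checked in the tests against the exact conditional null
  distribution.
* **Dichotomized χ²** — each group split at score < 2 vs ≥ 2, pairwise 2×2
  χ² tests with 1 df and no continuity correction (sample sizes here are
  hundreds to thousands; expected cells below 1 are flagged in the result
  rather than silently switching tests). Bonferroni correction
  `p_adj = min(1, m·p_raw)` with family size m defaulting to the number of
  comparisons performed; all pairwise contrasts of the four standard
  groups (up, down, two randoms) give the six-comparison family.

# Genotype contrast of reoxygenation repression

For the same contrast (reoxygenation vs hypoxia) measured in control and
knockout cells, `joinGenotypes()` inner-joins the two DE tables (dropped
ids are reported, never silently discarded). The KS contrast runs on the
default restriction "control-downregulated ARE transcripts" (FDR < 0.05,
FC < −1.5, score ≥ 2), all configurable.

"Greatest difference in repression" is operationalized as
`delta = log2fc_ko − log2fc_ctrl`, positive when control represses more.
No formula is stated in the source analyses for this ranking; the log2
difference is symmetric, matches the log2 axis on which such fold changes
are reported, and is recorded in output provenance. Ties break
lexicographically by id, so the ranking is a deterministic,
permutation-invariant function of its input set.

# Half-life estimation

Time courses are normalized as
`normalized[i] = 100 · (target[i]/reference[i]) / (target[0]/reference[0])`,
which cancels loading artifacts exactly and pins the pre-shutoff value to
100. The decay model is one-phase exponential with both asymptotes fixed,
`Y(t) = 100·exp(−k t)` (initial value 100, plateau 0), leaving the decay
rate k as the single free parameter; `t1/2 = ln 2 / k`.

The loss is least squares on the normalized linear scale — the standard
"one-phase decay" nonlinear regression — not on the log scale; the
log-linear closed form through the origin is kept as an independent test
oracle only. The optimum is located by golden-section search on
[0, 50·ln2/min Δt] and polished by Newton iterations on the stationarity
condition to a relative tolerance of 1e−12 in k, which recovers noiseless
inputs to better than 1e−8 relative error. A series whose least-squares
optimum sits at k ≤ 0 (flat or rising signal) is flagged `unbounded` with
infinite half-life instead of raising an error, so stable transcripts flow
through batch analyses. The t = 0 point is included in the fit; its
residual is zero by construction under this model.

Replicate time courses are fitted individually; summaries across
replicates are left to the caller (per-replicate fits plus a mean of fits
are easy to assemble, and pooling would hide replicate-level variance).

# The synthetic-data generator

The generator produces data with exactly the statistical structure the
analysis assumes, which defines what passing tests demonstrate — and what
they do not.

* `generateUTR()` plants an exact number of AUUUA motifs at fixed spacing
  in a background of controlled A+U composition, rejection-resampling the
  background until a rescan finds exactly the planted hits. ARE identity
  of a synthetic gene is therefore structural: the scoring engine is
  exercised, never bypassed by labels.
* `scrambleSequence()` permutes a sequence's characters (composition
  multiset preserved) and, by default, resamples until the permutation is
  motif-free — the scrambled-control construction.
* `generateExperiment()` emulates the two-condition × two-genotype design
  in biological triplicate: 20% of genes ARE-positive (three clustered
  pentamers in AU 0.6 context; non-ARE genes carry at most a lone
  pentamer in AU 0.45 context), hypoxic induction of mean +2 log2 applied
  to ARE genes with probability 0.5 and non-ARE genes with probability
  0.15 (so the induced set is ARE-enriched, ~45% vs the 20% background),
  10% of remaining genes hypoxia-downregulated, and reoxygenation
  repression of ARE genes of −2 log2 in control vs −0.5 in knockout.
  Baseline expression is lognormal around 100 counts and observations are
  negative-binomial with size 10 — values a bulk RNA-seq practitioner
  would call unremarkable. Gene-level noise (sd 0.25) perturbs each
  planted log2 effect; the knockout fold change is generated as the
  control fold change plus a per-gene delta, so `noiseSd` is the standard
  deviation of the genotype delta itself — the quantity the sensitivity
  ranking consumes. DE tables are produced by a deliberately simple
  estimator (log2 ratio of group means with pseudo-count 0.5, pooled
  label-permutation p-values, BH FDR): upstream DE testing is outside the
  package's scope, and the pipeline only needs well-formed inputs. The
  pooled permutation null is used because 3-vs-3 label splits alone cannot
  resolve p below 1/20.
* `generateTimecourse()` draws multiplicative lognormal noise (mean-1, a
  given cv) around the exponential decay law — blot-type intensities are
  positive, so multiplicative noise is the natural model — and re-pins the
  t = 0 value to 100.

Every generator is a pure function of its arguments and seed (verified
bit-identical across reruns), and never perturbs the caller's RNG stream.

What the generator does **not** emulate: library-size variation and
normalization, isoform-level expression differences, count-model
dispersion trends, secondary-structure context of motifs, and correlated
noise across conditions. Passing tests therefore demonstrate correctness
of the statistical machinery under the stated model, not robustness to
every artifact of real sequencing data.

# Numerical and scale choices

* Problem sizes in the test-suite simulations (hundreds of genes per
  synthetic experiment, 200 power replicates, 500 decay replicates,
  10,000 motif-scan comparisons) are chosen so the full suite runs in
  roughly two minutes while keeping Monte-Carlo standard errors well below
  the margins being asserted.
* The dichotomized power setting (background 20% ARE-positive at n = 2000
  vs 40% at n = 500, α = 0.01) and the ranking setting (30 planted genes
  with Δ = 1 log2, noise sd 0.25, among 250 ARE genes — mirroring the
  ~250 ARE genes from which a top-30 is drawn in this kind of analysis)
  are fixed study conditions, not tuning knobs.
* χ² with one degree of freedom equals the squared two-proportion z
  statistic; this identity is asserted in the tests as a cross-check.
* All file outputs are TSV with headers plus JSON sidecars; every run
  directory contains a manifest with the resolved configuration, seeds,
  package version and input checksums sufficient to reproduce the run
  bit-for-bit (timestamps live only in the manifest, never in reports).

# Known limitations

* The shipped scoring weights are this package's defaults, anchored at
  the lone-pentamer score of 1 and the functional threshold of 2; they
  are not calibrated against any external web tool's unpublished
  parameter values. Scores for richly structured UTRs may therefore
  differ from other scorers in the bonus terms while agreeing in rank
  ordering for typical architectures.
* The internal DE estimator is intentionally plain; analyses of real
  count data should feed the pipeline tables from a dedicated DE package.
* The one-phase model fixes both asymptotes; transcripts with a genuine
  plateau (incomplete decay) will show lack of fit in `rss` rather than a
  plateau estimate.

# A worked example

```{r example, eval = FALSE}
sim <- generateExperiment(nGenes = 300, seed = 42)
scores <- scoreTranscriptome(sim$db)
up <- expandToIsoforms(
  selectRegulated(sim$de$hypoxia_vs_normoxia_ctrl, "up",
                  fcThreshold = 1.5, fdrThreshold = 0.01), sim$db)
universe <- expressedUniverse(sim$counts, minReads = 10)
bg <- sampleBackground(universe, nGenes = 100, seed = 1, db = sim$db)
scoreOf <- setNames(scores$score, scores$transcript_id)
ksTwoSample(scoreOf[up@transcriptIds], scoreOf[bg@transcriptIds])
dichotomizedEnrichment(list(up = scoreOf[up@transcriptIds],
                            background = scoreOf[bg@transcriptIds]))
```
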