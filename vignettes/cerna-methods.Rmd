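---
title: "Methods: ceRNA network inference with cernet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network inference with cernet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem and the model

During the hair-follicle cycle, the transition from anagen (active
growth) to catagen (regression) reshapes the skin transcriptome. The
competing-endogenous-RNA (ceRNA) hypothesis proposes that a lncRNA can
act as a decoy ("sponge") for a miRNA through shared miRNA response
elements (MREs), derepressing the miRNA's mRNA targets. The observable
signature in a two-phase bulk design is a concordant triple: lncRNA and
mRNA moving together, the miRNA moving opposite — *up-down-up* or
*down-up-down* in catagen-vs-anagen orientation.

`cernet` implements this inference as a cascade of testable stages, each
with an explicit statistical contract, and ships a synthetic-data
generator whose planted ground truth lets the whole cascade be validated
end to end.

# Stages and their assumptions

## Novel lncRNA identification

Five sequential criteria over assembled transcripts: (1) at least 2
exons; (2) spliced length strictly greater than 200 bp; (3) known
lncRNAs set aside into the known catalog, only unknown transcripts
continue; (4) maximum FPKM across samples at least 0.5; (5) noncoding by
the *intersection* of all supplied coding-potential predictors.
Transcripts that fail unanimity without being called coding by every
predictor are classed as TUCP and reported separately.

Two wording ambiguities are resolved as follows and exposed as
parameters: the length criterion uses *spliced* transcript length (not
genomic span), and the expression criterion aggregates by the *maximum*
across samples — the most permissive reading of "quantification of each
transcript no less than 0.5" consistent with per-sample FPKM tables.

The built-in predictor scores the longest ATG→stop open reading frame
over the three forward frames (transcript sequences are sense-strand, so
no reverse-strand scan) and calls coding at ≥ 100 codons. It is a
deliberately simple, fully specified surrogate for external
coding-potential tools; the predictor slot accepts any
`function(ids) -> calls` closure, and the intersection rule means adding
predictors can only shrink the novel set.

## Differential expression

The DE engine is a documented surrogate, not a count model: Welch's
t-test on `log2(x + 1)` across the 3-vs-3 replicates, with group-level
abundance the arithmetic replicate mean and
`log2FC = log2(catagen / anagen)` (no pseudocount by default). DE is
called at p < 0.05, strict; q-values are Benjamini–Hochberg. Degenerate
ratios are carried explicitly: `+Inf`/`-Inf` when one group mean is
zero, `NaN` (direction *undefined*) when both are.

Numerical edge policy: a feature identical in all samples gets p = 1; a
feature constant within each group but different between groups has zero
within-group variance and is treated as perfectly separated, p = 0. This
makes noise-free simulations exactly recoverable rather than NaN-ridden.

Calibration note (computed in the acceptance suite): at n = 3 per group
Welch's test is conservative — its true size at α = 0.05 is ≈ 0.035, so
a 500-simulation empirical rate estimate sits near the lower edge of the
[0.03, 0.07] calibration band.

The `2^-ΔΔCt` utility implements standard qPCR relative quantification
against a reference gene and calibrator sample, for comparing assay fold
changes with sequencing fold changes on the same scale.

## lncRNA targets

*Cis*: for each lncRNA locus (min exon start to max exon end), coding
genes whose merged gene span lies within or overlaps the locus ± w for
w ∈ {10 kb, 100 kb}; both directions searched, strand ignored. Distance
is 0 for overlap, otherwise the signed difference between nearest span
edges (positive = gene downstream on the genome axis); each pair is
labelled with the smallest containing window. Gene spans (not TSSs)
anchor distances, and windows are evaluated on GTF-native 1-based
inclusive coordinates throughout.

*Trans*: Pearson correlation of every lncRNA × coding-gene pair across
all six samples pooled (pooling is the only reading that gives p < 0.01
any power at r ≥ 0.95 with these sample sizes), exact two-sided p from
`t = r·sqrt((n−2)/(1−r²))` on n−2 df, and BH over the *full* pair family
(matching a single global FDR statement). A pair is retained iff
|r| ≥ 0.95, p < 0.01 and q < 0.01. With n = 6 (4 df) and ~4×10⁴ pairs,
the global FDR gate is by far the binding constraint: q < 0.01 requires
p ≲ 10⁻⁶, i.e. |r| ≳ 0.996 unless many true pairs share the top ranks.
This is a real power limitation of these published thresholds at this
design size, not an implementation artifact; the screen is monotone in
all three thresholds.

## miRNA response elements

Canonical seed sites in the TargetScan convention, built from the miRNA
seed (positions 2–8, with the 2–7 core): `8mer` = reverse complement of
m2–m8 followed by a literal A, `7mer-m8` = rc(m2–m8), `7mer-A1` =
rc(m2–m7) + A, `6mer` = rc(m2–m7). The A1 anchor is a literal A in the
target regardless of the miRNA's first nucleotide. All matching is in
the DNA alphabet (U normalized to T on load). Each target position is
reported once with its highest-priority type
(8mer > 7mer-m8 > 7mer-A1 > 6mer); overlapping sites at distinct
positions are all reported — consequently a planted 8mer always carries
an inherent 7mer-A1 one position downstream. Non-canonical sites (G:U
wobble, offset/centered sites) and context scoring are out of scope;
site presence is binary. The search region is the full transcript for
both lncRNAs and mRNAs — a 3'UTR-only mode would be the TargetScan
default for mRNAs, but UTR annotation in non-model genomes is too
incomplete to rely on.

A shared MRE — one miRNA with at least one site on a lncRNA and one on
an mRNA — is the structural precondition for a ceRNA triad.

## Triad assembly and export

A triad (lncRNA decoy, miRNA center, mRNA target) is emitted iff all
three molecules are DE, a shared MRE exists, and the lncRNA–mRNA pair
passed the trans screen with r > 0 (the ceRNA hypothesis demands
positive decoy–target co-expression; the gate is a flag).
miRNA–mRNA anticorrelation is *not* numerically enforced — miRNA TPM and
transcript FPKM live in different normalizations — direction opposition
enters through the pattern rule instead. Of the eight direction triples
exactly two are concordant; discordant triads are suppressed unless
requested. Triads are transcript-level and collapse to gene level only
in the gene-centric report, which splits each gene's lncRNA partners
into cis (also genomic neighbours) and trans columns. Export is SIF
(two edges per triad, deduplicated) and GraphML with node type/shape
(triangle = lncRNA, circle = miRNA, square = mRNA) and direction
attributes.

## Enrichment

Over-representation by the exact hypergeometric upper tail P(X ≥ k)
with BH correction and rich factor k/K. The population is the expressed
background (features passing the configurable FPKM floor), not the whole
annotation. Gene-length bias correction (GOseq-style Wallenius) is not
implemented — a known limitation. Note the exact-tail monotonicity:
enlarging the population with irrelevant genes makes a fixed overlap
*more* surprising (p non-increasing in N).

# The synthetic data generator

`simulate_dataset()` emulates the 3-vs-3 anagen/catagen design on a
single synthetic chromosome. What it plants, and how:

* **Expression**: `log2` values are group means (baseline
  `mu ~ U(1, 8)` for lncRNAs, `U(2, 8)` for coding, log2 FPKM units)
  plus the planted log2 fold change for DE features (magnitude
  `|N(3, 0.5)|`, planted sign), plus i.i.d. log-normal noise
  (`noise_sd`, default 0.5 log2 units — a typical between-replicate
  spread for bulk RNA-seq at moderate expression).
* **Trans pairs**: partners share a per-sample latent factor
  (`latent_sd` = 0.4) *and* share their noise up to a small residual
  (`trans_resid_frac` = 0.05 of `noise_sd`), and carry an equal planted
  fold change. At `noise_sd = 0` the partners are exactly proportional
  (r = 1); under study noise their expected r (recorded per pair in the
  manifest as `target_r`) is ≈ 0.9995, chosen so planted pairs clear the
  full trans screen *including* the global-family FDR gate discussed
  above. This models tight co-regulation, which is what "planted
  high-correlation pair" must mean for the thresholds to be satisfiable.
* **Cis pairs**: unrelated loci are tiled with gaps larger than the
  biggest window (250 kb + jitter), so window membership is exact by
  construction; planted neighbours are placed at known signed distances
  inside the 10 kb or 100 kb class.
* **Sequences and triads**: the miRNA catalog has pairwise-distinct seed
  cores; every non-planted transcript sequence is rejection-sampled to
  contain *no* ≥ 6mer match for any catalog miRNA (a condition stricter
  than excluding 7mers, adopted so that every shared MRE in the dataset
  is planted and "zero false triads" is structural rather than a seed
  accident); triad lncRNAs and mRNAs carry one planted 8mer each for
  their miRNA, with junction effects and cross-miRNA collisions re-rolled.
  Coding sequences embed a 120-codon ORF (UTRs around it); noncoding
  sequences are verified below the 100-codon calling threshold.
* **Filter decoys**: small sets of single-exon, ≤ 200 bp (one exactly at
  the boundary), low-FPKM and coding-like-but-unknown transcripts
  exercise each funnel step.

Everything derives from one seed; the same seed reproduces every output
file byte-identically. What the generator does **not** emulate: read-level
sampling noise and its mean–variance relation, fragment/GC bias,
isoform complexity (one transcript per gene), miRNA-mediated repression
feeding back into expression levels, and any real genome structure.
Passing tests therefore demonstrate correctness of the inference
machinery under a clean planted-truth model — not performance on real
sequencing data.

# Validation strategy and problem sizes

The test suite checks every operation against independent oracles:
naive all-substring scans for seed sites, a quadratic all-pairs distance
scan for cis windows, a codon-walking state machine for ORFs, the
combinatorial sum for hypergeometric tails, `stats::cor.test` for
correlation p-values, and hand-computed BH examples. End-to-end
recovery is asserted on a noise-free full-size dataset (~500 transcript
features, 30 miRNAs, 3-vs-3) — 100% of planted DE features, trans pairs
and triads, zero false triads — and on smaller configurations for
per-module checks; noise-robustness is a monotone-degradation property
over a noise grid with replicate seeds, not a fixed-recall claim. The
published top-DE lncRNA abundance table shipped with the package
validates the fold-change convention to printed precision. These sizes
keep the full suite under a minute on one CPU while exercising every
stage at the study's design dimensions.

# Known limitations

* The DE surrogate ignores count overdispersion structure; it is
  pluggable by design and conservative at n = 3.
* Seed-site prediction is binary and canonical-only; no context scores,
  conservation, or thermodynamics.
* The trans screen's global-FDR gate has very low power at n = 6 (see
  above); per-lncRNA families or larger designs would behave
  differently.
* Enrichment lacks gene-length bias correction and GO-DAG topology.
* The ceRNA calls are correlational evidence assembled from DE,
  co-expression and shared sites — not causal inference.
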