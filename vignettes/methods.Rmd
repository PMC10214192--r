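---
title: "Methods: screening splicing profiles for immunotherapy targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening splicing profiles for immunotherapy targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicescreen)
```

# The model

`splicescreen` treats an alternative-splicing event as a binary choice
between two isoforms (inclusion vs skipping of an alternative segment),
quantified two ways: as a ratio — the percent-spliced-in (PSI) of the
inclusion isoform — and as counts — reads spanning each splice junction
(SJ). The two views carry the same biological signal but different
statistical behaviour, and the screens deliberately use both:

* The **tumor-association screen** works on PSI. For each event and each
  normal tissue type it runs a two-sample t test (Welch by default;
  pooled variance available because published analyses have used it) and
  computes ΔPSI as the difference of group means. A comparison counts as
  significant only if *both* p < `psi_p_threshold` (0.01) and
  |ΔPSI| > `delta_psi_threshold` (0.05, strict) hold — the ΔPSI gate
  keeps statistically significant but biologically negligible shifts out.
  The *degree of tumor association* is the number of normal tissues with
  a significant comparison in the consistent direction, and an event is
  tumor-associated at degree ≥ `association_degree_min` (8 of an
  11-tissue panel by default).
* The **tumor-specificity screen** works on junction counts, because a
  truly tumor-specific junction should be *absent* from normal tissue,
  not merely lower. Each sample either expresses a junction (count at or
  above a role-specific threshold: 5 for tumor, 2 for normal samples) or
  does not; a one-sided Fisher exact test per normal tissue asks whether
  the expressing fraction is higher in tumor. A junction is
  tumor-specific when p < 10⁻⁶ in at least 8 tissues, and an event only
  inherits the label when **every** junction of its tumor-enriched
  isoform is specific — one shared junction with normal transcripts
  disqualifies it.
* The secondary **CPM screen** normalizes junction counts to counts per
  million (count × 10⁶ / total mapped reads) and requires one-sided
  (tumor-greater) t significance in ≥ 8 tissues for every junction of
  the tumor-enriched isoform; it captures the joint effect of expression
  and splicing.
* The **recurrence screen** asks whether the association replicates in
  auxiliary cohorts of the same tumor type. The original procedure is
  not public; the rule implemented here — tumor-associated against the
  same normal panel, at the same thresholds, in the same direction, in
  *every* configured auxiliary cohort — is a documented, non-canonical
  stand-in.

Downstream, the tumor-enriched isoform (inclusion if tumor PSI is
consistently higher, skipping otherwise) is translated into a junction
peptide, chopped into HLA-I-sized windows that overlap the junction,
scored for HLA binding, and filtered into a validation shortlist.

# Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `psi_p_threshold` | 0.01 | p-value | published default of the PSI screen |
| `delta_psi_threshold` | 0.05 | PSI | minimum biologically meaningful shift; strict `>` |
| `association_degree_min` | 8 | tissues | of an 11-tissue panel; tolerates a few brain-like outlier tissues |
| `specificity_count_tumor` / `_normal` | 5 / 2 | reads | "expressing" uses ≥ (at-or-above); asymmetry favours sensitivity in normals |
| `specificity_p_threshold` | 1e-6 | p-value | Fisher test must be near-certain before a junction is called absent from a tissue |
| `min_tumor_nonmissing` | 3 | samples | below this the tumor mean is meaningless; event left untested |
| `fc_denominator_floor` | 0.01 | proportion | keeps fold-changes finite for isoforms absent from normals (flagged) |
| IC50 positive call | < 500 | nM | strict; the standard weak-binder cutoff |
| epitope lengths | 9, 10 | residues | typical HLA-I ligand lengths; the source analysis never states its windows |
| microexon cutoff | ≤ 30 | nt | field convention, inclusive |
| shortlist FC / FPKM | ≥ 2 / ≥ 20 | — / FPKM | published validation-selection filters, inclusive |

# Numerical and design choices

**Coordinates.** One canonical junction key — chromosome, first and last
intronic base (1-based, inclusive), strand — is used everywhere; rMATS
exon coordinates (0-based starts) are converted at read time. This
prevents off-by-one joins between event tables and STAR junction files.

**Masking.** PSI estimates for an event whose junctions average fewer
than `min_avg_total = 10` reads in a sample group are set to missing.
Granularity is per group by default (per sample available): group-level
masking is the interpretation that keeps a tissue type's testability an
all-or-nothing property, which in turn makes "untestable tissue" a clean
category for the degree computation. Untestable comparisons count as
non-significant, never as disqualifying — missing data is not evidence.

**Direction consistency.** "Consistently higher or lower" is read
strictly: a single significant comparison in the opposite direction
disqualifies the event, however high the degree. This is the strictest
defensible reading and prevents mixed-direction artifacts from reaching
the target list.

**Zero-variance t tests.** When both groups are constant the test
returns p = 1 for equal means and p = 0 otherwise (the limit behaviour);
constant-but-different groups therefore count as significant. Welch and
pooled statistics are computed in closed form, vectorized across events,
which keeps a 500-event × 11-tissue screen in milliseconds and is
verified against `stats::t.test` to 1e-10 in the test suite.

**Fisher p-values** are the one-sided hypergeometric upper tail
(`phyper`), verified against both `stats::fisher.test` and a brute-force
enumeration of all 2×2 tables with total ≤ 60 (tolerance 1e-12).

**Fold-change.** Normal tissues enter the FC denominator with equal
weight regardless of sample count (the panel is a set of tissue types,
not a pooled population). Denominators below 0.01 are floored and
flagged rather than allowed to explode.

**Multiple testing.** No correction enters any call — the screens use
raw p-value thresholds by design (the degree requirement is itself a
strong conjunction filter). A BH-adjusted minimum p per event is emitted
for information only.

**Translation.** The reading frame comes from annotated CDS intervals of
a coding transcript covering the exonic base immediately upstream
(transcript orientation) of the junction; ties break deterministically
(longest CDS, then lexicographic transcript id). The peptide window is
up to 10 complete codons per side plus the phase-split codon, so the
nominal length is 21 aa (20 for phase-0 junctions, where the junction
falls between codons). Skipped exons whose length is not a multiple of 3
frameshift the downstream flank; translation proceeds in the upstream
frame within the window. Retained-intron inclusion peptides read through
the exon–intron boundary. Translation stops at the first stop codon
(flagged), shrinks at exon boundaries (flagged), and truncates at the
first ambiguous base (flagged). Retained-intron events additionally
carry two 1-bp "boundary pseudo-junctions" so the specificity screen has
count keys for the retained isoform; with STAR input these are absent
(all-zero) and RI events are conservatively never tumor-specific.

**HLA binding is not re-implemented.** Real predictors are network
services; the package defines an `AffinityPredictor` contract and ships
a deterministic mock (cryptographic hash → log-uniform IC50 in
[1, 50000] nM) for tests. Median summarization over an even number of
tool values uses the midpoint mean. Mock scores carry no biology; tests
built on them verify plumbing (medians, strict thresholds, dedup), never
ranking quality.

**Proteomics.** I/L equivalence is off by default when intersecting
predicted epitopes with MS peptides (MS cannot distinguish them; the
flag exists, but exactness is the safer default). The package consumes
any PSM table with peptide and q-value columns; it never estimates FDR
itself.

# The synthetic world

`synthetic_spec()` defaults describe the stated world the screens were
published against: 11 normal tissue types × 20 samples, a 23-sample
tumor cohort, 500 skipped-exon events, 20 planted tumor-specific events
with ΔPSI = 0.3, a minimum of 3 non-missing tumor values, degree
thresholds of 8.

Per-sample PSI is logit-normal (SD 0.4 on the logit scale, ≈ 0.1 on the
PSI scale near 0.5 — the within-tissue spread typical of well-covered
events in consortium data). Junction depth is negative binomial
(mean 100, size 10) and inclusion/skipping counts are binomial splits of
depth at the sample's PSI, so the ratio and count screens see the same
signal through their own noise. Planted tumor-specific events have
near-zero baseline inclusion, inclusion-junction counts clamped below
the normal expressing threshold (< 2) in every normal sample, and counts
≥ 5 in ≥ 80% of tumor samples; these construction guarantees are
asserted after generation, not assumed.

What the generator does **not** emulate: correlated events within genes,
tissue-specific splicing programs (every normal tissue shares one null
distribution), overdispersed PSI near 0/1 beyond what the logit-normal
gives, read-length effects, and batch structure. A green planted-event
recovery test therefore establishes that the screens implement their
rules correctly with calibrated error rates under clean noise — not that
the thresholds are optimal for real cohorts.

One acceptance criterion deserves a note: the null-calibration criterion
asks that the per-comparison error rate of the compound condition
(p < 0.01 **and** |ΔPSI| > 0.05) match its "analytically expected rate".
That compound rate has no closed form under the logit-normal generator
(it depends on each event's baseline through the PSI-scale noise). The
test therefore asserts the p-condition alone against its exact nominal
rate (binomial 99% CI around 0.01), asserts the compound rate is bounded
by it (it is a strict subset), and asserts the zero-false-call clause
verbatim.

The toy genome is built from explicit codon strings, so every junction
peptide has a known answer; the answer key is produced by an independent
naive oracle (full spliced-mRNA translation via a hard-coded codon
table) while the production path extracts and translates genomic
windows. The two agree on every gene — including phase-1/2 junctions, a
12-nt microexon (exactly 4 contributed residues), a minus-strand mirror
gene, a frameshifting skip, retained-intron read-through, and a
premature stop.

# Known limitations

* Only binary AS event types (SE, A5SS, A3SS, RI); complex or nested
  events are out of scope, as are novel junctions without an annotated
  upstream frame (dropped and counted).
* Per-junction counts derived from rMATS event tables alone are the
  averaged inclusion support (`round(IJC/n_inc)`); supply STAR junction
  files for exact per-junction counts — they take precedence.
* The recurrence rule is a stand-in (see above).
* The mock affinity predictor is plumbing, not prediction; CAR-T calls
  depend entirely on the supplied extracellular annotation.
* Bulk-level screening only: clonality and single-cell heterogeneity of
  targets are invisible at this resolution.
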