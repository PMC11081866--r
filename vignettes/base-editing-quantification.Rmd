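---
title: "Quantifying adenine base-editing outcomes: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying adenine base-editing outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bequant)
```

# What the pipeline computes

Adenine base editors (ABEs) deaminate adenines within a protospacer
editing window; on sequencing a targeted amplicon, each read is one
observation of an edited (or unedited) allele. `bequant` turns a FASTQ
of such reads into per-sample outcome rates. The stages are: read
ingestion and optional pair merging, global alignment to the reference
amplicon, reduction of each alignment to its gapped sequence over a
quantification window, grouping into an allele table, and rate
computation with codon-level bystander annotation.

The central definitions:

- A read is **desired-edit-only** when its only deviation from the
  reference within the quantification window is the target A→G and it
  carries no indel in the indel window. The rate divides by *all*
  aligned reads.
- The **per-adenine rate** at a labelled adenine `A_x` is the fraction
  of aligned reads carrying G at that position (on the protospacer
  strand), excluding — from both numerator and denominator — reads with
  an indel or an N call overlapping that specific position.
- **Outcome classes** are mutually exclusive and partition the aligned
  reads: `indel` (an insertion or deletion overlapping the indel
  window; membership dominates every other label), then
  `nonsynonymous_bystander` (any non-target A→G whose codon consequence
  is nonsynonymous or affects a stop), `synonymous_bystander`,
  `on_target_only`, `wildtype`, and `other` (remaining substitution
  patterns, e.g. isolated sequencing errors). The bystander precedence
  mirrors how outcome plots colour each allele with a single class.
- The **indel rate** counts reads whose left-aligned indel overlaps the
  indel window, divided by all aligned reads. Indel reads are counted
  once — they do not additionally contribute to substitution rates.
  Editing and indel rates are thus parallel, non-overlapping outcome
  categories; the denominator is always the total aligned read count.

## Coordinates and windows

All internal coordinates are 0-based, half-open on the reference
amplicon; HGVS c. positions are 1-based and appear only in the
consequence module. Defaults, overridable per locus:

- `quant_window`: the combined interval of all protospacers at the
  locus. Restricting "only the desired edit" to this window (rather
  than the whole amplicon) keeps the desired-only rate from being
  dominated by sequencing errors far outside the editing window.
- `nick_offset`: canonical SpCas9-nickase geometry — the cut sits
  between protospacer positions 17 and 18, i.e. 3 bp 5′ of the PAM.
- `indel_window`: the union of the protospacer interval and
  `nick_offset ± 3` bp — a window covering both the deamination
  positions and the nick site.
- Adenine labels `A1…Ak` run 5′→3′ on the protospacer strand over the
  union of all protospacer intervals, so numbering is shared across
  editor variants whose guides overlap the same locus.

## Alignment model

Reads are aligned globally with affine gap scoring (Gotoh three-state
dynamic programming, implemented in C++), end-gap free on the read side
so a shorter read may sit anywhere inside the amplicon without penalty.
Defaults: match +2, mismatch −2, gap open −10, gap extend −1, a gap of
length *k* costing `open + k·extend`. With these values a 1-bp indel
(−11) is preferred over three scattered mismatches (−12 counting the
lost matches), so short indels near the nick are called as indels
rather than smeared into substitution columns. `N` scores 0 against
anything and never counts as a match.

Determinism: ties resolve by preferring substitution over deletion over
insertion during traceback, and every indel run is subsequently
left-aligned against its repeat context, so window membership never
depends on traceback internals. Orientation is detected by scoring the
reverse complement as well and flipping when it wins. Alignments with
identity (matching read bases over all read bases) below 0.6 are
rejected and counted; rejected and unmergeable reads are excluded from
the "total aligned reads" denominator, consistent with its name.

Read pairs are merged by the best-scoring ungapped overlap (≥ 10 bp,
+1/−1 match/mismatch, N neutral; the best overlap must score positive).
At disagreeing overlap positions the base with the higher Phred wins
(ties keep read 1), carrying that Phred; agreeing positions sum their
Phreds, capped at 93 (the Phred+33 printable ceiling). No base-quality
trimming or filtering is applied before alignment by default — the
quantification operates on all reads the instrument delivered.

# The simulator and what passing tests mean

`simulate_reads()` draws each read's allele from a declared mixture
(substitution sets, optional indels, proportions summing to 1), applies
independent per-base substitution errors uniformly over the three
non-template bases, and emits Phred+33 FASTQ plus the per-read allele
labels. One seed controls allele assignment, error positions and error
base choice; identical seeds give byte-identical files. Paired mode
produces perfectly overlapping opposite-strand mates with independent
errors, exercising the merge arbitration rule.

`spiked_truth()` encodes the canonical validation mixture — a
desired-edit-only allele, a bystander allele carrying the desired edit
plus one nonsynonymous A→G, a 1-bp deletion at the nick, and wildtype —
with defaults shaped like endpoint cortex editing in a treated mouse
model: 45.9% correction, 4.8% nonsynonymous bystanders, 0.1% indels.

On error-free simulations the quantifier must reproduce the simulator's
per-read label counts *exactly*, and the test suite asserts this. Under
sequencing error the desired-only class is intrinsically biased
downward: any error among the ~20 window positions removes a read from
the class, an expected relative loss of about `1 − (1−e)^20` (≈ 9.5% at
e = 0.005). Comparing the recovered rate against the nominal mixture
proportion would therefore conflate sampling noise with a deterministic
classification effect. The recovery tests instead compare against the
closed-form expectation under the error model — for each allele, the
product over window positions of the per-position agreement probability
(`1−e` where the allele already matches the desired pattern, `e/3`
where an error must hit exactly right) — and require agreement within 4
binomial standard errors at n = 10,000 over 20 seeds.

What the simulator does *not* emulate: PCR chimeras and amplification
bias, instrument-specific error spectra (errors are iid and uniform),
position-dependent quality decay, and large structural rearrangements.
Passing tests therefore demonstrate correctness of the quantification
given reads that differ from an allele by iid substitutions — not
robustness to every artefact of real libraries.

# Consequence annotation

Bystander substitutions are mapped to coding positions through a locus
anchor (a reference offset paired with its c. position and the coding
strand); only the local CDS segment overlapping the amplicon is
required, and splice effects are ignored — the supported amplicons are
intra-exonic. On a minus-strand CDS the substitution is complemented
before codon substitution. Translation uses the standard genetic code
(table 1; the loci are nuclear). Stop gains and losses are labelled
distinctly and grouped with nonsynonymous changes for class precedence.
Substitutions mapping outside the supplied segment are `noncoding`;
alleles whose only bystanders are noncoding fall into `other`, since no
synonymous/nonsynonymous call is possible (this is the situation at
intronic off-target sites, where only per-adenine rates are
meaningful).

# Off-target search

`find_candidate_sites()` scans both strands of supplied sequences for
windows within a Hamming-distance ceiling of the protospacer adjacent
to an IUPAC PAM match. The default ceiling of 6 mismatches is the
threshold used when verifying nominated sites by targeted amplicon
sequencing; discovery screens may raise it. Hits within 3 bp are merged
keeping the lower-mismatch representative; ranking is by (mismatch
count, contig, position). Bulged sites (`allow_gaps = TRUE`) are found
by anchoring on PAM-valid positions and testing bounded Levenshtein
alignments of the upstream window over lengths within the gap threshold
— a Hamming prefilter would be unsound here because a single bulge
shifts every downstream base. Read-level parameters of the wet-lab
discovery pipeline (mapping quality, start-position thresholds) have no
in-silico counterpart and are recorded as out-of-scope constants rather
than imitated. The search is desk-scale by design: provided contigs up
to megabases, not indexed whole-genome scanning.

Editing at a nominated site is quantified by deriving an amplicon spec
around the site (`off_target_amplicon_spec()`) and running the standard
stack; no consequence calls are made there.

# Statistics

`pearson()` reports the product-moment correlation with a two-sided p
value from the t transform (n−2 df) and a 95% confidence interval via
the Fisher inverse-hyperbolic-tangent transform, delegating to
`stats::cor.test`; `welch_t()` delegates to `stats::t.test` with
Satterthwaite degrees of freedom. Both are verified against
direct-formula oracles to 1e-12. ΔΔCt fold changes normalise each
sample's Ct to a reference gene, average within groups, difference
against the calibrator group and return `2^−ΔΔCt`; the calibrator
against itself is exactly 1 for any table. Omnibus ANOVA-family tests
are deliberately not re-derived — base R provides them.

Reported percentages and folds round half away from zero to one decimal
(`round_report()`: 1.25 renders as 1.3), while stored values stay
unrounded — this reconciles figure-style printed values with exact
machine output. Two printed endpoint values illustrate why the
distinction matters: from printed group means, the female bodyweight
increase computes to 5.9% (a manuscript printing 5.7% evidently used
unrounded underlying data), and a 6.0/4.8 dose ratio computes to 1.25,
rendered 1.3. The package asserts only the arithmetic on the printed
means and documents the discrepancy rather than chasing unpublished
precision.

The phenotype cohort generator plants its heterozygous-stratum
bodyweight~bystander correlation *exactly* (residual-orthogonalisation
construction) at a default magnitude of 0.54, the scale reported for
endpoint cohorts of about 24 animals, so correlation recovery can be
asserted against a known value rather than a noisy estimate. Phased
assignment of bystander edits to the wildtype versus mutant allele in
heterozygotes is not implemented — read-level data cannot resolve it
without a phasing rule, so per-allele breakdowns remain reporting-only.

# Numerical and scale choices

Degenerate inputs are errors, not silent results: empty FASTQ samples,
zero accepted alignments, zero-variance correlations, proportions not
summing to 1, out-of-range ataxia items. Allele display filtering
(default 0.20% frequency) affects rendered reports only; summary
statistics always use the unfiltered table.

Test problem sizes were chosen so the full suite runs in minutes on one
core while keeping binomial standard errors small enough to be
informative: 20,000 reads for exact round-trip checks, 20 seeds ×
10,000 reads for error-model recovery, 200 random pairs (length ≤ 12)
against an exhaustive alignment oracle, all 576 codon substitutions
against an independent genetic-code oracle, and 50 kb with five planted
sites (0–6 mismatches) against a brute-force search oracle.

# Known limitations

- No base-quality-weighted calling and no UMI deduplication; every
  aligned read counts once.
- Cytosine-editor (C→T) chemistry is structurally supported but
  untested.
- The demonstration locus is synthetic; analysing a real locus requires
  its amplicon reference, protospacer geometry and CDS anchor from the
  experiment.
- Multi-exon CDS stitching, protein-effect prediction and conservation
  scoring are out of scope.
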