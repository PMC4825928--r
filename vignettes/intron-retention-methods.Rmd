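---
title: "Quantifying intron retention and splicing efficiency from spliced alignments"
author: "spliceff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intron retention and splicing efficiency from spliced alignments}
  %\VignetteEncoding{UTF-8}
---

## The problem and the statistic

In intron-rich fungal genomes, loss of spliceosome-regulatory kinases does
not abolish splicing but degrades its efficiency: a fraction of transcripts
retain individual introns. Bulk RNA-seq measures this directly. For a
predicted intron $i$ within transcript $t$, the **intron retention level**
is

$$\mathrm{IR}_i = \frac{n_{\mathrm{intron}}(i)}{n_{\mathrm{transcript}}(t)}$$

where $n_{\mathrm{intron}}$ counts reads whose aligned blocks overlap the
intron by at least one nucleotide and $n_{\mathrm{transcript}}$ counts
reads aligned to the transcript's genomic span. Low IR means efficient
splicing; an $x$-fold *reduction in splicing efficiency* is operationalized
throughout as an $x$-fold *increase* in IR — the two phrasings are used
interchangeably in this field.

Counting rules (all configurable):

* A read is assigned to a transcript when any aligned block (CIGAR `M` run)
  overlaps the transcript span — exons plus introns — by at least
  `min_overlap` (default 1) nt. Retained-intron reads must be in the
  denominator, otherwise IR could exceed 1.
* A read counts toward an intron when any block overlaps it by at least
  `min_overlap` nt. Reads whose `N` gap spans the intron are **junction**
  evidence of the spliced form and never count as intron reads, keeping the
  numerator retention-only evidence.
* A junction read for intron $i$ must have a gap matching $[start, end)$
  exactly; a gap off by one nucleotide is not counted.
* Read strand is ignored (unstranded libraries).
* Genes are filtered by expression: CPM $= 10^6\, n_g / N$ with inclusive
  threshold (default CPM $\geq 10$ in *every* sample; a permissive CPM
  $\geq 1$ variant is available via `cpm_threshold = 1` — both conventions
  circulate for "detectable expression" and the stricter one drives the
  headline fractions here).

## Differential classification with replicate concordance

For each intron passing the filter, a fold change is computed per
replicate pair,

$$\mathrm{FC}_r = \frac{\mathrm{IR}^{\mathrm{test}}_r + \varepsilon}
                       {\mathrm{IR}^{\mathrm{ref}}_r + \varepsilon},$$

with pseudocount $\varepsilon = 0.001$ applied to the IR ratio (not to raw
counts) to absorb zero denominators. The intron is binned by the **minimum**
FC across replicates — the strictest reading of "in both replicate
experiments": a threshold counts only if met in every replicate. Assigned
bins partition the introns (`<2`, `2–4`, `>4` meaning $4 < \min FC \leq 8$,
and `>8`); "affected at threshold $t$" means $\min FC > t$, so the `>8`
introns are a subset of those affected at 4-fold. A gene is *affected* when
at least one of its introns passes the gene threshold (default 2-fold).
Alongside the per-intron bins, a Welch two-sample t-test compares the
pooled IR distributions of the two conditions (the box-plot comparison);
Welch is used because only "t-test" is conventional here and unequal
variances are the norm.

Suppressor recovery: the deficient set $D$ holds introns with
$\min FC > 8$ (mutant vs wild type, concordant). An intron is *recovered*
in a suppressor strain when its FC against the mean wild-type IR is below
2 in every suppressor sample; the statistic is $100\,|recovered|/|D|$.
Mutant fold changes pair replicate $i$ with wild-type replicate $i$;
suppressor samples are compared against the wild-type mean because
suppressor replicate structure is not necessarily matched to the original
design.

The two-isoform estimator for an individual intron is the PSI-like read
fraction $n_{\mathrm{intron}} / (n_{\mathrm{intron}} + n_{\mathrm{junction}})$,
requiring at least `min_informative = 10` informative reads. Note this is a
*read-level* fraction: because a retained intron offers $m + r - 1$ start
positions for overlap evidence versus $r - 1$ for a junction, it
over-represents the retaining isoform relative to its molecule fraction.

## Sequence features

* **Splice sites.** Windows of 3 exonic + 8 intronic nt (5'ss) and
  12 intronic + 3 exonic nt (3'ss), coding-strand oriented; minus-strand
  windows are reverse-complemented. Windows exceeding the intron or the
  chromosome are clipped and flagged, and excluded from matrices.
* **Branch point.** An IUPAC consensus scan (default `CTRAC`, the fungal
  CURAY-like consensus; the anchor is the consensus's single literal `A`).
  A candidate window must lie fully inside the intron with the branch A
  5–60 nt from the intron 3' end; its score is the fraction of consensus
  positions satisfied, the anchor being mandatory. The best-scoring window
  wins, ties broken toward the 3'ss (the biologically typical position),
  and a call requires score $\geq 0.8$ (one mismatch in five). These
  settings are package defaults, chosen because no standard tool or
  consensus is canonical for this genome; they are configuration, not
  constants.
* **Distances.** `dist_5ss_bp` is the 0-based offset of the branch A from
  the intron start; `dist_bp_3ss` is the offset from the branch A to the
  last intronic base, so `dist_5ss_bp + dist_bp_3ss = length - 1`.
* **PFMs.** Per-position base frequencies over ACGT with information
  content $2 - H$ bits per column. Matrices of affected vs unaffected
  introns are compared per column by Jensen–Shannon divergence (bits) and
  a chi-square test on counts, Bonferroni-corrected across columns — a
  conservative default suited to calling "no difference".
* Feature contrasts (length, distances, introns per gene) between the
  affected class (default the `>4`-fold bins) and the unaffected class
  (`<2`) use a Welch t-test by default, with Mann–Whitney as the
  nonparametric alternative; which test produced the original annotations
  is not knowable, so both are exposed.

## The simulator and its oracle

The synthetic-data generator is first-class, tested code: it defines the
study conditions under which every guarantee is verified.

A toy genome is built gene by gene: 0–4 introns per gene (uniform),
exon lengths 120–300 bp, intron lengths 60–110 bp (centered near the
~83 bp genome-wide average intron size of intron-rich fungi), genes on
both strands, 500 bp intergenic spacers. Every intron begins `GT`, ends
`AG`, and carries exactly one embedded branch-point motif (`CTAAC`, a
realization of the consensus) whose branch A sits a recorded 10–50 nt from
the 3' end; rejection sampling guarantees the planted site is the unique
call the scan can report, making recorded positions exact ground truth.
Expression is log-uniform across genes. Per-intron retention fractions
$\theta$ (the fraction of unspliced molecules) default to $\theta_{WT} =
0.02$ with mutant fold factors drawn from $\{1, 3, 6, 16\}$ — near-zero
wild-type retention with a spread of planted deficiencies.

Reads are drawn per gene from its $2^k$ splicing forms (each intron
retained independently with its $\theta$): a form is chosen with
probability proportional to abundance $\times$ (form length $- r + 1$),
and the start is uniform over valid positions, so read density is uniform
per molecule nucleotide. Alignments are emitted directly as coordinate-
sorted SAM (`M` blocks, `N` gaps at skipped introns, MAPQ 255, no
mismatches), removing any aligner from the loop — the analysis consumes
alignments, and alignment itself is out of scope. Per-gene read counts are
Poisson around the configured depth, giving natural replicate variation.
All randomness flows from one master seed plus the (condition, sample) id,
and reruns are byte-identical.

Under this scheme the expected retention level has a closed form. For a
single-intron transcript with intron length $m$, spliced length $L_e$,
unspliced length $L_u = L_e + m$ and read length $r$ (flanks $\geq r$):

$$E[\mathrm{IR}] = \frac{\theta\,(m + r - 1)}
  {\theta\,(L_u - r + 1) + (1 - \theta)(L_e - r + 1)}$$

(e.g. $\theta = 0.5, m = 80, r = 50, L_e = 300 \Rightarrow 64.5/291
\approx 0.2216$). Multi-intron transcripts are handled by enumerating all
forms and counting start positions (`expected_ir_enum()`). The test suite
verifies both against an independent coordinate-level enumeration oracle,
and verifies simulated counts against the expectation within binomial
error. Note $E[\mathrm{IR}]$ is a read-sampling quantity, not $\theta$:
it can exceed $\theta$ for short transcripts.

What the simulator does *not* model — sequencing errors, multi-mappers,
paired ends, fragment-length effects, positional coverage bias, overlapping
genes, alternative splice-site choice: passing tests therefore demonstrate
the correctness of the counting and classification machinery under clean
alignments, not robustness to alignment artifacts in real libraries.

## Study scenarios used by the scripts

The `analysis/` drivers and `scripts/acceptance.R` use a differential
scenario of 200 single-intron genes (exons 50–60 bp, so the retention
statistic is maximally informative per read), depth 1500 reads per gene
per sample, $\theta_{WT} = 0.02$, folds $\{1, 3, 6, 16\}$ assigned
cyclically (50 introns each), two replicates per condition. At this depth
a wild-type intron collects ~60 overlap reads, enough for the minimum-FC
rule to place $\geq 90\%$ of introns in their expected bins; the suite's
other simulations use 4–80 genes at depths of 20–20,000 reads per gene,
sized to finish in minutes on one CPU.

Suppressor strains are emulated by resetting $\theta$ to wild type for a
planted fraction of the >8-fold-deficient introns (strong suppressor 0.75,
weak 0.35, two samples each); the pipeline measures recovery blind to the
plant. The two-isoform scenario plants $\theta$ such that the *estimator's*
expectation is 15% retained (the spliced isoform ~85% of informative
reads), since the PSI-like statistic reports read fractions, not molecule
fractions (see above).

## Numerical and design choices

* Coordinates: GFF3 (1-based closed) and BED (0-based half-open) are
  converted at the I/O boundary by rtracklayer; internally everything is
  GRanges. Intron ordinals follow transcription order, so ordinal 1 of a
  minus-strand transcript is the highest-coordinate intron (this supports
  statements like "retention of the fourth intron").
* Identical intron intervals implied by multiple transcripts of a gene
  are merged into one catalog entry carrying all transcript ids; its IR
  denominator is the union of reads assigned to any of those transcripts.
* Degenerate inputs: transcripts with no reads give IR = NA and are
  excluded from classification; an empty deficient set gives NA recovery;
  constant IR vectors give no t-test rather than an error; single-exon
  transcripts simply contribute no introns.
* Threshold comparisons are inclusive ($\geq$) for CPM and for the 2-fold
  bin edge; "over $x$-fold" fractions are strict ($>$).
* The expression filter default (`CPM >= 10` in all samples) and the
  pseudocount $\varepsilon = 0.001$ are deliberate, documented choices
  where conventions diverge; both are arguments, not constants.

## Limitations

Fold-change classification with two replicates has no per-intron error
control — it mirrors the plain threshold-plus-concordance design rather
than a count-based model (a beta-binomial GLM would be the modern
alternative, and is intentionally out of scope). The branch-point scan is
a consensus heuristic; on real genomes a fraction of calls will be wrong
in a way the planted-truth simulations cannot reveal. EM-based multi-
isoform quantification, duplicate handling and paired-end fragment
unification are not implemented; each mate of a pair would be counted
independently.
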