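---
title: "Methods: two-library small RNA analysis with caprimir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-library small RNA analysis with caprimir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caprimir)
```

caprimir re-implements the classic two-library small RNA discovery
workflow — clean, map, annotate, quantify conserved miRNAs, predict novel
hairpins, test differential expression — as composable R functions with a
synthetic-data generator that makes every stage testable against known
ground truth. This vignette records the models, the tunable parameters,
the numerical choices, and the places where the original workflow left a
decision open and the package had to make one.

## Read cleaning

Reads are assigned to exactly one category in a fixed priority order:
low quality, no 3′ adapter, no insert, 5′-adapter contaminant, polyA,
shorter than 18 nt, clean. The filters themselves are standard; their
operational definitions are the package's own, since pipelines rarely
publish them:

* **Low quality** — any read containing `N`. Real base-callers emit
  quality strings; a presence-of-N rule is deterministic and sufficient
  for the accounting this package does.
* **3′ adapter detection** — the leftmost position where the read
  matches a ≥ 6 nt prefix of the 3′ adapter, with the match running to
  the read end or spanning the full adapter. The insert is everything
  before that position. This handles the two real read anatomies —
  `insert + truncated adapter` and `adapter + downstream junk` (an empty
  insert) — with one rule. Already-trimmed sequences carry no adapter
  and deliberately land in `adapter3_null`, which guards against double
  trimming.
* **5′ contaminant** — the insert begins with the 3′-most 8 nt of the 5′
  adapter (adapter-dimer ligation signature).
* **polyA** — the trimmed insert is ≥ 80 % adenosine.
* **Length** — clean inserts are 18–30 nt; the upper bound follows from
  the library construction (small RNAs under 30 nt), and with typical
  read lengths an insert over 30 nt cannot retain a 6 nt adapter match,
  so such reads fall into `adapter3_null` accounting.

Category percentages are reported over **raw** reads. The published
accounting table this mirrors is internally inconsistent about its
denominator (its sub-18-nt percentage only reconciles with a
high-quality denominator while its clean percentage requires the raw
one); the raw denominator reproduces the headline clean-read percentage
(94.55 % for the dry library) and is used throughout.

## Mapping

Tags map to the genome on both strands with at most one substitution and
no indels, reporting **all** loci. Matching is delegated to Biostrings'
C kernels (`matchPattern(max.mismatch = 1, with.indels = FALSE)`) on the
tag and its reverse complement; completeness over Hamming distance ≤ 1
is checked in the test suite against a naive all-positions scan, on a
50 kb genome with 1,000 tags. Uniqueness counts distinct loci
(chromosome, start, end): a palindromic site hit on both strands is one
locus.

## Annotation

Each mapped tag receives exactly one category by priority: known miRNA
first (so miRNA reads inside genes are not lost to exon), then the
structural RNA classes in conventional listing order (rRNA, tRNA, snRNA,
snoRNA, scRNA, srpRNA), then repeat > exon > intron, else unannotated.
Feature overlap is positional (any aligned base inside a labelled
interval, strand-agnostic) rather than similarity-based: the original
workflow triaged by BLAST against sequence databases, which is
database-version-dependent and non-deterministic across releases;
interval overlap against a fixed labelled feature set tests identically
everywhere. Strand-agnostic overlap was chosen because the original
triage did not state strandedness.

## Conserved miRNA quantification

A tag matches a reference mature when it aligns inside the precursor
with at most `max_mismatch` substitutions (default 0), overlaps the
mature, and has both ends within `max_shift` (default 2) nt of the
mature's ends — a minimal isomiR allowance. Both knobs are exposed
because the original "compared with miRBase" step states no tolerance.
A tag matching several references counts once, to its tie-break winner
(fewer mismatches, then smaller total end shift, then lexicographic
name), so per-miRNA totals never double-count a read. Arm categories
(miRNA / miRNA\* / miRNA-5p / miRNA-3p) come from reference naming
conventions.

## Folding model

Novel-miRNA candidates are folded by a built-in minimum-free-energy
engine (`fold_mfe()`, Rcpp) restricted to **single hairpins**:
structures are chains of nested pairs (Watson–Crick plus GU) joined by
stacks, bulges and internal loops and closed by a terminal loop of
≥ 3 nt. Multibranch loops are disallowed — miRNA precursors are single
stem-loops, and the restriction keeps both the dynamic program and its
exhaustive test oracle exact. The energy model is a compact
Turner-flavoured parameterisation (`fold_params()`): a 6 × 6 stacking
table over ordered pair types, and logarithmic loop penalties

* hairpin(n) = 5.4 + 1.08·log(n/3)
* bulge(n) = 3.8 + 1.08·log(n)
* internal(n₁,n₂) = 1.7 + 1.08·log((n₁+n₂)/2) + min(3, 0.3·|n₁−n₂|)

with interior loops capped at 30 unpaired nt between consecutive pairs.
This is **not** a reference-grade thermodynamic parameter set: its
purpose is ranking candidate hairpins against the −20 kcal/mol
stability criterion, where well-paired precursors score −25 to −50 and
random windows of the same length typically score −7 to −20. Published
reference MFE values are treated as directional sanity checks only,
never as exact targets. Ties in the DP resolve deterministically toward
the empty structure (MFE 0 exactly means no pairs) and then by a fixed
traceback scan order. The DP optimum is verified in the tests against
brute-force enumeration of every chain structure for 200 random
sequences up to 30 nt.

## The seven criteria

`apply_criteria()` evaluates, on features extracted from the folded
window: (1) stem pairs ≥ 18; (2) largest single-side unpaired run
within the stem ≤ 18 nt; (3) MFE strictly below −20 kcal/mol; (4)
≥ 80 % of mature bases paired; (5) hairpin span (outermost pair,
stem + terminal loop) ≥ 53 nt; (6) terminal loop ≤ 22 nt; (7) mature
A+U within 30–70 % inclusive. Two readings were genuinely open and are
configurable: criterion 2's "errors in one bulge" is implemented as the
longest one-sided unpaired run inside the stem (the only reading
checkable on a structure), and criterion 4's "percentage in the stem"
as the percentage of mature bases that are paired. Candidate windows
follow the Mireap convention — the tag at the 5′ end with 70 nt of
downstream flank, and at the 3′ end with 70 nt upstream, strand-aware —
applied to unannotated, single-locus tags with ≥ 5 reads pooled over
both libraries (pooling recovers weakly expressed hairpins that
condition-specific counting would drop). When both windows pass, the
lower-MFE window wins.

## Differential expression

Expressions are normalised to transcripts per million of clean reads;
zeros become 0.01 for the ratio; records below 1 per million in both
libraries are discarded from the comparison; the label `**` requires
|log2FC| > 1 (strict) and p < 0.01 (strict). The p-value is the exact
Audic–Claverie two-library test. Its conditional distribution is a
negative binomial (size x+1, prob N₁/(N₁+N₂)), so tails are computed
with `pnbinom(log.p = TRUE)` — exact, fast, and meaningful in log10 far
below double-precision underflow (`ac_pvalue(log10 = TRUE)`).

The variant question deserved care, because published tables rarely say
which tail convention they used. The package exposes the point
probability, one-sided and two-sided variants, and the choice of which
library to condition on. Empirically, the two-sided tail sum
conditioned on the **larger** of the two counts reproduces the
motivating study's printed p-values at printed precision (4.26e−175 vs
4.3E−175; 8.41e−74 exactly; 1.248e−68 vs 1.25e−68; 2.99e−227 vs
3E−227), while conditioning on a fixed library misses by 0.1–0.2 log10
on half the rows; `condition = "larger"` is therefore the default. The
test's calibration (null rejection ≤ gate) and sensitivity to planted
four-fold changes are exercised in the acceptance checks rather than
asserted here.

## qPCR quantification

`qpcr_relative()` implements the Livak 2^−ΔΔCt method with replicates
averaged on the ΔCt scale before referencing to the calibrator sample
(standard Livak practice; the alternative — averaging folds — is
reported as the replicate SD). Amplification efficiency is assumed to
be 2 per cycle; no efficiency correction is fitted.

## The synthetic study

The generator's defaults define the simulated study: a 100 kb uniform
i.i.d. genome; 30 known-miRNA hairpins (both arms named, half with
star/plain naming and half with -5p/-3p), 10 novel hairpins, 10 decoy
hairpins, 3 loci per structural/feature class, 400 background loci;
2 × 200,000 reads with insert-length mode 22 nt; artifact rates
mirroring the published accounting of a real run (0.5 % low quality,
0.1 % adapterless, 0.1 % insertless, 0.5 % 5′ contaminated, 4.3 %
sub-18 nt, 2.5 × 10⁻⁵ polyA); star arms at 5 % of hairpin reads; log2
fold changes of ±2 planted on three known and two novel loci each way.

Three construction choices matter for interpreting test results:

* **Hairpins are constructed, not sampled.** Mature arms (A+U
  constrained to 35–65 %) pair against an imperfect star — the reverse
  complement with two interior substitutions. The imperfection is
  biological (miRNA duplexes carry mismatches) and operational: a
  perfect-complement star would make every mature read map to both
  arms, two loci, and be discarded by the single-locus filter. Every
  planted novel hairpin is certified at build time by the package's own
  prediction machinery in exactly the window the pipeline will excise,
  with failing flanks regenerated; decoys are certified to fail both
  windows including their named criterion (AU-composition decoys
  violate the 30–70 % rule by construction; weak-stem decoys have no
  complementary arm and must fail the −20 kcal/mol rule, with their
  unexpressed tail regenerated until they do). Build-time certification
  is what turns the recovery tests into exact oracles at any seed.
* **Counts are one multinomial per library** over artifact classes and
  loci (the conditional of independent Poissons given the fixed library
  total), so category counts conserve the library size exactly. The
  fixed total means planted fold changes are **compressed** by the
  weight-sum ratio between conditions — exactly the compositional
  effect real per-million normalisation has — and the manifest records
  the realised expectations so tests compare against the design, not
  against a naive 4×.
* **Every read is verified at generation** to classify into its
  intended cleaning category (inserts that would spuriously contain an
  adapter seed, start with the 5′-adapter tail, or look polyA are
  rejected and redrawn). QC accounting therefore matches the manifest
  exactly, deterministically, at any seed.

What the generator does **not** emulate: sequencing errors and quality
score distributions (low quality is modelled as N-containing reads),
multi-copy repeat families (every locus is single-copy, so multi-mapping
arises only by chance), isomiR end heterogeneity (each locus emits fixed
fragment sequences), and inter-animal variability (one pooled sample per
condition, as in the motivating design). Passing recovery tests on this
generator demonstrates the pipeline's bookkeeping and decision rules are
correct, not that the seven criteria are well-calibrated on real
genomes — on random background windows of real length the criteria
accept a small percentage (roughly 1–2 % of candidate windows), which
mirrors the false-positive behaviour expected of structure-only novel
miRNA prediction.

## Problem sizes and determinism

The shipped tests run the generator at two scales — a reduced
configuration (2 × 20,000 reads, 40 kb genome) for stage-level checks
and the full default (2 × 200,000 reads, 100 kb) for end-to-end
recovery — chosen so the whole suite completes in a few minutes while
every planted locus class stays well represented. All randomness flows
from a single integer seed; identical configuration and seed give
byte-identical genomes, FASTQ files and reports. The folding oracle
comparison uses 200 sequences of 10–30 nt (exhaustive enumeration is
exponential in length); the mapping oracle uses 1,000 tags of 18–24 nt
against 50 kb.

## Known limitations

* The energy model is deliberately compact; absolute MFE values are not
  comparable to reference folding engines, only the pass/fail behaviour
  around −20 kcal/mol is calibrated.
* No multiple-testing correction is applied (the motivating workflow
  applied none); with hundreds of miRNAs the `**` label should be read
  as a screening call.
* Novel prediction requires no star-strand expression evidence, so
  single-arm artifacts can pass where evidence-based tools (miRDeep)
  would demand duplex support.
* The mapper is exact but naive in scale; it is sized for the package's
  toy genomes, not mammalian chromosomes.
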