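---
title: "Methods: marker-based detection of a rare gut commensal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-based detection of a rare gut commensal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raretaxa)
```

# The problem

Segmented filamentous bacteria (SFB) sit near 10⁻⁶ relative abundance in
the gut community they colonize. Under the Lander–Waterman model a taxon
at relative abundance $a$ with genome length $L$ in a metagenome of depth
$D$ bases has expected covered genome fraction $1 - e^{-aD/L}$; requiring
a minimum covered fraction $f$ for a confident call gives the minimum
detectable abundance

$$a^* = -\frac{L \ln(1-f)}{D},$$

which for $D = 4\times10^9$, $L = 1.6\times10^6$ and $f = 0.01$ is about
$4\times10^{-6}$ — above where SFB live. Detection therefore runs through
taxon-specific markers: DNA markers found by subtractive comparative
genomics and validated by PCR, protein markers via clade-unique tryptic
peptides, and absolute quantification by qPCR. This vignette records the
models, parameter choices and numerical conventions behind each stage,
and what the synthetic data do and do not establish.

# Subtractive marker discovery

## Alignment model

Homology is assessed by Smith–Waterman local alignment with match $+1$,
mismatch $-1$ and a *linear* gap penalty of $-2$ per base (no separate
opening cost). Both subject strands are searched, since gene orientation
in assembled gene sets is arbitrary. From the maximal-scoring alignment
we report

* **identity** — matching columns as a percentage of all alignment
  columns, gap columns counted as non-matching;
* **query coverage** — the aligned query span as a percentage of query
  length (coordinates 0-based, half-open throughout the package).

Determinism is part of the contract: the reported cell is the
maximal-scoring one with the smallest query end (then smallest subject
end), and traceback prefers diagonal over a gap in the subject over a gap
in the query. The compiled kernel is checked exactly against a plain-R
dynamic-programming oracle in the test suite; identity and coverage of
*an* optimal alignment are not unique in general, which is why both
implementations pin the same tie-break order.

## Conservation, subtraction, ranking

A reference gene is **conserved** when every inclusion-clade genome has a
best hit with identity ≥ 70% and coverage ≥ 70%; it is **subtracted**
when *any* exclusion-clade genome has a hit at the deliberately
permissive "some homology" thresholds of 50%/50%. All four thresholds
are exposed as arguments since no canonical values exist for this
procedure. The conservation score is the mean over inclusion genomes of
$\frac{\text{identity}}{100}\cdot\frac{\text{coverage}}{100}$ (a genome
with no hit contributes 0), giving a value in $[0,1]$; this product form
is this package's definition — it penalizes both divergence and partial
homology without extra weights. Ranking sorts by score descending with
lexicographic gene-id tie-break, so output order is reproducible.

A consequence of the permissive subtraction thresholds worth knowing: an
optimal local alignment between two *unrelated* ~150 bp sequences can
occasionally span half the query (any positive-scoring alignment under
±1 scoring automatically exceeds 50% identity), so very short genes can
be subtracted by chance. At the 300 bp default gene length a chance
≥ 150 bp alignment is far into the tail and planted-marker recovery is
exact across all tested seeds.

# Primer design and in-silico PCR

The designer enumerates every template window satisfying the
single-primer constraints and every pairing satisfying the pair
constraints — no heuristics, so "no output" genuinely means the
constraints are infeasible. Defaults: primer length 18–25 nt, GC 40–60%,
melting temperature 55–62 °C, product 80–300 bp, $|\Delta T_m| \le 3$ °C.
$T_m$ uses the Wallace rule $2(A{+}T) + 4(G{+}C)$: closed-form and
exactly testable; nearest-neighbor thermodynamics is out of scope.
Pairs are ranked by the additive penalty

$$|\Delta T_m| \;+\; \tfrac{1}{2}\left(|GC_F - 50| + |GC_R - 50|\right)
\;+\; |\,\text{product} - 150\,|$$

with unit weights (°C, percentage points, bp) — a simple, documented
stand-in for a full design-tool penalty model, not a replication of one.
Ties break by template position, keeping the output deterministic.

In-silico PCR reports every site where the forward primer matches the
plus strand and the reverse primer the minus strand downstream, within
3000 bp (a scan-cost bound), allowing a configurable number of mismatches
per primer but requiring the 3′-terminal base to match exactly — the
polymerase-extension end is where mismatches actually kill amplification.
Both template orientations are searched and minus-strand hits are mapped
back to plus-strand coordinates, so hit counts are invariant under
reverse-complementing the input. Degenerate (IUPAC) bases are rejected
rather than expanded. A pair is **specific** if it amplifies in every
inclusion genome and never in the exclusion clade; exclusion amplicons
take precedence (`non_specific`) over inclusion gaps (`non_universal`).

# qPCR quantification

The standard curve is ordinary least squares of Ct on
$\log_{10}(\text{copies})$; amplification efficiency is
$10^{-1/\text{slope}} - 1$, so slope $-1/\log_{10} 2 \approx -3.3219$
means perfect doubling. Quantification inverts the curve,
$\text{copies} = 10^{(Ct - b)/m}$, and multiplies by a single
user-supplied copies→CFU/ml factor (default 1): extraction volume,
dilution and marker copy number are assay constants the package refuses
to invent. Values outside the calibrated 1–10⁷ copy range are still
converted but flagged as extrapolated (with a tiny relative slack so the
exact range limits are in range despite floating-point wobble).
Replicates are averaged as mean Ct per sample before conversion (median
available).

Positivity uses the assay detection limit of 10⁴ CFU/ml, **inclusive**:
only loads *below* the threshold are negative. Note the related
literature quotes both "10⁴ CFU/ml in 10¹¹" and "10⁵ in 10¹¹ total" in
different places; the threshold is an argument precisely so neither
constant is hard-wired. Relative expression is the standard
$2^{-\Delta Ct}$ against a housekeeping gene (actin in the motivating
study), which satisfies the reciprocal identity
$2^{-\Delta Ct(a,b)} \cdot 2^{-\Delta Ct(b,a)} = 1$.

# Peptide evidence

Tryptic digestion cleaves after K or R except before P (the convention
consistent with all 18 published SFB peptides, several of which carry
internal missed sites), enumerating peptides with up to 2 missed
cleavages and length ≥ 4 — the published identification filters.
Monoisotopic masses use the standard 20-residue table plus one water
(18.010565 Da); mass matching is inclusive at ±15 ppm. N-terminal
methionine is not clipped (the upstream protocol does not mention it) and
isoleucine/leucine are distinct: uniqueness here is a sequence-level
claim; users wanting mass-level caution can collapse I/L themselves
before searching.

Uniqueness calling replaces "100% identity, full-coverage BLAST" with
exact substring search, which is mathematically the same predicate for a
short peptide and fully deterministic: a peptide is unique when it occurs
in at least one inclusion protein and zero background proteins.

# The synthetic-data module

The generators *are* the study conditions; their defaults are fixed once
and used everywhere:

| parameter | default | rationale |
|---|---|---|
| inclusion genomes | 4 (incl. reference) | desk-scale stand-in for an 11-genome clade |
| exclusion genomes | 3 | a few *Clostridium*-like neighbours |
| reference genes / conserved / shared | 12 / 6 / 2 | small enough to audit by eye, planted markers = 4 |
| gene length | 300 bp | typical partial gene; long enough that chance 50% coverage is negligible |
| point mutation rate | 0.02 /base | within-clade divergence; substitutions only so planted identity stays analytic |
| sIgA medians (±) | 118.60 / 69.21 μg/ml | the published group medians |
| sIgA log-sd | 0.4 | gives realistic right-skew; the published "median ± SEM ± SEM" double interval is ambiguous and is treated as metadata, not a dispersion parameter |
| cohort sizes | 23 / 24 | the published group sizes |
| ages | uniform 8–48 months | the sampled age window |
| curve slope / intercept | −3.3219 Ct/log₁₀ / 37 Ct | perfect-efficiency assay; intercept in the usual SYBR range |
| Ct noise | 0.2 Ct | typical replicate scatter |

sIgA concentrations are log-normal with log-median $\ln(\text{median})$
— concentrations are positive and right-skewed, and parameterizing by
the median makes the published statistic the exact population parameter
(the sample-median estimator is then unbiased enough that its mean over
200 replicates sits within 5% of the parameter, which the tests check).
Reproducibility is by one root seed with fixed per-generator offsets, so
each generator's stream is independent of the others and every output is
a pure function of its configuration.

Proteome generation embeds each planted peptide between clean tryptic
boundaries (preceded by K, not starting with P, placed C-terminally when
it does not end in K/R) so digestion releases it exactly. Background
proteins are grown residue-by-residue avoiding every 4-mer of the
inclusion proteome. This is deliberately stronger than "does not contain
the planted peptides": it guarantees the two proteomes share *no*
peptide of length ≥ 4, which random sequences would violate with high
probability at realistic proteome sizes.

What the generators do **not** emulate: read-level sequencing (no FASTQ,
chimeras or contamination), phylogenetically structured divergence
(mutations are i.i.d. substitutions; an indel option exists but default
off), 16S copy-number variation, qPCR inhibition or plate effects, and
any correlation structure between sIgA, age and colonization beyond the
group medians. Passing tests therefore establish the *procedures* —
recovery of planted truth under the stated models — not performance on
real sequencing data.

# Statistics

Group comparisons default to Student's t (the motivating study's choice)
with Welch and Mann–Whitney one flag away, since sIgA-like quantities
are skewed. Prevalence strata use the conventional closed age bins
(0–36, 37–72, 73–108, 109–181 months); an empty stratum reports a
missing percentage rather than 0, and percentages are rounded to two
decimals to match how such tables are printed. The published table's
"total" row percentage is internally inconsistent with its own counts;
this package always recomputes from counts. BH adjustment delegates to
`stats::p.adjust` and is verified exhaustively against the textbook
step-up formula for all inputs of length ≤ 6 on a p-grid. Differential
selection keeps genes with fold change ≥ 2 or ≤ 0.5 (boundary inclusive,
"at least twofold") and adjusted p < 0.05 (strict). Shannon diversity is
natural-log via `vegan::diversity`, base 2 by argument.

# Problem sizes and runtime choices

The test suite and acceptance script run everything at desk scale,
chosen as the package's own audit sizes: 200 random pairs ≤ 200 bp for
the alignment-oracle comparison, 100 random proteins for the digestion
oracle, 40 planted pan-genomes (20 seeds × mutation 0 and 0.02) for
marker recovery, 200 replicate cohorts for the sIgA calibration, and two
full pipeline runs for the determinism check. The alignment kernel
dispatches to an integer DP when the scoring parameters are whole
numbers, which keeps the pan-genome scans fast without changing any
result.

# Known limitations

* Alignment thresholds act on the single best-scoring hit per genome; a
  lower-scoring hit with higher coverage could in principle pass a
  threshold the best hit fails. With the planted-truth structure this
  does not occur, but real pan-genomes with repetitive genes could care.
* The Wallace rule is crude above ~25-mers and ignores salt and
  concentration corrections.
* The in-silico PCR mismatch model is positional only (count + exact 3′
  base); no thermodynamic weighting of mismatch position.
* The detectability calculator treats depth as uniformly distributed
  across the community and ignores read length and mapping error; it is
  a planning tool, not a sensitivity guarantee.
* Uniqueness is exact-substring on the supplied proteomes; it cannot see
  proteins absent from the background set.
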