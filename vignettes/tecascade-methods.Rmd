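---
title: "Models and methods behind tecascade"
author: "tecascade authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tecascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tecascade` infers recent transposable-element (TE) invasions from three
complementary signals: copy-number time series in strains sampled over
decades, sequence-level evidence of horizontal transfer in genome
assemblies, and the small-RNA response of the host. This vignette explains
the models behind each stage, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the design
decisions taken where several reasonable choices existed.

## Coordinates and scoring conventions

All coordinates in the package are 0-based and half-open. The standard
formats keep their own conventions at the boundary: GFF3 and SAM are written
1-based, BED intervals are read as 0-based half-open.

All alignment stages share one affine-gap scoring scheme
(`alignment_scoring()`): match +1, mismatch −2, gap open −3, gap extension
−1, where a gap of length $g$ scores $open + g \cdot ext$ (the opening
penalty is charged once on top of a per-column extension). This is the
convention of `Biostrings::pairwiseAlignment`, which lets the test suite
compare the C++ engine against an independent implementation *exactly*, and
a second pure-R brute-force dynamic program provides a dual, in-repo oracle
on small instances. The downstream similarity statistic is a score *ratio*,
so it is robust to the particular scheme; a property test confirms that the
similarity ordering of assemblies is preserved under an alternative scheme
(+2/−3/−5/−2).

## TE consensus and LTR detection

A young LTR retrotransposon begins and ends with near-identical direct
repeats; their residual divergence dates the insertion. `detect_ltrs()`
compares the 5′ terminal window against the 3′ terminal window at every
candidate length and returns the longest equal-length terminal pair with
identity at least $1 - \text{max\_mismatch\_frac}$.

* `min_ltr = 100` nt — short terminal coincidences are not meaningful
  repeats; anything below 20 nt is rejected outright.
* `max_mismatch_frac = 0.05` — the two LTR copies of an element young
  enough to be invading are near-identical, so 5% is permissive.
* Substitutions only: any alignment register shift destroys the terminal
  correspondence, so indel handling adds nothing at these identity levels.
  `N` bases count as mismatches (conservative).

Automated boundary placement can differ from a curated annotation by a few
nucleotides; the detector is therefore tested against planted truth with a
±5 nt tolerance rather than to the base.

## Synthetic data: what it emulates, and what it does not

The generator (`sim_config()`, `make_genome()`, `simulate_reads()`,
`simulate_pirnas()`, `simulate_cohort()`) produces every input the pipeline
consumes, with recorded truth. Defaults describe one fixed study condition:

| parameter | default | meaning |
|---|---|---|
| `read_length` | 100 nt | single-end read length after trimming |
| `depth` | 30× | fold coverage of the genome |
| `error_rate` | 0.5% | per-base substitution error |
| `insertion_divergence` | 1% | per-copy substitutions from the consensus |
| `n_scg` / `scg_length` | 3 / 2000 nt | single-copy normalisation genes |
| `pirna_n` | 20000 | piRNA pool size |
| `growth_rate` / `copy_cap` | 3 copies/yr, 30 | post-invasion dynamics |

Reads are single-end (the quantification never uses pair information),
errors are substitutions only (pileup columns stay exact), insertions carry
no target-site duplications (no downstream statistic uses them), and
copy-number growth after the invasion year is linear with a cap — only the
presence/absence pattern over time matters downstream, not the dynamics.
Planted TE SNPs are sampled per copy at their stated population frequency,
so the realised allele frequency carries binomial noise by design; a
population frequency of 0.15 over 50 copies realises at or below the 0.1
MAF call threshold about 7% of the time, and such sites are genuinely
uncallable in that simulated population. Passing tests on these data show
the estimators recover what was planted under uniform coverage and
substitution-only noise; they do not speak to mappability variation, indel
sequencing errors, copy-number heterogeneity along the element, or
contamination structure beyond the single-strain contaminant the cohort
generator can inject.

## Short-read quantification

`trim_reads()` truncates reads to a common length (default 100 nt) from the
3′ end and discards shorter reads, removing read-length effects from the
coverage ratio.

The built-in mapper (`map_reads()`) seeds with exact 31-mers at strided
offsets and extends candidates by affine-gap dynamic programming that is
**end-to-end in the read and local in the reference** (glocal). The glocal
choice matters for allele frequencies: a fully local extension clips
terminal mismatches, which systematically removes minor-allele bases from
pileup columns near read ends and attenuates every measured MAF by several
percent. With glocal extension, terminal read bases stay aligned; a query
overhang that cannot match (a read spanning an insertion junction) becomes
a soft clip. Reads whose mismatches leave no clean 31-mer — at a 2%
mismatch rate a non-negligible fraction — are rescued by disjoint 16-mer
seeds (pigeonhole: any read with fewer than six mismatches retains a clean
16-mer in one of the six disjoint windows). Multi-mapping reads go to the
single best hit (ties: reference order, then leftmost position); a
coverage-ratio estimator is robust to within-family ambiguity, and
fractional assignment would buy nothing here. `min_identity = 0.85` accepts
copies up to ~10% diverged plus sequencing error while rejecting unrelated
sequence.

`estimate_copy_number()` divides the mean depth over all TE consensus
positions by the unweighted mean of the per-gene mean depths of the
single-copy genes (three by default). Averaging per-gene-first, rather than
pooling all SCG positions, keeps one unusually long or short gene from
dominating the yardstick. Presence is `copy_number > 1`, strictly: degraded
sub-unit background (ancient fragments) stays below the threshold. Note a
strain whose true copy number is exactly 1 sits on this threshold by
construction — an unbiased estimate falls on either side with equal
probability — so the strict call is only meaningful away from 1.

`call_te_snps()` calls a consensus position a SNP iff depth ≥ `min_depth`
(default 10 — below that, binomial noise makes a 0.1 MAF threshold
meaningless) and the second-most-frequent base exceeds `maf_threshold = 0.1`
strictly: a 90/10 column at depth 100 is not a SNP, an 89/11 column is.

## Assembly scanning

`scan_assembly()` seeds each contig against the consensus (both strands)
with exact 13-mers — at 10% divergence a given 13-mer window is clean with
probability $0.9^{13} \approx 0.25$, so a >750 bp insertion yields many
seeds — clusters seeds by diagonal (distinct copies sit at least one element
length apart, hence on well-separated diagonals), and aligns each candidate
locus with the full local dynamic program. Same-strand hits within 100 bp
are chained into one insertion, mirroring how repeat annotators defragment
fragmented young elements around indels; overlapping duplicates collapse to
the best-scoring member, chained fragments sum their scores and
length-weight their divergences.

Retained insertions must satisfy, strictly: aligned length on the assembly
> 750 bp and substitution divergence < 10%. Divergence excludes gap columns
(mismatches over match+mismatch columns) — stated explicitly because
including gaps would change what the 10% filter removes. The aligned length
is measured on the assembly, not the consensus.

`classify_full_length()` calls an insertion complete iff it spans >80% of
the consensus (strict) and covers at least 80% of each LTR interval — a
solo LTR or an internal fragment is never complete.

`similarity_scores()` computes, per assembly, $s = score_{best} /
score_{max}$ over all analysed assemblies. The assembly carrying the
best-preserved copy scores 1 (ties allowed), assemblies without a hit score
0; monotone decay with divergence makes $s$ a donor-search statistic.

Genic context gives promoters (within 1 kb upstream of a transcription
start site, strand-aware) precedence over everything, then the innermost
overlapping feature (UTRs before exon before intron), and intergenic
otherwise. Cluster counting uses ≥1 bp overlap; under the trap model a
somatic TE is expected to leave exactly one insertion in the somatic piRNA
cluster or its duplicates (`trap_check()`: `pre_trap` / `consistent` /
`multi`). Independence of cluster insertions across strains is decided by
flank synteny: two insertions are the same event iff the ordered TE names
within 2 kb match on at least one side; events are connected components of
that relation (the relation is not transitive, components make it an
equivalence).

`ht_divergence_test()` encodes the classical divergence argument for
horizontal transfer: support requires the cross-species TE identity to
strictly exceed the identity of *every* host ortholog (≥10 required). Under
vertical transmission the TE diverges with the hosts, and because the TE
alignment is typically several-fold longer than a single gene, its identity
estimate has less sampling noise than the noisiest of ten host genes — the
test then almost never fires, which the suite verifies by simulation at
equal divergence rates.

## Small-RNA analysis

`trim_adaptor()` removes the 3′ sequencing adaptor at its first occurrence,
allowing one mismatch, and keeps reads of 18–35 nt. `map_small_rnas()`
matches trimmed reads full-length on both strands, exact first with a
one-mismatch fallback; a read matching $n$ positions within the element
receives weight $1/n$ at each (whether to weight multimappers is not
standardised in the field; $1/n$ is recorded here for sensitivity
analysis).

The ping-pong signature tallies, for every sense/antisense pair of
overlapping reads, the distance from the sense 5′ end to the antisense 5′
end (inclusive). Secondary piRNA biogenesis leaves an excess at exactly
10 nt; `z10` standardises the overlap-10 count against the background of
overlaps 1–9 and 11–20 — the field-standard background, fixed here
explicitly because published pipelines differ silently. `z10` is undefined
(NA) for single-strand pools or zero background variance. Relabelling which
strand of the consensus is "sense" mirrors the coordinate system and leaves
the histogram unchanged; the suite tests this symmetry. The z-score's null
distribution is calibrated empirically: with dense pools (20000 reads on a
~2 kb element) the shared sampling noise across overlap bins makes the
statistic slightly conservative, and $|z_{10}| < 2$ holds in ≥95% of null
pools.

A somatic-type response shows antisense-limited piRNAs without ping-pong
pairing; a germline-type response shows both strands and a strong `z10` —
the package reproduces this contrast qualitatively from its own simulator.

## Invasion windows and the cascade

`infer_invasion_window()` defines the window by data alone: the last
sampling year without the TE and the first with it. An isolated early
positive is flagged as a contamination outlier iff the next-oldest positive
lies more than `outlier_gap_years = 10` later *and* at least two TE-free
samples fall in between; both knobs are configurable since published
contamination calls are narrative rather than criterion-based. Windows from
sparse sampling can therefore differ from narratively reported ranges.

`cooccurrence()` reports the concordance of two TEs' presence across
strains plus a two-sided Fisher exact p (via `stats::fisher.test`, verified
exhaustively against hypergeometric enumeration for all tables up to
n = 20). `geographic_patchiness()` classifies sampling locations as all
present / all absent / mixed; at least one fixed-present and one
fixed-absent location makes the distribution patchy — the signature of an
invasion caught in progress.

`reconstruct_cascade()` is deliberately a transparent rule engine rather
than an optimiser: each invaded recipient is linked to the invaded,
contact-connected donor whose first-present year does not exceed the
recipient's; candidate donors are ranked by evidence class — more than one
shared segregating TE SNP (multi-variant transfer, hybridisation-compatible)
beats a hybridisation edge, which beats plain range overlap — then by
earliest invasion. One or zero shared SNPs is treated as single-origin
transfer. Recipients without an eligible donor are reported unresolved
(external or unsampled donor); equal first-present years make the direction
ambiguous and both orderings are emitted without time-order evidence. Every
fired rule is visible in the per-event evidence set.

## Problem sizes and numerical choices

The test and acceptance workloads use consensus elements of 1–2 kb, genomes
of 20–120 kb, depths of 10–50×, piRNA pools of 2000–20000 reads, 50
alignment-oracle pairs up to 2 kb, and 100 seeded cohorts/null pools —
sizes at which every property is measurable with comfortable margins on a
single CPU. All simulations run from explicit integer seeds; equal
configurations give byte-identical FASTQ output. Degenerate inputs are
handled explicitly: empty read sets warn and return empty, all-zero SCG
coverage is an error (normalisation impossible), single-strand piRNA pools
give `z10 = NA`, constant presence vectors give an undefined Fisher p with
a warning, and an all-same-year time series is `undated`.

## Known limitations

* The mapper and scanner assume a single consensus per family; nested or
  rearranged insertions are reported as chained fragments.
* Copy numbers are haploid-equivalent coverage ratios; they do not separate
  fixed from segregating insertions within a strain.
* The cascade engine encodes evidence as strict rules; it reports what the
  rules imply, not a posterior over histories, and cannot resolve donors
  outside the sampled species set.
* Invasion windows are bounded by sampling, not by the transfer event
  itself; a lag between transfer and population spread widens the true
  uncertainty beyond the reported window.
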