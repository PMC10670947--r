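---
title: "Detecting orthologous SINE insertion loci between assembled genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting orthologous SINE insertion loci between assembled genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Short interspersed elements (SINEs) are non-autonomous retrotransposons
that amplify to tens or hundreds of thousands of copies per genome. Because
a SINE inserts essentially irreversibly — precise excision is rare — the
presence of a copy at an orthologous genomic site in two species is a
shared derived character, and the *polymorphism* of insertion sites
(present in some taxa, absent in others) carries phylogenetic signal.

`sineortho` identifies such orthologous insertion loci between two or more
assembled genomes without computing a whole-genome alignment. The central
assumption is that the ~300 bp of sequence immediately upstream of an
insertion (the "left flank", in the element's own orientation) diverges
slowly enough between the compared taxa to identify the orthologous site
by local alignment, while being long enough that a chance match is
unlikely. Orthology is therefore established **per flank**, and the
presence or absence of the element at the matched site is decided
afterwards, from a segmented triple alignment of the two locus sequences
with the family consensus. This makes the method robust to assemblies that
are fragmented or difficult to align globally, at the cost of losing loci
whose flanks have diverged beyond recognition or that sit in repetitive
flank context (multimappers).

```{r, eval = FALSE}
library(sineortho)
sim <- simulate_genomes(sim_config(seed = 1))
res <- sine_ortho_pair(sim$genomes$A, sim$genomes$B, sim$consensus)
summary(res)
evaluate_report(sim$truth, res$report)$confusion
```

## Pipeline stages and their parameters

All thresholds below are the method's printed defaults and are exposed
through `pair_params()`; all coordinates are 0-based half-open, with
minus-strand features in forward coordinates.

| stage | parameter | default | meaning |
|---|---|---|---|
| discovery | `min_identity` | 65 % | identity over the aligned region for an accepted copy |
| discovery | `min_coverage` | 0.80 | aligned consensus span / consensus length |
| discovery | `scan_min_score` | 100 | iteration floor of the masked search (termination control, not an acceptance rule) |
| proximity | `min_gap` | 300 nt | minimum end-to-start distance between retained copies; **both** members of a closer pair are removed |
| flanks | `flank_len` | 300 nt | orthology anchor length |
| mapping | `seed_k` | 19 | exact seed length of the internal mapper |
| mapping | `map_min_score` | 60 | local alignment score floor |
| mapping | `secondary_frac` | 0.8 | keep secondary alignments down to this fraction of a flank's best score |
| mapping | `min_mapped_len` | 100 nt | minimum aligned flank length |
| extension | `pad` | 300 nt | added to the SINE length when growing each interval downstream |
| clustering | `min_overlap` | 1 bp | overlap needed to merge candidate loci |
| classification | `flank_min_len` | 150 nt | shorter flank (either locus) discards the pair |
| classification | `flank_min_ident` | 65 % | between-locus flank identity floor |
| classification | `sine_min_len` | 100 nt | SINE-region length for a "plus" call |
| classification | `sine_min_ident` | 65 % | identity to the consensus for a "plus" call |
| resolver | `member_sim_threshold` | 65 % | whole-locus identity below which extra members of a multiple group are dropped |

All boundary comparisons are inclusive: a value exactly at a threshold
passes. The printed thresholds come from the method itself; where only a
qualitative rule was available ("sufficient similarity" of extra cluster
members) the universal 65 % identity threshold is reused.

Two readings of "mapping in both directions" exist; this package maps
**reciprocally** (A-flanks onto B *and* B-flanks onto A, each against both
target strands), because the downstream clustering explicitly combines
both mapping result sets. Flanks are extracted only for copies that
survive the proximity filter.

## Numerical choices

**Masking.** The iterative discovery search masks found regions with `N`
runs, which preserves contig lengths and therefore coordinate stability
across iterations. Every found region is masked in the working copy of the
pass (otherwise a sub-threshold region would be re-found forever), but
only *accepted* copies enter the mask shared between the two strand
passes: a weak antisense self-similarity of the element must not hide the
genuine minus-strand copy underneath it.

**Alignment scoring.** Discovery and flank mapping use match +5, mismatch
−4, gap open −12, gap extension −4 — conventional DNA local-alignment
weights; the method pins only the acceptance thresholds, not the matrix.
The locus-versus-locus global alignment inside `align_triple()` instead
uses gap extension −1: a polymorphic locus pair differs by a true indel of
SINE length (hundreds of nt), and at extension −4 the optimal global
alignment of `flank–SINE–flank` against `flank–flank(+downstream)` smears
the SINE across unrelated sequence rather than opening the biological gap,
destroying the segmentation. The resolver's whole-locus identity
deliberately goes back to extension −4: with near-free gaps an alignment
can "fish" isolated matches out of unrelated sequence and inflate the
identity of a 75–85 % paralog past the 65 % member threshold; the
straight-through global identity is the honest similarity measure there.

**Consensus placement.** The consensus row of the triple alignment is
computed by aligning the consensus (globally on the consensus, locally on
the locus) to whichever of the two ungapped locus sequences scores higher,
then threading it through the already-computed pairwise columns; consensus
insertions become columns gapped in both locus rows. For a two-row
"profile" this is equivalent to profile addition, and choosing the
better-scoring carrier handles plus–minus loci, where only one row
contains the element at all.

**Identity convention.** Segment identities divide identical aligned
positions by the *smaller ungapped length* of the two segments
(`denominator = "aligned_columns"` is available). With this convention a
minus allele's empty SINE region yields identity 0 rather than undefined.

**Discard precedence.** A SINE span touching the first or last alignment
column (`leftSINE`/`rightSINE`, i.e. a flank is missing entirely) is
reported before the short-flank reasons, which would otherwise always
mask it; then flank length, then flank identity, then the presence calls.
Pairs where both presence calls are negative are discarded as
`minus_minus` rather than counted as polymorphic.

**Tie-breaks and determinism.** The closest-pair search orders candidates
by identity, then identical-nucleotide count, then lexicographic locus id;
merged loci and groups are canonically sorted before ids are assigned, so
re-running on permuted input yields identical output. Group membership and
report rows are byte-stable across runs.

**Degenerate inputs.** Empty genomes or genomes without accepted copies
produce an empty report with a warning, not an error. Zero-length flanks
(a copy starting at a contig edge) are dropped with a warning; flanks
shorter than the seed are reported unmapped; a zero-width locus fetch is
an error.

## What the simulator emulates — and what it does not

`simulate_genomes()` plants cassettes of `flank–SINE–flank` (or
`flank–flank` for minus alleles) on contigs separated by random spacers,
evolves each along the configured topology (substitutions uniform across
sites; indel lengths geometric with mean 3, flanks only), randomizes the
orientation of each locus (shared across genomes, as for a true
orthologous insertion), and emits a truth table with exact per-genome
coordinates. Locus classes cover the full taxonomy: PP/PM/MP pairs,
multimapper loci with a decoy paralogous flank planted in the second
genome, contig-edge truncated copies, and — for 3–4 genomes — the
presence/absence pattern classes (`shared_all`, `informative`,
`contradicting`, `unique`).

Deliberate simplifications: uniform base composition (no GC structure or
repeat landscape beyond the planted decoys), no target-site duplications
or poly-A tails, substitution-only evolution of the planted element
(keeping consensus coverage interpretable), and one SINE family at a time.
Consequently, a passing simulation demonstrates the *mechanics* of the
method — threshold behaviour, strand handling, clustering, resolution,
joining — not its performance on real repeat-rich genomes, where flank
multimapping and assembly artefacts are far more common.

Two generator defaults deserve explanation:

* **Spacers (1400–1800 nt).** The rightward extension grows every flank
  interval by SINE + 300 (= 660 nt with the bundled consensus). If
  planted loci sat closer than twice that extension, neighbouring
  candidate intervals would chain into multi-locus clusters *by
  construction* — a real property of coordinate-file extension, but one
  that would misrepresent the sparse copy spacing (tens of kilobases)
  of real genomes whose copies survive the proximity filter. The default
  therefore keeps spacers above 2 × extension; the chaining regime
  remains reachable by configuring shorter spacers.
* **Decoy flank identity (0.85).** Decoys straddle the 65 % member
  threshold realistically. Note an interaction: with the mapper's
  0.8×best-score secondary retention, a decoy flank much below ~85 %
  identity scores out of the retention band whenever the true ortholog
  maps well, and never reaches the resolver through mapping — which is
  why resolver behaviour is additionally exercised on directly
  constructed groups in the tests.

## Problem sizes

The test suite and the acceptance script run, as the package's reference
desk-scale conditions: a two-genome simulation of 110 loci (50 PP + 30 PM
+ 30 MP) at 5 % flank divergence and 10 % copy-to-consensus divergence;
200 replicates of closest-pair recovery against 1–5 decoys at 60–80 %
identity; oracle-equivalence checks on 1,000 random interval/graph
instances and a 45 kb mapping target; and a four-genome pattern run of 16
loci on `((pra,pmu),dva,lag)`. On one CPU the whole suite finishes in
about three minutes and the acceptance script in about two.

## Known limitations

* Orthology rests on a single 300-bp left flank; loci whose left flank
  diverged past 65 % or was disrupted by another insertion are invisible,
  and the method cannot distinguish "insertion absent" from "ortholog not
  found" (`unknown` is therefore a distinct state in pattern joining).
* Multiple groups are resolved to at most one pair; genuinely duplicated
  orthologous loci export as multilocus sets and leave the pairwise
  statistics.
* Chimeric merged loci are not split; oversized merges surface as poly
  groups for manual inspection.
* The anchor-genome interval join for 3–4 genomes can merge distinct loci
  that overlap in the anchor, and statuses conflicting between tables
  collapse to `unknown`.
* No insertion dating, target-site-duplication calling, or subfamily
  assignment; the consensus is an input, never inferred.
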