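---
title: "Screening metabarcoding ASV tables for non-local species: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening metabarcoding ASV tables for non-local species: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asvscreen)
```

## The problem

Dietary and environmental-DNA metabarcoding is sensitive enough to detect
trace amounts of DNA, which makes it equally sensitive to contamination.
When a well-curated barcode reference library and good knowledge of the
local fauna are available, species-level taxonomic assignment becomes a
contamination detector in its own right: a confidently identified species
whose known range lies hundreds of kilometres away is more plausibly a
false positive than a range extension. `asvscreen` packages that idea as a
reproducible pipeline over denoised amplicon sequence variant (ASV)
tables: assign, filter, flag, characterize the occurrence pattern, and
trace candidate sources.

## Taxonomic assignment rules

Each ASV (typically a 145 bp COI fragment) is aligned against every record
of a reference library of full-length (~658 bp) barcodes. The decision
rules mirror how careful manual identification against a barcode database
proceeds:

* **Coverage.** Matches resting on less than 140 bp of usable overlap are
  discarded. For a 145 bp query that is 96.55% coverage; the package
  treats the base-pair rule (>= 140 bp) as operative and the percentage as
  advisory, because a discard decision needs an unambiguous operational
  form. Such short-overlap matches typically rest on a single partial
  reference record and are phylogenetically isolated.
* **Identity.** An assignment requires at least 97% identity (inclusive)
  over the aligned overlap. Below that the ASV is recorded as "No match".
* **Best match wins.** A unique best-matching species is assigned
  directly. Per species, only its best-identity record is considered, so
  deep reference coverage of common species does not crowd out rarer
  alternatives.
* **Ties.** When several species tie at the top identity, a tie that
  contains at least one locally occurring species resolves to the local
  species (`local_preference_applied` records this); a tie among species
  none of which occurs locally is assigned at the lowest taxonomic rank
  the tied species share — typically the genus, since near-identical
  barcodes are usually congeneric.
* **Confidence classes.** A match with at most 1 bp difference (`strict`,
  equivalent to >99% on 145 bp) is distinguished from an ordinary >= 97%
  match (`standard`). Non-local flags require the strict class: a claim
  that a species occurs far outside its known range should rest on the
  strongest evidence the data can offer.

Two edge cases the rules above do not determine are resolved as follows
and are deliberate package choices: a top tie containing two or more
*local* species resolves to the lowest shared rank of the local candidates
(still recording the local preference), and a tie whose members share no
rank at all — different orders — is conservatively recorded as "No match".

## Alignment: numerical choices

`overlap_align()` computes an end-gap-free *fitting* alignment: the
shorter sequence is placed in full within the longer one, whose unaligned
overhangs are free. Within the aligned overlap, substitutions and internal
gaps each count as one mismatch, and identity is
`100 * (overlap - mismatches) / overlap`. Among all alignments the package
minimizes the mismatch count and, among co-optimal alignments, maximizes
the number of matching columns. This lexicographic objective has a useful
property: the reported overlap length equals `matches + mismatches`, so
identity, overlap and mismatch count are all uniquely determined by the
optimum — no dependence on traceback order, which keeps reports
deterministic.

A score-maximizing local/overlap alignment was considered and rejected:
for divergent pairs it retreats to short high-identity windows, which
would leave distances between distant taxa undefined and would misreport
coverage. The fitting formulation matches how query coverage is actually
assessed (overlap relative to query length) and degrades gracefully: a
100 bp partial reference yields a 100 bp overlap and fails the coverage
rule, exactly the situation the rule exists for.

Ambiguous bases (N and other non-ACGT codes) are accepted on input but
never match anything. This is conservative in the right direction — an
uncertain base pushes an ASV toward "No match" rather than toward a
species claim. Identity ties during adjudication are compared with an
absolute tolerance of 1e-9, i.e. only genuinely equal percentages tie.

## Abundance filtering

Relative read abundances (RRA) are percentages summing to 100 within each
sample. The filter removes, in a single pass over the *raw* abundances,
every entry strictly below 0.1% RRA and every "No match" entry, then
renormalizes the survivors to 100%. Three details matter:

* The comparison is strict (`< 0.1%`): an entry at exactly 0.1% survives.
* Both criteria are evaluated against the raw RRA in one pass; there is no
  cascade in which removing one entry pushes another below the threshold.
  Because renormalization only increases surviving values, the filter is
  idempotent.
* Merging by identity sums abundances per exact assignment (rank plus
  name): two ASVs assigned the same species pool, while a genus-level
  assignment in that genus remains a separate key.

An optional per-sample minimum read total (`min_total_reads`, default off)
drops grossly under-sequenced samples at load time, and an optional
negative-control filter (`negative_control_filter`, default off) zeroes
cells at or below the maximum count of that ASV across negative controls.
Both default off because the workflow this package models reports control
counts but applies no subtraction, and fixes no read-total cutoff.

## Non-local flagging and occurrence patterns

A species is *non-local* when its nearest known occurrence lies strictly
more than 200 km from the study area (200 km exactly counts as local).
A flag is one (ASV, sample) occurrence whose assignment is species-rank,
strict-confidence, and non-local. Occurrences that narrowly miss — a
standard-confidence match to a non-local species, or a genus-level tie
whose candidates are all non-local — are reported in a near-threshold side
list rather than flagged, because such cases repay manual inspection but
do not carry flag-grade evidence. Species absent from the locality
checklist are listed as "unknown locality", never silently treated as
local.

Patterns across samples are summarized three ways:

* **Occurrence matrices** order samples by field collection date or by lab
  processing index (ties broken lexicographically by sample id). Clusters
  in processing order but not collection order point at a laboratory
  point-source event; the reverse points at a field-side process.
* **Ordering concentration** makes that visual comparison quantitative:
  the statistic is the mean absolute pairwise difference of occupied
  positions, and its p-value is the fraction of uniform random position
  sets (drawn without replacement; 10,000 permutations by default, seeded)
  at least as concentrated. This statistic is a package addition, labelled
  as such in output — the underlying study design compares the orderings
  visually.
* **Depth and richness correlates** are Spearman rank correlations
  (average ranks for ties) between each sample's total non-local RRA and
  (i) its total raw read count, (ii) its raw ASV richness — both computed
  on pre-filter data including "No match" and sub-threshold ASVs, since
  artefact-prone samples are precisely the ones whose filtered data look
  clean. Per-sample totals (not per-ASV points) are used; samples with
  zero non-local content contribute zeroes. A constant vector has no rank
  correlation and yields `NA`.

Technical replicate pairs are compared with `replicate_concordance()`:
Jaccard similarity of presence sets, the same restricted to taxa at or
above 1% RRA, and the discordant-taxon list. Abundant taxa are expected to
agree between subsamples; rare taxa often appear in only one.

## Provenance tracing

Flagged sequences are compared against suspect source sets (e.g. sequence
sets handled in the same laboratory by unrelated projects) with the same
aligner; exact matches short-circuit, and near matches report mismatch
counts and 0-based mismatch offsets. Pairwise p-distances
(mismatches/overlap, no substitution-model correction — on 145 bp
fragments model correction would be spurious precision) feed
neighbor-joining trees. The NJ implementation is the canonical
agglomeration with two determinism policies: equal Q-criterion pairs are
joined smallest-label-pair first, and negative branch lengths (possible on
non-additive inputs) are clamped to zero with the deficit moved to the
sister edge so the joined pair's mutual distance is preserved. On additive
matrices the generating topology and branch lengths are recovered exactly
(verified for up to eight taxa against an independent implementation).

`homopolymer_discrepancies()` detects the characteristic
semiconductor-sequencer error in which a homopolymer run is read one base
short (seven T's read as six): it reports alignment positions where the
only local difference is a run-length change inside a single-base run of
length at least two in both sequences. Substitutions are never reported as
run events. `near_threshold_neighbors()` scans unassigned ("No match")
sequences for members within four mismatches of a flagged cluster — just
beyond the 97% assignment radius on 145 bp — since error variants and
chimera fragments of a contaminant tend to accumulate below the
assignment threshold.

## The synthetic-data generator

`generate_dataset()` produces complete, loadable datasets with
ground-truth origin labels. Its defaults are the study conditions the
package models, fixed once and not tuned per analysis:

| Parameter | Default | Unit / meaning |
|---|---|---|
| samples | 94 across five categories + 2 negative controls | the focal batch layout |
| sequencing depth | mean 28,000, sd 7,000, min 1,000 | reads/sample, drawn normally |
| season | 2017-05-14 – 2017-07-17 | field collection dates, uniform |
| reference pool | 20 local + 10 foreign species, 2 congeneric pairs | 658 bp barcodes |
| amplicon | positions 201–345 of the barcode | fixed 145 bp window |
| interspecies divergence | >= 2% p-distance in the window | the "barcode gap" |
| within-species haplotypes | 3 species with a 1 bp-variant second record | <= 1% divergence |
| lab scenario | middle third of processing order, 5 foreign species, 0.5–20% RRA, p = 0.7 | per-sample injection |

Community composition is log-normal over a random subset of the local
pool, sampled multinomially — the standard abundance model; observed RRA
ranges (per-sample non-local totals up to ~55%) calibrate the injection
levels, as no quantitative contamination rate is available to emulate.
Contaminant ASVs are the amplicon window of the foreign species' own
reference, so a perfect library makes them 100%-match, strict, species
assignments — which is the point: the generator tests the *screening*
logic, not the assignment difficulty. Sequencing noise (substitution
variants, homopolymer run-shortening, chimeric recombinants at a uniform
breakpoint) is off by default and switched on explicitly in the tests that
target it.

What the generator does **not** emulate: PCR primer bias and
taxon-specific amplification efficiency, tag-jumping between samples,
reference-library misannotation, intraspecific haplotype geography, and
NUMT co-amplification. Passing recovery tests therefore demonstrate that
the decision rules compose correctly under the stated statistical model —
they do not certify performance on real data, where assignment ambiguity
and abundance distortion are harsher.

## Validation scale and reproducibility

The shipped test-suite checks run at desk scale: alignment equivalence
against a brute-force dynamic-programming oracle on 500 random pairs up to
80 bp; 1,000 random tie structures for the adjudication properties; 1,000
random profiles for filter idempotence and conservation; NJ recovery for
4–8 taxa; 50 seeded replicates for the paired ordering-concentration
comparison (24-sample datasets, 400 permutations). The acceptance script
simulates the full 94-sample layout with 2,000 permutations. A single
master seed is threaded through every random draw; repeated runs are
byte-identical, and report files are written with fixed column order and
fixed float formatting so identical analyses produce identical bytes.

## Known limitations

* The identity rules emulate careful manual use of a barcode database but
  make no claim of being byte-equivalent to any particular database's
  internal scoring, whose gap treatment is not published; the gap-as-
  mismatch choice is documented above.
* Species-name synonymy is the caller's responsibility: checklist and
  reference names must be pre-normalized binomials.
* The concentration statistic tests position clustering only; it has no
  power against a contamination process spread uniformly across the
  processing order.
* No probabilistic (Bayesian) taxonomic placement is included; the
  package's rules are deterministic by design so that every flag is
  auditable.
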