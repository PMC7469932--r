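---
title: "CAPS marker design and S-RNase genotyping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CAPS marker design and S-RNase genotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsforge)
```

## The problem

Gametophytic self-incompatibility (GSI) in *Prunus* is controlled by the
multi-allelic S-locus: a pollen grain whose S-haplotype matches either
S-allele expressed in the pistil is arrested in the style. Orchard design
and breeding therefore need a reliable way to determine each tree's pair
of S-alleles. The pistil-side determinant, the S-RNase gene, is the
standard proxy: its C2–C3 intragenic region (which contains Intron II and
the hypervariable RHV segment) is both length- and sequence-polymorphic,
so a CAPS (cleaved amplified polymorphic sequence) assay — PCR with
degenerate primers anchored in the conserved C2 and C3 regions, followed
by restriction digestion — can assign alleles from agarose band patterns
alone.

`capsforge` implements the full workflow around such an assay: choosing a
target region by alignment variability statistics, simulating digestions,
searching for a minimal set of discriminating enzymes, emitting a
human-readable CAPS guide, calling alleles and genotypes from observed
band sizes, and classifying crosses under the GSI model. It also ships
the published capuli (*Prunus serotina* subsp. *capuli*) reference guide
as a validated machine-readable fixture.

## Digestion model

Recognition sites are IUPAC motifs with a cut offset (`RsaI = GT^AC`).
All coordinates in the package are 0-based and half-open; cut positions
are between-base indices. Digestion is *complete*: every site is cut, so
each allele maps deterministically to one fragment multiset. This mirrors
assay practice, where digests are run to completion precisely so that one
allele shows one pattern.

Sites are recognised on both strands. A window matching the motif on the
top strand cuts at `position + offset`; a window matching only as the
reverse complement cuts at `position + site_length − offset` (the
bottom-strand offset mapped back to top-strand coordinates). A window
matching in both orientations — every occurrence of a self-reverse-
complementary motif such as `GANTC` — is a single double-strand break and
is counted once, at the top-strand cut. Counting both orientations
independently would double every staggered palindromic cutter's site.
Cuts falling exactly at a sequence end are discarded (they would create
empty fragments).

In-silico PCR is identity-based: a degenerate primer binds wherever its
IUPAC motif matches (set-intersection semantics); there is no
thermodynamic or mismatch model. Each forward site is paired with the
nearest downstream reverse site, the shortest product that dominates a
real PCR. Heterozygous or concatenated templates legitimately produce
two products; digestion is always per-amplicon, reflecting the practice
of gel-purifying each PCR band before digestion.

## Gel observation model

Fragment multisets are reduced to what a 2% agarose lane shows by three
tunable parameters of `gel_model()`:

* `min_detectable` (default 80 bp) — smaller fragments run off or stain
  too weakly to score;
* co-migration tolerance `max(comigration_floor, comigration_tol ×
  larger)` (defaults 10 bp and 5%) — fragments closer than this merge
  into one band at the rounded mean;
* `rounding_step` (default 5 bp) — band sizes are read off at this
  granularity, matching the granularity of published band tables (e.g.
  465, 495, 225).

Merging proceeds greedily from the largest fragment downward and is
iterated to a fixed point: a single pass of merge-and-round can leave two
bands within tolerance of each other, and the fixed point makes
`observe_bands()` idempotent (observing an already-observed band set
changes nothing), a property the test suite asserts. The published assay
does not state its resolution criterion, so these defaults are explicit
knobs, not facts; `exact_gel_model()` disables all three effects for
purely in-silico comparisons.

## Panel search and guide construction

`screen_enzymes()` annotates a catalogue with the fraction of alleles cut
and shortlists enzymes cutting at least 80% of them — the screening
criterion used in assay design practice. `min_discriminating_panels()`
then searches for the smallest enzyme subset whose combined fingerprints
separate every allele pair under the active gel model. The search is
exhaustive for shortlists of up to 15 enzymes (at most 2^15 subsets,
trivially fast) and greedy forward selection beyond; equal-size panels
are ranked by the band-size gap at their hardest allele pair (robuster
gels first), then lexicographically, making results deterministic.
Because indistinguishability depends on the gel model, the search can be
run both at gel tolerance and at zero tolerance to see whether ambiguity
is sequence-level or resolution-level.

`build_guide()` groups each enzyme's indistinguishable patterns
(transitive closure under the gel model), assigns pattern letters in
ascending order of largest band size, and composes one letter code per
allele (e.g. `PJN`). Guide codes must be pairwise distinct or
construction fails, naming the confounded pairs. The packaged capuli
guide is loaded as data with its published letters: the published
per-enzyme letter ordering is not fully derivable from any single sorting
rule, so re-deriving letters for published data is deliberately avoided.

## Calling model

`match_pattern()` accepts a letter when band counts agree and every size
pair lies within `max(tol_bp, tol_frac × size)` — defaults 10 bp and 5%,
reflecting 2% agarose resolution; the published assay matched patterns
visually and states no numeric criterion, so the tolerance is fully
configurable and a zero-tolerance mode serves in-silico data. Among
multiple matching letters the smallest total deviation wins; exact ties
propagate as an ambiguous call listing candidates rather than a guess.
Observed bands below the guide's detection limit are dropped before
matching, in symmetry with the design-time gel model.

A composite code absent from the guide (or containing an unmatched
letter) is a novel allele. Novel designations continue the registry
numbering (`S_19` after a catalogue ending in `S_18`) and are keyed by
the observed pattern, so the same unknown pattern in different
individuals receives the same designation within a calling session.
Genotype calling follows the two-bands-per-individual heterozygote model
used in the reference study; single amplicons are accepted only with an
explicit homozygote flag, and more than two are rejected — the species is
allotetraploid, but the published assay resolves exactly two amplifiable
S-RNase bands per tree, and the package models that observation rather
than a dosage model. This is a documented biological caveat, not a claim
about ploidy.

## GSI crossing model

`classify_cross()` applies the standard GSI rule: each pollen haplotype
is rejected iff its allele occurs in the receptor pair, giving a
compatible pollen fraction of 0, 0.5 or 1 (incompatible, semi-compatible,
compatible). Semi-compatibility is modelled and reported distinctly even
though fully contrasted crossing designs avoid it: it is the standard GSI
consequence of sharing one allele and is needed for orchard planning.
Selfings of heterozygotes are always incompatible under the model.
Observed breakdown of GSI (crosses in which pollen tubes of a nominally
incompatible pairing reach the ovary) is outside the model: the package
predicts expected classes only.

## Variability statistics

Per-column Shannon entropy, `H = −Σ p·log2 p` in bits (base 2 matches the
protein-variability-server convention), is computed on protein
alignments; gap characters are excluded from column counts by default
(configurable to count the gap as a 21st symbol), and all-gap columns are
flagged undefined. A region's value is the arithmetic mean of its
defined positional entropies — published region indices do not state
their aggregate, and the mean is the transparent choice.

Ka/Ks follows Nei–Gojobori (1986): synonymous site fractions by the
one-third rule (mutations to stop codons count as nonsynonymous, so
`S + N = 3` per codon exactly), differences averaged over all mutational
pathways with stop-passing pathways excluded (when every pathway passes a
stop, all are kept with stop steps counted as nonsynonymous), and
Jukes–Cantor correction `d = −3/4·ln(1 − 4p/3)`, flagged as saturated
when `p ≥ 3/4`. Codons containing gaps or ambiguity codes are skipped
pairwise — per sequence pair, not per column — and counted. The sliding
window (default 20 codons, step 1 codon; published analyses state only
the window length) computes per-pair Ka and Ks from window-local site and
difference sums, averages over all sequence pairs, and reports the ratio
of mean Ka to mean Ks; windows with zero or undefined mean Ks are flagged
undefined rather than infinite. At full window length this reproduces the
global pairwise aggregate by construction.

## Synthetic panels

`generate_panel()` emulates the data regime the assay was designed for: a
scaffold in the 1000–2150 bp amplicon range whose interior hypervariable
region (default the central half) is diversified per allele by
substitutions (default 5% per base) and indels (Poisson events, default
mean 3 per allele; geometric sizes, default mean 15 bp — producing the
length-polymorphic amplicons seen on assay gels), flanked by embedded
binding sites for the capuli degenerate primer pair. Primer sites and
flanks are never mutated, so amplification succeeds for every allele;
pairwise distinctness is enforced by regeneration, and a mandatory seed
makes output byte-identical across runs. The generator does *not*
emulate real S-RNase evolution (no recombination or balancing-selection
dynamics), no sequencing error, and no partial digestion — so passing
round-trip tests demonstrate correctness of the pipeline under its own
model, not robustness to every laboratory artefact. Test problem sizes
(11-allele panels, ≤200 bp property-test sequences, 60-codon scan
alignments) were chosen as the smallest sizes that exercise every code
path of interest.

## Numerical and degenerate-input choices

* Band sets are compared in descending rank order; sets of unequal size
  are always distinguishable.
* An all-sub-detectable digest yields an empty band set with a warning,
  not an error.
* `find_cut_sites()` deduplicates overlapping occurrences by cut
  coordinate; overlapping motif occurrences all count.
* Ambiguous letter matches refuse to guess; crossing refuses unresolved
  genotypes with a reason.
* The novel-allele index parser reads any trailing integer, falling back
  to the catalogue size when ids are non-numeric.

## Known limitations

* No nicking enzymes, two-site enzymes, or methylation sensitivity; no
  partial-digest ladders; linear amplicons only.
* No thermodynamic PCR model: primer binding is IUPAC identity.
* The genotype model is diploid-style (two alleles) despite the species'
  allotetraploidy, following the observed two-band behaviour.
* Region-level entropy and Ka/Ks values for the published capuli
  alignment depend on accession sequences and on region boundaries that
  are published only graphically; the package provides the machinery and
  region annotations as inputs rather than asserting those coordinates.
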