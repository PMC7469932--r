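# capsforge

CAPS marker design and S-RNase allele genotyping for gametophytically
self-incompatible *Prunus*.

## What problem this solves

In *Prunus*, fruit set is limited by gametophytic self-incompatibility
(GSI): a pollen grain carrying an S-allele that matches either pistil
S-allele is arrested in the style, so trees sharing both S-alleles (an
*incompatibility group*) cannot pollinate each other. Orchard design and
breeding therefore require S-genotyping every tree. The S-RNase gene is
the standard pistil-side proxy for S-haplotype identity, and its C2–C3
intragenic region — containing Intron II and the hypervariable RHV
segment — is polymorphic enough that a CAPS (cleaved amplified
polymorphic sequence) assay can resolve alleles from agarose band
patterns: amplify the region with degenerate primers anchored in the
conserved C2/C3 regions, digest with a small panel of restriction
enzymes, and read each allele's composite fingerprint (e.g. `PJN` =
pattern P with RsaI, J with MboI, N with HinfI).

`capsforge` is a toolkit for building and using such assays:

* **in-silico digestion** — IUPAC recognition sites with cut offsets,
  double-strand site mapping, complete-digest fragment multisets, and a
  tunable gel-observation model (detection limit, co-migration merging,
  size rounding);
* **in-silico PCR** — degenerate-primer binding-site search and amplicon
  extraction, including multi-product (heterozygous) templates;
* **marker design** — enzyme screening by fraction of alleles cut,
  exhaustive/greedy search for minimal discriminating enzyme panels, and
  CAPS-guide construction with per-enzyme pattern letters and composite
  codes (JSON serialisable);
* **genotyping** — tolerance-based matching of observed band sizes to
  guide patterns, composite-code lookup, consistent novel-allele
  designation (`S_19` after a catalogue ending at `S_18`), and two-allele
  genotype calling;
* **GSI crossing** — compatible / semi-compatible / incompatible
  classification by the pollen-rejection rule, incompatibility groups,
  and full cross matrices;
* **target-region statistics** — per-column Shannon entropy on protein
  alignments and Nei–Gojobori (NG86) Ka/Ks with Jukes–Cantor correction
  and a sliding window (default 20 codons) on codon alignments;
* **synthetic panels** — seeded generation of primer-flanked,
  indel-rich allele panels with ground truth for end-to-end testing;
* a packaged, validated transcription of the published capuli
  (*Prunus serotina* subsp. *capuli*) S-RNase CAPS reference guide,
  orchard genotyping observations and crossing plan.

The core statistic of the calling model: a pattern letter matches
observed sizes iff band counts agree and every size pair is within
`max(tol_bp, tol_frac × size)` (defaults 10 bp, 5%); Ka/Ks follows NG86
with one-third-rule site counts, pathway-averaged differences and
`d = −3/4·ln(1 − 4p/3)`.

## Worked example

Genotype the seven orchard trees of the packaged capuli reference data
against the published guide:

```r
library(capsforge)
guide <- capuli_guide()            # published Tables: letters + codes
obs   <- capuli_observations()     # per-band sizes, letter-expanded
res   <- call_observations(obs[, 1:4], guide)
res$genotypes
#>   individual allele1 allele2
#> 1          1     S_8    S_19
#> 2         12     S_4     S_9
#> 3         13     S_4     S_9
#> 4         14    S_20    S_21
#> 5         15    S_10     S_6
#> 6         17     S_4     S_1
#> 7         22     S_4     S_1
```

Nine distinct alleles are called; `S_19`–`S_21` are novel designations —
their composite codes (`QPR`, `OQI`, `RRF`) match no catalogue entry, so
the registry numbers them after the last catalogued allele `S_18`. Trees
sharing both alleles form incompatibility groups and cannot pollinate
each other, while allele-disjoint pairs are fully compatible:

```r
incompatibility_groups(res$genotypes)
#>   group alleles members
#> 1   IG1 S_1,S_4   17,22
#> 2   IG2 S_4,S_9   12,13
classify_cross(c("S_1", "S_4"), c("S_8", "S_19"))
#> Cross (S_1,S_4) x (S_8,S_19): compatible (pollen fraction 1.0)
```

Digestion and the gel model compose the same way for your own sequences:

```r
rsai <- default_enzymes()[["RsaI"]]
digest_complete("AAGTACAATTTTGTACGG", rsai)
#> Digestion with RsaI : 10, 4, 4 bp
observe_bands(c(212, 208, 950, 60))   # merge 212/208, drop 60
#> Bands : 950, 210
```

A command-line interface wrapping the same functions is installed at
`exec/capsforge` (subcommands `digest`, `design`, `guide`, `call`,
`cross`, `scan`, `simulate`); see `capsforge help`.

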