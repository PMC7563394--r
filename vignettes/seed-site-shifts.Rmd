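---
title: "Methods: allele-aware seed-site scanning for 3'UTR variant prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-aware seed-site scanning for 3'UTR variant prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedshift)
library(dplyr)
```

## The problem

MicroRNAs repress their target mRNAs by pairing with miRNA recognition
elements (MREs) in 3' untranslated regions. Recognition is dominated by the
miRNA *seed*, nucleotides 2-8 from the 5' end. A single-nucleotide variant
(SNV) inside or next to an MRE can therefore rewire post-transcriptional
regulation in one of three ways: it can **destroy** an existing site
(target loss), **create** a site where none existed (target gain), or do
both at once, handing the site from the curated miRNA to a different one
(**substitution**). seedshift implements a reproducible pipeline for
finding and prioritizing such variants in curated miRNA-gene pairs:
allele-aware seed-site scanning, an isoform-wide 3'UTR-exclusivity filter,
tissue-expression normalization and brain-enrichment ranking,
variant-centered window extraction for cross-species motif work, and a
Fisher exact test for motif presence across 3'UTR sets.

## Site model

We use the canonical seed-match taxonomy, in decreasing efficacy:

| type | UTR match (mRNA-sense) | length |
|---|---|---|
| 8mer | revcomp(miRNA 2-8) followed by A | 8 |
| 7mer-m8 | revcomp(miRNA 2-8) | 7 |
| 7mer-A1 | revcomp(miRNA 2-7) followed by A | 7 |
| 6mer | revcomp(miRNA 2-7) | 6 |

Pairing is strict Watson-Crick; there is no G:U wobble, no 3'-supplementary
pairing and no context scoring. The A1 adenosine is treated as a sequence
requirement of the UTR (it is recognized by Argonaute directly, not by
pairing), which is why a variant hitting the A1 position can alter the site
type. Every site is anchored at an occurrence of the 6mer core
(`revcomp(2-7)`); at each core locus only the strongest applicable type is
reported, so a reported 7mer-m8 really means "m8 pairs but the A1 position
is not an A". U and T compare as equal; UTRs are stored as mRNA-sense DNA
and miRNAs as RNA.

This scanner is deliberately a transparent, testable stand-in for database
lookups of precomputed target-site SNVs, which aggregate heterogeneous
prediction tools behind closed scores. We make no claim of per-variant
concordance with any such ensemble; what the scanner guarantees is an
exact, brute-force-verifiable definition of "site", which is what a
classification of loss/gain/substitution needs to be falsifiable.

## Variant classification

For a variant and its curated pair, `classify_snv_effect()` compares the
sites *overlapping the variant's UTR offset* on the reference and
alternate alleles, across the whole mature miRNA library:

* **loss** - the paired miRNA has an overlapping reference site, none on
  the alternate, and no other library miRNA gains one;
* **substitution** - the paired miRNA loses its site and a *different*
  library miRNA has an alternate-only overlapping site;
* **gain** - the paired miRNA has no overlapping reference site and some
  library miRNA (any) has an alternate-only overlapping site;
* **none** - otherwise.

Gain is assessed against the whole library, not just the paired miRNA,
because a new site is biologically a new binding regardless of which miRNA
acquires it; all alternate-only matchers are reported in `gained_mirnas`.
"Overlapping" includes the A1 position, since the A1 base is part of the
site definition here. Alleles in variant records are plus-strand genomic
bases; for minus-strand transcripts they are complemented and applied at
the mirrored offset, and a reference-allele mismatch against the stored
UTR sequence is a hard error rather than a silent skip.

## Isoform exclusivity

A variant position can be 3'UTR in one isoform and coding in another.
The filter keeps a variant only when it is covered by at least one
transcript and **every** covering transcript annotates the position as
3'UTR. Transcripts that do not cover the position carry no information
about it and are ignored; a variant covered by no transcript at all fails
the filter (its region is unknowable, and downstream stages need a gene
assignment); a position claimed by transcripts of two different genes is
flagged ambiguous and dropped with an audit record. The filter is
annotation-agnostic: it applies to whatever transcript set it is given and
makes no assumption about a particular release.

## Expression normalization and brain enrichment

Tissue expression (median-TPM-like, genes x tissues) is normalized as
`10 * log10(x + 1)`. Base 10 with pseudocount 1 is the only choice under
which "take the logarithm and multiply by ten" maps 0 to exactly 0 and
yields the conventional decibel-like scale (9 -> 10, 99 -> 20); the
transform is strictly monotone, so it never reorders values within a gene.
Brain enrichment is summarized per gene as
`(mean brain + eps) / (mean non-brain + eps)` with `eps` defaulting to the
same pseudocount; the ratio is an explicit addition of this package - the
qualitative claim it makes reproducible is "high in brain relative to
elsewhere" - and ties are broken by gene label so ranks are deterministic.
Brain columns are identified by a configurable label list defaulting to
the 13 GTEx brain sub-tissues.

## Windows and the motif presence test

`extract_window()` cuts a fixed-width window around a variant for
cross-species comparison; with the default even width 100 the variant sits
at offset 50 (the window spans 49 bases before and 50 after), and windows
are clipped at UTR boundaries with the offset adjusted. `count_motif()`
counts a motif and its reverse complement at every start offset, overlaps
allowed, counting palindromes once per offset; a transcript is *present*
when either orientation occurs at least once.

`fisher_presence_test()` builds the 2x2 presence/absence table and
computes the standard two-sided exact p (sum of all tables with the
observed margins whose probability does not exceed the observed one).
Because the original report does not state how its contingency table was
constructed, two background modes are provided:

* **control** (default) - a second transcript set supplies the background
  row, observed counts on both sides;
* **analytic** - the expected presence count under an i.i.d. nucleotide
  model with the foreground's own base composition: per transcript of
  length L, window hit probability `p = P(motif) + P(revcomp)` and
  presence probability `1 - (1 - p)^(L - m + 1)`, summed and rounded.

Presence, not occurrence count, enters the test; occurrence totals are
reported descriptively. One numerical caveat worth knowing: the exact
two-sided p is discrete, and on small transcript sets (tens per side) it
is visibly conservative - the null p-value distribution sits above
uniform. At the scale the test is meant for (hundreds to thousands of
3'UTRs per side) calibration is good; the acceptance suite checks
near-uniformity (Kolmogorov-Smirnov distance < 0.1 over 500 null
replicates) at 1000 transcripts per side, which runs in about a minute.

## The synthetic-data generator

Nothing in the pipeline can be validated against public downloads from a
desk, so `synthesize_study()` generates every input with planted ground
truth: background UTR sequence i.i.d. at configurable GC; an 8mer of the
paired miRNA written in and then broken by the variant (loss); a
one-base-broken 6mer of another library miRNA that the variant repairs
(gain); a destroyed 8mer whose alternate-allele neighborhood is the seed
match of a purpose-built helper miRNA (substitution); and untouched
positions (none). Every planted event is re-checked at generation time
with an exhaustive window-comparison scanner, and events are re-drawn
until the realized classification equals the intended label, so emitted
labels are guaranteed consistent with emitted sequences - the generator
refuses to emit otherwise. Multi-isoform models share the 3'UTR interval,
except in designated non-exclusive genes where a second isoform's CDS
extends over the first 60 UTR bases, making the planted variant fail the
exclusivity filter by construction. Expression gets a planted
brain/non-brain ratio rho with lognormal noise (mean-corrected, so the
planted ratio is unbiased on the TPM scale).

Default scale mirrors a small curated study: ~100 pairs, a few dozen
genes, 2-4 isoforms per gene, UTRs of 0.3-3 kb, 53 tissues of which 13
are brain, rho = 10, lognormal sdlog 0.25. Identical seeds give
byte-identical bundles. What passing recovery tests show is that the
pipeline's bookkeeping - coordinates, strands, alleles, isoforms,
classification logic - is exact; what they cannot show is performance on
real sequence, where sites cluster, composition is non-i.i.d., and real
prediction requires context the canonical seed model deliberately omits.

## Other numerical and design choices

* Internal coordinates are 1-based inclusive on the plus strand
  everywhere; conversions (BED 0-based half-open, GTF 1-based) happen only
  at file boundaries, and chromosome labels compare after stripping an
  optional `chr` prefix.
* Multi-allelic VCF rows split into one record per alternate allele;
  non-SNV rows are skipped with a warning, malformed rows are hard errors
  naming the line.
* Alias resolution is case-insensitive and single-hop; tables with alias
  chains are rejected at load, so resolution can never cycle. Unknown
  names are carried as explicit unresolved markers, never dropped:
  input count = resolved + unresolved, always.
* Precursor-level miRNA names expand to their mature arms. Which arm a
  curated pair means is genuinely ambiguous in pair lists, so the policy
  is configurable (`both`/`5p`/`3p`) and defaults to both arms (union of
  sites), the choice that cannot silently miss a planted or real site at
  the cost of some extra scanning.
* When several miRNAs gain at the same locus, all are reported;
  classification is unaffected by the tie.
* Degenerate inputs: empty variant sets, empty site lists, header-only
  reports and zero-count Fisher tables are all legal and exercised in the
  tests; `p = 1` is returned for the empty table.

## Known limitations

* Canonical seeds only - no wobble pairing, no 3' compensatory sites, no
  thermodynamic or machine-learned context scores; a site here is a
  necessary-but-not-sufficient signal for repression.
* The exclusivity filter is only as good as the transcript models given;
  with a partial annotation, "exclusive" means exclusive within that
  annotation.
* The brain-enrichment ratio is a descriptive ranking statistic, not a
  tissue-specificity test; it comes with no p-value by design.
* The analytic Fisher background assumes i.i.d. composition, which real
  3'UTRs violate; the control-set mode is the default for that reason.
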