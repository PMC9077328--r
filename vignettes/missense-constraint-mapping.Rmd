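---
title: "Mapping missense constraint onto protein sequences and structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping missense constraint onto protein sequences and structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(missensemap)
```

## The model

Population exome databases record, for each gene, the missense variants
observed in a large cohort of unrelated adults together with their allele
frequencies. Under purifying selection, residues essential for function
accumulate fewer neutral missense variants than the protein average.
`missensemap` turns that depletion signal into three quantities:

* a **per-residue profile**: for each residue with at least one retained
  variant, the summed allele frequency, the variant count, and a
  log-frequency bin;
* the **whole-protein variant density** `Vp = variable positions / length`,
  where a *variable position* is a residue carrying at least one retained
  missense variant (multiallelic residues count once);
* the **per-domain depletion ratio** `Vd/Vp`, with
  `Vd = variable positions in the domain / domain length`. A ratio below 1
  indicates the domain tolerates fewer substitutions than the protein
  average; a domain covering the whole protein scores exactly 1 by
  construction.

The method's central assumptions are that (i) the filtered variant set is
effectively neutral, so depletion reflects selection rather than
ascertainment; (ii) allele frequencies of distinct substitutions at one
residue can be treated as probabilities of disjoint events and summed; and
(iii) the export's protein consequences are reported on the same canonical
sequence numbering as the user's domain boundaries and structures.

## The neutral filter

A record is kept when its VEP consequence is missense (both the export
spelling `missense_variant` and the plain `missense` are accepted) and its
ClinVar clinical significance is absent, benign-class, or otherwise not in
the excluded set {pathogenic, likely pathogenic, conflicting
interpretations of pathogenicity, uncertain significance}. Matching is
case-insensitive after trimming and collapsing whitespace, and multi-valued
cells (`Benign/Likely benign`) are split on `/` and `;` with exclusion if
*any* token matches — the intent is to filter by annotation class, not by
exact string. Three further rules are defensive: rows whose parsed
consequence is synonymous never survive (so `ref != alt` holds for every
retained record even if the export mislabels a row), rows with
`allele_number = 0` or a frequency outside [0, 1] are rejected at parse
time, and rows with no VEP annotation at all fail the filter and are
counted separately in the filter report. Duplicate rows are kept as-is
unless the caller opts into deduplication; an export is trusted to mean
what it says.

## Aggregation and binning

Frequencies at a shared residue are summed and capped at 1 — the sum of
disjoint-event probabilities cannot exceed 1, and adversarial synthetic
input can otherwise push it past. The summed frequency is assigned to one
of six bins, one per decade on a base-10 log scale: bin *k* covers
`(10^(k-6), 10^(k-5)]`, every frequency at or below `1e-5` (including
those below `1e-6`) falls in bin 1, and `af = 1` lands in bin 6. Intervals
are half-open on the left and closed on the right; the decade edges are
compared against literal powers of ten via `findInterval()`, so `1e-4`
sits deterministically in bin 2 without floating-point log/ceiling
round-off. The profile stores the raw summed frequency — the log transform
is implicit in the bin edges — so exports round-trip exactly.

Records with `af = 0` are dropped before aggregation (log-scale binning is
undefined at zero) and records whose position exceeds the protein length
are skipped, both with warnings and counters rather than errors: numbering
mismatches between isoforms are common in real exports and should not kill
a batch run. `Vp` uses the canonical protein length supplied by the caller
as its denominator, not the length of whatever structure fragment is later
annotated.

## Vd/Vp numerics

Ratios are computed from integer position counts, so they are exact:
whole-protein domains give `1` identically, disjoint partitions of the
protein are additive in variable-position counts, and the ratio is
invariant to any rescaling of allele frequencies (only *which* positions
are variable matters). When a protein has no retained variants, `Vp = 0`
and the ratio is reported as an explicit undefined flag rather than a
division by zero — legal on sparse synthetic inputs. Overlapping or nested
domains are each scored independently. Reported tables carry the ratio to
full precision alongside a two-decimal label for figures.

## Structure mapping and script emission

Profiles map onto a single chain of a PDB or mmCIF structure through a
constant integer offset (`structure residue = profile position + offset`).
Every profile position resolves to exactly one of *mapped* or *unmapped*,
with a reason: absent from the chain, lacking a Cα atom (spheres are drawn
at Cα), or — when a pLDDT threshold is active — confidence at or below the
cut-off. For predicted models the conventional default is `plddt_min = 70`,
the usual boundary for a generally correct backbone, read from the
B-factor column; for experimental structures masking is off unless
requested. Chains containing insertion codes are rejected outright: a
constant offset cannot address them unambiguously, and silent mis-mapping
is worse than failure. Multi-chain structures are annotated one chain per
invocation.

The emitted PyMOL script creates one named selection per non-empty bin
(`af_bin1` … `af_bin6`, residues in ascending order) plus a `pathogenic`
selection for overlaid curated variants. The default style is radii
0.8–2.8 Å in 0.4 Å steps and a six-step light-to-dark blue ramp, with
pathogenic positions in red at 2.0 Å; only the monotone increase of size
and shade with frequency is meaningful, and all values are configurable
through `style_spec()`. Emission is a pure function of its inputs —
identical annotation, style and structure path give byte-identical files —
so scripts can be diffed and versioned.

## The synthetic generator

`generate_variant_table()` emulates a per-gene population export with known
ground truth: region-wise variant densities with engineered depleted
segments, log-uniform allele frequencies, multiallelic residues, benign and
empty ClinVar annotations on neutral rows, and contaminating rows that the
filter must remove (excluded ClinVar classes; synonymous and stop-gained
consequences). Its defaults are fixed study conditions, not tuning knobs:

* background density 0.35, inside the 0.29–0.42 band observed for
  well-covered human proteins in population exome data;
* allele frequencies `10^U(-6.5, 0)`, wide enough to populate all six
  bins; counts are materialised as `AC = max(1, round(af * 251496))` out
  of a fixed 251,496 alleles (a full exome call set), so `AF = AC/AN`
  holds exactly and the rarest achievable frequency is one allele;
* contamination of 1.5% excluded-ClinVar and 5% non-missense rows, the
  order of magnitude such exports carry;
* a 10% multiallelic rate among variable residues.

By default each region contributes **exactly** `round(length * density)`
variable positions, placed uniformly at random (stratified sampling); a
`bernoulli` mode draws each residue independently instead. The stratified
default was chosen because domain-recovery experiments at realistic domain
sizes (hundreds of residues) should measure the pipeline's arithmetic, not
the binomial noise of the generator — under independent draws the sampling
error of a 200-residue domain's density (±20% relative) would dominate any
pipeline defect. The Bernoulli mode exists precisely to test that noise
model where it is wanted.

What the generator does **not** emulate: codon structure and per-codon
mutability (substitutions are drawn uniformly from the 19 non-reference
amino acids), sequencing-coverage variation along the gene, per-site
allele-number variation, linkage between variants, and mutational hotspots
such as CpG transitions. Tests passing on synthetic data therefore
demonstrate that the filtering, aggregation, ratio and rendering machinery
is correct, not that biological conclusions from any particular real
export are.

The toy structure generator writes an ideal poly-alanine Cα helix (rise
1.5 Å, 100° twist, radius 2.28 Å, hence consecutive Cα–Cα distances near
3.8 Å), sufficient for mapping and emission tests without real
coordinates; it is synthetic and labelled as such.

## Test problem sizes

The suite checks aggregation against a brute-force per-position oracle on
random instances of up to 50 records, Vd/Vp against a counting oracle on
1,000 random small proteins, domain recovery on 100 generator seeds at
length 10,000 (background 0.4, one 200-residue domain at 0.1, generating
ratio ≈ 0.25), and end-to-end agreement between the generator's sidecar
and the full filter → aggregate → map pipeline at lengths of a few hundred
to a few thousand residues. These sizes were chosen to exercise every code
path and keep the default test run fast on a laptop.

## Known limitations

Vd/Vp depends on the user's domain boundaries; poorly defined boundaries
can over- or under-state depletion, and short motifs can score high even
when a handful of critical residues inside them are depleted — the 3D view
is the complement for that case. The method does not normalise for codon
mutability or sequence composition, performs no statistical significance
test of depletion, and treats the export's protein consequences as ground
truth (no re-annotation, liftover or transcript selection). Numbering
offsets between UniProt and structure coordinates must be supplied by the
user; nothing is inferred from sequence alignment.
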