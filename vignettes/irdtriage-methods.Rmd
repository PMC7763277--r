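---
title: "Pedigree-aware variant triage for inherited retinal dystrophies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-aware variant triage for inherited retinal dystrophies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irdtriage)
```

# The diagnostic problem

Inherited retinal dystrophies (IRD) are Mendelian photoreceptor
degenerations with extreme locus heterogeneity: more than 250 associated
genes, all inheritance patterns, and frequent compound heterozygosity.
Molecular diagnosis typically escalates through sequencing strategies —
a population-specific gene panel (PS) first, then a clinical exome (CES,
~4,800 disease genes, ~12 Mb) and a whole exome (WES, ~47 Mb) for cases the
panel leaves unsolved. At every stage the analytical core is the same:
given an annotated variant table for a family, a pedigree, and a target
design, rank a handful of plausibly causal genotypes out of thousands of
calls, check that they co-segregate with disease, and decide whether the
family is solved.

`irdtriage` implements that core as composable, tibble-native functions:
the prioritization cascade, coverage-ratio CNV calling, Mendelian
segregation checking (including 47,XXY karyotypes), X-chromosome STR
haplotype linkage, a sequencing-strategy comparator, and seeded simulators
that generate every input with planted ground truth.

# The prioritization cascade

`run_cascade()` runs, for each of four inheritance hypotheses (autosomal
and X-linked, recessive and dominant), the ordered filter sequence:

1. **QC** — keep calls with depth ≥ 20 reads and Phred-scaled strand bias
   FS ≤ 60. Thresholds are removal-strict (`< 20`, `> 60`); boundary values
   are kept.
2. **Population frequency** — effective MAF must be below 0.01 for
   recessive and 0.0001 for dominant hypotheses. The effective MAF is the
   *maximum* over the GnomAD, EVS, 1000GP and CSVS columns; a variant
   absent from all four counts as zero. Taking the maximum is the most
   conservative aggregation for rare-disease filtering; a per-database rule
   would let a variant common in one population survive on the strength of
   its absence elsewhere.
3. **Consequence** — intronic/UTR variants are dropped unless within 10 bp
   of a canonical splice site. Synonymous variants are kept unconditionally
   in known IRD genes, and in other genes only within the first/last two
   exonic bases (potential splicing effect).
4. **Zygosity and pairing** — dominant hypotheses keep index heterozygotes
   and discard homozygotes; AR keeps homozygotes plus heterozygotes with at
   least one surviving partner in the same gene (compound-het
   compatibility); XLR keeps hemizygotes (XY) or alternate homozygotes
   (XX/XXY index). Hemizygous males under a dominant X hypothesis are
   handled by the XLR branch: X handling is per-genotype legality, not a
   fifth mode.
5. **Control genotypes** — recessive: no homozygous or hemizygous carriers
   in GnomAD; dominant: additionally no heterozygous carriers. Variants
   with an existing pathogenic assertion bypass this filter. GnomAD
   genotype counts are used as "control individuals" because that is the
   observable a diagnostic lab actually has.
6. **ACMG class** — evidence codes are combined by `acmg_combine()`
   (the standard ACMG/AMP rule table; contradictory evidence yields VUS)
   and classes 1–2 are discarded. VUS are retained: novel-candidate work
   is impossible otherwise, and every candidate the cascade is expected to
   surface in practice is class 3–5.
7. **Tiering and ranking** — candidates in known IRD genes (a packaged,
   replaceable RetNet-style snapshot) rank before novel-candidate genes;
   within a tier, by ACMG class descending, then effective MAF ascending,
   then position. The ordering is a determinism guarantee, not a clinical
   judgement.
8. **Segregation** — each candidate is checked against every genotyped
   relative (below); non-segregating candidates are removed with an audit
   entry.
9. **Recovery** — only when a hypothesis ends empty-handed: variants
   removed *solely* for low depth, and reported-pathogenic variants removed
   *solely* for exceeding the frequency ceiling, are re-admitted and the
   tail of the cascade re-run. "Solely" is evaluated pointwise: a variant
   that also fails any other filter stays out.

`lax = TRUE` skips steps 5 and 6 — the re-analysis mode used when external
evidence (e.g. a linkage interval) justifies loosening the screen, usually
together with a `design` restricted to that interval.

Every removal carries a machine-readable reason (`mode`, `variant_id`,
`step`, `reason`), so the removed set is exactly reconstructible and
recovery decisions are auditable.

## Cross-strategy comparison

When two affected relatives are sequenced on different designs,
`cross_strategy_compare()` applies an absence argument: a candidate seen in
only one relative, at a position both designs cover, is contradicted by the
other genome — removed when the relatives share the phenotype, but kept and
flagged `modifier_flag` when phenotypes differ, since an unshared variant
is then a candidate second-site modifier rather than noise. Outside the
common regions absence is not evidence and nothing is touched.

# Segregation model

`check_segregation()` assumes complete penetrance and checks every
genotyped non-index relative:

* AR homozygous: affected are `hom_alt`, unaffected are not.
* AR compound het: affected carry both variants *and* are not proven cis;
  an unaffected relative carrying both is a violation only when parental
  genotypes prove the pair in trans. With phase unresolvable, a
  double-carrier unaffected sib is tolerated — flagging it would reject
  true candidates on unknowable phase.
* AD: affected carry the variant; unaffected carry nothing.
* XLR: affected XY are hemizygous; affected XX/XXY are homozygous (both X
  copies); unaffected XY must not be hemizygous; heterozygous females are
  tolerated carriers.

Counts are reported in the `Yes(A/H)` convention — affected/healthy
relatives checked and consistent, index excluded. Carrier females who later
turn out mildly affected (the classic X-linked RPGR situation) are handled
by revising the phenotype and re-checking, not by a penetrance parameter:
a penetrance model would need frequencies this package has no basis to
estimate.

# Coverage-ratio CNV calling

`normalize_ratios()` uses double-median normalization:
ratio~i~ = (s~i~ / median(s)) / (r~i~ / median(r)) for sample and reference
depths. It is parameter-free, scale-invariant in both profiles, and gives
ratio 1 on identical profiles. The upstream protocol this emulates does not
publish its normalization; this one is a documented, replaceable stand-in.
`call_cnvs()` then flags maximal runs of at least `min_consecutive_targets`
(default 2; set 1 to allow single-exon events) consecutive targets with
ratio < 0.6 (deletion) or > 1.40 (duplication), attaching a zygosity hint
for deletions (run mean < 0.25 → homozygous, else heterozygous — the
midpoint between the expected 0 and 0.5).

A numerical caveat worth stating: with 5% multiplicative depth noise, a
heterozygous-deletion target (expected ratio 0.5) sits 4σ from the 0.6
cut-off, but a duplicated target (expected 1.5, noise scaling with the
level) sits only ~1.3σ above 1.40, so individual duplicated targets escape
the threshold with ~9% probability and exact-span duplication calls degrade
as ~0.91^span. Deletion spans are recovered essentially always;
duplication spans are not, and no threshold-on-targets caller can do
better at that noise level. The cut-offs are kept as published.

# STR haplotype linkage on the X chromosome

`assign_haplotypes()` reconstructs which maternal haplotype each child
carries at each of 26 microsatellite markers. XY sons are trivially
maternal; daughters subtract the paternal allele (identifiable from the
father's hemizygous genotype); 47,XXY sons are resolved against both
parents, and when no allele can be paternal the two X copies are both
maternal. The mother's phase is the only free variable; it is chosen by a
two-state dynamic program minimizing the total number of recombinations
implied across all children — the discrete analogue of minimum-recombinant
haplotyping. Markers with Mendelian inconsistencies are flagged and dropped
rather than repaired; markers where the mother is homozygous are
uninformative and transparent (they neither support nor break a segment).

`shared_regions()` scans for maximal marker runs where every affected
carries the same maternal haplotype in a disease-compatible dose
(hemizygous in XY; on both X copies — i.e. homozygous for the haplotype's
allele — in XX/XXY under the gene-dosage hypothesis) and each excluder
lacks it somewhere inside. Region bounds extend outward to the flanking
discordant (recombinant) markers: the *maximum* common region. When
uninformative markers sit between the last shared marker and the flank,
the breakpoint cannot be placed and the boundary is flagged ambiguous —
the widened-interval representation of an undecidable recombination
(e.g. a crossover that may fall on either side of one uninformative
marker).

Marker names follow the standard DXS nomenclature, but the packaged
positions are synthetic stand-ins on a realistic scale (the file is named
accordingly): the haplotype logic depends on marker *order* only, and no
authoritative coordinate list is bundled. The packaged X gene map
(the eight mid-X IRD genes plus CITED1 and RPGR) is synthetic in the same
sense: relative order is preserved, coordinates are round numbers.

# Strategy comparator

`per_sample_output()` is the standard coverage identity
`target_size × coverage / (on_target × (1 − duplicates))`; samples per run
and cost per sample follow by division (`samples_per_run_and_cost()`).
Defaults encode the three compared strategies: a ~0.8 Mb panel at 200×
with 96.6% on-target, a 12 Mb clinical exome and 47 Mb whole exome at
100× with 75.3% and 74% on-target, all at 10% duplicates. The panel
footprint is this package's estimate of a typical custom IRD panel;
run outputs and reagent prices are deliberately configuration inputs
(they are instrument- and contract-specific), and without them the module
reports relative quantities only.

`estimate_first_line_yield()` asks, for each design, what fraction of the
diagnosed cohort it could have diagnosed as the first-line test, counting a
case diagnosable when its causal gene is in the design's gene set. The
packaged panel design is a gene-level reconstruction: the panel-diagnosed
genes plus RPGR, with RPGR excluded from the *covered* gene set because its
repetitive ORF15 mutational hotspot is in the design but not sequenceable
by short-read capture. Yield uses design membership ("included in design"),
which is the question the comparator answers; the covered set drives stage
visibility in `run_family_workflow()`, which is the question escalation
answers — that distinction is exactly why the RPGR family needed the
second-line strategy.

# Synthetic data: what it emulates, and what it does not

`simulate_family()` generates, under a fixed integer seed, a nuclear family
(six members for autosomal scenarios; the five-member two-affected-brothers
structure, one 47,XXY, for the X-linked ones), a background of `n` variants,
and a planted causal genotype in a known IRD gene whose annotations are
drawn from the passing region of every pointwise filter (damaging
consequence, effectively absent from population databases, clean control
counts, ACMG class 4–5, adequate depth). Background annotations follow:

* MAF: point mass at 0 (weight 0.3) + Beta(0.5, 50) tail — most variants
  effectively private, a thin tail into the percent range; each database
  observes the value with probability 0.8 under ±20% jitter.
* Consequences: a categorical mix dominated by missense (0.48) and
  synonymous (0.18), with intronic/UTR mass to exercise the splice-distance
  rule.
* Depth ~ NegBin(mean 150, size 3) and FS ~ Exp(rate 0.15), putting a few
  percent of variants under the QC thresholds.
* GnomAD genotype counts ~ Poisson with intensities proportional to MAF
  (heterozygotes ∝ 2·MAF·N, homozygotes ∝ MAF²·N, N = 50,000), so common
  variants fail the control filter and rare ones do not.
* Genotypes by Mendelian gene-dropping: founder copies carry the allele at
  its own population frequency, one founder copy is then forced to carry it
  (ascertainment — a site absent from the family would not be in the VCF),
  and children inherit by coin flips. A 47,XXY child receives a duplicated
  maternal gamete, so his X genotypes are never heterozygous.
* About 1.5% of background genes are real IRD genes — the exome-wide
  density of retinal-disease genes (~280 of ~20,000) — so tier-1 false
  positives occur at a realistic rate rather than never or constantly.

The generator does *not* emulate linkage disequilibrium, site-frequency
spectra, sequencing reads, annotation errors, or population stratification.
Passing the planted-recovery suites therefore shows the cascade's logic is
correct and its thresholds behave as specified on statistically plausible
inputs; it does not estimate real-data diagnostic yield, which the packaged
study tables address instead.

`simulate_str_and_coverage()` drops maternal STR haplotypes with requested
crossover positions (per-child start haplotype and breakpoints are fully
scriptable; XXY children take two specified maternal copies, so
homozygous-by-descent blocks can be planted), and produces exon-level
coverage profiles with a planted CNV scaling sample depth by 0.5/0/1.5
under 5% multiplicative noise, embedded among enough unaffected filler
targets that the event cannot shift the profile-wide median — as in a real
multi-hundred-target panel.

# Reproducibility and problem sizes

All simulation entry points take a single integer seed and are
deterministic given it; the same seed reproduces byte-identical output
files. The test-suite property checks use 200 seeded families per scenario
for planted-causal recovery, 200 seeded coverage profiles for CNV span
recovery, and 200 random families for the STR brute-force comparison;
`scripts/acceptance.R` re-derives the same rates at 150 families per
scenario. These sizes put Monte-Carlo error on the checked proportions
near or below one percentage point, which is what the asserted bounds
require.

# Known limitations

* Complete penetrance is assumed everywhere; no likelihood or LOD-score
  machinery.
* Compound-het phase without parents is reported as unresolved, never
  guessed.
* The CNV caller is a threshold-on-ratios method; it inherits the
  duplication sensitivity ceiling described above and performs no
  segmentation or GC correction.
* STR marker and X-gene coordinates are synthetic stand-ins; conclusions
  about real coordinates require supplying a real map.
* The strategy comparator models sequencing output and reagent cost only —
  no analyst time, storage, or instrument amortization.
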