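---
title: "Methods: germline variant prioritization for hereditary-cancer panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline variant prioritization for hereditary-cancer panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcscreen)
```

## The problem

Multi-gene panel screens of families at high risk of hereditary breast
cancer produce tens of thousands of germline variant calls per cohort, of
which only a few dozen are plausibly disease-causing. `hcscreen`
implements the prioritization logic such studies apply between the
annotated call table and the final list of deleterious mutations, as a
deterministic, auditable pipeline: every input variant leaves the pipeline
either as a call or with exactly one machine-readable exclusion reason.

The package operates downstream of alignment, variant calling and
annotation. It consumes an annotated table (gene, transcript, cDNA and
protein HGVS, region class, 1000 Genomes minor allele frequency,
categorical SIFT/PolyPhen-2/PhyloP/LRT calls, genotype, and call-level QC
metrics) and never consults a reference genome.

## Consequence classification

`parse_hgvs()` extracts, from the cDNA/protein HGVS pair, the intronic
offset, the indel length, and the protein-level evidence (frameshift tag,
immediate stop, in-frame deletion). `classify_consequence()` then assigns
one class in priority order: splicing, frameshift indel, nonsense,
non-frameshift indel, missense, synonymous, other.

Three conventions matter and are deliberate:

* **Protein evidence outranks cDNA arithmetic.** A deletion spanning a
  splice acceptor but annotated `p.A1823Gfs*9` is a frameshift indel, not a
  splice variant: the annotation records the realized coding effect.
* **Nonsense means stop-gain substitution.** Single-base indels whose
  protein annotation is a bare stop (`c.320dupA` / `p.Y107*`) are
  truncating *indels* and are counted with the frameshift class, as curated
  panel tables count them. "Nonsense" is reserved for substitutions.
* **In-frame status requires a deletion-type protein annotation.** An
  indel is non-frameshift when its protein annotation is an in-frame
  deletion (`p.I397del`, `p.A57_A62del`) and its length is a multiple of
  three; with no protein annotation the length rule alone decides. An
  annotated duplication whose protein effect is an insertion of new
  residues is grouped with the frameshift/disruptive indels. This mirrors
  the counting convention of curated mutation tables in this field, where
  "non-frameshift InDel" is in practice the in-frame *deletion* category;
  it is a reporting convention, not a biological claim about such
  duplications.

The splice window defaults to 2 bases and is applied symmetrically to
donor (`+`) and acceptor (`-`) offsets, covering the canonical GT/AG
dinucleotides.

## The filter cascade

`filter_variants()` evaluates a QC pre-filter and four candidate criteria.
All stages are always evaluated — the retained set is the conjunction, so
it cannot depend on evaluation order — and the reported exclusion reason is
the first failing stage in the fixed order qc, region, class, frequency,
inheritance.

| stage | rule | default |
|---|---|---|
| qc | quality ≥ `qual_min`, neighbor distance ≥ `neighbor_min`, depth ≥ `depth_min` | 20 / 5 / 4 |
| region | exonic, or splice-region within the window | window 2 bp |
| class | frameshift/non-frameshift indel, nonsense, missense, splicing | — |
| frequency | MAF absent **or** ≤ `maf_max` | 0.01 |
| inheritance | see below | — |

Two details:

* **Absent MAF ≠ zero MAF.** A printed `0` means queried and not observed;
  an absent value means never queried. Both pass the frequency criterion,
  but they round-trip differently through the table reader and writer.
* **QC scope.** The QC metrics are produced by the SNV caller, so the
  pre-filter applies to substitutions only by default; `qc_indels = TRUE`
  extends it to indel calls.

The inheritance criterion operationalizes "consistent with the known
pattern of inheritance": any genotype passes in a dominantly acting (or
unknown-mode) gene; in a recessively acting gene a variant passes when
homozygous, when part of a compound heterozygote (≥ 2 class-passing
variants of that gene in one sample), or when it is a single heterozygous
*strong candidate* — a change introducing an immediate stop or a canonical
splice-site variant. The strong-candidate clause models the manual
literature step such studies apply to heterozygous carriers of recessive
genes: the variant is flagged (`recessive_flagged`) and resolves to
`retained` only when a curation entry with database or literature evidence
matches its gene and cDNA change; otherwise it stays
`retained_needs_curation` and is *not* counted as a deleterious call. The
stop-gain form of the clause is judged on the protein annotation (a bare
terminating stop), not on the consequence class, so truncating single-base
indels qualify alongside nonsense substitutions.

## Pathogenicity

`call_pathogenicity()` is class-scoped. The four truncating classes
(frameshift indel, non-frameshift indel, nonsense, splicing) are
deleterious outright; prediction columns on such variants are ignored.
Missense variants are decided by a two-feature rule:

* *prediction* (amino-acid level): SIFT damaging **or** PolyPhen-2
  probably/possibly damaging;
* *conservation* (nucleotide level): PhyloP **or** LRT conserved;

a variant is in-silico damaging only when **both** features flag it, and
deleterious only when, additionally, a curation entry with evidence matches
it. Within a feature an absent tool call contributes "not damaging", but a
missense variant with both tools of a feature absent is an input error:
the rule would otherwise silently decide without evidence. The rule is
monotone: upgrading any single tool call can never turn a damaging verdict
off.

## Pedigrees, eligibility, segregation

Pedigrees use a header-row PED dialect with cancer types, diagnosis ages
and per-variant carrier columns (`M/w` / `w/w` / `0`). Eligibility
implements the three age-tiered family-history rules (≤ 35 with ≥ 1
affected relative; 36–50 with ≥ 2 in the same lineage; > 50 with ≥ 3 in
the same lineage). "Same lineage" is not defined mechanically in clinical
practice; here a relative is paternal or maternal by the parent through
whom they connect to the proband, siblings and descendants belong to both,
and the lineage count is `max(paternal, maternal) + nuclear`. When an
individual carries several diagnosis ages (bilateral disease), the first
is used for age-based rules.

`score_segregation()` reports carriers among tested members as the
familiar `x/y` string (`U/A` when nobody was tested). Completeness is
judged on **affected** tested members only: segregation is complete when
every tested affected member carries the variant. An unaffected tested
non-carrier is the expected outcome, and an unaffected carrier merely
reflects incomplete penetrance; neither should — and neither does — break
completeness.

## MSI and EMAST calling

`classify_msi()` scores two panels from per-marker stability calls: the
five consensus NCI markers, and the NCI panel extended with two further
dinucleotide markers (D18S64, D18S69). Thresholds are parameterized in the
style of the mono/dinucleotide criteria of Haugen and colleagues: zero
unstable markers is MSS; at least one unstable marker with an unstable
fraction below `low_fraction` (default 0.30) is MSI-low; at or above the
fraction is MSI-high. EMAST positivity is instability at ≥ 1 of the seven
tetranucleotide markers. Failed assays are dropped from numerator and
denominator; a panel with no informative markers left is an error, not a
status. With these defaults a sample with 2 of 7 extended-panel markers
unstable (fraction 0.29) is MSI-low, and 3 of 7 (0.43) is MSI-high.
Whether the underlying criterion is best expressed as a count or a
fraction is not recoverable from panel-study reports, which is why the
fraction is exposed as configuration rather than fixed.

IHC staining change (`score_ihc()`) compares 0–3+ scores between normal
and tumor tissue; a drop of ≥ 2 (`loss_delta`, configurable) is a marked
loss, 1 a reduction.

## Cohort summarization

`summarize_cohort()` reports variant, gene and carrier counts, per-category
counts (a carrier contributes to every gene category it belongs to;
multi-gene carriers are counted once in `multi_gene_carriers`), and
labeled fractions. Percentages round **half-up** to one decimal, the
convention of clinical cohort reports (e.g. 18/88 → 20.5), which differs
from R's default round-half-even. The onset-age comparison
(`onset_age_ttest()`) is a classical pooled-variance two-sample t-test by
default — the convention of 2012-era SPSS reporting, where an unqualified
"t-test" means the equal-variance form — with Welch selectable. Onset-age
means are reported from whatever ages are supplied; the package makes no
attempt to reconstruct incompletely recorded relative ages.

## The synthetic-cohort generator

`simulate_cohort()` generates, from a mandatory seed, a cohort with exact
truth labels. Its defaults define the regime the pipeline is tested in:

* **Background polymorphisms** (50 per proband by default): allele
  frequencies follow a two-part mixture with 70% of mass uniform on
  (0.01, 0.5] — so the frequency criterion does visible work — and the
  rest uniform on [0, 0.01]; 15% of variants are synonymous, 15% deep
  intronic, and the remainder are missense with benign prediction
  profiles. Every background variant therefore violates at least one
  criterion or fails the in-silico rule *by construction*, which is what
  makes sensitivity/specificity exactly computable.
* **Spikes**: ten deleterious variants per cohort spanning all five
  retained classes, with grammatically generated HGVS strings (templates
  per class; coordinates arbitrary but internally consistent, since the
  pipeline never consults a reference), damaging profiles and curation
  entries where the class needs them. A heterozygous spike in a recessive
  gene must be a strong candidate, or the configuration is rejected as
  infeasible.
* **Adversarial overlap**: `n_adversarial_missense` background variants
  get damaging profiles *and* curation entries — constructed false
  positives. Specificity then degrades by exactly the constructed count,
  which the tests assert.
* **Pedigrees** satisfy the eligibility rules with a configurable margin
  of additional affected relatives (default 1–3).
* **Marker profiles** draw per-marker instability as independent
  Bernoulli trials: mismatch-repair-deficient samples with elevated
  dinucleotide (0.25) and EMAST (0.50) rates and near-zero mononucleotide
  rates (0.02) — the signature expected of MSH3 loss — and proficient
  samples near-zero everywhere.

Each family consumes its own pseudo-random substream derived from the
seed and family index, so cohorts are reproducible under partial
regeneration. Default sizes (20 families × 50 background variants; the
tests use 5–10 families over 20 seeds) keep the whole suite in tens of
seconds while every rule still fires; the full study scale (99 families,
hundreds of background calls each) is a configuration change, not a code
change.

What the generator does **not** emulate: linkage and haplotype structure,
mutation-rate or penetrance models, sequencing artifacts, or annotation
noise (a spiked variant's HGVS, region label and prediction calls are
always mutually consistent). Passing recovery tests therefore shows the
*logic* is right, not that the pipeline is robust to inconsistent
annotation — real tables violate consistency in ways the simulator does
not model.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive `[start, end]`; the minimal VCF reader
  converts at the boundary (`End = POS + nchar(REF) - 1`).
* A frequency threshold of 0 keeps exactly the variants never observed in
  the frequency resource (MAF absent or 0).
* Identical constant onset-age groups return t = 0, P = 1 rather than the
  0/0 form.
* Empty call sets summarize to all-zero reports; an empty marker panel
  after removing failures is an error.
* Ties in the exclusion reason are broken by the fixed stage order; the
  retained *set* is order-free.

## Limitations

The classifier validates HGVS strings syntactically, not against
transcript sequences; it trusts the annotation. The inheritance criterion
cannot detect phase (a "compound heterozygote" may be in cis). Syndrome
criteria (HBOCS, Li-Fraumeni, Lynch) are consumed as per-family input
flags; the package ships no encoding of the clinical guideline texts.
Marker-panel thresholds are calibrated for the mono/di/tetranucleotide
panel described here and are not a general MSI caller.
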