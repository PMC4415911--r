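# Example data

A worked 99-family hereditary breast-cancer panel screen, shipped as small
plain-text tables so every pipeline stage runs without downloads.

- `hbc99_variants.tsv` — the 42 curated deleterious germline variants of the
  cohort (one row per variant call; columns described in
  `?read_variant_table`). The HGVS strings, coordinates, population allele
  frequencies, in-silico prediction calls, segregation strings, syndrome
  flags and onset ages are curated study values. The call-level QC columns
  (`Qual`, `NeighborDist`, `Depth`) and `Transcript` were not part of the
  curated table; they carry synthetic passing placeholders (99 / 10 / 50, ".").
- `hbc99_panel.tsv` — the gene panel: inheritance mode and gene-category
  assignment for the 21 genes carrying deleterious variants.
- `hbc99_curation.tsv` — curation-evidence lookup (mutation-database and
  literature support) for the missense variants and the heterozygous
  candidates in recessively acting genes.
- `hbc99_syndrome_flags.tsv` — per-family hereditary-cancer-syndrome flags
  (HBOCS / LFS / LS). The 34 carrier families carry their curated flags; the
  65 non-carrier families carry *synthetic* completions chosen
  deterministically so cohort totals are 88 / 11 / 15. Only the totals are
  meaningful for the non-carrier rows.
- `msh3_markers.csv` — per-sample microsatellite marker stability calls
  (+ unstable / - stable) for the 8 tumor-normal pairs from the three MSH3
  mutation families, plus their immunohistochemistry scores.
- `family49_reconstruction.ped`, `family22_reconstruction.ped` — *synthetic
  reconstructions* of two study pedigrees: member structure is invented, but
  the tested/carrier patterns encode the published segregation results
  (family 49 MSH3 5/5 complete; family 22 BRCA1 5/6 complete, MSH3 5/6
  incomplete, MUTYH 1/2). Dialect described in `?read_pedigree`.
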