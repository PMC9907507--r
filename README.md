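# ctdprof

Comparative profiling of the CtBP corepressor's C-terminal domain.

CtBP (C-terminal Binding Protein) is a bilaterian transcriptional
corepressor built from a conserved, NAD(H)-binding dehydrogenase core and
an intrinsically disordered C-terminal domain (CTD) of roughly 90–100
residues. The CTD is where most of the family's evolutionary action is:
conserved sequence blocks separated by P/G/A-rich spacers, long/short
splice isoforms with lineage-specific terminal motifs, vertebrate paralog
families distinguished by characteristic CTD start/end signatures, and
PTM consensus sites. `ctdprof` is for molecular evolution and IDR
researchers who want to run that comparative analysis reproducibly over
their own FASTA files — and to validate every stage against synthetic
families with known ground truth.

## What it computes

* **Domain segmentation** — each protein is split into NTD, core and CTD
  using the `RPLVALL` and `NCVN` anchor motifs (Hamming tolerance 1 by
  default). The core is the window from `RPLVALL` through `NCVN`
  inclusive; the CTD starts immediately after `NCVN`.
* **Percent identity** — end-to-end Needleman–Wunsch alignment
  (+1/−1 match/mismatch, −2 linear gap) with identity over the full
  alignment length, and the anchored-window variant restricted to the
  core used for paralog comparisons.
* **CTD composition panel** — length, P/G/A fraction, hydrophobic
  fraction (M, I, V, L, F, Y, W), charged fractions f⁺ (K, R) and f⁻
  (D, E), FCR = f⁺ + f⁻, NCPR = f⁺ − f⁻ (signed and magnitude), the
  Das–Pappu phase region, and a weak-polyampholyte flag
  (FCR < 0.3 and |NCPR| < 0.25).
* **Alignment-column conservation** — columns classed `conserved`
  (one residue in > 50% of non-gap rows), `chemical` (a pooled chemical
  group in > 50%), with secondary residues in the 25–50% band, and
  conserved-block extraction.
* **Paralog calling** — rule-based CtBP1/CtBP2-family assignment from
  core identity to two references plus CTD motif signatures
  (`KEYL…PADQ` vs `KEFF…LTEQ`), with `unresolved` on conflicting
  evidence and within-species ranking of CtBP1-like vs CtBP1a.
* **PTM scaffolding** — ψKx(D/E) SUMO-consensus scanning and
  reference-site audits (e.g. CtBP1 S422/K428; CtBP2 tetramerization
  residues S128, A129, R190, G216, L221).
* **Synthetic families** — a seeded generator of CtBP-like families
  with conserved blocks, composition-tuned spacers, short isoforms and
  paralog duplications, recording true alignments, boundaries and
  labels.

## Worked example

```r
library(ctdprof)

fam  <- generate_family(family_spec(n_species = 6, seed = 42,
                                    short_isoform_prob = 0.5))
segs <- segment_records(fam$records)
head(segs[, c("id", "core_start", "core_end", "ctd_length")], 4)
#>             id core_start core_end ctd_length
#> 1 sp001_CtBP_L         86      356         95
#> 2 sp002_CtBP_L         86      356         95
#> 3 sp003_CtBP_L         86      356         95
#> 4 sp003_CtBP_S         86      356          5
```

Species `sp003` carries both isoforms: the long form with the full
95-residue CTD and a short form whose open reading frame stops five
residues after the core (here a sampled `SNQEK`-type ending).

```r
long <- segs$ctd_length > 10
prof <- composition_profile(setNames(segs$ctd[long], segs$id[long]))
head(prof[, c("id", "frac_pga", "frac_hydrophobic", "fcr", "ncpr",
              "phase_label")], 3)
#>             id frac_pga frac_hydrophobic   fcr   ncpr phase_label
#> 1 sp001_CtBP_L    0.316            0.189 0.147 0.0211     R1_weak
#> 2 sp002_CtBP_L    0.316            0.179 0.168 0.0000     R1_weak
#> 3 sp003_CtBP_L    0.305            0.200 0.158 0.0105     R1_weak
```

The CTDs look like canonical disordered tails: P/G/A-heavy, hydrophobe-
poor, lightly and symmetrically charged — region R1 of the Das–Pappu
diagram, weak polyampholytes.

```r
window_identity(fam$records[1, ], fam$records[3, ])
#> Global alignment: score 361, identity 90.8% over window columns [86, 356]
```

Core identity between two simulated species is ~91% at the default
substitution rate, the regime typical of within-clade dehydrogenase-core
comparisons.

A full run (segmentation → isoform typing → profiles → endings → SUMO
scan → optional conservation and paralog calls), with a JSON manifest:

```r
run_pipeline(pipeline_config("family.fa", "out/"))
```

or from a shell via the thin wrapper `inst/scripts/ctdprof.R`
(`segment`, `profile`, `identity`, `conserve`, `classify`, `simulate`,
`run` subcommands).

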