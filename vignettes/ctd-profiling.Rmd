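---
title: "Profiling disordered CtBP C-terminal domains: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling disordered CtBP C-terminal domains: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdprof)
```

CtBP corepressors pair a folded, NAD(H)-binding dehydrogenase core with
an intrinsically disordered C-terminal domain (CTD) of about 90–100
residues. Comparative work on this family keeps asking the same small
set of questions — where does the disordered tail start, how alike are
two cores, what is the tail made of, which alignment columns are
conserved, which vertebrate paralog is this — and `ctdprof` packages
those questions as testable operations. This vignette explains the
models behind each operation, the tunable parameters and why their
defaults are what they are, what the synthetic-family generator does and
does not emulate, and the numerical conventions adopted where the
underlying biology does not dictate one.

## Anchor-based segmentation

The dehydrogenase core is operationalized as the window from the
`RPLVALL` motif through the `NCVN` motif, both inclusive. Everything
before the window is the NTD, everything after is the CTD. Two
conventions matter:

* **The `NCVN` motif belongs to the core, and the CTD starts
  immediately after it.** Arthropod CTD alignments are often displayed
  starting at `NCVN(KEY)`, so either convention is defensible; the
  exclusive boundary is the default here because it keeps composition
  statistics on the disordered region only. Callers who want the
  `NCVNKEY`-inclusive view can simply offset the CTD interval by four.
* **Coordinates are 1-based and inclusive**, following the
  IRanges/Biostrings convention that R users of this package will
  already hold in their heads. Intervals tile `[1, L]` with no gaps or
  overlaps, which makes `|NTD| + |core| + |CTD| = L` an invariant the
  test suite checks on every input.

Anchors are located by Hamming distance with a default tolerance of one
mismatch: divergent lineages (nematodes are the usual offenders) vary
individual anchor residues, and a single-substitution budget recovers
those without inviting spurious matches of a 4–7-mer. An exact match is
always preferred, and the leftmost match wins ties. A sequence missing
one anchor degrades gracefully (empty NTD or CTD plus a flag); a
sequence missing both fails loudly, since nothing downstream is
meaningful.

Isoforms are typed by CTD length. Short CtBP forms terminate at most a
few residues past the core while long forms carry the ~90-residue
extension, so the regimes are separated by a wide margin; the default
threshold of 40 residues sits in the middle of that gap. Terminal motifs
(`SNQEK`, `APECARP`, `RLSSRC`, the ancestral `SEVH`/`PEPSEVH`,
paralog-specific `PADQ`/`LTEQ`, …) are matched as sequence suffixes with
a longest-motif-wins tie-break, so `…PEPSEVH` is labelled `PEPSEVH`
rather than `SEVH` when both are in the catalog. NTDs of 300+ residues
are flagged as RIBEYE-like extensions; observed RIBEYE-like NTDs run
550–620 residues, so 300 again separates the regimes with margin.

## Pairwise identity

`global_align()` is a plain end-to-end Needleman–Wunsch with +1/−1
match/mismatch and a −2 linear gap penalty, implemented in C++ with a
fixed traceback preference (diagonal, then gap-in-subject, then
gap-in-query) so results are bit-reproducible. The scheme is
deliberately simple: the quantity of scientific interest is percent
identity — the percentage of completely conserved positions — not an
alignment score, and identity under end-to-end alignment is insensitive
to the details of the scoring matrix in the high-identity regime where
the core comparisons live. Identity uses the full alignment length as
denominator, with gap columns counted as non-identical, which is the
natural reading of "completely conserved". Substitution-matrix scoring
can be emulated through the `match`/`mismatch` arguments but is not the
default. Under other gap/matrix choices, reported identities in the
50–90% band can shift by a few points; comparisons should therefore use
one scheme consistently.

`window_identity()` aligns full sequences and then restricts the
identity computation to the alignment columns spanned by the *first*
sequence's anchored core window. Restricting after a full-length
alignment (rather than aligning excised cores) keeps flanking homology
available to steer the alignment, which matters when one sequence has a
long NTD extension.

## CTD composition and phase classification

The composition panel counts exact fractions: P/G/A
(disorder-promoting; proline has disorder propensity 1.0, alanine 0.45,
glycine 0.43), hydrophobics {M, I, V, L, F, Y, W}, positives {K, R} and
negatives {D, E}. Three conventions:

* **Histidine is uncharged.** The charged sets are K/R and D/E only,
  matching common practice for IDR charge statistics at physiological
  pH.
* **`X` is excluded from numerator and denominator**, so ambiguity
  codes cannot dilute fractions; `length_aa` still counts all residues.
* **NCPR is stored signed and as a magnitude.** The signed value
  distinguishes polyelectrolyte direction; thresholding uses the
  magnitude.

Phase classification reports two things side by side. The full
Das–Pappu regions use the standard boundaries (R1 at FCR < 0.25, the
R2 boundary band to 0.35, R3 strong polyampholytes above it, R4/R5
polyelectrolytes past |NCPR| = 0.35). Independently, a coarser
weak-polyampholyte flag is set for FCR < 0.3 and |NCPR| < 0.25 — a
cutoff pair in common use for CTD-like tails whose FCR boundary (0.3)
deliberately differs from the canonical R1/R2 boundary (0.25). The two
classifications are reported separately rather than reconciled, because
they answer slightly different questions and neither subsumes the
other.

Species-level summaries use one CTD per species — the longest, with
ties broken by smallest record id (and logged) — and group summaries
are unweighted means across species, so a densely sampled genus cannot
dominate a clade average.

## Column conservation

Per alignment column, among non-gap rows: one residue above 50% makes
the column `conserved`; failing that, a chemical group (aliphatic
M/V/I/L, aromatic W/Y/F, acidic D/E, basic K/R, hydroxyl S/T) pooled
above 50% makes it `chemical`; a distinct second residue in the closed
band [25%, 50%] is recorded independently of the primary class. Three
conventions are this package's own, since a display-oriented coloring
scheme does not fully specify an algorithm: denominators exclude gaps;
columns under 50% occupancy are classed `none` (a majority of an
eighth of the rows is not conservation); and the chemical quota reuses
the primary >50% threshold. Conserved blocks are maximal runs of
conserved/chemical columns allowing a bounded number of interrupting
columns (default one), at least five columns long — an
operationalization of the visually identified "central" and "terminal"
blocks.

## Paralog calling

Vertebrate paralog assignment combines two signals: nearest reference
by anchored-window core identity against designated CtBP1 and CtBP2
references, and CTD motif signatures — CtBP1-family CTDs typically
start `KEYL` and end `PADQ`, CtBP2-family `KEFF`…`LTEQ`. Because the
motifs are typical rather than absolute, matching allows Hamming
distance 1 per 4-mer; a family must win the summed start+end distance
strictly, otherwise the motif signal is ambiguous and the call falls
back to identity alone. Concordant signals yield `CtBP1_like` /
`CtBP2_like`; conflicting signals yield `unresolved` with both rule
firings in the evidence trail — the classifier abstains rather than
guesses. Within a species, when several CtBP1-family paralogs co-occur,
the highest-identity one keeps `CtBP1_like` and the rest become
`CtBP1a`; identity ranking is the implementable reading of a
distinction that is otherwise descriptive, and the demotion is recorded
in the evidence.

The SUMO consensus ψKx(D/E) needs a membership for ψ; the package
reuses its hydrophobic set {M, I, V, L, F, Y, W}. Overlapping sites are
all reported. Reference-site audits (CtBP1 S422/K428; CtBP2 S128,
A129, R190, G216, L221, S365, T414, S428) ship as editable tables in
reference numbering; the human reference sequences themselves are
user-supplied.

## The synthetic-family generator

`generate_family()` exists so that every stage of the pipeline can be
exercised, with known truth, without any sequence retrieval. It
emulates the family's architecture, not its phylogenetic detail:

* an ancestor of NTD + core template (326 residues, carrying `RPLVALL`
  and `NCVN` exactly once, ~34% hydrophobic and ~20% P/G/A like a
  folded core) + a 95-residue CTD of four conserved blocks (`KEY`
  prefix, `PELNGAIYRY` central block, `AHSTT`, `PEPSEVH` terminal
  block) separated by three spacers;
* spacers sampled from a weight table tuned to disordered-tail
  composition: expected P/G/A 0.45, charged 0.14, hydrophobic 0.07;
* descent by independent per-site substitution with probability
  `p_sub` (default 0.05) per branch, uniform over the 19 alternative
  residues, damped ×0.1 inside anchors and blocks (`block_protection`);
* optional short isoforms (default probability 0.25 per species),
  truncated after the core with a sampled `SNQEK`/`APECARP` ending;
* optional paralog duplication: each family ancestor receives extra
  divergence (default 0.08 per site) and has its CTD start/end motifs
  overwritten with the family signature; the overwritten motifs are
  then protected, mirroring the observation that paralog-specific
  terminal motifs are essentially invariant within a family;
* optional deletions restricted to spacers, so the true alignment
  remains exactly constructible; insertions are not modelled.

The substitution model was chosen for its closed forms, which the test
suite uses as oracles: under a star tree, two descendants match at an
unprotected site with probability \((1-p)^2 + p^2/19\), and freshly
sampled spacers have expected P/G/A equal to the normalized weight mass
on {P, G, A}. One consequence worth knowing: the ancestral spacers are
drawn once per family, so all species in a family share that single
draw, and composition-recovery checks must replicate over independent
families rather than over species of one family. A second: one branch
of substitution at rate 0.05 pulls realized spacer P/G/A from 0.450 to
about 0.434, a drift the ±0.03 recovery tolerance absorbs.

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: no LG/WAG-style exchangeabilities or
rate heterogeneity beyond block protection, no insertions or repeat
expansions (the polyalanine blocks of drosophilids, the wholesale CTD
replacements of mites and tardigrades), no codon-level structure, no
among-clade composition differences. Tests on synthetic families
validate the machinery — that boundaries, labels, compositions and
conservation classes are recovered when the truth is known — not the
biological conclusions one might draw from any particular real
alignment.

## Numerical conventions and degenerate inputs

* Traceback ties in alignment: diagonal > up > left, fixed.
* Anchor ties: exact before inexact, leftmost among equals.
* Ending labels: longest catalog motif wins.
* CTD-length ties in species selection: smallest record id, logged.
* Secondary-residue ties in a column: higher frequency first, then
  alphabetical.
* Empty sequences, all-`X` sequences, all-gap alignments, species with
  only tailless records, unmapped species in a grouping, and reference
  sites beyond the reference length all fail with named errors rather
  than propagating NaNs; records that fail segmentation travel through
  the pipeline with `ok = FALSE` and the reason attached, so no record
  is silently dropped.
* TSV reports format doubles to four decimals and fix the column
  order, so identical inputs give byte-identical outputs.

## Validation scale

The shipped validation uses problem sizes chosen to make Monte-Carlo
noise negligible relative to the tolerances while keeping a full run
fast: 500 random pairs against an exhaustive alignment oracle, 1,000
random strings against counting and SUMO-scan oracles, 150 independent
single-species families for spacer-composition recovery (±0.03), 25
two-species families (~10,000 unprotected sites) for the per-site
identity closed form, and a 100-species two-paralog family (200
records) for classifier accuracy. `scripts/acceptance.R` recomputes all
of these from a single seed.

## Limitations

Segmentation presumes the anchor architecture; proteins whose cores
have drifted past one mismatch per anchor need custom anchors or
looser tolerance, at increasing risk of spurious matches. Identity
values depend (weakly, at high identity) on the scoring scheme. The
conservation annotator is frequency-based and ignores phylogeny, so a
clade of near-duplicates inflates apparent conservation — subsample or
weight externally if that matters. The paralog rules assume the
two-reference framing; lineage-specific duplications outside the
CtBP1/CtBP2 split (e.g. an independent duplication in jawless fish)
will come back `unresolved` or identity-only, which is the intended
abstention. The pipeline does not build alignments; supply MSAs from
your aligner of choice.
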