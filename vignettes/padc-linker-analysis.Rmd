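---
title: "Linker-length families, registers and networks in PadC photoreceptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linker-length families, registers and networks in PadC photoreceptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biology in one page

Phytochrome-activated diguanylate cyclases (PadCs) couple a red-light
sensing bacteriophytochrome core (NTS–PAS–GAF–PHY) to a GGDEF effector that
condenses two GTP into cyclic-di-GMP; PadC-EALs append an EAL
phosphodiesterase domain that hydrolyses c-di-GMP. The sensor and effector
communicate through a parallel coiled-coil linker. Because a coiled coil is
built from heptad repeats (*a b c d e f g*, hydrophobics at *a* and *d*),
the *length* of this linker constrains its mechanics: families whose
lengths differ by multiples of seven keep the heptad frame intact and can
switch between two overlapping registers (the structural basis of
light-activated upregulation); a deletion of four residues (−4 families) is
compensated by local overwinding of the coil (ten residues spanning three
helical turns); an insertion of two (+2 families) breaks the frame outright
and impairs register stabilisation. `padctools` turns that picture into a
reproducible pipeline: classify, measure the linker, call registers, build
the similarity network, build the jackknife consensus tree.

## The model and its conventions

**Classification.** Family membership is motif-gated: the
chromophore-binding cysteine within an N-terminal window (30 residues by
default; the window is configurable because how far the cysteine can drift
in remote homologs is unknown), then `DIP`, `PR.SF`, `D.LT` and `GG[DE]EF`
in order. Motifs are located by a chained leftmost search — each motif is
the first match downstream of the previous one — which makes the verdict
robust to chance later copies of a short motif. EAL-domain evidence is an
`E[AILV][LF]` match downstream of GGDEF **with at least `min_eal_tail`
(150) residues behind it**. This tail requirement is a deliberate design
choice: the bare tripeptide occurs by chance roughly once per two thousand
residues, so without it a non-trivial fraction of genuine PadCs would be
misclassified as PadC-EALs; an EAL motif without a domain's worth of
sequence behind it is not a phosphodiesterase. PDE competence is withdrawn
when the motif is the degenerate EAF variant or `DDFGTG` is absent, as in
the naturally occurring PDE-dead PadC-EALs.

**Linker length.** The statistic counts residues *strictly between* the
conserved hydrophobic anchor of the terminal PHY helix and the D of the
DXLT motif: `abs = dxlt_idx − anchor_idx − 1`. "Between" is ambiguous about
endpoint inclusivity; the exclusive convention is fixed package-wide and
validated by the 28-residue reference linker. The anchor is located through
the alignment column occupied by a named reference residue (I495-style);
there is deliberately no alignment-free fallback — a query gapped at the
anchor column is reported as `anchor not alignable`, never guessed, so
report denominators stay explicit. Relative lengths are `abs − 28`, binned
with mathematical modulo so that −7 lands in `div7`.

**Registers.** The heptad phase is counted in frame with the DXLT end of
the linker, the structurally conserved wide turn: for 0-based linker index
`i` and length `n`, `j(i) = (i − n) mod 7`, with *a* positions at
`j == phase` and *d* at `j == phase + 3`. For `n` divisible by seven this
coincides with N-terminal counting. The score of a phase is the fraction of
its *a*/*d* slots occupied by stabilisers — hydrophobics plus Asn. Alanine
is included among the hydrophobics by default; that is a judgement call and
the stabiliser set is an argument everywhere. The top-scoring phase is
labelled "inhibiting" and the runner-up "stimulating" purely by the
dark-state naming convention; the labels are not structure predictions.
Ties resolve to the lowest phase index.

**Overwinding.** A −4 linker is modelled as a complete coil that lost one
near-turn, compensated by a single local phase retardation: for breakpoint
`b`, positions N-terminal of `b` are scored as if the four deleted residues
were still present downstream of them (`j` shifted by −4 mod 7). The
breakpoint maximising the combined stabiliser fraction is reported. Note an
intrinsic identifiability limit: breakpoints are only determined up to the
nearest slot-informative residues on either side, so a tie plateau is
common and the smallest-index rule returns its left edge. The tests
therefore pin the breakpoint only on designed linkers whose flanking slots
disambiguate it, and otherwise assert equality with an exhaustive
enumeration oracle.

**Similarity network.** Pairwise scores come from optimal local affine-gap
alignment under BLOSUM62 with gap costs 11/1, converted to bits with the
standard gapped Karlin–Altschul constants (λ = 0.267, K = 0.041). This
reimplements the all-vs-all BLAST step without BLAST's compositional
adjustments, so absolute bitscores can deviate slightly from NCBI's; the
edge threshold (default 380 bits, strict `>`) is an argument for exactly
that reason. One score is computed per unordered pair, which makes the
keep-higher-of-pair rule an idempotent canonicalisation here; it is still
applied (and exposed) for score tables imported from directed scorers.

**Phylogeny.** Distances are Kimura-corrected p-distances
`d = −ln(1 − p − 0.2p²)` with pairwise deletion of gapped columns,
saturating pairs (`p ≥ 0.85`) clamped at `d_max = 5` substitutions/site.
Trees are neighbour-joining (negative NJ branch estimates clamped to zero);
support comes from delete-half jackknife resampling — each replicate keeps
`floor(L/2)` distinct columns in original order, replicate *i* on seed
substream `seed + i` — and an extended-majority consensus: bipartitions in
more than half the replicates are retained, remaining ones added greedily
by frequency when compatible. Supports are raw replicate counts. The
original analysis used PROTDIST's default model and Fitch–Margoliash; the
substitutions were chosen for closed-form transparency and speed, and are
adequate at the clustering level the family claims live at — branch-level
support values on real data carry this caveat.

## The synthetic world

The generator emits what the analysis assumes: multi-domain proteins in the
canonical block order (NTS 30, PAS+GAF 320, PHY 150, linker 28 + rel,
GGDEF 160, and for PadC-EALs a 25-residue EAL-linker plus a 250-residue EAL
domain — block lengths are order-of-magnitude realistic defaults; only the
order is biologically fixed). All essential motifs are planted at fixed
offsets and masked against mutation, the anchor is the last PHY residue,
and DXLT opens the effector block. Linkers are built in frame with the DXLT
end, with hydrophobics (L/I/V/M) on the *a*/*d* slots of phase 0 and Asn on
the slots of phase 2 — the unique second phase for which both planted
registers score exactly 1 while all others stay at or below ½. −4 linkers
are built as in-frame 28-mers with residues 10–13 deleted, so the
overwinding path has a real deletion to compensate; +2 (and other
frame-breaking) linkers insert polar residues into an in-frame core.

Divergence is substitution-only: within a family, each unmasked site
mutates with probability `within_divergence` to a uniformly drawn different
residue; between families, every template is drawn independently, which
guarantees families are far closer within than between — the property the
SSN and tree tests need. There are no indels outside the linker, no
substitution-matrix weighting, and no rate heterogeneity; a green recovery
test therefore establishes correctness of the measurement pipeline, not
robustness to realistic alignment error. Defaults follow the stated world
of the analysis: six families at relative lengths {−7, −4, 0, +2, +7, +14}
(the −7 family a PDE-dead PadC-EAL, echoing its natural counterparts), ten
members each, `within_divergence = 0.15` (a free choice — the source data
carry no quantitative within-family diversity figure — exposed in
`family_spec()`), plus one motif-free random outgroup for rooting.

Two guards keep the planted truth exact. The linker polar alphabet excludes
D (so the anchor–DXLT span can never contain a premature `D.LT`) and N
(reserved for the stimulating register) and A (a stabiliser, which would
blur register scores); and template/mutation draws that would by chance
plant a shadowing motif — a premature `D.LT` before the true DXLT, a
premature `GG[DE]EF`, a premature qualifying EAL — are rejected and redrawn
deterministically from the same seeded stream. Without this, the chance of
at least one shadowed sequence in a 60-member dataset is a few percent,
and 100 % recovery would be unattainable by construction rather than by
implementation error.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally (`anchor_idx`, `dxlt_idx`,
  hit spans); printed reports use 1-based residue numbers.
* Ties: phase ranking and overwind breakpoints resolve to the smallest
  index; SSN components are labelled by their lexicographically smallest
  member.
* `X` is allowed in input sequences; it matches wildcard motif positions
  only, and is scored through the substitution matrix's X column.
* Degenerate inputs fail loudly and locally: empty sequences, missing
  DXLT downstream of the anchor ("effector start not found"), linkers
  shorter than one heptad, alignment pairs with zero comparable columns
  (named in the error), non-monophyletic outgroups. Inside the pipeline
  these become per-sequence status rows so every input appears exactly once
  in the output.
* The jackknife default in the pipeline configuration is 200 replicates — a
  documented scale-down of the original 1000 to keep a desk run in minutes;
  supports are reported as counts of the configured replicate number, and
  `n_replicates = 1000` restores the original setting.

## Known limitations

* Absolute bitscores are not BLAST-bit-exact (no compositional adjustment),
  so the 380-bit cut-off may need adjustment on real data; the threshold
  sweep (`threshold_sweep()`) is the tool for choosing it.
* NJ + Kimura distances replace Fitch–Margoliash + PROTDIST; family-level
  monophyly and high/low support contrasts are expected to be stable under
  this substitution, exact branch support values are not.
* The register caller scores stabiliser occupancy only; it is not a
  free-energy or structure prediction, and the inhibiting/stimulating
  labels are conventions.
* The database search that assembled the natural sequence set (iterative
  PSI-BLAST) and the structure-informed multiple alignment are consumed as
  inputs, not reproduced.
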