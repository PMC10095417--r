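---
title: "Mining and verifying nisin-family lanthipeptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and verifying nisin-family lanthipeptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lanthominer)
library(dplyr)
```

## The problem

Nisin is the best-studied lantibiotic: a class I bacteriocin, ribosomally
synthesized as a precursor with an N-terminal leader peptide and a mature
core of 31–35 residues. During maturation, serines and threonines of the
core are enzymatically dehydrated (Ser → dehydroalanine, Thr →
dehydrobutyrine, each losing one water, 18.011 Da monoisotopic), and a
subset of the dehydrated residues condense onto downstream cysteines to form
five thioether rings — lanthionine (Lan, from Ser) or 3-methyllanthionine
(MeLan, from Thr). The leader is cleaved after a conserved −1 residue
(arginine in most variants, lysine in a minority) to release the active
peptide.

Discovering a new natural variant therefore runs along a characteristic
evidence chain, and `lanthominer` implements that chain as composable,
tested steps:

1. **Mining** — find a precursor ORF in a genome by similarity of some
   window of its protein to known mature cores; split leader and core at the
   matched window.
2. **Intact-mass reconciliation** — the gene predicts an unmodified core
   mass; the spectrometer observes a lighter peptide; the gap, divided by
   the mass of water, counts the dehydrations.
3. **Digest targeting and matching** — an in-silico tryptic digest with
   fixed/variable modifications yields an inclusion list of m/z targets;
   matching them against observed peaks gives fragment-level evidence and
   sequence coverage.
4. **Topology threading** — ring positions are strongly conserved across
   natural nisins, so the candidate core is threaded position-by-position
   onto the nisin A five-ring template and each bridge classified by its
   donor residue.
5. **Variant comparison** — percent identity, substitution lists, residues
   unique to the candidate, p-distances and a neighbor-joining dendrogram
   place the new peptide among the known variants.

## Mass model

All mass arithmetic lives in one place. A peptide's neutral mass is the sum
of its residue masses plus one water, plus any modification deltas:

$$M(p) = \sum_i m_{\mathrm{res}}(p_i) + m_{\mathrm{H_2O}} + \sum_j \delta_j$$

Monoisotopic residue masses are the standard most-abundant-isotope values;
average masses follow the ExPASy reference table; both ship as a plain-text
resource (`inst/extdata/residue_masses.tsv`) so the tables can be diffed
against any other implementation. Two conventions matter and are fixed
deliberately:

* **Average vs monoisotopic.** Intact masses from linear-mode MALDI are
  average-like, so intact reconciliation defaults to average mass; fragment
  work on a high-resolution instrument is monoisotopic. These defaults are
  per-call arguments (`mass_type`), not globals.
* **Protonation.** The neutral mass is canonical; charged species are
  formed only at the inclusion-list stage as
  $m/z = (M + z \cdot 1.007276)/z$ (proton mass, not the hydrogen atom:
  published detected m/z values at two decimals are reproduced by the
  proton convention).

Dehydration counting is a rounding problem:

$$n = \mathrm{round}\!\left(\frac{M_\mathrm{deduced} - M_\mathrm{observed}}{m_{\mathrm{H_2O}}}\right),
\qquad r = (M_\mathrm{deduced} - M_\mathrm{observed}) - n\, m_{\mathrm{H_2O}}$$

with $n$ clipped at zero and the residual $r$ reported, never silently
absorbed. A count is only accepted when it does not exceed the core's
Ser+Thr capacity and $|r|$ is within a configurable bound (default 0.5 Da
for MALDI-grade intact masses).

```{r}
core <- nisin_panel() |> filter(name == "nisin S") |> pull(core)
peptide_mass(core, "avg")
tidy(infer_dehydrations(peptide_mass(core, "avg"), 3347.15, "avg"))
dehydration_capacity(core)
```

## Mining model and its knobs

ORFs are extracted from all six frames: every start codon (ATG/GTG/TTG,
translated as Met, the gene-calling convention) is paired with its nearest
in-frame stop, so nested ORFs sharing a stop are all reported and no ORF
reads through a stop. ORFs lacking an in-frame stop inside the contig are
dropped rather than truncated. Candidate ranking breaks ties toward the
longest ORF of a shared stop, which makes recovery of a planted gene exact
on both strands.

Precursor scoring is deliberately simple: the best *ungapped* equal-length
window identity of any panel core against the ORF protein. Natural nisin
cores are 31–35 residues and near-identical, the published comparisons are
plain percent identities, and an ungapped window cannot hallucinate
alignments on short peptides — so profile models and gapped alignment are
out of scope by design, not omission. The window start marks the
leader/core boundary; the core extends to the ORF's C-terminus because
nisin precursors carry no follower peptide.

Defaults, and why:

| parameter | default | rationale |
|---|---|---|
| `min_identity_pct` | 40 | random 60-mer proteins score ≈ 6 % expected identity against a 34-mer core; 40 % leaves a wide margin (measured false-positive rate ≈ 0 over seeded random genomes) while catching distant family members |
| `min_protein_len` | 30 | nisin precursors are ≈ 57–60 aa; 30 keeps the ORF set small without risking the target |
| `family_threshold_pct` (annotation) | 35 | family identity uses the *longer* sequence as denominator (the shorter is effectively padded with mismatches), so an unmutated fragment 40 % of its reference's length scores 40 % — the threshold must sit below that to flag frameshift remnants as truncated rather than lose them |
| `truncation_ratio` | 0.8 | an assigned ORF shorter than 80 % of its reference is flagged truncated |

Coordinates are 0-based half-open everywhere in memory (unambiguous
arithmetic) and 1-based inclusive in every written artifact (TSV, GFF3,
JSON report).

## Digest and inclusion lists

Trypsin specificity is cleavage after Lys/Arg except before Pro. Fragments
with zero missed cleavages tile the parent exactly — a property the tests
assert — and missed-cleavage variants are generated up to a limit.
Modification forms are enumerated combinatorially (fixed mods on every
eligible residue; all position-wise combinations of at most `max_variable`
variable mods), then positional isomers with the same modification multiset
are collapsed: they are isobaric, an MS1 inclusion list cannot distinguish
them, and published fragment tables print one row per mass. Default charge
states are 2–4, the window a targeted method typically selects precursors
from. Output ordering is by m/z and fully deterministic, so repeated runs
are byte-identical.

```{r}
build_inclusion_list(core) |> filter(charge == 2)
```

## Matching, coverage and tolerances

Each target is assigned its nearest peak; ties between equidistant peaks
break toward the lower value. Defaults: 0.02 Th for m/z matching (a
high-resolution orbitrap-class instrument) and 0.5 Da for intact MALDI
masses. The m/z tolerance is tight enough that a known unexplainable
published low-m/z value does not acquire a spurious match, and loose enough
that peaks jittered at a third of the tolerance match >99 % of the time
(asserted by simulation). Coverage is the union of parent spans of matched
targets — monotone in matches, bounded in [0, 100].

## Topology threading

The nisin A template fixes five bridges (3–7, 8–11, 13–19, 23–26, 25–28)
and the hinge at 20–22. Threading validates that every mapped donor is
Ser/Thr and every acceptor Cys, errors name the violated rings, and bridge
type is a pure function of the donor residue. For cores of different
length, an optional gapless offset (±3, chosen by maximum identity over the
overlap — in practice anchored by the conserved N-terminal ring-A region)
maps template positions onto the variant; the default is strict
equal-length threading because all natural variant comparisons the package
targets are 34-vs-34. Non-ring Ser/Thr are reported as "dehydratable,
unassigned": threading predicts connectivity, not which residues end up as
Dha/Dhb, and the predicted topology is a hypothesis to be confirmed
experimentally, not a measurement.

## Variant comparison

p-distance (fraction of mismatching positions) is used without model
correction: the panel members are near-identical short peptides, multiple
substitutions per site are vanishingly unlikely at these distances, and
percent identity is the currency of the field's own comparisons. Trees are
standard Saitou–Nei neighbor joining (via `ape::nj`); on an exactly
additive input matrix the tree metric is reproduced to numerical precision
(asserted to 1e−9), and negative branch lengths arising from noisy inputs
are clamped to zero on output. Only nisin A, F and S cores are built in;
any further panel members are user-supplied FASTA, because hard-coding
sequences not printed in a verifiable source invites silent error.

## The synthetic-data generator

`make_precursor`, `embed_cluster`, `simulate_peaks` and `mutate_panel`
generate every pipeline input with known ground truth. They emulate the
study conditions the package targets: a 25-residue leader ending in Lys, a
34-residue core with eight dehydrations, genomes of a few kilobases with
the gene on either strand, fragment m/z observed at charges 2–4 with
carbamidomethylated cysteines and up to two methionine oxidations.

What they deliberately do **not** model: GC skew or codon bias (mining is
similarity-based and composition-insensitive), isotope envelopes,
intensity structure, retention time, assembly artifacts. Passing the
planted-truth tests therefore demonstrates the *logic* of the chain —
coordinate arithmetic, mass bookkeeping, matching, threading — not
robustness to instrument idiosyncrasies; real peak lists should be
pre-processed (deisotoped, decharged) upstream.

Every generator is a pure function of (parameters, seed) and restores the
caller's RNG state. Decoy peaks are uniform over the fragment m/z range
widened by 50 Th. The simulated peak table carries a per-row `value_kind`
(`neutral_mass` for the intact species, `mz` for fragments and decoys) so
each verification stage selects its own value space.

## Numerical and degenerate-input choices

* Ties in candidate ranking: identity desc, contig asc, start asc, end desc
  (the last term prefers the maximal ORF of a shared stop).
* Negative deduced−observed differences yield $n = 0$ with the residual
  reported, never a negative count.
* Empty peak lists are legal everywhere and produce "no result" values
  (`NULL` reconciliation, 0 % coverage, all-unmatched targets) rather than
  errors; empty *inputs* that indicate malformed files (empty FASTA,
  non-numeric peak values) are classed errors.
* Equal-length checks are strict; unequal-length comparisons must go
  through the explicit offset-threading path.
* All text output is UTF-8, decimal-point only, and row-order
  deterministic, so byte-level diffs are meaningful.

## Problem sizes in the test suite

The property-style tests run at sizes chosen to exercise every code path
while keeping the default suite fast: 20 wrapped FASTA files against an
independent parser; 100 random concatenation pairs and 200 seeded
infer-recover cases for the mass identities; digest brute-force equivalence
on 20 random 60-mers at 0–2 missed cleavages; ORF brute-force equivalence
on 12 random 1.5-kb sequences plus strand-symmetry checks; 60 seeded 10-kb
precursor-free genomes for the false-positive calibration; 500 jitter
trials for the match-rate floor and 200 seeded decoy simulations for the
precision floor (≥ 0.95).

## Limitations

* Mining is similarity-based; it will not find lanthipeptides unrelated to
  the supplied panel, and it does not model biosynthetic-gene-cluster
  context beyond family labeling of flanking ORFs.
* The intact-mass model accounts for dehydrations only; other maturation
  chemistry (e.g. C-terminal decarboxylation in some lantibiotics) would
  surface as a persistent residual.
* Threading assumes conserved ring positions; a genuinely rearranged
  topology would be rejected as a threading error, which is the honest
  failure mode but not a prediction.
* MS2-level identification (fragment-ion ladders, spectral scoring, FDR)
  is out of scope; the package stops at MS1 evidence and coverage.
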