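---
title: "gapstitch: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gapstitch: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapstitch)
```

## The method

gapstitch predicts multimeric protein assemblies with a monomer-trained
structure-prediction network by reformulating the multimer as a single
chain. Three ideas carry the method:

1. **Gap-spaced merging.** All target chains are concatenated into one
   pseudo-chain. No physical residues are inserted at the boundaries;
   instead the per-position *residue index* jumps by `gap_size + 1`
   (default gap 200) at each boundary. Relative-position encodings in the
   network saturate far below 200, so the chains are effectively
   independent polymers that may still pack against each other in 3D.
2. **Template unmasking.** A user-supplied multimeric template (PDB or
   mmCIF) is mapped — chain by chain, through a target/template sequence
   alignment — onto the merged positions *without* discarding inter-chain
   geometry. Because the merged target is a single chain, what the
   standard pipeline would treat as forbidden inter-chain information is
   now ordinary intra-chain template signal. This is the entire trick.
3. **Distogram contact read-out.** The network's distogram (a per-pair
   probability distribution over binned Cβ–Cβ distances) is integrated
   below a distance cutoff; inter-chain pairs whose integrated mass
   exceeds a probability threshold are reported as predicted contacts.

The pipeline runs: per-chain MSA acquisition → greedy template chain
assignment → merging → block-diagonal MSA merging → backend prediction →
splitting/renumbering/pTM ranking → contact analysis. Only network models
1 and 3 are requested (the two that accept templates), so a run produces
two models rather than the twenty-five of multimer pipelines.

## Parameters that matter

| parameter | default | units | why this value |
|---|---|---|---|
| `gap_size` | 200 | residue indices | large enough to exceed the network's relative-position horizon; the merged index of chain *k*'s first residue is `sum(L_j, j<k) + (k-1)*gap_size + 1` |
| `contact_cutoff` | 8 | Å (Cβ, Cα for Gly) | the conventional residue-contact radius; deliberately a proximity criterion, **not** a physical-bond claim |
| `contact_threshold` | 0.8 | probability | a conservative operating point on the distogram mass; predictions above it are empirically far more precise than coordinates |
| `min_contacts` | 3 | contacts | plausibility classifier operating point: complexes with ≥ 3 predicted interface contacts are overwhelmingly genuine in large benchmarks |
| `model_ids` | 1, 3 | — | the only network models that accept input templates |
| `rotrans` | off; `c(30, 5)` for benchmarks | degrees, Å | emulates rigid-body-fitted chains in a ~4–10 Å map: each chain independently rotated ≤ 30° about its centre and shifted ≤ 5 Å |

## Chain assignment and sequence identity

Targets are assigned to template chains greedily by pairwise sequence
identity: all pairs are scored, then accepted in descending identity,
skipping used rows/columns. The identity metric (the literature leaves it
open) is: global alignment, match 1, mismatch 0, affine gaps costing
`0.5 + 0.1·L` per run of length `L`, identity = identical aligned
positions / shorter length. Two determinism choices are ours:

* **Ties** break by lower target index, then lexicographic chain ID, so
  homomers always assign the same way.
* Among co-optimal alignments the one **maximising the match count** is
  taken (the dynamic program optimises the pair (score, matches)
  lexicographically). Off-the-shelf aligners leave this tie-break
  unspecified, which is why the aligner is implemented in-package: the
  test suite compares it against an exhaustive enumeration oracle, and
  that comparison must be exact to be meaningful.

Greedy is not optimal assignment; on random tie-rich matrices it agrees
with the Hungarian optimum in roughly three quarters of cases (the suite
records, but does not assert, this rate). Greedy is kept because it is
the field's convention for this step and is deterministic under the tie
rules above.

## The mock backend and what a green test establishes

The network is a pluggable backend. The bundled mock is built from a
ground-truth complex: its coordinates are the truth mapped through the
merge layout plus Gaussian noise of scale σ (`noise_scale`), and its
distogram is, per pair, a Gaussian centred on the *noisy* anchor distance
with s.d. σ, discretised over explicit bins (a point mass in the
containing bin at σ = 0). pTM is a constant supplied by the caller.

Two deliberate fixture choices:

* The mock's bins are quarter-Å wide from 2 to 22 Å, so **8 Å is a bin
  edge**. At σ = 0 every true contact then integrates to exactly 1 and
  every non-contact to exactly 0, making "predicted = reference, exactly"
  a meaningful oracle. The integrator itself never assumes this grid —
  bin edges travel inside every distogram and random-grid tests cover the
  straddling-bin path.
* Contacts at exactly 8.000 Å are excluded (the rule is strict `< 8`),
  and the mock's right-open bins agree with that convention.

The synthetic complexes are ideal α-helices (2.3 Å radius, 1.5 Å rise,
100°/residue, Cβ 1.53 Å radially outward, ~8% glycine) on parallel axes
9.5 Å apart, giving tens of interface contacts per adjacent chain pair —
the magnitude of a real dimer interface. What this world does **not**
emulate: real side-chain packing, non-helical folds, conformational
change on binding, MSA depth effects, or any actual network behaviour. A
green suite therefore establishes that the *bespoke computations* —
merging arithmetic, template projection, MSA layout, distogram
integration, scoring, perturbation — are correct, not that predictions of
real complexes are accurate.

Increasing σ degrades the mock smoothly: the acceptance suite checks that
mean contact recall over 60 seeds is non-increasing across
σ ∈ {0, 0.5, 1, 2, 4} Å, mirroring the qualitative template-quality
dependence of the real method without asserting its benchmark numbers.

## Numerical and degenerate-input conventions

* **Straddling bin**: the bin containing the cutoff contributes the
  linear fraction of its width below the cutoff (continuous in the
  cutoff); a `"floor"` mode counts whole bins only. The open lower bin
  always counts fully; a cutoff below the first edge warns and uses that
  bin alone.
* **Perturbation sampling** ("uniform up to 30° and 5 Å" leaves the
  measure open): rotation axis uniform on the sphere, angle ~ U(0, max),
  translation direction uniform on the sphere, magnitude ~ U(0, max).
  Both choices are recorded in the perturbed object's metadata and in run
  manifests. Rotation is about the chain's anchor-atom centroid (only Cα
  and Cβ are retained per residue, so this stands in for the centre of
  mass; rigidity and the sampled bounds are unaffected by the choice of
  fixed point).
* **Missing atoms**: Cβ falls back to Cα for glycine (by definition) and,
  with a warning, for any residue lacking a Cβ; residues missing both
  anchors are dropped with a warning. Modified residues (MSE, SEP, …) map
  to parent one-letter codes; unknown polymer residues become X. Only the
  first model and first altloc of a structure file are read; residues
  with insertion codes are skipped.
* **Empty denominators** score as NA with an explicit `defined` flag —
  except recall of an empty prediction against a non-empty reference,
  which is 0.
* **Ranking ties** (equal pTM) break toward the lower model ID.
* **Splitting** uses the stored chain-of-position map, never coordinate
  or index heuristics, so it inverts merging for any `gap_size ≥ 1`.
* Chains are renumbered 1..L on output (original author numbering is a
  template-side concept; the assignment report preserves the mapping).
* All randomness flows through explicit integer seeds; identical
  config + seed gives byte-identical manifests, models and contact
  tables.

## Open design points we resolved

* Target/template alignments are always recomputed internally; user
  override of the alignment (as opposed to the MSA) is not supported.
* Per-chain MSAs are not deduplicated before merging; duplicate target
  sequences (homomers) share one parsed MSA replicated per block, with
  zero deletion counts in padded columns.
* Unmatched template chains are dropped with a warning; unmatched targets
  proceed template-free — permissive automation over hard failure.
* Remote MSA generation sits behind the same per-chain MSA contract as
  user a3m files and is not part of the test surface (no network in
  tests); the a3m path is the tested path.
* The plausibility classifier's error rates (the ≥ 3-contact operating
  point) are properties of an external GPU-scale benchmark, quoted as a
  default only — the tests assert the classifier's arithmetic, not those
  rates.

## Known limitations

* No nucleic acids, ligands, or altloc handling beyond the first
  conformer; no relaxation (the mock emits unrelaxed coordinates and a
  flag; a real backend may relax its top model).
* The PDB/mmCIF writer emits anchor atoms only (CA/CB) — sufficient for
  contact analysis and round-tripping, not a full-backbone model file.
* Sequence identity is the only assignment signal (no structural
  superposition), mirroring the published procedure; pathological
  templates with many near-identical chains rely entirely on the
  deterministic tie rules.
* The mock backend's pTM is a constant, so pTM-ranking is exercised by
  contract tests rather than by the mock varying it meaningfully.
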