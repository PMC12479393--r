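# gapstitch

Multimeric protein-complex prediction with monomer-trained structure
networks, via gap-spaced single-chain merging and **unmasked** multimeric
templates.

## The problem

Complex-prediction networks routinely fail on weakly bound assemblies —
the very complexes where an experimentalist often *has* an approximate
multimeric model (a crystal form, chains rigid-body fitted into a
medium-resolution cryo-EM map) and wants residue-level detail of the
interface. Standard template featurization masks all inter-chain
information from such templates, throwing away exactly the evidence that
matters.

gapstitch implements the alternative: all target chains are concatenated
into a **single pseudo-chain** whose per-position residue index jumps by a
large gap (200 by default) at every chain boundary, so a monomer-trained
network treats the assembly as one protein with chain breaks — and the
multimeric template is passed through with its inter-chain geometry
**retained**. Concretely, for chains of lengths `L1, L2, …` the merged
residue index of chain *k*'s first residue is

```
idx_k = sum(L_j, j < k) + (k - 1) * G + 1,        G = 200
```

Per-chain MSAs are merged block-diagonally with **no pairing**: a row from
chain *k*'s alignment covers only chain *k*'s columns and is gap-padded
elsewhere. Only the two network models that accept templates (1 and 3)
are used, ranked by pTM (monomeric models emit no ipTM).

Predicted **inter-chain contacts** are read from the network distogram:
residue pair (i, j) is called a contact when its integrated distogram mass
below 8 Å (Cβ anchors; Cα for glycine) exceeds 0.8. Contacts are scored as

```
precision = |P ∩ R| / |P|     recall = |P ∩ R| / |R|
template_satisfaction = |P ∩ T| / |P|
```

against a reference contact set *R* and the template's own contact set
*T*, and a prediction with ≥ 3 predicted inter-chain contacts is
classified plausible. For benchmarking against degraded templates, each
template chain can be rigid-body perturbed about its centre (rotation up
to 30°, translation up to 5 Å — the `rotrans = c(30, 5)` protocol).

The network inference step itself is a **pluggable backend**: the bundled
deterministic mock backend fabricates coordinates and distograms from a
known ground-truth structure (with tunable Gaussian degradation), so the
entire pipeline — merging, template featurization, MSA merging, contact
extraction, scoring, classification — is testable on a laptop. An adapter
to a real AlphaFold2 installation satisfies the same contract but is not
bundled.

## Worked example

```r
library(gapstitch)

# a synthetic two-chain complex (60 + 55 aa) with a known interface,
# a perturbed template (rotrans 30,5), and fabricated per-chain a3m MSAs
fx <- write_fixture_set("demo_fx", lengths = c(60L, 55L), seed = 42,
                        rotrans = c(30, 5))

res <- run_pipeline(run_config(
  fasta_path = fx$fasta, template_path = fx$template,
  output_dir = "demo_run", msa_dir = "demo_fx/msas",
  mock_truth_path = fx$truth,   # the mock backend's ground truth
  mock_noise = 0.5,             # degrade the "network" by 0.5 Angstrom
  seed = 42))

nrow(res$contacts)                     # 81
res$plausible                          # TRUE  (81 >= 3 contacts)
res$metrics$template_satisfaction      # 0.58  (vs the perturbed template)

ref <- reference_contacts(read_structure(fx$truth))
m <- score_contacts(res$contacts, ref)
c(m$precision, m$recall)               # 0.938 0.752

head(as.data.frame(res$contacts), 4)
#   chain_a res_a aa_a chain_b res_b aa_b      prob
# 1       A     1    Y       B     1    A 0.9797206
# 2       A     1    Y       B     2    T 1.0000000
# 3       A     1    Y       B     5    F 0.9183086
# 4       A     2    Y       B     5    F 0.9999977
```

Reading: with a rigid-body-perturbed template and a mildly degraded mock
backend, 81 inter-chain contacts clear the 0.8 probability threshold;
93.8% of them are real (precision) and they cover 75.2% of the true
interface (recall), while 58% are already present in the (perturbed)
template. With `mock_noise = 0` the predicted set equals the reference
set exactly — the pipeline's end-to-end correctness oracle.

`demo_run/` contains the ranked models (`models/ranked_*.pdb|.cif`),
`contacts.tsv`, `contacts.json` (per-interface counts + classifier
verdict), `assignment.json`, `merged_msa.a3m`, and a `manifest.json` that
fully records the run configuration and seeds.

## Command line

```sh
inst/scripts/gapstitch fixtures --out-dir fx --lengths 60,55 --seed 1
inst/scripts/gapstitch predict  --fasta fx/target.fasta \
    --template fx/template.pdb --output run --msa-dir fx/msas --seed 1
inst/scripts/gapstitch contacts --run-dir run --threshold 0.9
inst/scripts/gapstitch perturb  --template fx/template.pdb \
    --out shaken.pdb --rotrans 30,5 --seed 1
```

## Documentation

The methods vignette (`vignettes/gapstitch-methods.Rmd`) describes the
model, its assumptions, every tunable parameter, what the synthetic world
does and does not emulate, and the package's numerical conventions.
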