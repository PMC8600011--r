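---
title: "Predicting protein–nucleic acid binding affinity changes upon mutation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein–nucleic acid binding affinity changes upon mutation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nabind)
```

## The problem

Missense mutations in nucleic-acid-binding proteins can strengthen or
weaken binding to their DNA or RNA partners, with consequences ranging from
transcriptional misregulation to disease. `nabind` predicts the change in
the Gibbs free energy of binding,

$$\Delta\Delta G \;=\; \Delta G_{\mathrm{wt}} - \Delta G_{\mathrm{mut}}
\quad [\mathrm{kcal/mol}],$$

for single- and multiple-point mutations in a protein–nucleic acid (NA)
complex of known structure. Under this sign convention a *negative* value
is destabilizing (reduced affinity), a *positive* one stabilizing.
Everything is computed from the wild-type structure, a cheaply modelled
mutant, and a supervised regression model.

## Feature model

Five classes of structural and sequence features describe one point
mutation:

1. **Graph-based signatures** (cutoff scanning matrix). Heavy atoms are
   nodes labelled with pharmacophore classes — seven for protein atoms
   (aromatic, hydrophobic, negative, positive, H-bond donor, H-bond
   acceptor, neutral) and four for NA atoms (phosphate, sugar, purine base,
   pyrimidine base). For the environment of the mutated residue (every
   heavy atom within 10 Å of the site, site atoms included) we count, for
   each unordered class pair and each cumulative distance cutoff, the
   number of atom pairs within that distance. Defaults: cutoffs 2, 4, 6, 8,
   10 Å in 2 Å steps, giving 66 class pairs × 5 bins = 330 counts. Both the
   wild-type vector (`sig:*`) and the mutant-minus-wild difference
   (`dsig:*`) are exported; the grid and radius are configurable because
   the published grids of this model family are not disclosed.
2. **Substitution scores** (`sub:*`): BLOSUM62 plus two property-difference
   matrices built from the Kyte–Doolittle hydropathy scale and Zamyatnin
   residue volumes (score = property(mutant) − property(wild-type)). All
   three are swappable 20×20 tables; the two property matrices ship as
   plain-text package resources.
3. **Vibrational entropy change** (`nma:delta_s_vib`). An anisotropic
   elastic-network model with uniform springs (cutoff 10 Å) is built for
   the wild-type and mutant complexes; with eigenvalues
   $\lambda_i$ of the mass-free Hessian, $S_{vib} = -\tfrac12 \sum_i \ln
   \lambda_i$ over the nonzero modes, and the feature is
   $S_{vib}^{mut} - S_{vib}^{wt}$. Units are model-relative: only the
   difference enters the feature vector. The default node set is *all heavy
   atoms*, because Cα/P coarse-graining is blind to a side-chain
   replacement (the network is then identical and the delta identically
   zero); a `calpha` mode exists for coarse analyses.
4. **Interaction network** (`int:<type>:wt`, `int:<type>:delta`). A
   geometric classifier assigns each close heavy-atom pair all matching
   types among 13: clash, covalent, van der Waals, vdW clash, hydrogen
   bond, weak hydrogen bond, proximal, halogen bond, aromatic, ionic,
   carbonyl, hydrophobic and metal. All thresholds sit in one
   configuration block (`interaction_config()`); hydrogen-free criteria
   are distance-based with a ≥ 90° donor-antecedent angle applied where an
   antecedent heavy atom exists. By default counts are taken over the
   contacts of the mutated residue (inter- and intra-molecular): whole-
   interface counts are constant across sites of a complex, whereas the
   effect of a point mutation concentrates at its site. Positive side
   chains within 4 Å of phosphate oxygens count as ionic — the dominant
   salt bridge at protein–NA interfaces — since NA atoms carry no
   `negative` pharmacophore label.
5. **Nucleic-acid type and geometry**: binaries `na:is_rna`,
   `na:is_double`, plus the minimum heavy-atom distance of the site to the
   NA (`geo:min_dist_na`). RNA is detected by O2′ atoms; a complex is
   double-stranded when at least three purine-N1/pyrimidine-N3 contacts
   within 3.5 Å exist (so paired single strands type as double-stranded);
   a user override is available. Residues within 8 Å of the NA (inclusive)
   are "proximal"/interface residues.

An optional user-supplied protein-stability change occupies
`opt:stability_ddg` (imputed as 0 when absent). Multiple-point constructs
aggregate their single-point vectors: counts and deltas are summed, scores,
distances and binaries averaged (per-feature map; global `mean`/`sum`
modes also exist).

### Mutant structures

Mutants are built by `naive_mutant()`: the side chain is replaced with an
idealized template rotamer (standard bond lengths/angles, extended χ
angles) anchored on the wild-type N/CA/C, keeping the wild-type CB when
both residues have one; the backbone is untouched and mutation to glycine
simply removes the side chain. There is no energetic refinement — this is
a deliberate fidelity gap relative to pipelines that relax mutants with
molecular mechanics, and any externally refined mutant PDB can be supplied
in its place.

## Dataset protocol

* **Mutation strings**: `CHAIN WTnumMUT`, multiple sites joined by `;`
  (`"A R45G;A K50A"`).
* **Kd conversion**: $\Delta\Delta G = RT \ln (K_D^{wt}/K_D^{mut})$,
  R = 1.98720425×10⁻³ kcal/(mol·K), default T = 298.15 K.
* **Reverse augmentation**: ΔΔG is a state function, so the reverse
  mutation has exactly the negated value. Reverse records are added only
  for forward ΔΔG ≥ −2 kcal/mol (inclusive): strongly destabilizing
  mutations imply structural rearrangements a template mutant cannot
  capture. Reverse records share their forward partner's group.
* **Direction labels**: neutral iff −0.5 ≤ ΔΔG ≤ 0.5 (both boundaries
  neutral), else increasing/decreasing.
* **Hot-spots**: defined on single mutations to alanine; hot-spot iff
  ΔΔG ≤ cutoff (−2 or −1 kcal/mol in common benchmarks; inclusive).
* **Additivity**: a multi-point construct with component singles summing
  to $S$ is additive when $|\Delta\Delta G_{multi} - S| < 0.2$ kcal/mol or
  $< 0.1\,|S|$ (the relative criterion's denominator is the summed single
  effects — the natural reading of a percentage criterion), otherwise
  synergistic.

Boundary conventions (all inclusive) are explicit package decisions where
only inequality directions are conventionally quoted.

## Regression model and evaluation

The default regressor is extremely randomized trees (300 trees, all
features per split candidate, one random cut per feature, no bootstrap),
seeded for determinism; random-forest and SVR alternates exist. Feature
selection follows a bottom-up greedy procedure: starting empty, each round
adds the feature maximizing group-cross-validated Pearson correlation,
stopping below a 10⁻³ gain or at 13 features (the cap mirrors the compact
final models typical of this family; the stop rule is ours).

Validation is always group-aware: all records of a complex — and every
forward/reverse pair — stay in one fold, under group k-fold (k ∈ {5, 10,
20}) or leave-one-complex-out. Reported metrics: Pearson/Spearman/Kendall
(τ-b) and RMSE; direction classification derived from the regressor after
removing true-neutral records (accuracy, F1 and MCC, AUC with the raw
prediction scoring the "increasing" class); hot-spot confusion metrics
(SEN/SPE/PRE/ACC/F1/MCC); and 10 %-trimmed variants that drop the
⌈0.1 n⌉ worst-predicted records (ties broken by record order).

## Synthetic fixtures and what they do (not) show

`generate_toy_complex()` builds deterministic fixtures: an ideal α-helical
peptide (φ = −57°, ψ = −47°, template side chains, seed-determined
sequence) docked at a configurable gap (default 4 Å) against an idealized
NA strand or duplex. The duplex is a geometric ladder — planar idealized
bases with Watson–Crick N1–N3 contacts at 2.9 Å, 4.0 Å rise, 36°
(DNA) or 32.7° (RNA) twist — chosen so strandedness detection is
unambiguous rather than to reproduce fibre-diffraction geometry. RNA
templates carry O2′.

`generate_synthetic_dataset()` samples mutation constructs on interface
residues and draws $\Delta\Delta G = \sum_k \beta_k f_k +
\mathcal N(0, \sigma)$ over *computed* features. The recovery experiment
used by the test-suite and the acceptance script uses five complexes
(2 dsDNA, ssDNA, dsRNA, ssRNA — echoing the type mix of curated affinity
sets), 500 records, σ = 0.2 kcal/mol and coefficients
(`sub:hydropathy` 0.25, `geo:min_dist_na` 0.3, `int:hbond:wt` −0.8); the
negative hydrogen-bond coefficient makes contact-rich sites destabilizing
on average, which mirrors real alanine-scanning data. These sizes keep the
whole experiment to a few minutes on one core.

Passing these experiments demonstrates that the pipeline is internally
consistent (features deterministic, CV leak-free, a known signal in its
own features is recoverable near the noise floor). It does **not**
demonstrate accuracy on real complexes: toy geometry lacks solvation,
packing heterogeneity, crystallographic noise and refined mutants, and the
linear generative model is far simpler than real energetics. Training on
the published curated tables (with real PDB structures) uses exactly the
same code path via `read_affinity_csv()`.

## Numerical choices

* Altloc resolution keeps the highest-occupancy conformer (ties →
  alphabetically first); first model only; hydrogens and waters dropped —
  every geometric criterion is defined on heavy atoms.
* Eigenvalues below 10⁻⁸ × the largest are treated as rigid-body modes;
  entropy uses nonzero modes only, so disconnected networks degrade
  gracefully with a warning.
* Residue identity is (chain, author number, insertion code).
* Greedy selection and outlier trimming break ties by schema/record order,
  making every reported number reproducible bit-for-bit under a fixed
  seed.
* The schema fingerprint stored in model bundles is an FNV-1a hash of the
  ordered feature names; prediction refuses mismatched schemas.

## Known limitations

* Naive template mutants: no rotamer search, no relaxation; side-chain
  clashes in tight pockets are represented as `clash`/`vdw_clash` counts
  rather than resolved.
* The interaction classifier is a re-specified geometric approximation of
  atom-typed contact tools; thresholds are documented defaults, not fitted
  constants, and an adapter can ingest external contact lists instead.
* The elastic-network entropy is harmonic and spring-uniform; absolute
  values are meaningless, only differences are used.
* Pharmacophore typing is table-driven and pH-independent (His counted
  positive; no pKa model).
* Complexes mixing DNA and RNA chains are typed by majority chain with a
  warning; the binary NA-type features cannot represent hybrids.
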