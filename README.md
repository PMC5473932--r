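# mdrin — dynamic residue interaction networks from MD ensembles

`mdrin` analyzes two labeled conformational ensembles of a multi-domain
protein — typically oxidized ("ox") versus reduced ("red") molecular-dynamics
trajectories of a four-domain a–b–b′–a′ redox chaperone such as protein
disulfide isomerase — and asks two questions: *which collective motions and
geometric features distinguish the two states*, and *which residue–residue
interactions persist in one state but not the other*.

## The method

For every frame *t* a typed **residue interaction network** (RIN) is built
from documented geometric criteria for five non-covalent interaction types
(hydrogen bond, van der Waals, salt bridge, π-π, cation-π), giving a binary
adjacency series A<sub>ij</sub>(t) per residue pair and type. Each series is
reduced to its **maximum interaction lifetime**

&nbsp;&nbsp;&nbsp;&nbsp;Γ<sub>ij</sub> = max { τ : ∃ τ₀ with A<sub>ij</sub>(t) = 1 for all t ∈ [τ₀, τ₀+τ−1] },

the length of the longest unbroken run of frames in which the interaction is
present. One weighted residue graph per state — the **dynamic residue
interaction network** (DRIN) — collects these lifetimes. The two states are
contrasted through the differential network

&nbsp;&nbsp;&nbsp;&nbsp;Δ<sub>ij</sub> = log₂ ( (Γ<sub>ij</sub><sup>ox</sup> + ε) / (Γ<sub>ij</sub><sup>red</sup> + ε) ),

with pseudocount ε > 0; thresholding |Δ| and merging the five type channels
yields a single graph of state-dominated interactions, exportable to GraphML
or SIF for network viewers.

Around this core the package provides the standard ensemble-comparison
stack: domain-center geometry (six inter-domain distances R<sub>ij</sub>,
two hinge angles Θ, one torsion Φ), Kabsch superposition and RMSD,
displacement cross-correlation (DCCM), principal component analysis of Cα
coordinates with eigenvector-overlap convergence checks, free-energy
landscapes F = −ln(p/p<sub>max</sub>) on principal-component planes, optimal
single-threshold (V<sub>sep</sub>) and radial-basis SVM classification of
the states from single features, and the residue-pair
discrimination-accuracy matrix. A synthetic-trajectory generator with exact
ground truth (rigid hinge motions, scripted interaction schedules, mixture
features) makes every stage testable without any external data.

## Worked example

Two synthetic 400-frame ensembles share the same fold; the "ox" state keeps
a salt bridge between residues 10 and 80 for a 300-frame stretch while the
"red" state holds it for at most 12 consecutive frames and swings its
terminal domain through a wider hinge:

```r
library(mdrin)

ox_spec <- synthetic_spec(n_frames = 400, hinge_amplitude = 10, seed = 42,
  interaction_schedule = list(schedule_entry(10, 80, "salt_bridge",
                                             longest_run = 300, total_on = 340)))
red_spec <- synthetic_spec(n_frames = 400, hinge_amplitude = 25, seed = 42,
  interaction_schedule = list(schedule_entry(10, 80, "salt_bridge",
                                             longest_run = 12, total_on = 40)))
ox  <- make_hinge_trajectory(ox_spec)
red <- make_hinge_trajectory(red_spec)
part <- synthetic_partition(ox_spec)

domain_geometry_features(domain_centers(ox, part))[1, c("R_ab", "R_bbp", "theta_abbp")]
#>   R_ab R_bbp theta_abbp
#> 1 29.8  29.6      173.4

aligned <- superpose_trajectory(red, fit_residues = domain_residues(part, c("b", "bp")))
pca_modes(aligned)
#> PcaModel: 300 components over 100 residues; PC1-PC4 variance fractions: 0.982, 0.012, 0.000, 0.000

tab   <- make_feature_samples(ox_spec, n_per_state = 5000)
split <- split_train_test(nrow(tab), seed = 7)
fit_linear_threshold(tab$R_bpap, tab$state, split, feature = "R_bpap")
#> LinearDiscriminator [R_bpap]: 'ox' > V_sep = 1.086; accuracy train 85.1%, test 83.7%
evaluate_svm_rbf(tab$R_bbp, tab$state, split)   # bimodal feature: SVM 96.8% vs linear 73.5%

drin_ox  <- compile_drin(build_adjacency_series(ox),  "ox")
drin_red <- compile_drin(build_adjacency_series(red), "red")
drin_ox
#> DRINGraph [ox]: 105 edges over 400 frames (salt_bridge: 1, van_der_waals: 104)
sig <- threshold_merge(differential_drin(drin_ox, drin_red, eps = 1), cutoff = 1)
sig
#> DifferentialGraph: 1 edges (eps = 1, |Delta| >= 1)
#>   salt_bridge 10-80: Gamma 300 vs 12, Delta = 4.53
export_graph(sig, "diff.graphml", partition = part)
```

The one edge surviving the |Δ| ≥ 1 cutoff is exactly the planted pair:
Δ = log₂(301/13) ≈ 4.53. The PC1 variance fraction (0.98) and the hinge
geometry are likewise recovered from the generator's ground truth.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/mdrin.R features  --traj ox.pdb --domains domains.yaml --out features.tsv
Rscript inst/cli/mdrin.R pca       --traj ox.pdb --domains domains.yaml --fit b,bp --out proj.tsv
Rscript inst/cli/mdrin.R fel       --traj ox.pdb --domains domains.yaml --pcs 1,2 --out fel.tsv
Rscript inst/cli/mdrin.R classify  --features labeled.tsv --feature R_bbp --seed 17
Rscript inst/cli/mdrin.R drin-diff --traj-ox ox.pdb --traj-red red.pdb --eps 1 --cutoff 1 --out diff.graphml
```

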