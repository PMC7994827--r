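# hingeshift

Residue-level conformational dynamics analysis for protein design by the
hinge-shift mechanism.

`hingeshift` computes perturbation-response flexibility and coupling
profiles of proteins from elastic network models or coordinate ensembles,
classifies rigid "hinge" residues across an ancestor/descendant pair, and
applies coupling-based selection rules to propose the minimal substitution
sets that mold one protein's flexibility profile into another's — the
strategy used to convert a promiscuous ancestral β-lactamase into a
penicillin specialist. It is aimed at structural bioinformaticians and
protein engineers who want dynamics-aware mutation candidates rather than
active-site redesign.

## The method

The protein is coarse-grained to one node per residue at its Cα. Linear
response theory gives the displacement under a force **F** applied at one
site as **ΔR** = **H**⁻¹**F**, where **H** is the 3N×3N network Hessian;
equivalently **ΔR** = **G F**, with **G** the positional covariance matrix
(ENM pseudo-inverse, or estimated from an ensemble). Perturbation response
scanning applies unit forces ("Brownian kicks", averaged over directions)
at every site j and records the response magnitude |ΔR^j|ᵢ at every
residue i, giving the N×N response matrix **A**.

From **A**:

- **DFI** (dynamic flexibility index):
  DFIᵢ = Σⱼ Aᵢⱼ / Σᵢⱼ Aᵢⱼ — the fraction of total response concentrated at
  residue i. %DFI is its percentile rank; residues with %DFI < 0.2 are
  *hinges*.
- **DCI** (dynamic coupling index):
  DCIᵢ = (Σ_{j∈functional} Aᵢⱼ/|functional|) / (Σⱼ Aᵢⱼ/N) — preferential
  coupling of residue i to a functional set; the pairwise form
  DCIᵢʲ = Aᵢⱼ/(Σⱼ Aᵢⱼ/N) scores individual partners, compared by
  percentile rank (%DCI).

Across an aligned protein pair, hinges are classified as common (hinge in
both) or non-common (hinge in exactly one), and three mutation sets are
selected:

- **X** — sequentially non-conserved non-common hinges with %DCI ≥ 0.8 to
  another non-common hinge (the hinge shifts themselves),
- **Y** — non-conserved common hinges coupled to non-conserved non-common
  hinges (compensatory substitutions),
- **Z** — DARC spots: mid-flexibility residues (0.3 < %DFI < 0.5), more
  than 8 Å from the active site, allosterically coupled to conserved
  non-common hinges.

Trajectory mode estimates **G** from windowed, backbone-superposed frames
and declares the dynamics converged when mean DFI profiles agree across
window sizes (pairwise Pearson r ≥ 0.9). Profiles of several proteins are
compared by SVD/PCA reduction, biplot coordinates, Euclidean distances and
average-linkage dendrograms.

## Worked example

```r
library(hingeshift)

# a deterministic two-protein fixture with a known hinge shift
hp  <- hinge_shift_pair()
aA  <- response_matrix(hp$covA)   # PRS on the ancestor covariance
aB  <- response_matrix(hp$covB)   # ... and the descendant
pA  <- dfi(aA, "ancestor"); pB <- dfi(aB, "descendant")

map <- align_sequences(paste(hp$structureA$aa, collapse = ""),
                       paste(hp$structureB$aa, collapse = ""))
tab <- classify_hinges(pA, pB, map, hinge_threshold = 0.2)
table(tab$class)
#> common_hinge non_common_A non_common_B    non_hinge
#>            3            4            4           29

sx <- select_set_X(tab, pairwise_dci(aB), dci_threshold = 0.8)
sx
#> MutationSet X: 7 substitution(s)
#> N12V
#> P13V
#> Q14V
#> L30V
#> M31V
#> N32V
#> P33V
```

The three stiffened positions (12–14) gained hinge status in the
descendant, the four softened ones (30–33) lost it; all eight non-common
hinges that pass the %DCI ≥ 0.8 coupling filter (here seven of them) are
proposed for substitution with the descendant's amino acids.

The same pipeline runs from the shell on PDB inputs:

```sh
Rscript inst/cli/hingeshift.R dfi    --input protein.pdb --out prof
Rscript inst/cli/hingeshift.R design --input-a ancestor.pdb \
    --input-b descendant.pdb --active-site 45,70,130 --out design
```

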