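---
title: "Elastic-network community analysis of allosteric protein complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic-network community analysis of allosteric protein complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allonet)
```

## The problem

Allosteric proteins are regulated by ligands that bind away from the active
site; the signal travels through the structure's dynamics. In multi-chain
complexes a central question is whether that communication crosses
protein–protein interfaces. Two observable proxies organize the analysis:

* **Binding-site class.** A ligand pocket whose residues come from more than
  one chain is a *multichain binding site* (MBS); a pocket confined to one
  chain is a *single-chain binding site* (SBS).
* **Community class.** Residues that move together form dynamical
  *communities*; a community holding a substantial share of residues on each
  of two or more chains is a *multichain community* (MCC), the dynamical
  signature of inter-subunit coupling. Residues sitting on the
  highest-betweenness edges between communities are *critical residues* —
  the bottlenecks of inter-community signal transfer.

`allonet` computes both classifications from coordinates alone and supplies
the cohort statistics used to compare them, plus a synthetic-structure
generator so the entire pipeline can be validated against planted ground
truth without downloading anything.

## Model and procedure

**Coarse-graining.** Each polymer residue becomes one bead, either at its
C-alpha atom (`mode = "CA"`) or at its heavy-atom center of mass
(`mode = "COM"`, the default). The COM variant exists because side-chain mass
displacement matters for identifying functionally relevant residues; running
both modes and comparing is a first-class use case. Hydrogens are excluded
throughout: deposited structures rarely have them, and leaving them out keeps
the CA/COM comparison well defined on heavy-atom input.

**Elastic network.** Beads closer than `cutoff_enm` (default 15 Å, standard
anisotropic-network practice; the value is a reproduction-limiting unknown of
the original tooling and therefore configurable) are joined by springs of
uniform constant $\gamma$. The Hessian's off-diagonal $3\times3$ block for a
spring $(i,j)$ is $-\gamma\,\hat u\hat u^{\mathsf T}$ with $\hat u$ the unit
inter-bead vector; diagonal blocks make block rows sum to zero. The model is
mass-free: residue mass moves the bead position (COM mode) but never enters
the dynamics. Ligand atoms are excluded from the network — ligand influence
enters only through the coordinates of the apo and holo forms.

**Modes and correlations.** Eigenvalues below $10^{-8}\lambda_{\max}$ are the
rigid-body nullspace; a connected three-dimensional network has exactly six,
and more than six is reported as a disconnection error rather than silently
analyzed. From the remaining modes (all of them up to 2000 beads, the lowest
100 beyond that) the covariance blocks
$\Sigma_{ij}=\sum_k \lambda_k^{-1}V_{ik}V_{jk}^{\mathsf T}$ give normalized
cross-correlations
$C_{ij}=\operatorname{tr}\Sigma_{ij}/\sqrt{\operatorname{tr}\Sigma_{ii}\,
\operatorname{tr}\Sigma_{jj}} \in [-1,1]$. Correlations are basis-invariant
under rotations within degenerate eigenspaces, so tests compare correlation
matrices, never individual degenerate eigenvectors.

**Residue network and communities.** Residues in physical contact (any
heavy-atom pair within `contact_cutoff`, default 4.5 Å) are joined by an
edge carrying an affinity $a_{ij}=|C_{ij}|$ and a length-like weight
$w_{ij}=-\log|C_{ij}|$: strongly correlated contacts are short. Communities
come from divisive Girvan–Newman partitioning — repeatedly remove the edge of
maximal betweenness (weighted, $w$ as length) and keep the intermediate
partition maximizing the affinity-weighted modularity $Q$. The choice of
betweenness on $w$ with modularity on $a$ is the package's main modelling
commitment: the upstream method publishes neither objective, so this "strong
correlation means short path" reading is flagged as the chief reproduction
risk. Disconnected graphs are partitioned per component. Communities smaller
than `min_community_size` (default 5) are merged into the neighbouring
community with the greatest total edge affinity; this prevents singleton
communities from making the MCC fraction ill-defined and can be disabled.

**MCC rule.** A community is an MCC when at least two chains each hold
*strictly more than* `mcc_threshold` (default $\tau = 0.10$) of its residues.
A 99/1 split of a 100-residue community is not an MCC; neither is an exact
90/10 split. Lowering $\tau$ can only grow the MCC residue fraction.

**Critical residues.** For each community pair joined by at least one contact
edge, the inter-community edge(s) of maximal weighted betweenness — computed
on the original, pre-removal graph, ties keeping all tied edges — contribute
both endpoints. This is the interior-residue notion: surface critical sites
found by docking simulations are out of scope.

**Binding sites.** Site residues have a heavy atom within `cutoff_bs` of a
ligand heavy atom, boundary inclusive. The default is 4.0 Å, a standard
heavy-atom contact radius; 3.0 Å (the stricter pocket-similarity convention)
is available through the same argument because published MBS/SBS calls have
used both conventions. A site is MBS when ≥ 2 chains each contribute at
least `min_minor_chain_residues` residues (default 1); a complex is MBS when
any of its sites is. Peptide-category ligands are removed before analysis and
ligand roles (activator/inhibitor/regulator vs orthosteric by default) come
from a user-supplied modulator table — chemistry-based key computation is a
lookup here, not a computation.

**Surfaces.** SASA uses Shrake–Rupley quadrature with a deterministic
golden-spiral point set (default 960 points per atom, probe 1.4 Å); accuracy
against closed-form sphere geometry is ~1–2%, and translation invariance is
exact because points ride on atom centers. The reference method in the
literature is Lee–Richards slicing; the method difference is accepted and
covered by the quoted tolerance. Per-chain interface area is SASA(isolated)
− SASA(in complex); the complex totals are $I=\sum_c I_c$ (not halved,
matching the printed definition literally), $S$ the in-complex total, and
$\rho = I/S$. RSA divides a residue's in-complex SASA by its value in an
extended Gly-X-Gly tripeptide (packaged theoretical table), so
interface-buried residues can legitimately score 0. Subunit flexibility is
$A_{\mathrm{rel}} = A_s/(c\,M^d)$ with the classical monomer constants
$c = 6.3$, $d = 0.73$ as editable defaults, since the constants used by the
cited flexibility method are not printed anywhere accessible.

**Annotations.** Externally computed per-position scores (conservation as
1/rate, so higher = more conserved) are mapped onto structure residues by
global pairwise alignment (BLOSUM62, affine gaps 10/0.5); structure positions
aligned to reference gaps carry no score, mismatched aligned positions
inherit the reference score but are flagged, and identity below 30% is
treated as a wrong pairing. Evolutionary-coupling tables are standardized by
the within-domain standard deviation, exactly once — a `standardized`
attribute guards against double application.

**Statistics.** Class comparisons use the pooled two-sample $z$-test of
proportions (continuity correction off by default, switchable) with Wilson
95% intervals — Wilson rather than Wald because cohort panels are small.
Wilcoxon rank-sum tests use exact enumeration over rank assignments when
$\min(n) \le 8$ (valid under ties; guarded by an enumeration-size cap of
$2\times10^6$ subsets beyond which the tie-corrected normal path is used) and
the tie-corrected normal approximation otherwise. The apo–holo comparison is
an ordinary ANCOVA, `holo ~ apo + class`, with the F-test on the class term
(one factor, so the type-II and sequential tests coincide) and
inhibitor-bound holo structures excluded, because an inhibitor-bound holo
form is the inactive state. No multiple-testing correction is applied by
default — panels report raw p-values — though Bonferroni is one call away via
`p.adjust`.

## The synthetic generator: what it emulates, and what it does not

`generate_complex()` builds C2-symmetric two-chain complexes from jittered
lattice blobs: per chain, a compact main cluster (2×2×k lattice, 4 Å
spacing) and a 6-residue interface plate, joined by a thin contact layer.
Chain B is the exact C2 image of chain A at atomic resolution, so
correlation symmetry under chain swap is assertable to numerical precision.
Residues are written as alternating GLY/ALA with idealized N/CA/C/O(/CB)
local geometry so CA and COM coarse-graining, SASA, and contact detection
are all well defined. All randomness flows through one seeded private RNG;
the same seed yields byte-identical PDB output.

The planted truth mirrors the study contrasts:

* In the **apo** form of both pocket modes the seam between the two plates is
  packed (3.6 Å face gap): the plates move as one rigid unit spanning both
  chains — an MCC.
* **Interface-pocket (MBS) holo**: the ligand sits in the seam and keeps it
  locked; the MCC persists.
* **Single-chain-pocket (SBS) holo**: each chain binds its own ligand copy on
  the outer face of its main cluster and the seam releases to a 9.5 Å gap —
  still coupled through the elastic network (so the normal-mode analysis sees
  one connected assembly) but with no inter-chain contacts, so the multichain
  community disappears. This is the planted apo–holo class effect: ligand
  binding decouples the subunits only in SBS complexes, the direction the
  cohort comparisons are designed to detect.

Geometric constants were chosen once so that the generator's announced truth
is self-consistent under the default analysis parameters, and then frozen.
Two choices matter most. The main cluster is kept *compact* (2×2×2 or
2×2×3): modularity maximization happily splits elongated uniform lattices at
jitter-dependent internal planes, and with a compact cluster any such
fragment falls below `min_community_size` and is re-merged, making recovery
deterministic. The interface plate has 6 residues so that it stands as its
own community (above the merge threshold), which also guarantees every
complex has an intra-chain community boundary and hence critical residues.
Cohorts cycle chain sizes over 14 and 18 residues so complex size — and with
it the MCC residue fraction and the apo covariate of the ANCOVA — varies
across the cohort rather than being a single repeated value.

What the generator does **not** emulate: folded-protein geometry, sequence
realism, rotamers, crystallographic artifacts (altlocs and occupancies are
exercised by hand-built fixtures instead), asymmetric assemblies, and any
stoichiometry beyond C2 dimers. Passing the synthetic checks therefore
demonstrates that the machinery — parsing, coarse-graining, modes,
correlations, community detection, classification, surfaces, statistics —
does what it claims on structures whose truth is known; it does not
demonstrate that real allosteric complexes behave like the toys.

## Numerical choices and degenerate inputs

* Zero modes: $\lambda < 10^{-8}\lambda_{\max}$; more than six aborts with a
  disconnection error naming the cure (`cutoff_enm`).
* Edge weights: affinities floored at $10^{-6}$ (weight cap ≈ 13.8); weights
  additionally floored at $10^{-6}$ so $|C| = 1$ edges stay strictly positive
  for the betweenness solver.
* Tie-breaks are deterministic everywhere: equal-betweenness edge removal
  picks the lexicographically first endpoint pair; representative selection
  falls back to the PDB id; altloc occupancy ties prefer conformer 'A';
  community relabeling follows first appearance in vertex order. Outputs are
  bit-stable across runs.
* Coincident beads (< $10^{-6}$ Å) are an error, as are empty binding sites
  at classification time (an empty site is flagged, not an error, at
  detection time), zero-SD coupling domains, and alignment identity < 30%.
* `summarize_complex` reports the critical-in-interface fraction as absent
  (`NA`), never as zero, when a complex has no critical residues.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated data:
toy graphs of ≤ 20 nodes against brute-force oracles (exhaustive modularity
maximization over all 4.2 million partitions of 12 nodes is done in compiled
code), synthetic complexes of 28–36 residues, a 20 + 20 classification
cohort, and 33 apo–holo pairs analyzed in both CA and COM modes. These sizes
give sub-second per-complex analyses while exercising every stage; the same
code paths scale to real complexes of a few thousand residues, where dense
eigendecomposition becomes the dominant cost.

## Known limitations

* The Girvan–Newman objective pairing (betweenness on $-\log|C|$, modularity
  on $|C|$) is a reconstruction; the upstream tool's exact stopping rule and
  weighting are unpublished.
* The elastic-network cutoff and mode count of the original pipeline are
  likewise unpublished; defaults follow standard anisotropic-network
  practice.
* Shrake–Rupley quadrature differs from Lee–Richards slicing at the ~1%
  level; all surface tolerances are quoted accordingly.
* Symmetry labels, conservation rates, coupling scores, binding-energy
  tables and modulator keys are consumed as inputs, never computed.
* The generator produces C2 dimers only; higher-order and asymmetric
  assemblies are analyzable by the pipeline but not synthesized.

## A worked run

```{r example}
out <- generate_complex(synthetic_spec(pocket_mode = "interface", seed = 42))
x <- preprocess(parse_structure(out$pdb))
analysis <- analyze_complex(x, allonet_config(mode = "COM"))
analysis
table(community = analysis$per_residue$community,
      chain = analysis$per_residue$chain)
```

The interface-pocket complex is called MBS, and the community spanning both
chains (the packed plates) is flagged as an MCC; its residues are the
MCC residue fraction reported in the summary.
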