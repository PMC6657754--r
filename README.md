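# allonet

Elastic-network community analysis of allosteric protein complexes.

## What it is for

Allosteric regulation in multi-chain protein complexes raises a structural
question: does the signal between a regulatory site and the active site cross
protein–protein interfaces, or does each subunit work on its own? `allonet`
answers it from coordinates alone, for structural biologists and
bioinformaticians studying quaternary structure and allostery. It classifies
every ligand-binding site as **multichain (MBS)** — residues from more than
one chain — or **single-chain (SBS)**, partitions the complex's dynamics into
**communities** of correlated residues, flags **multichain communities
(MCCs)** whose residues are spread over several chains, and identifies the
**interior critical residues** bridging communities. Cohort-level functions
compare the two classes and apo–holo pairs with the appropriate statistics.

## The model

1. **Coarse-grain**: one bead per residue, at the C-alpha atom or the residue
   heavy-atom center of mass (default).
2. **Anisotropic elastic network**: beads within 15 Å joined by uniform
   springs γ; Hessian block for spring (i,j) is −γ·û ûᵀ.
3. **Normal modes**: eigendecomposition; the six rigid-body modes are
   discarded; residue cross-correlations are

   C_ij = tr Σ_ij / √(tr Σ_ii · tr Σ_jj),  Σ_ij = Σ_k λ_k⁻¹ V_ik V_jkᵀ.

4. **Residue network**: contact edges (heavy atoms within 4.5 Å) weighted by
   affinity a = |C| and length w = −log|C|.
5. **Communities**: Girvan–Newman — iteratively remove the edge of maximal
   weighted betweenness, return the partition maximizing affinity-weighted
   modularity Q; merge communities smaller than 5 residues.
6. **MCC rule**: a community is multichain when ≥ 2 chains each hold strictly
   more than 10% of its residues.
7. **Critical residues**: endpoints of the maximal-betweenness edges between
   community pairs.
8. **Surfaces**: Shrake–Rupley SASA; interface area I = Σ per-chain
   (isolated − in-complex) SASA; relative interface area ρ = I/S; relative
   solvent accessibility against Gly-X-Gly tripeptide references; subunit
   flexibility A_rel = A_s/(6.3·M^0.73).
9. **Statistics**: pooled two-proportion z-tests with Wilson 95% CIs,
   Wilcoxon rank-sum tests (exact enumeration for min(n) ≤ 8), and apo–holo
   ANCOVA `holo ~ apo + class` excluding inhibitor-bound structures.

A seeded generator builds C2-symmetric toy complexes with planted
communities, interface or single-chain pockets, and apo/holo variants, so the
whole pipeline is testable against known ground truth.

## Worked example

```r
library(allonet)

out <- generate_complex(synthetic_spec(pocket_mode = "interface", seed = 42))
x   <- preprocess(parse_structure(out$pdb))
analyze_complex(x, allonet_config(mode = "COM"))
```

```
allonet analysis of 'SYNT' (COM mode)
  2 chains, 28 residues, 1 ligand(s), site class: MBS
  3 communities (1 multichain), MCC residue fraction 0.429
  4 critical residue(s), fraction in interfaces: 0.500
  interface I = 438.1 A^2, surface S = 1603.7 A^2, rho = 0.2732
```

The ligand sits in the inter-chain seam, so the site is called MBS; the
packed interface plates of the two chains are detected as one community
spanning both chains (an MCC holding 12 of 28 residues, fraction 0.429);
half of the critical residues bridging communities lie in the
protein–protein interface; and 27% of the complex's surface is buried in the
interface (ρ).

Cohort comparison on generated data:

```r
d <- tempfile(); generate_cohort(4, 4, d, seed = 7)
run_cohort(d, alternative = "greater")
```

```
allonet cohort: 8 complexes (4 MBS, 4 SBS)
  MCC fraction Wilcoxon p = 0.0143; has-MCC proportion test p = 0.00234
```

MBS complexes carry significantly more residues in multichain communities
than SBS complexes — the package's central comparison.

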