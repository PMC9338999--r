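---
title: "Models and methods behind abrescue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind abrescue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abrescue)
```

## The problem

Therapeutic antibodies against cell-surface receptors can lose efficacy when
the tumor acquires point mutations inside the antibody's epitope. A classic
mechanism is steric: a small epitope residue that nestles into a cavity of
the antibody paratope mutates to arginine, whose long guanidinium side chain
no longer fits, and binding collapses. Because the epitope is tied to the
antibody's mechanism of action, the therapeutic goal is not to find a new
antibody but to *rescue* the existing one: find one or two paratope
substitutions that re-open the cavity (and ideally add a compensating
salt bridge to the new arginine) while keeping the rest of the molecule, and
hence its developability, untouched.

`abrescue` implements the computational arm of this strategy as a reusable
toolkit: interface ddG scanning over a structural ensemble, nomination of
"hotspot" paratope positions whose substitutions are predicted to restore
binding in every structural cluster, translation of those positions into a
degenerate-codon (NNS) focused phage-display library, and a stochastic
simulator of the coselection panning campaign that would isolate dual
binders from such a library.

## Binding-energy model

Binding is scored as `dG_bind = E(complex) - E(separated partners)` with the
partners rigidly separated (no repacking of the unbound state). The effect
of a point mutation is the familiar

    ddG = dG_bind(mutant) - dG_bind(wild type)

computed on the antigen side (resistance mutations; positive ddG = binding
weakened) or on the antibody side against a mutant antigen (candidate
rescues; negative ddG = binding restored). An identity substitution
short-circuits to the unchanged input, so ddG of a null mutation is exactly
zero by construction, which the tests exploit as an invariant.

The energy function is package-defined and deliberately simple; exact
reproduction of any production molecular-mechanics scale is a non-goal. Its
terms, all in package energy units (eu):

* **Lennard-Jones 6-12** on heavy atoms, with `r_min` the sum of per-element
  van der Waals radii (Lorentz combining) and geometric-mean well depths.
  The repulsive branch is clamped at 10 eu per pair so that clashes are
  strongly but finitely penalized: greedy optimization over rotamers stays
  well-behaved and no conformation can produce a non-finite energy.
* **Coulomb on formal charges** (Asp/Glu carboxylates -0.5 per oxygen,
  Lys +1, Arg +1 spread over the guanidinium nitrogens) with a
  distance-dependent dielectric `eps(r) = k r`, `k = 4`, and the standard
  electrostatic conversion constant 332 eu A/e^2. With these choices a
  carboxylate-guanidinium contact at 2.9 A scores about -2 eu, on the same
  scale as the other terms, so the Asp-Arg salt bridge that motivates the
  rescue designs is visibly rewarded.
* **Hydrogen bond**: a distance-window well (default 2.4-3.4 A, optimum
  2.9 A, depth 2 eu) between typed donors and acceptors. The model is
  hydrogen-free, so no angular term is possible; the window is a deliberate
  simplification consistent with heavy-atom-only structures.
* **Solvation**: Shrake-Rupley buried surface area. The interaction energy
  adds `w_solv * sum(sigma_a * dSASA_a)` over atoms whose accessibility
  changes on complexation, with negative sigma for carbon/sulfur (burial of
  hydrophobic surface is favorable) and positive sigma for nitrogen/oxygen.
  SASA uses a deterministic golden-spiral quadrature (92 points per atom by
  default; the suite checks 92- vs 960-point agreement within 5 %).

Term weights default to `(w_lj, w_elec, w_hb, w_solv) = (1, 1, 1, 0.5)` and
the pairwise cutoff to 8 A. All parameters ship as plain-text tables
(`inst/extdata/ff_elements.tsv`) and can be overridden through
`default_forcefield()`.

Two modeling decisions deserve emphasis. Hydrogens are stripped on input and
never rebuilt: the force field is heavy-atom only, which keeps mutation
scanning cheap and deterministic at the cost of angular hydrogen-bond
realism. And the separated state of `dG_bind` is rigid: separated partners
are not repacked. Rigid separation is deterministic, symmetric in the two
partners, and avoids coupling the ddG of a mutation to an optimizer's luck
in the unbound state.

## Side chains, mutation and ensembles

Side chains are rebuilt from ideal internal coordinates (tabulated bond
lengths and angles, planar rings) with a small backbone-independent rotamer
library (`inst/extdata/rotamers.tsv`, at least three modal chi tuples per
flexible amino acid; Gly/Ala have no chi search and Pro is built with one
fixed ring pucker). `mutate_residue()` preserves the backbone and CB stub,
tries every packaged rotamer of the target amino acid and keeps the
best-scoring placement, ties resolved by library order. `repack_shell()`
runs a greedy one-residue-at-a-time rotamer descent (3 sweeps by default)
over a 6 A shell; the scored shell energy is asserted non-increasing after
every sweep, so the descent guarantee is a hard invariant rather than a
hope.

Structural heterogeneity is emulated by `generate_ensemble()`: model 1 is
the repacked input, and every further model applies Gaussian chi jitter
(sigma 10 degrees) to the flexible interface side chains before repacking.
The reference campaign size is 100 models, matching the scale at which
per-mutation ddG distributions are summarized by their median. All
stochastic steps take an explicit seed (default 1729) and are exactly
reproducible.

Ensembles are clustered on their antibody-side interface fingerprints (the
set of antibody residues with any heavy atom within 5 A of the antigen)
using average-linkage hierarchical clustering on Jaccard distance, cut at
k = 3 clusters by default. The fingerprint metric was chosen because the
procedure clusters "by interface residues" conceptually, and Jaccard is the
natural distance between residue sets; no geometric superposition is
needed. When an ensemble has fewer distinct fingerprints than k (common for
the rigid toy fixture), the largest clusters are split by model index and
the padding is logged. Each cluster's representative is its lowest-energy
member, ties broken by the lowest model index.

## Hotspot nomination

Each cluster representative is saturation-scanned: every antibody-side
interface position x 19 non-native substitutions, each substitution built
by rotamer placement plus shell repack, each scored by ddG against the
mutant antigen. A position is a *candidate* in a cluster when its best
(minimum over substitutions) ddG is at most a threshold tau, default 0 -
the simplest reading of "some substitution is predicted to restore
binding". The hotspot set is the exact intersection of the per-cluster
candidate sets, so a hotspot must be rescuable in every structural cluster;
the reported per-position score is the max-over-clusters of the
min-over-substitutions ddG, a worst-case guarantee. Raising tau can only
grow the hotspot set (a tested monotonicity property). The scan is
antibody-side by default; record counts obey the exact identity
`19 * n_positions`, which is how the package reproduces the published
bookkeeping (clusters of 36/35/35 positions give 684/665/665 predictions,
2014 in total; 36/33/34 give 684/627/646, 1957 in total) independently of
any force field, via the roster mode of `saturation_scan()`.

## Focused library mathematics

Hotspot positions are randomized with NNS codons (N = A/C/G/T,
S = C/G): 32 codons covering all 20 amino acids with exactly one stop
(TAG), verified in the tests against a brute-force enumeration of the
genetic code. Diversity products are exact: six NNS positions give
`32^6 = 1,073,741,824` DNA variants and `20^6 = 64,000,000` protein
variants, with stop-free fraction `(31/32)^6 ~ 0.827`. Coverage under the
uniform-sampling model is `p = 1 - (1 - 1/D)^N` for `N` transformants (a
Poisson approximation `1 - exp(-N/D)` is reported alongside, flagged as
such). The report deliberately surfaces, rather than resolves, the gap
between a focused library of 1e6-1e7 phages and the 1.07e9 DNA diversity of
six NNS positions: at 1e7 transformants less than 1 % of DNA variants are
expected to be sampled, which is the realistic operating regime of such
campaigns and the reason selection, not exhaustive coverage, does the work.

## Panning simulator

The simulator is equilibrium-occupancy based: each variant carries one Kd
per target, derived from scan ddG tables through the additive model
`Kd = kd_ref * exp(beta * sum(ddG) + eps)`. A round applies, per particle:
prepan depletion (removing flagged nonspecific binders with probability
`prepan_depletion`), capture with probability
`capture_max * [T] / ([T] + Kd)`, `W` washes each surviving with
probability `1 - Kd/(Kd + K_w)` (a Kd-monotone proxy for off-rate, since no
wash kinetics are modeled), and amplification of the survivors back to a
fixed pool size. Expected-value propagation is the default mode - it makes
selection monotonicity exact and test oracles closed-form - and a seeded
stochastic mode (binomial survival, multinomial amplification) is available;
the suite checks that the two agree within Monte-Carlo error. The default
campaign is three rounds with ten washes each against the mutant target,
followed by a dual screen on the wild-type target that removes
mutant-only binders; affinities more than 1e4-fold above the reference are
treated as non-binding (capture probability zero). Defaults
(`[T]` = 10 nM, `capture_max` = 0.9, `K_w` = 100 nM, `amplify_to` = 1e6)
are package-defined, chosen so that a ten-fold-advantaged dual binder
resolves within three rounds, and are echoed in every report as
configuration rather than asserted as biology.

## The synthetic fixture and what passing tests mean

No structure download is ever required: `build_toy_complex()` constructs a
desk-scale two-chain complex (58 atoms) from ideal internal coordinates in
which the clash/rescue mechanism is *provable*. The antigen chain carries a
small cavity residue (Ser by default); the antibody chain carries a bulky
residue (Trp) facing the cavity plus Ala cage residues placed by a numeric
search so that

* every packaged Arg rotamer at the cavity position overlaps opposing heavy
  atoms by at least 0.4 A (the build achieves ~1.8-3.0 A),
* exactly one Arg rotamer's corridor is blocked only by the bulky antibody
  side chain, and substituting Asp for Trp opens it while placing a
  carboxylate oxygen 2.7-3.2 A from a guanidinium nitrogen, and
* intra-antibody "braces" make the corridor-blocking Trp rotamer the
  greedy optimizer's best choice even when it clashes, so the rescue
  geometry cannot be dodged during repacking.

All three properties are verified numerically at build time and re-verified
by independent brute-force distance checks in the test suite. The fixture
emulates the *mechanism* of resistance and rescue - steric exclusion and
salt-bridge compensation - for any clash-penalizing, charge-rewarding
energy function. It does not emulate real antibody loops, backbone
flexibility, glycosylation, or production-scale energy magnitudes; passing
its tests therefore demonstrates that the pipeline's logic and its
qualitative physics are correct, not that any particular kcal/mol value
would be reproduced on a crystal structure. The accession-based sign check
(median antigen-arginine ddG over 100 models being positive) runs on this
synthetic stand-in; the same entry points accept a user-supplied PDB file
and chain partition for real complexes.

## Numerical choices and degenerate inputs

* Ties everywhere break deterministically: first-encountered rotamer,
  lowest model index for cluster representatives, first occurrence for
  equal-occupancy alternate locations.
* Diversity products use double-precision integers, exact below 2^53 -
  far above any codon-library diversity.
* Degenerate inputs fail loudly: empty structures, water-only files,
  malformed coordinate fields (reported with the offending line number),
  residues missing from ddG tables (reported with position and amino
  acid), pool extinction ("library collapsed" with the round number), and
  empty hotspot sets abort library design with an explicit message.
* Problem sizes used by the tests and the acceptance script: 100-model
  ensembles on the 58-atom toy complex, 9-variant panning pools amplified
  to 1e6, and full-codon-table enumerations. These sizes keep every check
  closed-form or brute-force verifiable.

## Known limitations

Backbone geometry is frozen; only side chains move. The hydrogen-bond term
is distance-only. Formal charges ignore protonation equilibria (His is
neutral). The panning model has no phage biology - display valency,
helper-phage dynamics and PCR error are out of scope - and its parameters
are not fitted to any measured titers. Interface fingerprints ignore
near-interface second shells. The 1-based/0-based convention is: all
user-facing coordinates (residue numbers, codon positions in reports) are
1-based; DNA offsets inside `emit_oligos()` templates are 0-based frame
offsets, stated in its documentation.
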