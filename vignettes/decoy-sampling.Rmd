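---
title: "Evolutionary and memetic decoy sampling: models, parameters and design choices"
author: "evodecoy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary and memetic decoy sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evodecoy)
```

## The problem

De novo protein structure prediction asks for a protein's native structure
from its amino-acid sequence alone. Energy surfaces probed with current
coarse-grained potentials are weakly funneled and rich in deep non-native
minima, so practical first-stage pipelines do not hunt the single global
minimum energy conformation. They instead collect a *decoy ensemble* — a
broad, diverse set of low-energy conformations — and pass a reduced subset
on to expensive all-atom refinement. Diversity in the ensemble is what makes
it likely that the native basin was captured at all.

`evodecoy` implements two population-based stochastic searches for this
first stage:

* a **basic evolutionary algorithm (EA)**: a fixed-capacity population of
  conformations evolves by fitness-biased parent selection, molecular
  fragment replacement, and truncation survival;
* a **memetic EA (MEA)**: identical, except that every child is first mapped
  to a nearby local minimum by a greedy fragment-replacement descent before
  competing for survival, so the population evolves over *local minima* of
  the energy surface rather than arbitrary conformations.

Both are budgeted in energy evaluations, never in generations: energy
calculation dominates runtime, and a shared evaluation budget is what makes
EA-vs-MEA comparisons fair.

## Conformation model

A chain of $n$ residues is represented by its backbone dihedral angles
$(\phi_i, \psi_i, \omega_i)$, three per residue, under the idealized-geometry
assumption: bond lengths and bond angles are fixed at standard values
(CHARMM22-derived; see `ideal_geometry()`), which reduces the search space
to $3n$ dimensions. Forward kinematics (`build_coordinates()`) realizes
cartesian coordinates for the N, CA, C, O backbone atoms and a single CB
side-chain atom (absent for glycine), placing residue 1 in a canonical frame
(N at the origin, CA on +x, C in the xy-plane); every energy and similarity
measure used downstream is rigid-invariant, so the frame choice is
immaterial. Angles are degrees in $(-180, 180]$ with the IUPAC sign
convention (trans $\omega = 180$). Three stored angles are kinematically
inert — $\phi_1$ and $\omega_1$ (no preceding peptide) and $\psi_n$ (no
following amide) — and `measure_dihedrals()` reports them as `NA`
sentinels. The *extended* start conformation sets every stored angle to 180:
the fully extended trans chain is the simplest reproducible choice, and the
$n-2$ randomizing replacements that build each initial-population member
erase its details anyway.

Structural similarity is the least RMSD over CA atoms: optimal rigid-body
superposition by the Kabsch algorithm, proper rotations only, so mirror
images are not identified. The test suite cross-checks it against an
independent quaternion (Kearsley) eigenvalue formulation and against
`bio3d::rmsd`. The unweighted CA form is used throughout; no per-atom
weights are applied.

## The move operator

A *fragment configuration library* maps every window start
$i \in [1, n-2]$ to a list of 9-angle configurations for the 3-residue
window $[i, i+2]$. The move operator (`replace_fragment()`) draws a window
uniformly at random and overwrites its 9 angles with a configuration drawn
uniformly from that window's list. Libraries may be measured from known
structures (`build_library_from_structures()`) or synthesized from
secondary-structure basins (`synthetic_fragment_library()`). Two design
choices to be aware of:

* **Position-independent pooling** is the default window policy when
  building from structures: every target window receives the full pool of
  3-mers from all sources. A position-specific policy exists
  (`policy = "positional"`), but pooling maximizes the usability of small
  source sets.
* **Duplicates are retained** — uniform sampling then weights
  configurations implicitly by their observed frequency.
* The randomizing initializer (`randomize_conformation()`) performs its
  $n-2$ replacements as a deterministic *sweep* over windows $1 \ldots n-2$
  (random entry within each window), not at random positions. The sweep
  guarantees every residue is rewritten, so with single-entry windows the
  outcome is fully forced — the property that makes planted-target systems
  exactly reconstructible.

## The energy

The bundled potential sums five non-local terms (local terms would be
constant under idealized geometry): a soft-core 12-6 Lennard-Jones term, a
backbone hydrogen-bond term, a compaction term, a burial term, and a
water-mediated contact term. Published descriptions of coarse-grained
potentials of this family fix the intent of each term but not a complete
parameterization, so the concrete functional forms here are the package's
own, chosen to be simple, testable and brute-force checkable; the
`energy_model()` contract lets any other potential (for instance an adapter
to an external scoring program) stand behind the same interface. Absolute
energies are unitless — only their ordering matters, since selection is
rank-driven.

Term by term (all defaults live in one table, `amw_params()`):

* **Lennard-Jones**: $\sum \epsilon_{ij}[(r_{min,ij}/r)^{12} -
  2(r_{min,ij}/r)^6]$ over atom pairs at residue separation $\ge 2$, with
  AMBER-style per-type radii and depths. Below $0.8\, r_{min,ij}$ the curve
  continues linearly with its slope at the cap, so van der Waals spheres may
  interpenetrate softly and the term is finite everywhere — fragment moves
  produce occasional clashes and the search must survive them.
* **Hydrogen bonds**: donor N$(i)$ / acceptor O$(j)$ pairs at separation
  $\ge 3$ (so the $i,i{+}4$ helical bond is visible) score
  $-w_{hb}\, g(d)\, \cos^2\theta$, with $g$ a unit-peak Gaussian at the
  ideal N$\cdots$O distance of 2.98 Å ($\sigma = 0.3$ Å, hard cutoff 1 Å)
  and $\theta$ the C=O$\cdots$N angle, gated to $\theta > 90^\circ$.
* **Compaction**: $w_c \max(0, R_g - 2.2\, n^{0.38})^2$ — a hinge on the CA
  radius of gyration against the standard globular scaling law. Only
  expansion is penalized; collapse is never rewarded, to avoid over-rewarding
  compaction artifacts.
* **Burial**: each residue's side-chain centre (CB; CA for glycine) counts
  neighbours within 7 Å at separation $\ge 2$; a piecewise-linear well
  penalizes exposed hydrophobics and buried polars, with a binary H/P
  hydrophobicity classification (A, C, F, I, L, M, V, W, Y hydrophobic).
* **Water-mediated contacts**: class-pair weights times a smooth switching
  function equal to 1 in the 6.5–9.5 Å shell with 0.5 Å cosine tapers.

Sanity direction rather than calibration is what is asserted: a 12-residue
ideal helix ($\phi = -57, \psi = -47$) scores below the extended chain, each
term equals its brute-force double-loop oracle to $10^{-9}$, and every term
is rigid-invariant.

## The search

Each generation: `num_child` children are created (parent drawn by the
linear fitness weighting $w_i = (E_{max} - E_i) + 0.01(E_{max} - E_{min})$,
one fragment replacement applied); in the MEA each child is then minimized
by greedy descent — fragment replacements accepted only on *strict* energy
decrease, halting after $n$ consecutive rejections (budget permitting). The
merged parent+child set is truncated to the `pop_size` lowest energies
(stable order, parents before children at ties — deterministic, mildly
elitist), and the surviving population is appended to the running ensemble
$\Omega$. Numerical and semantic choices made where the design was open:

* The 1% floor in the selection weights keeps the worst member selectable
  and degrades an all-equal population to the uniform law.
* Strict decrease (`<`) in the greedy acceptance guarantees termination on
  finite libraries; equal-energy moves are rejected.
* The budget guard is checked before each child's first evaluation, and a
  greedy descent in flight halts the moment the counter reaches
  `eval_max`, returning its best-so-far: every minimization proposal is
  booked against the same budget, and the final count never overshoots.
  A generation in which at least one child was scored completes its
  survival step, so $|\Omega| = $ `pop_size` $\times$ (generations + 1)
  always holds.
* Parents are never re-minimized; a fragment move applied to a
  previously-minimized parent is precisely the "jump out of the minimum"
  that resets the memetic search, and the child is then re-minimized.
* All randomness flows from one root seed through five named streams
  (initialization, parent selection, move proposals, minimization,
  analysis subsampling), so toggling minimization or diversity logging does
  not perturb the other streams, and identical seed + configuration gives
  byte-identical archives.

Production-scale defaults (`pop_size` 1000; `num_child` 250 for the MEA, 4000
for the EA; $10^7$ evaluations) are retained as the function defaults, but
desk-scale work should use far smaller budgets — the examples below and the
bundled analyses run at toy scale.

## Ensemble analytics

`lowest_lrmsd_summary()` reports the average and minimum over runs of each
run's lowest lRMSD to a native — the standard Avg(Min) benchmark statistic.
`reduce_p95()` retains exactly $\lceil 0.05 |\Omega| \rceil$ decoys; "95th
percentile according to energies" is read as the *best* (lowest-energy) 5%,
the only reading consistent with using the reduced ensemble to seed stage
two — the opposite reading is available via `keep = "worst"`.
`median_pairwise_lrmsd()` is the structural-diversity measure (median over
all population pairs, subsampled above a 50,000-pair cap and flagged as
such); `energy_vs_lrmsd_table()` and `lrmsd_histogram()` export the funnel
and distribution views, flagging decoys within 5 Å as having captured the
native basin. The per-run percentile reduction can also be applied to the
pooled multi-run ensemble (`pool_ensembles()`), which is the default way
multi-run figures are assembled.

## The synthetic toybox and what it does (and does not) show

Everything above is testable offline through synthetic systems
(`make_toy_system()`): a random sequence, a target conformation drawn from
helix/strand basins, and a synthetic library. The separable toy energy
(`toy_energy_model()`) scores the summed squared wrapped angular deviation
of every 3-mer window from the target's windows: its global minimum (zero,
at the target) is known by construction, and small instances can be solved
by exhaustive enumeration, giving the search code an independent oracle
that no physical potential could provide.

Two bundled configurations (`bundled_toy_system()`) define the package's
standard study conditions, chosen once:

* **recovery** — $n = 20$, 3 entries per window, target planted; run with
  `pop_size` 50 and 12 children per generation over a 50,000-evaluation
  budget, three seeds. Desk-scale population and child counts preserve the
  production-scale MEA ratio (`num_child` = `pop_size`/4). The planted library
  makes the landscape funneled and the native exactly reachable, so the
  memetic search is expected to reach it (lowest lRMSD $\le$ 2 Å).
* **diversity** — $n = 30$, 25 entries per window (a realistic per-position
  library richness), target *not* planted; `pop_size` 100 with 400 (EA)
  vs 25 (MEA) children — the production-scale 16:1 EA:MEA child ratio — over
  200,000 evaluations. Because the target is unreachable, conflicts between
  overlapping windows frustrate the landscape into many near-degenerate
  local minima. This is the regime in which the qualitative contrast
  appears: the EA's population diversity collapses after an early peak and
  never recovers, while the MEA's stays well above zero. A planted library
  at this size is deliberately *not* used for the contrast: with the target
  reachable, both algorithms converge to the single global optimum and both
  curves hit zero — a degenerate regime that says nothing about search
  character.

What passing on these systems does **not** show: the toy energy is smooth
per window, has no inter-residue physics, and its landscape ruggedness comes
only from window overlap; real fragment libraries are sequence-conditioned
and real potentials have far richer minima structure. Toy results certify
the *search machinery* — budget accounting, selection laws, minimizer
semantics, diversity bookkeeping — not predictive accuracy on real
proteins. Conversely, absolute energies of the bundled physical potential
are not comparable to any published potential's values, since its
parameterization is the package's own.

## Known limitations

* Side chains beyond CB, flexible covalent geometry, and all-atom
  refinement are out of scope; the representation is a first-stage
  coarse-grained model only.
* The lRMSD is unweighted over CA atoms.
* Crossover operators and multi-objective selection are not implemented.
* Per-generation diversity logging uses subsampled pairs (200 by default)
  and is therefore an estimate; exhaustive mode is available through
  `median_pairwise_lrmsd()`.

## A worked toy run

```{r toy-run}
sys <- bundled_toy_system("recovery", seed = 1)
sys
run <- sample_decoys(sys$sequence, sys$library, toy_energy_model(sys$target),
                     algorithm = "mea", pop_size = 50, num_child = 12,
                     eval_max = 5000, seed = 1)
run
lowest_lrmsd(run$ensemble, sys$target)
```
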