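# evodecoy

Population-based evolutionary decoy sampling for de novo protein structure
prediction, in R.

## What problem this addresses

Predicting a protein's structure from sequence alone means searching an
enormous conformational space over an energy surface that — as probed by
any current coarse-grained potential — is weakly funneled and full of deep
non-native minima. First-stage ("decoy sampling") pipelines therefore do
not chase the single global minimum energy conformation; they collect a
broad, *diverse* ensemble of low-energy decoy conformations, hoping the
native basin is among them, and hand a reduced subset to all-atom
refinement. This package is for people who study that first stage: it
provides two budgeted stochastic searches over coarse-grained backbone
conformations, the machinery around them (fragment libraries, a pluggable
five-term energy, Kabsch lRMSD), and the ensemble analytics used to compare
them.

## The algorithms

A conformation is its 3n backbone dihedrals (φ, ψ, ω per residue) under
idealized covalent geometry; forward kinematics realizes N/CA/C/O/CB
coordinates. Moves are **molecular fragment replacements**: the 9 dihedrals
of a random 3-residue window [i, i+2] are overwritten by a configuration
drawn from a fragment library.

* **Basic EA** — a population P of fixed capacity evolves by
  fitness-weighted parent selection (linear weighting
  w_i = (E_max − E_i) + 0.01 (E_max − E_min)), fragment-replacement
  children, and truncation survival (the |P| lowest-energy members of
  parents ∪ children). Highly exploitative.
* **Memetic EA (MEA)** — identical, but every child is first mapped to a
  nearby local minimum by greedy descent: fragment replacements accepted
  only on strict energy decrease, halting after n consecutive rejections.
  The population becomes a population of local minima; a later fragment
  move on a surviving minimum "jumps out" of its basin and restarts the
  descent, which is what preserves ensemble diversity.

Both run against a fixed budget of energy evaluations (every greedy
proposal counts), never a fixed generation count. Every generation's
population is appended to the running decoy ensemble Ω, the object all
analytics operate on: lowest-lRMSD-to-native summaries (average and minimum
over independent runs), reduction to the lowest-energy 5% (Ω_p95), median
pairwise-lRMSD diversity per generation, energy-vs-lRMSD funnel tables and
lRMSD histograms.

## A worked example

Everything is runnable offline through synthetic toy systems with planted
targets and a separable toy energy whose global minimum is known by
construction:

```r
library(evodecoy)

sys <- bundled_toy_system("recovery", seed = 1)
sys
#> Toy system: n = 20, 3 entries/window, seed 1 (planted target reachable via certificate)

run <- sample_decoys(sys$sequence, sys$library, toy_energy_model(sys$target),
                     algorithm = "mea", pop_size = 50, num_child = 12,
                     eval_max = 20000, seed = 1)
run
#> Decoy sampling run (MEA, toy energy)
#>   sequence: n = 20; pop_size 50, num_child 12
#>   55 generations, 20000 / 20000 energy evaluations
#>   ensemble Omega: 2800 decoys; best energy 0

summary(run, native = sys$target)
#> Run summary (MEA): 55 generations, 20000 evaluations
#>   |Omega| = 2800, best energy 0
#>   final population median pairwise lRMSD: 0 A
#>   lowest lRMSD to native over Omega: 0 A
```

The memetic search found the planted target exactly: best toy energy 0 (the
known global minimum) and lowest lRMSD to the planted native 0 Å over the
2800-decoy ensemble (50 decoys × 56 populations, the initial one included).
On the physical side, `amw_energy_model(sequence)` scores conformations
with the bundled five-term coarse-grained potential behind the same
contract, and `write_run_archive()` / `read_run_archive()` persist runs as
hash-stamped, byte-reproducible TSV/JSON archives.

A thin command line covers the same surface:

```sh
Rscript inst/cli/evodecoy.R toybox --n 20 --entries 3 --seed 1 --out toy
Rscript inst/cli/evodecoy.R sample --algorithm mea --seq toy/target.fasta \
    --fraglib toy/fraglib.tsv --pop-size 50 --num-child 12 \
    --eval-max 20000 --seed 1 --out run1
Rscript inst/cli/evodecoy.R analyze --archive run1 \
    --native toy/planted_target.synthetic.pdb --p95 --out analysis
```

## Scope

Backbone-plus-CB coarse graining only; no side-chain packing, no all-atom
refinement, no crossover or multi-objective variants. The bundled potential
implements the standard five-term intent (soft-core LJ, H-bonds,
compaction, burial, water-mediated contacts) with the package's own
parameterization — orderings are meaningful, absolute values are not. See
`vignettes/decoy-sampling.Rmd` for the full model description and design
rationale.
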