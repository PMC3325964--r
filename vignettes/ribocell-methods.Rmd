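---
title: "The ribocell model: Monte-Carlo dynamics of cooperating ribozymes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ribocell model: Monte-Carlo dynamics of cooperating ribozymes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

ribocell simulates an early-evolution scenario in which three functionally
distinct RNA species — a replicase (**Rep**), a nucleotide synthetase
(**Nsr**) and an amphiphile synthetase (**Asr**) — replicate by
template-directed ligation and may spread together while competing for a
common pool of raw material.  The model has "micro-resolution": every
nucleotide, every amphiphile and every phosphodiester bond is an explicit
object, and template-directed synthesis is not a single assumed event but
the emergent outcome of base-pairing, ligation and dissociation of
individual substrates.

## The world

The system is an `n_grid` x `n_grid` toroidal lattice of *grid rooms*.
Molecules interact only within a room.  A room is either *naked* (it holds a
free pool of nucleotide precursors, nucleotides of the four bases,
amphiphile precursors, amphiphiles and RNA strands) or it hosts exactly one
*protocell*, whose membrane (a count `b` of amphiphiles) encloses an
interior pool.  Three stages are supported:

* **naked** — no amphiphile chemistry at all (`t_apb = 0`);
* **pseudo-protocell** — membranes exist but Asr exerts no catalysis;
* **true-protocell** — all three ribozyme functions are active.

At step 0, `t_npb` nucleotide precursors and `t_apb` amphiphile precursors
are scattered uniformly over the rooms.  Everything else — nucleotides, RNA,
membranes — is built by the event dynamics, apart from the molecules
introduced by an inoculation protocol.

## Ribozymes as sequence motifs

A ribozyme function is carried by a stem-loop *characteristic domain*:
`stem_len` residues, a function-specific 4-base loop (`AGUC` Rep, `ACUG`
Nsr, `AUCG` Asr, `UCAG` control) and a second arm pairing the first
(Watson-Crick or G-U wobble).  A strand at least twice the domain length is
assumed misfolded and has no function.  Classification scans all windows, so
one strand can carry two overlapping domains.  The *control* species has a
recognizable domain but no catalytic effect; it serves as an explicitly
tracked parasite.  `classify_rna()` exposes the classifier;
`ribozyme_sequence()` builds the minimal inoculum sequence for each species
(an all-A arm, the loop, an all-U arm).

Strand polarity is treated antiparallel throughout: the released copy of a
template is its reverse complement.  This matters: the residue-wise (parallel)
complement of the Rep loop `AGUC` happens to be the control loop `UCAG`, so
a parallel-complement model would interconvert Rep and the control on every
replication round and the two species could never evolve apart.  Under the
antiparallel rule each ribozyme's complement is a function-less minus strand
and replication is a two-step plus/minus cycle, which also reproduces the
natural competition between a ribozyme and its complementary chain.

## Events and their per-step probabilities

All probabilities are per Monte-Carlo step.  The full set (29 event
probabilities plus the scale constants) lives in a validated `rw_params()`
object; `rw_variant()` returns the printed configurations of the published
experiments.  Each step executes a fixed phase order:

1. **Nucleotide turnover** — precursors become nucleotides (random base)
   with `p_nf`, or `p_nfr` when a folded Nsr shares the compartment;
   nucleotides decay back with `p_nd`.
2. **Amphiphile turnover** — `p_af`/`p_afr` (Asr, true-protocell stage
   only) and `p_ad`; membrane amphiphiles decay with `p_adm`, their
   products released to the exterior bath.
3. **Strand decay** — chain ends decay with `p_nde` (interior residues are
   protected), internal bonds break with `p_bb`, multiplied by `f_bo`
   outside protocells in the protocell stages.  Strands engaged in a duplex
   (templates carrying substrates or a bound Rep, and Reps serving a
   template) are protected by their pairing.
4. **Random ligation** — free nucleotides join another nucleotide or a
   chain end with `p_rl`.
5. **Template dynamics** — folding-state flips (`p_rtt`, with optional
   per-class overrides; an empty template refolds with `1 - p_rtt`), Rep
   binding and release (`p_rb`, `p_rd`; one Rep serves one template at a
   time), substrate attraction (below), template-directed ligation (`p_tlr`
   with a bound Rep, `p_tl` otherwise, and the `p_flr` gate when a flanking
   pair is false), and dissociation (`p_sp`).
6. **Membranes** — assembly above the `l_am` threshold, amphiphile
   join/leave exchange with the osmotic-pressure reduction, precursor
   permeation (nucleotides and RNA never cross).
7. **Protocells** — breakage, fusion of adjacent pairs, division with
   random partition of membrane and contents.
8. **Movement** — free molecules hop between naked rooms with `p_mv`
   (strands with `p_mv/m^(1/3)`; in the protocell stages extracellular RNA
   and nucleotides are immobile by default), protocells with `p_mc`.

Derived closed forms (membrane leave rate, permeation, division, membrane
formation, RNA movement) are exported as plain functions
(`amphiphile_leave_prob()` and friends) and tested against hand-evaluated
values.

## Replication kinetics: the choices that matter

The published event list fixes the probabilities but leaves the fine
structure of substrate handling open, and the dynamics depend on it
strongly.  The package's defaults encode the following model, selected so
that the documented behaviours of the system — ribozymes spreading from a
small inoculum, the control parasite dying out, replication collapsing when
non-enzymatic ligation is weak and Rep is absent — emerge from the printed
probability values:

* **Attraction is substrate-flux limited** (`attraction = "flux"`).
  Attachment events in a compartment arrive at rate `p_at` *per free
  substrate molecule*, and each event fills a growth site: the position
  flanking an existing attachment (so copies grow contiguously, like primer
  extension), or a uniform position on a bare template to nucleate.  Rooms
  rich in free nucleotides therefore replicate proportionally faster; this
  is precisely the local benefit that Nsr confers and that makes the
  metabolic cooperation visible.  A nucleotide arrival takes the
  complementary base with probability `1 - p_fp` and a random
  non-complementary base otherwise; an oligomer must pair — or pass an
  independent `p_fp` draw — at every residue.
* **The replicase clamps its product** (`separation = "processive"`).
  Substrates (attachments never ligated on the template) dissociate when
  all of their base pairs separate in one step, i.e. with `p_sp^length`.
  A run ligated *by a bound Rep* is a clamped reaction intermediate and
  stays until elongation completes it; the completed full-length copy then
  dissociates with `p_sp^length`, which is the model's product inhibition
  (about one release per thousand steps at the printed `p_sp = 0.5` for a
  10-mer).  Chains joined non-enzymatically are *not* clamped — they remain
  ordinary substrates and almost always dissolve before completing, so at
  the printed `p_tl` non-enzymatic template copying cannot sustain a
  species on its own and replication genuinely requires Rep.
* **One Rep serves one template at a time.**  Because the folding-state
  phase precedes binding, a Rep that drops (or refolds) still gets its own
  chance to unfold and be copied; occupancy also caps a room's total
  catalytic throughput at its Rep count, which keeps runaway amplification
  of short parasitic fragments in check.

The alternative readings remain available as parameters (`attraction`:
`"extension"`, `"template"`, `"site"`; `separation`: `"memoryless"`,
`"ratchet"`) and are exercised by the unit tests; they are documented
because they illustrate sharp failure modes: per-site attraction with
ratchet separation floods the system with 2-4-mer debris, while fully
memoryless separation hands short templates a release-rate advantage of two
orders of magnitude and ends in a short-parasite collapse.

## Parameters without printed values

The published tables fix all event probabilities and the naked-stage scale
constants.  A few protocell-stage constants are never printed and are
package choices, made once: grid side `n_grid = 30` (between the naked
`n_grid = 20` and the sweep-scale grids), `t_npb = 8e4` (back-computed from
the published display scale, where a plotted value of 400 denotes `8e4`
precursors at the 1/200 scale), `t_apb = 4e4` (half the nucleotide-precursor
total: enough amphiphile material for a few hundred protocells at the
`l_am = 100` membrane minimum), `f_op = 1`, `f_si = 2` (the only printed
value), and `f_bo = 10` (degradation outside protocells an order of
magnitude faster, reflecting the higher water activity of the bulk phase).
The membrane-formation law is `p_mf * (1 - l_am/(a + 1))` for `a >= l_am`
free amphiphiles (the printed source for this one formula is illegible; the
chosen form is gated on the lower limit, increases with `a` and saturates at
`p_mf`, and a flat `"constant"` alternative is selectable).

## Conservation and reproducibility

Nucleotide units (precursors + free nucleotides + strand residues +
attached substrates) and amphiphile units (precursors + free + membrane)
are conserved by every event; the engine recomputes both totals after every
step and stops on any discrepancy.  Inoculations add material and shift the
audited baselines accordingly (`rw_audit()`).

Every stochastic draw flows through R's RNG, and each simulation handle
owns its stream, so a (parameters, seed) pair reproduces a trajectory
bit for bit.  The draw discipline — iteration orders, when a binomial is
drawn versus short-circuited, the single-uniform inversion walk used for
small expected counts — is part of the engine contract, and the test suite
contains an independent plain-R reimplementation of the whole step that
replays engine runs exactly, state for state, on small grids.

## What the generator does and does not emulate

Simulated data reproduce the model's own idealizations: per-step hazards
(no physical time units), a two-dimensional torus, single-room protocells,
binary folded/template states with no secondary-structure thermodynamics,
and sequence-only fitness (no chemistry beyond Watson-Crick/wobble
pairing).  Passing tests therefore demonstrate internal consistency of the
model and qualitative agreement with the published system-level behaviours;
they say nothing about real prebiotic chemistry rates.

## Problem sizes used by the tests

The test suite and the acceptance script run the model at the sizes the
analyses need rather than at figure-production scale: conservation audits
use the full printed configurations for 1e4 steps; the naked-stage
co-spread ensemble uses the printed naked configuration (`n_grid = 20`,
`t_npb = 8e4`) with a 6e4-step horizon (inoculation at 1e4) and three
seeds, checking the published spreading criterion (counts strictly above
the 50-copy inoculum) at the horizon; the movement-rate perturbation
continues one run for a further 4e4 steps with `p_mv` raised to 0.01; and
the protocell-stage comparison runs matched pseudo/true configurations to
6e4 steps.  On horizons several times longer the naked system is
boom-bust: parasitic by-products accumulate and the replicase count can
fall back under the inoculum after its spread peak, a known limitation
discussed above.  The sweep machinery
itself is scale-free: `run_sweep()` accepts any number of seeds and any
horizon, so the full published design (100 seeds per value, checked at step
5e5) runs unchanged given the computing time.

## Known limitations

* The spreading-chance landscape is sensitive to the kinetic fine structure
  discussed above; quantitative bar heights of published sweeps are not
  expected to be matched, only directional behaviour.
* Fusion of protocells across a torus of side 2 double-counts shared edges;
  grids of side >= 3 are assumed.
* Oligomer substrates attach with their ends aligned to a growth site;
  interior placements unreachable by contiguous growth are not sampled in
  flux mode.
* The inoculum protocell membrane size defaults to `l_am`; the published
  protocol states only that protocells "contain" the molecules.
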