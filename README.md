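# epimode

Binding-mode identification for rigid protein binders from docking
ensembles and mutational binding data.

## The problem

Rigid scaffold binders (leucine-rich-repeat repebodies, DARPins,
affibodies, nanobodies) present a fixed binding face, so rigid-body docking
against their target yields an ensemble of plausible complex models — and
force-field energy alone is a poor judge of which one is native. `epimode`
implements the integrated computational workflow that resolves the
ensemble experimentally:

1. **Epitope extraction.** Every docking model hypothesizes an epitope: the
   target residues within a heavy-atom contact cutoff *d* (default 5 Å,
   CAPRI convention) of the binder.
2. **Variant panel design.** Epitope residues are clustered into spatial
   patches (single-linkage on Cβ, 8 Å radius) and an exact minimum set
   cover selects the fewest ≤ *k*-point mutants (default *k* = 3, one patch
   per variant) such that every model is probed by at least one variant.
   Homodimer symmetry (e.g. the two Fc protomers) is handled explicitly.
3. **Position calls.** Measured Kd fold changes, *f* = Kd(variant)/Kd(WT),
   classify positions: disrupted (*f* ≥ 1.5 by default), neutral, or
   untested.
4. **Filtering and ranking.** A model survives iff it contacts every
   disrupted position (under symmetry) and no neutral one; survivors are
   ranked by interface energy (built-in coarse LJ + screened-Coulomb
   scorer, or imported force-field energies), ascending, deterministic
   tie-breaks.
5. **Quality control.** CAPRI-style metrics against a reference complex:
   f_nat (fraction of native contacts), I-RMSD (backbone RMSD over
   reference-defined 10 Å interface residues after Kabsch superposition)
   and interface-residue recovery.
6. **Redesign.** Cross-species conservation classes per target position,
   ranking of binder residues by divergent contacts (specificity
   engineering, loop truncation records), multi-target substitution scans
   and greedy two-position affinity design.

Deterministic synthetic fixtures (toy complexes with planted contact sets,
graded rigid-body decoys with oracle labels, exact C2 homodimers, simulated
ITC-style assay tables) make the whole pipeline testable without any
external data.

## Worked example

An 8-pose decoy ensemble around a planted native, panel design, a simulated
binding assay, filtering and ranking:

```r
library(epimode)

native <- make_toy_complex(toy_spec(6, 16, contacts = cbind(1:3, c(4, 5, 6))),
                           id = "native")
part <- chain_partition("R", "T")
ds <- make_decoy_set(native, decoy_schedule(c(0, 0, 0, 0, 90, 0, 180, 0),
                                            c(0, 3.5, 5, 7, 10, 14, 20, 28)))
epis <- lapply(ds$decoys, epitope_of_model, part = part)

panel <- design_variant_panel(epis[lengths(epis) > 0],
                              cluster_patches(epis[lengths(epis) > 0], native))
panel
#> <panel_set> best panel: 1 variant(s), 0 alternate(s)
#>   variant: T:4/T:5/T:6  covers: D01

assay <- simulate_assay_outcomes(epitope_of_model(native, part),
  lapply(panel$panels[[1]]$variants, `[[`, "positions"), seed = 42, s = native)
calls <- call_positions(assay)
calls
#>   position    status fold_change
#> 1      T:4 disrupted    2.835285
#> 2      T:5 disrupted    3.110941
#> 3      T:6 disrupted    3.195995

keep <- filter_models(epis, calls)
energies <- vapply(ds$decoys, function(d) score_interface(d, part)$value,
                   numeric(1))
rank_and_select(energies, filtered = keep)
#> <model_ranking> selected: D01
#>   model_id     value
#> 1      D01 -6.062519

sel <- ds$decoys[["D01"]]
c(fnat = fnat(sel, native, part), irmsd = irmsd(sel, native, part))
#>  fnat irmsd
#>     1     0
```

The three panel mutations all fall in the native epitope, so their
simulated Kd fold changes (~2.8–3.2×) call them disrupted; only the planted
native pose `D01` contacts all three, the other seven poses are filtered
out, and the survivor's quality against the native is perfect (f_nat = 1,
I-RMSD = 0 Å). `planted_native_recovery()` repeats this under a noisy
scorer (noise SD = half the score range, 100 trials) and shows that energy
ranking alone recovers the native only a minority of the time while
filtering plus ranking is near-certain.

A thin command-line front end over the same functions lives at
`inst/cli/epimode.R` (subcommands `contacts`, `epitope`, `qc`, `filter`,
`rank`, `simulate`), and the methods vignette
(`vignettes/binding-mode-identification.Rmd`) documents the model,
parameters and design choices in detail.

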