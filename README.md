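# ligfid

Profiling the fidelity and sequence bias of DNA ligases in cohesive
end-joining.

## The problem

End-joining ligation — sealing two DNA fragments whose short 5′ overhangs
have annealed — underpins cloning, Golden Gate assembly, adaptor ligation
and many diagnostic workflows. Ligases differ in two ways that matter for
these applications:

* **Sequence bias**: some four-base overhangs are ligated far more
  efficiently than others (GC-rich overhangs anneal more strongly; certain
  families such as TNNA are systematically inefficient).
* **Fidelity**: ligases join not only Watson–Crick-paired overhangs but also
  partners carrying mismatched base pairs at the junction, with G:T the most
  tolerated mismatch and edge positions (N1:N4) more permissive than middle
  positions (N2:N3).

Multiplexed assays measure both at once: a substrate pool with a randomized
four-base overhang lets every overhang compete for every partner in one
reaction, and sequencing the products yields, for each ligation event, the
ordered pair of overhangs that were joined. `ligfid` implements the complete
analysis for such assays, together with a generative model that makes every
stage testable without sequencing data.

## The model

An overhang is a 4-base 5′ extension read 5′→3′; there are 256 of them, and
the Watson–Crick partner of overhang *o* is its reverse complement. In an
annealed pair (top, bottom), top position *i* opposes bottom position
5 − *i*. Products are counted **in both orientations** (strand designation is
arbitrary), giving a symmetric 256 × 256 pair-count matrix *C* with total
ordered count 2 × products.

The generative model assigns each ordered pair (a, b) the propensity

```
propensity(a, b) = w_a · w_b · exp(α · gc_pairs(a, b)) · Π_mismatches tol(type, class)
```

where `w` are per-overhang weights, `α` is a log-scale annealing boost per
correctly paired G:C position, and `tol` ∈ [0, 1] is keyed by unordered
mismatch type (G:T ≡ T:G) and position class (edge/middle). Ligation events
are a multinomial draw over pairs with these propensities, which gives exact
closed forms for every statistic the package reports:

* **normalized ligation frequency** `freq(o) = 256 · Σ_b C[o,b] / Σ C`
  (uniform usage = 1),
* **fidelity** = fraction of events in Watson–Crick cells, overall and per
  overhang (`C[o, revcomp(o)] / Σ_b C[o,b]`),
* GC-stratified summaries (bins 0/25/50/75/100% GC hold 16/64/96/64/16
  overhangs), positional mismatch spectra, multi-mismatch distributions,
  pattern-group summaries (TNNA, CNNG, ...), cross-sample Pearson
  correlations, and synthesis-bias correction from the substrate's
  randomized control region.

A kinetics module fits initial velocities of defined-overhang timecourses by
OLS over the linear regime (≤ 25% product conversion).

## Worked example

```r
library(ligfid)

model <- ligase_model_preset("moderate")   # mild GC bias, G:T-dominated tolerance
counts <- sample_events(model, 1e5, seed = 42)
prof <- ligation_profile(counts)
summary(prof)
```

```
Ligation profile: 1e+05 products, overall fidelity 64.5%
Mismatch-containing products: 35.5%
  single-mismatch share of mismatch products: 85.9%
  double-mismatch share of all products: 4.7%
  double mismatches involving an edge position: 97.3%

Normalized frequency by GC content:
 gc_percent n_overhangs n_defined  mean median
          0          16        16 0.485  0.479
         25          64        64 0.668  0.651
         50          96        96 0.943  0.926
         75          64        64 1.329  1.342
        100          16        16 1.872  1.900
...
Top mismatches by position class:
 label position_class weight frequency
   G:T           edge  17361    0.2675
   T:G           edge  17361    0.2675
   G:G           edge   8578    0.1322
```

Reading the output: 100,000 simulated ligation events gave 64.5% correct
(Watson–Crick) products; frequency rises with GC content (mean 0.49 in the
0% GC bin vs 1.87 at 100% GC — the α = 0.35 annealing boost at work), and
the edge mismatch spectrum is dominated by G:T/T:G (53.5% combined), with
both labels appearing because every product is counted in both orientations.

The same functions run on real data: `read_counts_csv()` loads pair-count
tables (long or wide form), `combine_replicates()` pools replicate runs, and
`read_products_fasta()` + `extract_counts()` go from product strand reads to
counts. The `run_*` functions (or `inst/cli/ligfid.R`) wire the stages into
a file-based pipeline with manifests.

```r
# two replicates of one condition, from CSV to a profile
reps <- lapply(c("rep1.csv", "rep2.csv"), read_counts_csv)
prof <- ligation_profile(combine_replicates(reps, override = TRUE))

# condition comparison (e.g. with and without PEG)
compare_profiles(prof_std, prof_peg)
```

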