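# prfkin

Kinetic modelling of −1 programmed ribosomal frameshifting at the
*E. coli* *dnaX* slippery sequence.

## The problem and who this is for

On the *dnaX* frameshift mRNA, three signals — an internal
Shine–Dalgarno (SD) sequence, the A_AAA_AAG slippery sequence and a
downstream hairpin — drive most elongating ribosomes into a long pause
in a rotated conformation, from which they resume translation in the −1
reading frame.  `prfkin` is for modellers and single-molecule
experimentalists who want a quantitative, simulable account of that
pathway: where the pause decision is made, what sets its probability,
how tRNA and EF-G sample the paused ribosome, and what dwell times and
binding statistics a fluorescence or optical-trapping experiment should
see.

## The model

The decision happens at the unlocked pre-translocation state.  One
reverse intersubunit rotation must cross one of three free-energy
barriers, and the outcome probabilities are their Boltzmann weights:
effective translocation (barrier ΔE_SD(3) + 3·E_bp), futile
translocation (barrier E_PE(50S), which recycles), or incomplete +2
translocation into the long-paused state (barrier
ΔE + ΔE_SD(2) + 2·E_bp).  Because futile rounds recycle, the per-codon
pause probability is a logistic function in which the futile barrier
cancels:

    P_LP = exp[−(ΔE − ΔΔE_SD − E_bp)] / (exp[−(ΔE − ΔΔE_SD − E_bp)] + 1)

with all energies in kBT.  Inside the pause, the ternary complex and
EF-G·GTP compete for the open 30S site; codon recognition and
accommodation race against dissociation, giving geometric sampling
numbers, closed-form bound lifetimes and arrival times, and the mean
rotated-state dwells of pausing and non-pausing ribosomes.  Under an
external force F pulling the mRNA, each nucleotide stepped costs F·p of
work (p = 0.34 nm) and the pause probability becomes a logistic in
−(ΔE − F·p); over n tandem slippery sites the total frameshift
efficiency is 1 − (1 − P_LP)^n.

Every closed form is backed by an exact Gillespie simulator over the
declared elongation state networks, which also generates synthetic
single-molecule traces (rotated/non-rotated dwells, labelled-tRNA
pulses, EF-G binding events).

## Worked example

```r
library(prfkin)

# Branch probabilities of the wild-type slippery site
branch_probabilities(dnax_energies("wt"))
#> Single-rotation branch: P_LP(1) = 0.4276  P_E(1) = 0.1424  P_F(1) = 0.4300
#> Per-codon long pause:   P_LP = 0.7503  (P_Nor = 0.2497)
```

Three quarters of ribosomes reaching the slippery codon enter the long
pause; of single rotations, 43% take the incomplete +2 path, 14%
translocate, and the rest are futile.

```r
# From measured aggregates back to the kinetic constants
run_inference_chain(observed_aggregates())
#>           quantity value          units
#> 1          p_e1_sd 0.250    probability
#> 2            p_lp1 0.429    probability
#> 3             p_e1 0.143    probability
#> 4             n2_G 1.750 bindings/codon
#> 5           n_lp_G 4.733 bindings/pause
#> 6              t_G 1.220              s
#> 7            kb1_G 0.410       1/(uM s)
#> 8             kb_G 1.562       1/(uM s)
#> ...
```

The chain recovers, from the published per-codon aggregates alone, the
single-rotation probabilities (0.43/0.14), the EF-G binding numbers
(1.75 canonical per cycle, 4.73 per pause), the 1.22-s EF-G dwell on
the paused ribosome and the two EF-G binding rates (0.41 and
1.56 µM⁻¹s⁻¹).

```r
# Synthetic single-molecule traces and their summary
tr <- generate_synthetic_traces("fig3_wt_slippery", 300, seed = 42)
summarize_trajectories(tr$sim)
#> Trace summary (duplex_slippery, 300 cycles):
#>   p_lp_hat                      0.7 +/- 0.0265  (n = 300)
#>   n_samplings_hat             1.848 +/- 0.0939  (n = 210)
#>   tau_hat                     34.97 +/- 1.66  (n = 388)
#>   t_efg_lp_hat                1.289 +/- 0.0678  (n = 397)
#>   t_rot_lp_hat                  156 +/- 6.98  (n = 210)
#>   t_rot_nl_hat                11.91 +/- 1.13  (n = 90)
#>   ...
```

300 simulated molecules reproduce the pause fraction (0.70 ± 0.03), the
two-sampling tRNA statistics, the ~33-s ternary-complex arrival time at
80 nM EF-G / 200 nM tRNA, the 1.2-s EF-G dwell on the paused ribosome
and the long conditional rotated dwells — each with the Monte-Carlo
standard error a real data set of that size would carry.

`reproduce_all("outdir")` regenerates every report table (pause
probabilities, arrival-time and rotated-lifetime grids, the
force–efficiency surface, the inference chain and a pass/fail
regression table) as CSV.

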