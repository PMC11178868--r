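# dsbflow

Classification and kinetic modeling of CRISPR-Cas9 double-strand break
(DSB) repair from single-molecule amplicon sequencing time courses.

## The problem

Indel frequency after a CRISPR-Cas9 cut is the product of two things that
amplicon sequencing cannot separate: how often the locus is actually cut,
and how often a break is repaired precisely — restoring the original
sequence and leaving no trace. Single-molecule (UMI-consensus) capture
assays that ligate adaptors directly onto broken ends observe the
unrepaired-DSB intermediates alongside intact and indel-bearing molecules
across a sampled time course. `dsbflow` turns those reads into per-category
counts and fits kinetic models that decouple cutting from repair fidelity,
estimating the otherwise invisible precise-repair flux.

**Read classification.** Inside a 100 bp reference window centred on the
expected cut (3 bp upstream of the PAM), 12 bp end indicators call each
consensus read INTACT (both indicators align at ≥10/12), DSB (left
indicator only) or NA (>4 `N`s, or a primer-tailed PCR artifact). Intact
reads are aligned to the reference to name indel footprints (`+AG`,
`-TGTTGCCT`), annotate deletions flanked by ≥2 bp microhomology, and
promote non-WT reads to the NHEJ state. Captured DSB ends are typed by
position: direct (at an expected cut position, including dual-cleavage
targets with both −3 and −4 ends), guide-side (shorter), PAM-side (longer,
reference-matching) or extended (longer, non-reference filler).

**Kinetic models.** Category counts per (time point, replicate) are
multinomial observations of a compartment model driven by a logistic RNP
activity curve `RNP(t) = max(0, (1−U)·2^(−d·t)·logistic(r(t−t₀)) −
(1−[intact]))`, `t₀ = ln(10⁶)/(r+10⁻¹²)`. The 3-state model (intact, indel,
DSB) estimates cutting `K_cut`, precise repair `P`, error repair `E`, and a
processed-DSB observation probability `e`; the 4-state model adds a
processed-DSB pool fed at `K_processing` with its own repair rates.
Fitting is exact-multinomial maximum likelihood with box constraints
(rates ≤ 10/h) and multi-start search (5000 exponential-distributed starts
screened, the best refined by L-BFGS-B). Uncertainty comes from a
stratified bootstrap (resampling molecules within each time point ×
replicate; 1%/99% percentile CIs, one-sided p-values), model choice from
AIC relative likelihood with bootstrap stability, and cumulative flows
(e.g. cutting flow `∫ K_cut·RNP(t) dt`, which may exceed 100% because
precisely repaired molecules are re-cut) from RK4 integration at 500
steps/hour.

**Simulation.** `simulate_counts()` draws multinomial time courses from
either model; `generate_reads()` builds synthetic consensus reads with
planted footprints so the whole pipeline round-trips against known truth.

## Worked example

Simulate a 72 h time course with known rates, refit it, and compute flows:

```r
library(dsbflow)

truth <- rates3(k_cut = 0.02, P = 0.06, E = 0.04, e = 0.1)
ip <- induction_params(U = 0, r = 1e4, d = 0)   # near-step induction
sim <- simulate_counts("3state", truth, ip,
                       times = c(0, 6, 12, 24, 36, 48, 72),
                       n_molecules = 10000, replicates = 2, seed = 42)

fit <- fit_kinetics(sim$counts, "3state", n_starts = 200, n_refine = 10,
                    seed = 1)
fit
#> <dsb_fit> 3state model: loglik = -160.89, AIC = 335.79 (7 parameters)
#>   k_cut          0.0198159
#>   P              0.0586727
#>   E              0.0406605
#>   e              0.100899
#>   U              0.00274271
#>   d              0
#>   r              3229.06

compute_flows("3state", fit$rates, fit$induction, T = 72)
#> <dsb_flows> 3state model, T = 72 h
#>   cutting              0.9979
#>   precise_repair       0.5231
#>   error_repair         0.3625
#>   repair_accuracy      0.5907
```

The refitted rates land within a few percent of the simulated truth
(k_cut 0.0198 vs 0.02, P 0.0587 vs 0.06, E 0.0407 vs 0.04). The flow
report says: over 72 h, cutting events equivalent to ~100% of the molecule
pool occurred (precisely repaired molecules are re-cut, so this can exceed
100%), 52% of the pool was broken and repaired precisely (an event
invisible to endpoint sequencing), and 36% ended as indels; 59% of all
repair events were precise.

Classification runs the same way from a FASTQ and a sample sheet — see the
`classify_molecules()` / `read_sample_sheet()` help pages, or the CLI at
`inst/cli/dsbflow-cli.R` (`classify`, `fit`, `bootstrap`, `flows`,
`compare`, `simulate` subcommands).

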