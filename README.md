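# hdxdigly

Differential hydrogen–deuterium exchange (HDX-MS) analysis and
diGly-remnant ubiquitylation-site quantification, with a forward
simulator that makes every stage testable without instrument data.

## Who this is for

Structural mass spectrometrists and E3-ligase biochemists who compare
backbone-amide deuterium uptake between two conformational states of a
protein complex (for instance a cullin–RING ligase before and after
neddylation) and who quantify which lysines of a substrate carry
ubiquitin from label-free tryptic evidence tables. Everything runs on
long-format CSV centroid tables, PEAKS-style evidence CSVs and FASTA
sequences; no vendor software is needed.

## What it computes

**Deuterium uptake.** For each peptide, state, deuteration time and
technical replicate, uptake is the centroid shift of the deuterated
isotope envelope against the undeuterated control,

D(t) = (m̄_deut(t) − m̄_control) / Δm_D,  Δm_D = m(²H) − m(¹H) ≈ 1.00628 Da.

A single global back-exchange factor *b* is estimated from peptides in
the disordered chain termini, which saturate well before the longest
labelling time: *b* = 1 − mean(D(t_max)/N_amides) over those peptides.
Corrected uptake is D/(1 − *b*), clipped to [0, N_amides], where
N_amides counts backbone amides excluding the peptide's first residue
and prolines. Curves are summarised as mean ± SEM over technical
replicates and fitted (for display) with D(t) = A(1 − e^(−kt)) under
0 ≤ A ≤ N_amides.

**Differential calls.** Peptides pass the usual identification filters
(score ≥ 6.5, ≥ 0.2 products per amino acid, MH⁺ error ≤ 5 ppm,
retention-time SD ≤ 5%, seen in ≥ 2 of 3 runs). For each peptide a
two-way ANOVA (state × time) on replicate uptake plus per-timepoint
two-sample t-tests are run; a peptide is called
increased/decreased when the ANOVA state effect and at least one
timepoint are below α = 0.05, and the calls are projected onto
residues by majority consensus of the covering peptides.

**diGly occupancy.** After trypsin digestion a ubiquitylated lysine
retains a Gly-Gly stub (monoisotopic +114.043 Da, printed 114.04).
Per-lysine occupancy is the area ratio

occ(K) = Σ area(peptides with diGly at K) / Σ area(all peptides covering K),

with acetylated (chemically blocked) lysines counted in the
denominator. diGly positions on ubiquitin itself are mapped through an
in-silico tryptic digest of the canonical 76-residue sequence to
report chain-linkage usage (K6/K11/K27/K29/K33/K48/K63/M1).

**Forward simulator.** Per-residue intrinsic exchange rates
(poly-DL-alanine reference rates with side-chain corrections, pD- and
temperature-dependent) combined with per-state protection factors give
EX2 uptake 1 − e^(−k_int t / P); Poisson-binomial deuteration of the
natural isotope envelope, a global back-exchange loss and Gaussian
centroid noise produce synthetic centroid tables whose ground truth is
known exactly, plus matched evidence tables for the diGly statistic.

## Worked example

```r
library(hdxdigly)

cfg <- read_system_config(system.file("extdata", "demo_config.yml",
                                      package = "hdxdigly"))
map <- generate_peptide_map(cfg$system$sequence, target_length = 10,
                            overlap = 5)
tab <- simulate_exchange_dataset(cfg$system, map, seed = 42)

raw <- compute_raw_uptake(tab)
(b <- as.numeric(estimate_back_exchange(raw, map)))
#> [1] 0.2502
corr <- correct_uptake_table(raw, b)
res <- compare_states(corr, "apo", "bound")
table(res$verdict)
#>       decreased       increased not-significant
#>               1               6              16
res[res$verdict != "not-significant",
    c("peptide_id", "start", "end", "anova_p", "delta_max", "verdict")]
#>   peptide_id start   end  anova_p delta_max verdict
#> 1 pep_0003      11    20 2.58e- 2   -0.0562 decreased
#> 2 pep_0007      31    40 3.04e- 2    0.0387 increased
#> 3 pep_0011      51    60 1.24e-15    0.390  increased
#> 4 pep_0012      56    65 1.29e-38    2.44   increased
#> 5 pep_0013      61    70 6.38e-45    3.36   increased
#> 6 pep_0014      66    75 4.44e-39    4.45   increased
#> 7 pep_0015      71    80 2.46e-32    1.79   increased
```

The demo ground truth destabilises residues 60–75 of a 120-residue
protein (protection factor lowered tenfold) in the `bound` state. The
estimator recovers the simulated 25% back exchange (0.2502), and the
contiguous block of increased-exchange peptides (51–80, Δuptake up to
4.5 deuterons at p ≈ 10⁻⁴⁵) brackets the true region to within one
peptide overhang. The two isolated calls with |Δ| < 0.06 deuterons are
the false positives expected of an uncorrected α = 0.05 rule over 23
peptides — region interpretation should rest on contiguous blocks with
material effect sizes (see the methods vignette).

Occupancy from the shipped synthetic evidence table (true occupancies
0.6 / 0.2 / 0.2 / 0.6):

```r
prot <- as.character(read_fasta(system.file(
  "extdata", "demo_substrate_synthetic.fasta", package = "hdxdigly"))[[1]])
ev <- read_evidence(system.file("extdata", "demo_evidence_synthetic.csv",
                                package = "hdxdigly"))
subset(site_occupancy(filter_evidence(ev), prot), covered)
#>   position occupancy n_evidence
#> 1       45     0.641         50
#> 2      101     0.205         50
#> 3      107     0.209         50
#> 4      381     0.605         50
```

The same workflow is scriptable from a shell via the `exec/hdxdigly`
wrapper (`simulate`, `uptake`, `compare`, `digly`, `plot`
subcommands); see `?cli`.

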