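# spirorate

Tip-dated substitution-rate estimation and genome-degradation analysis for
serially sampled bacterial endosymbiont genomes.

Inherited endosymbionts such as *Spiroplasma* can be re-sequenced from the
same laboratory host line or axenic culture years apart. Because the
sampling dates are known, the changes between isolates give a direct
estimate of the molecular clock:

    r = k / (L · t)

with *k* the observed changes at third codon positions, *L* the considered
third codon positions, and *t* the elapsed years. `spirorate` implements
this estimator with conservative filtering — per-library coverage masks
(depth ≥ 5 by default) intersected across libraries, CDSs kept only when
*entirely* covered in every library, variants kept only on fully masked
spans — plus variant-effect classification under the Mollicutes genetic code
(translation table 4, TGA = Trp), strand-collapsed substitution spectra
(GC→AT bias), and comparative degradation metrics: the ≤60 % orthologue
truncation (pseudogenization) rule, coding density, a 60 %-identity /
50 %-coverage prophage-gene rule, greedy best-first syntenic blocks
(≥1000 bp, ≥95 % identity) with per-kb CDS-density differentials, and
divergence-time arithmetic t = d/(2r).

A synthetic genome-evolution generator (`simulate_dataset()`,
`cmd_simulate()`) produces annotated AT-rich genomes, evolved isolates with
every true variant recorded, depth tracks with contiguous dropouts,
rearranged genome pairs with exact block ground truth, and orthogroup tables
with known truncations — so the whole pipeline is testable without any
external data.

## Worked example

Simulate a 200 kb genome with 160 CDSs evolving at 2×10⁻⁵ substitutions per
third position per year for 10 years, then run the rate analysis on the
written fixture files:

```r
library(spirorate)

cfg <- simulation_config(genome_length = 200000L, n_cds = 160L,
                         rate_per_site_per_year = 2e-5, years = 10,
                         n_libraries = 2L, seed = 5L)
cmd_simulate(cfg, "demo")

res <- cmd_rate(list(
  reference_fasta = "demo/reference.fasta",
  reference_gff3  = "demo/reference.gff3",
  comparisons = list(list(id = "evolved",
                          vcf = "demo/evolved.vcf",
                          depth = list("demo/depth_lib01.tsv",
                                       "demo/depth_lib02.tsv"),
                          years = 10))),
  out_dir = "demo/rate-out")
res$rates
#>   comparison_id k_changes L_sites t_years         rate
#> 1       evolved         9   41330      10 2.177595e-05
```

Nine third-position changes were observed over 41 330 considered
third-position sites (CDSs fully covered at ≥5× in both libraries,
intersected with the mask) in 10 years: an estimated rate of 2.18×10⁻⁵ per
site per year, within Poisson error of the simulated 2×10⁻⁵ (E[k] ≈ 8.3,
sd ≈ 2.9). The accompanying `report.json` shows 30 of the 31 called variants
surviving the all-libraries coverage mask (17 nonsynonymous, 5 synonymous,
8 intergenic) and a GC→AT spectrum fraction of 0.433 — the configured bias
is 0.6, and at n = 30 substitutions the multinomial noise is about ±0.09.

The degradation command compares the reference against its rearranged,
CDS-eroded partner genome:

```r
deg <- cmd_degradation(list(
  genome_a_fasta = "demo/reference.fasta",
  genome_a_gff3  = "demo/reference.gff3",
  genome_b_fasta = "demo/genome_b.fasta",
  genome_b_gff3  = "demo/genome_b.gff3",
  hits_tsv       = "demo/hits.tsv",
  orthogroups_tsv = "demo/orthogroups.tsv"),
  out_dir = "demo/degr-out")
deg$block_summary
#> $n_blocks   [1] 17
#> $n_fewer_a  [1] 0
#> $n_more_a   [1] 11
#> $n_equal    [1] 6
#> ...
```

All 17 ground-truth syntenic blocks are recovered; 11 contain more CDSs in
genome A than in B (and none fewer), reflecting the CDSs lost at
rearrangement breakpoints in B — the same per-block CDS-density differential
used to quantify relative genome deterioration. Coding densities come out at
71.3 % (A) vs 65.5 % (B), and 30 of 600 truncation calls are flagged at the
≤60 % rule, exactly the simulator's eroded set.

## Command-line use

A thin wrapper over the same functions is installed at `exec/spirorate`:

```sh
spirorate simulate    --config sim.yaml  --out fixtures/
spirorate rate        --config rate.yaml --out rate-out/ --min-depth 5
spirorate degradation --config degr.yaml --out degr-out/
```

Configs are flat YAML; every threshold (minimum depth, genetic code,
truncation ratio, synteny and prophage cut-offs, denominator choice,
divergence formula) is overridable and echoed into each run's
`manifest.json` alongside input checksums and record counts.
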