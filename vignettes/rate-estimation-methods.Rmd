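---
title: "Methods: substitution rates and genome degradation in endosymbionts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: substitution rates and genome degradation in endosymbionts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spirorate)
```

## The problem

Maternally inherited bacterial endosymbionts such as *Spiroplasma* can be
re-sequenced repeatedly from laboratory host lines or axenic cultures over a
span of years. Because the sampling dates are known, the accumulation of
substitutions between serially sampled isolates yields a direct, tip-dated
estimate of the molecular clock — no phylogenetic rate model is needed. The
same genome pairs also record genome *degradation*: pseudogenized
orthologues, falling coding density, decaying prophage regions, and
rearrangement-scrambled synteny. `spirorate` implements both analyses as a
tested pipeline over standard file formats (FASTA, GFF3, VCF,
samtools-depth TSV, BLAST outfmt-6 TSV, orthogroup TSV), plus a synthetic
genome-evolution generator that provides full ground truth for every stage.

## The rate model

For one isolate compared against the reference it descends from, the
substitution rate is

$$ r = \frac{k}{L \cdot t}, $$

where \(k\) is the number of observed changes at third codon positions,
\(L\) the number of *considered* third codon positions, and \(t\) the
elapsed time in years. Third positions are used because most changes there
are synonymous, so \(r\) approximates the neutral (mutation-limited) rate.
No multiple-hit correction is applied: in the regimes this package targets
(\(r t \le 10^{-4}\) per site) saturation is negligible, and back mutations
remain a caveat rather than a correction.

Counting is deliberately conservative:

* **Coverage mask.** Per sequencing library, only positions with depth at
  least `min_depth` (default 5) are trusted; the per-library masks are
  intersected, so a position counts only if *every* library covers it.
* **CDS filter.** A CDS enters the analysis only if *entirely* covered by
  the intersection mask — a single uncovered base disqualifies it, so that a
  partially sequenced gene can never contribute a spurious zero.
* **Variant filter.** A variant is kept only if every reference base it
  spans is masked in.
* **Numerator.** SNPs at third positions of retained CDSs count 1;
  multi-nucleotide substitutions of equal length are decomposed base by base;
  indels and length-changing complex records count 0, because "a change at a
  third codon position" is only well defined for substitutions.
* **Denominator.** Third positions of retained CDSs intersected with the
  mask (default), or all third positions of retained CDSs
  (`denominator = "all-third"`). Both are exposed because the two readings
  differ only through the mask, and the intersection is the self-consistent
  choice: the numerator can only see masked positions.

Positions claimed by two overlapping CDSs have no unique codon position and
are excluded from numerator and denominator alike, as are CDSs whose length
minus phase is not a multiple of 3 (their frame is undefined; such records
are typically annotation artefacts or pseudogenes).

Elapsed time \(t\) is supplied per comparison, either directly in decimal
years or as two ISO dates (converted at 365.25 d/yr). For lineages that
split before either was sampled, the natural \(t\) is the sum of both branch
lengths since the split; since published timelines are often ambiguous on
this point, the package never infers \(t\) — the configuration states it
explicitly.

## Effect classification and the substitution spectrum

Variant effects are classified under a configurable NCBI genetic code,
default table 4 (the Mollicutes code: TGA encodes tryptophan). Coding SNPs
become `synonymous`/`nonsynonymous` by codon translation; MNPs confined to
one codon are judged on the whole-codon amino-acid change; in-CDS indels are
`frameshift` when the net length change is not a multiple of 3, otherwise
`inframe_indel`; variants outside CDSs are `intergenic`; anything
unresolvable (ambiguous frame, codons containing N, multi-codon MNPs,
length-changing complex records) is `complex`. The test suite checks all
576 single-nucleotide codon changes against an independent, literal codon
table.

Single-nucleotide substitutions are also binned into six strand-collapsed
classes (GC→AT, GC→TA, GC→CG, AT→GC, AT→TA, AT→CG; e.g. G→A and C→T are the
same class). The GC→AT fraction summarises the AT-ward mutational bias
typical of host-restricted bacteria.

## Degradation metrics

* **Truncation rule.** Within an orthogroup shared by two strains, a strain
  is flagged as carrying a likely pseudogenized/truncated gene when its
  longest member spans at most 60 % (`truncation_ratio`) of the other
  strain's longest member. Exactly 60 % is flagged ("at most"); the longest
  member is the conservative reading of "the CDS length from the other
  strain".
* **Coding density.** 100 × |union of CDS intervals| / genome length;
  overlaps count once.
* **Prophage rule.** A gene is "prophage related" if any protein hit against
  a viral-protein set is at least 60 % identical over at least 50 % of the
  viral protein's length; both thresholds are inclusive.
* **Synteny blocks.** Nucleotide hits shorter than 1000 bp or under 95 %
  identity are discarded (hits *at* either bound survive); survivors are
  taken greedily best-first by bitscore (ties: longer alignment, then
  subject coordinates), and a hit is kept only if its interval on genome A
  overlaps no previously kept interval — one best match per region. The
  legend-style rule names an outcome, not an algorithm; greedy best-first
  with zero overlap tolerance is the deterministic choice, and ground-truth
  recovery on simulated rearrangements confirms it reconstructs the true
  block set exactly when hits are noise-free.
* **Block density.** CDSs belong to a block when their midpoint falls inside
  it (midpoints avoid double-counting genes straddling block edges); density
  is CDS count per kb, and blocks are partitioned by the sign of the A−B
  count difference.
* **Divergence time.** \(t = d / (2r)\) by default (two lineages
  accumulating changes independently); \(t = d/r\) is available as
  `formula = "d-over-r"`. The divergence measure \(d\) is an explicit
  argument — all-site and third-position divergences are both legitimate,
  and the choice belongs to the caller.

## The synthetic generator

`simulation_config()` fixes the study conditions; the defaults are the
conditions under which the package's claims are tested:

| parameter | default | why |
|---|---|---|
| `genome_length`, `n_cds` | 1 Mb, 800 | a small endosymbiont chromosome at ~72 % coding |
| `gc_content` | 0.27 | AT-rich, as host-restricted Mollicutes genomes are |
| `cds_length_range` | 300–1500 bp | typical bacterial CDS lengths, multiples of 3 |
| `rate_per_site_per_year` | 1e-5 | a fast, hypermutator-like clock |
| `years` | 10 | a decade-scale resequencing interval |
| `nonthird_rate_fraction` | 0.5 | first/second positions and intergenic sites evolve slower |
| `spectrum_weights` | 0.60 GC→AT, …| GC→AT-dominated mutational bias |
| `mean_depth`, `n_libraries` | 20×, 3 | routine Illumina resequencing |
| `dropout_fraction` | 0.05 | contiguous zero-coverage segments |
| `n_inversions`, `n_translocations` | 5, 2 | enough rearrangement to scramble synteny |

Design points worth recording:

* **Spectrum vs composition.** A per-site i.i.d. mutation model cannot make
  the realized class distribution equal the configured spectrum on an
  AT-rich genome (only 27 % of sites can source a GC→AT change). The
  generator therefore draws the number of mutations binomially per site
  category (so E[third-position changes] = \(r t L_3\) exactly), draws
  classes multinomially from `spectrum_weights`, and places each mutation
  uniformly on a base-compatible site. GC sites consequently mutate faster
  per site — which is precisely what a GC→AT-biased process does.
* **Single hit.** At most one mutation per site; valid because
  \(rt \le 10^{-4}\) in all target regimes.
* **Dropout is contiguous**, not i.i.d., so the "entirely covered CDS"
  filter is exercised by realistic coverage holes.
* **Rearrangements** are tracked as an ordered fragment list; the fragment
  list at the end *is* the ground-truth block set, so recovery checks are
  exact, not approximate. Breakpoints are resampled until every fragment is
  at least `min_block_bp` (default 5 kb), keeping all true blocks above the
  synteny length filter.
* **Seeds.** One user seed; each generator stage seeds its RNG at a fixed
  documented offset (+0 genome, +1 evolution, +2 depth, +3 rearrangement,
  +4 orthogroups), so stages are reproducible independently and in
  combination.

What the generator does *not* emulate: sequencing error, read-level
artefacts, indel evolution, selection (dN/dS structure), recombination, and
real mutational context effects. Passing tests therefore demonstrate that
the *estimator* is correct under its stated model, not that real libraries
are free of calling artefacts — on real data the coverage mask and the
caller upstream carry that burden.

## Numerical and policy choices

* Coordinates are 1-based inclusive throughout (the native
  IRanges/Biostrings convention); GFF3 and VCF already use it, so no
  conversions cross the package boundary.
* IUPAC ambiguity codes are mapped to N on read and excluded from all
  denominators; codons containing N classify as `complex`.
* Multi-allelic VCF rows are split per ALT allele, each record counting
  independently; symbolic alleles are skipped with a warning.
* Ties in the synteny greedy order are broken by longer alignment, then
  subject coordinates, so results are permutation-invariant.
* Problem sizes in the test suite (1 Mb × 100 replicate seeds for rate
  recovery; 150–300 kb for bias and spectrum checks) were chosen so the
  Poisson/multinomial tolerances are informative while the whole suite runs
  in a few minutes.

## Known limitations

* Rates are raw observed-change rates; over century scales saturation and
  back mutation would bias them downward.
* The truncation rule compares longest members only; paralogue-rich
  orthogroups with mixed erosion are summarised coarsely.
* Synteny blocks come from single best-hit intervals; duplicated regions on
  genome B may attract multiple A intervals (only A-side uniqueness is
  enforced, matching the one-best-match-per-region rule).
* `estimate_divergence_time` assumes rate constancy on both lineages and is
  only as good as the divergence measure supplied.
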