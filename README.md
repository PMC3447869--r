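# founderdrift

How much genetic diversity does a population keep when it is founded by a
handful of animals?  `founderdrift` studies this question for the textbook
case of the Finnish white-tailed deer (*Odocoileus virginianus*):
introduced in 1934 as three females and one male, completely isolated
since, and today numbering tens of thousands.  The package provides

* a forward-time, **individual-based simulator** of the introduction:
  overlapping generations, age-structured survival and fecundity, random
  mate choice, and Mendelian transmission of 14 unlinked microsatellite
  loci, with the documented 1934–1938 establishment years scripted from
  the historical record;
* **founder-scenario constructors**: maximal founder heterozygosity (A1),
  minimal heterozygosity given the observed allele counts (A2, founder
  H = 0.39), maximal allelic richness (B, 8 alleles per locus), and a
  putative successful second introduction of four novel-allele
  heterozygotes in 1949 (C);
* the **empirical diversity statistics** the simulation is judged
  against: Nei's unbiased expected heterozygosity
  ĥ = n/(n−1)·(1 − Σᵢ pᵢ²), observed heterozygosity, allelic richness,
  over-loci summaries, and a tie-corrected one-tailed Mann–Whitney
  comparison of per-locus diversity between two populations;
* the **classic-theory comparator** Hₜ = H₀·Πᵢ(1 − 1/(2Nₑᵢ)), whose
  prediction is linear in the (unknown) founder heterozygosity — the
  contrast that motivates the individual-based approach;
* **Genepop and wide-CSV** genotype input/output and a Hardy–Weinberg
  genotype sampler, so every statistic is testable on synthetic data.

## Worked example

```r
library(founderdrift)

## the published per-locus summaries of both populations
fin <- summarize_population(published_diversity("finland"))
fin
#> Diversity over 14 loci: mean A_R = 5.36, mean H_E = 0.692

okl <- published_diversity("oklahoma")
mann_whitney_one_tailed(published_diversity("finland")$allele_count,
                        okl$allele_count)
#> $Z
#> [1] -2.56488
#> $p_one_tailed
#> [1] 0.005160582

## minimal founder heterozygosity given the observed allele counts
min_founder_heterozygosity(finland_allelic_richness(), 4)
#> [1] 0.3928571

## simulate founding scenario A1 (maximal founder heterozygosity)
sim <- run_scenario("A1", n_replicates = 200, seed = 1)
sim
#> Scenario A1: 200 replicates (7 extinct, excluded)
#>   final H  = 0.636 (0.505-0.727)
#>   final AR = 4.48 (2.91-5.36)
#>   final N: mean 9560 after 45 steps
plot(sim)   # trajectory with 95% band over the census record

## classic theory: linear in H0, here with ~75% retention over 45 years
sched <- example_ne_schedule()
0.742 * retention(sched)   # source-population H0
#> [1] 0.5564992
0.39 * retention(sched)    # minimal founder H0
#> [1] 0.2924996
```

The simulated final heterozygosity (~0.63) sits close to the observed
0.679/0.692 and far above the classic-theory prediction for a
low-heterozygosity founder group — the central point: with overlapping
generations and rapid growth, final heterozygosity is nearly independent
of founder heterozygosity, so a four-animal founding is compatible with
the diversity seen today.

`reproduce_study("out/", replicates = 1000, seed = 1)` runs all four
scenarios and writes the scenario table, the two-population comparison,
the classic-theory contrast, and a run manifest with content digests.

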