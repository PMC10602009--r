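# loxcross

Transmission genetics for dual-marker Cre-Lox transgenes: exact cross
enumeration, seeded breeding simulation, and the estimators used on progeny
score tables.

## What problem this solves

In model organisms without balancer chromosomes, homozygosing and
maintaining transgenic lines means genotyping progeny generation after
generation. Dual-marker Cre-Lox constructs solve this phenotypically: a
construct carries two eye-specific fluorescent transformation markers (e.g.
mCe and mVe) between interweaved LoxP/LoxN pairs; germline Cre excises
exactly one marker, leaving two distinguishable single-marker "flavors" of
the same insertion. Crossing the flavors makes hemizygotes,
trans-heterozygotes and homozygotes all visibly different at the steps that
matter, so whole breeding schemes run on eye color alone.

`loxcross` is for geneticists designing or analysing such schemes. It
computes:

* **Exact progeny distributions** for any cross of genotypes built from
  such constructs — germline Cre excision with bias β and completeness c,
  two-point linkage at recombination fraction r (1 cM = 1% recombinants),
  independent assortment, X/Y segregation, homozygous lethality with
  survivor renormalization.
* **Whole mating procedures in silico** — the single-transgene F3→F7 scheme
  (helper cross, excision cross, flavor intercross, homozygosing sibling
  cross) and the double-transgene F7→F10 scheme (including the linked and
  the X-allosome special cases), with phenotype-only selection and
  step-labelled abort logic.
* **Estimators on score tables** — two-point genetic linkage in cM
  (maximum-parsimony recombinant counting, mean ± sample SD over
  repetitions), Cre excision bias (first:second ratio and β̂),
  insert-number (≤ 60% rule) and homozygous-viability (> 70.8% rule)
  classification, and one-sample two-tailed t-tests of observed versus
  theoretical Mendelian ratios.
* **Synthetic study fixtures** — reproducible multi-subline,
  multi-generation score tables with recorded ground truth.

## Worked example

Theoretical ratios of the F6 heterozygous sibling cross — the cross that
produces both homozygous flavors:

```r
library(loxcross)
su <- setup_acos_fire()
expected_ratio_table(acos_cross(su, "F6"))
#>   cross_id   class theoretical_percent granularity prob genotype_classes
#> 2       F6 mCe,mVe                  50   phenotype 0.50    ACOS(mCe/mVe)
#> 1       F6     mCe                  25   phenotype 0.25    ACOS(mCe/mCe)
#> 3       F6     mVe                  25   phenotype 0.25    ACOS(mVe/mVe)
```

Half the progeny show both markers (trans-heterozygotes), a quarter each
show only mCe or only mVe — and those are guaranteed homozygotes, because
every gamete of a heterozygous parent carries one flavor or the other.

Two-point linkage from three repetitions of recombinant/total gamete
counts (the counts scored for two transgenes 2.17 Mbp apart on the same
chromosome):

```r
estimate_linkage(data.frame(recombinant = c(98, 96, 147),
                            total = c(1248, 1171, 1651)))
#> <linkage estimate> 8.32 cM ± 0.54 cM  (3 repetitions)
```

A full single-transgene procedure, simulated with 200 conceived progeny
per cross:

```r
res <- run_acos_procedure(su$genome, su$acos, su$helper, lx_params(),
                          n_per_cross = 200, seed = 42)
res
#> <lx_procedure_result> scheme: acos, status: completed
#>   crosses executed: F3, F4, F5, F6
#>   cultures established:
#>     first: ACOS(mCe/mCe)
#>     second: ACOS(mVe/mVe)
```

With a homozygous-lethal construct the same call returns
`status: aborted` at step F7 ("lack of suitable progeny": the homozygote
selection finds only lethal classes).

## Command line

A thin wrapper (`exec/loxcross`, or `loxcross::cli()` from R) exposes
`enumerate`, `simulate`, `run-procedure`, `estimate-linkage`, `classify`,
`ratio-test` and `make-fixture`, all reproducible under `--seed`. Example
configurations live in `inst/extdata/`, next to a small committed example
fixture (`example_fixture/`, three sublines at 50 progeny per cross, with
completed and aborted runs recorded in its `truth.json`).

```sh
loxcross enumerate --config inst/extdata/f6_cross.yaml
loxcross estimate-linkage --counts '98/1248;96/1171;147/1651'
```

## Package layout

* `R/genome.R`, `R/genotype.R` — genome/construct definitions, genotypes,
  zygosity, phenotypes and class labels
* `R/meiosis.R` — Cre excision model and gamete distributions
* `R/cross.R` — progeny enumeration, ratio tables, phenotype resolution
* `R/sim.R` — stochastic sampling and the two mating procedures
* `R/estimators.R` — linkage, bias, classification, ratio tests
* `R/synthetic.R` — fixture and linkage-experiment generators
* `R/io.R`, `R/cli.R` — TSV/YAML I/O and the CLI
* `vignettes/transgene-transmission.Rmd` — the methods vignette

## License

MIT
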