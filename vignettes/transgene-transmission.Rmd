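---
title: "Transmission genetics of dual-marker Cre-Lox transgenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transmission genetics of dual-marker Cre-Lox transgenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loxcross)
```

## The problem

Maintaining transgenic lines in organisms without balancer chromosomes
(most non-drosophilid insects, for instance the red flour beetle) requires
repeated genotyping across generations. Dual-marker Cre-Lox constructs make
every genotype of a breeding scheme readable from eye-marker phenotypes
alone: a construct carries two eye-specific fluorescent transformation
markers between interweaved LoxP/LoxN site pairs, germline Cre excises
exactly one of them, and from then on the two single-marker "flavors" of
the same insertion are phenotypically distinguishable alleles. Crossing the
two flavors lets hemizygotes, trans-heterozygotes and homozygotes all look
different at the right steps of a mating scheme.

`loxcross` implements the transmission genetics behind such schemes:

* an **exact cross-enumeration engine** — the oracle for every theoretical
  progeny ratio;
* a **seeded stochastic breeding simulator** that runs the complete
  single-transgene (F3–F7) and double-transgene (F7–F10) mating procedures
  with phenotype-only selection and abort logic;
* the **estimators** used on progeny score tables: two-point linkage in
  centimorgan, Cre excision bias, insert-number and homozygous-viability
  classification, and one-sample t-tests of observed against theoretical
  segregation ratios;
* a **synthetic-data generator** that emulates multi-subline,
  multi-generation raw-score tables with known ground truth.

## The transmission model

An individual is a sex (XX or XY) plus, per chromosome, an ordered pair of
haplotypes carrying transgene alleles at fixed insertion loci (1-based TTAA
coordinates). Gamete formation composes three mechanisms, in this order:

1. **Germline Cre excision.** Each dual-marker (`DUAL_PRE`) allele in a
   Cre-carrying germline resolves independently to `FIRST_ONLY` with
   probability $c\beta$, to `SECOND_ONLY` with $c(1-\beta)$, and stays
   `DUAL_PRE` with $1-c$, where $\beta \in [0,1]$ is the excision bias and
   $c \in [0,1]$ the completeness. Single-marker states are absorbing: the
   remaining LoxP and LoxN sites are incompatible, so no second excision
   can occur.
2. **Two-point meiosis.** For two loci on one chromosome with recombination
   fraction $r$, the four gamete classes have probabilities $(1-r)/2$,
   $(1-r)/2$ (parental) and $r/2$, $r/2$ (recombinant). Map distance is
   identified with recombination percentage ($1\,\mathrm{cM} = 1\%$
   recombinant gametes, capped at $r = 0.5$); no Haldane or Kosambi map
   function is applied because the schemes score recombination frequency
   directly over a short interval. At most two transgene loci per
   chromosome are supported — sufficient for every cross the schemes use —
   and crossover interference is not modeled.
3. **Assortment and sex linkage.** Chromosomes assort independently; an XY
   parent emits X- and Y-bearing gametes with probability 1/2, the Y
   carrying no loci. X-linked transgenes therefore pass from father to
   daughters only.

A cross is the outer product of the two parental gamete distributions,
fused into diploid genotype classes. Classes are canonicalized ignoring
parental origin *except* where cis/trans arrangement differs — a cis
[mO,mCe]/[mC,mVe] individual is a different class from the trans
arrangements, which matters for recombination accounting — and a
coarser "flavor" granularity collapses arrangement and reports only the
marker-flavor content per locus (the granularity at which the unlinked
double-hemizygote cross has sixteen classes of 6.25% each).

**Lethality.** A construct may be flagged homozygous lethal; classes
carrying two same-state doses of it get probability zero and the survivors
renormalize. The trans two-flavor heterozygote is *not* treated as
homozygous — the scheme's vocabulary reserves "homozygous" for two alleles
of the same state — so a lethal construct still yields viable F6
heterozygotes and the procedure aborts only at the F7 homozygote
selection. This is the semantics under which the survivor marker fraction
of a hemizygote sibling cross is 3/4 for a viable and 2/3 for a lethal
construct.

```{r ratios}
su <- setup_acos_fire()
expected_ratio_table(acos_cross(su, "F6"))

lethal <- setup_acos_fire(homozygous_lethal = TRUE)
phenotype_distribution(hemizygote_sibling_cross(lethal$genome, "ACOS"),
                       apply_lethality = TRUE)
```

## Phenotype-only genotyping

Phenotypes are visible marker sets; a `DUAL_PRE` allele co-occurring with a
Cre source is additionally annotated mosaic (somatic excision gives patchy
expression), but mosaic markers stay visible and do not form a separate
detection channel. Some genotypes are indistinguishable in isolation — a
hemizygote and a homozygote of the same flavor — so `resolve_genotypes()`
always works inside a cross context: it returns exactly the progeny classes
of positive survivor probability whose visible set equals the observation.
The breeding simulator's selections use only (sex, phenotype, cross
context) and require the resolution to be unique at flavor granularity; a
completed run therefore certifies end-to-end unambiguous genotyping, and
the round-trip property (every enumerated class is contained in the
resolution of its own phenotype) is tested over all canonical crosses.

## The two mating procedures

`run_acos_procedure()` executes F3–F7: pre-recombination hemizygous female
× X-linked Cre-helper male; double-hemizygous female × wild-type male
(germline excision splits the construct); first-flavor female ×
second-flavor male sibling; trans-heterozygous siblings inter se, from
which both homozygous flavors are established. `run_agoc_acos_procedure()`
executes F7–F10 for two constructs, switching automatically to the
X-allosome variant (reciprocal F8 crosses, hemi-heterozygous males,
hemi-homozygous F10 males) when the first construct is X-linked. Both
return per-cross score tables and either `completed` with the established
cultures or `aborted` naming the first generation whose required
individuals were missing.

```{r procedure}
res <- run_acos_procedure(su$genome, su$acos, su$helper, lx_params(),
                          n_per_cross = 200, seed = 42)
res$status
unlist(res$cultures)
```

Selection takes one individual of the required class per target, sampled
proportionally to the sampled class counts when several cis/trans
arrangements share the observable flavor; culture-establishing selections
(F7, F10) require one individual of each sex per flavor, since a
continuative culture needs a breeding pair. Backup pairs are an
experimental redundancy, not a distributional feature, and are not
modeled.

## Estimators

**Linkage.** For a two-locus cross with known parental arrangements, each
scored progeny contributes two gametes; `count_recombinant_gametes()`
assigns the *minimum* number of recombinant gametes over all compatible
parental gamete pairs (maximum parsimony), flagging the ambiguous
double-heterozygote class, whose parsimonious count is 0 although a
double-recombinant origin is possible. Parsimony is the only scheme
consistent with integer per-progeny scoring when the ambiguity cannot be
observed; it biases the estimate downward by at most $100 \cdot r^2/2$ cM
(the double-recombinant mass assigned zero), which the tests assert. The
per-repetition recombinant fraction, its mean ×100 and sample standard
deviation give the linkage estimate:

```{r linkage}
estimate_linkage(data.frame(recombinant = c(98, 96, 147),
                            total = c(1248, 1171, 1651)))
```

**Cre bias.** From first-flavor and second-flavor post-recombination
counts, `estimate_cre_bias()` reports the first:second ratio and
$\hat\beta$. The default $\beta = 0.5$ encodes the theoretical expectation
that interweaved Lox pairs of similar spacing recombine equally often;
empirically a strong bias (around 5:1) can occur, and the recovery tests
exercise $\beta = 5/6$.

**Classification.** Insert number: a marker distribution of at most 60%
in a hemizygote × wild-type cross is called a single insertion (one insert
transmits to 50%, $k$ unlinked inserts to $1 - 2^{-k}$). Viability: the
threshold is the midpoint of the viable (75%) and lethal (66.7%)
expectations, stored as the exact value $(0.75 + 0.667)/2 = 0.7085$ (the
conventional display rounds it to 70.8%); fractions strictly above it are
called viable.

**Ratio tests.** `t_test_vs_theoretical()` wraps the one-sample two-tailed
Student's t-test of per-repetition observed fractions against the
theoretical ratio, reporting t, df $= n-1$, p and conventional
significance stars; it refuses $n < 2$ or zero variance. No
multiple-testing correction is applied.

## Synthetic data: what it does and does not emulate

`generate_study_fixture()` runs the configured procedure per subline and
repetition, emitting score tables shaped like a per-subline,
per-generation raw-score spreadsheet plus truth metadata (every parameter
and derived seed); regeneration is byte-identical.
`generate_linkage_experiment()` produces repetitions of the linked F9-type
sibling cross (parents carrying the two transgenes in cis, the arrangement
the double-recombinant F8 selection produces) for end-to-end linkage
recovery.

The generator emulates Mendelian segregation, Cre excision stochastics,
two-point linkage, X linkage and homozygous lethality under multinomial
sampling with per-cross brood sizes. It does not emulate scorer error,
stage-dependent marker visibility, brood-size variation, fitness effects
other than binary lethality, segregation distortion, or recombination-rate
differences between strains and sexes. Passing recovery tests therefore
show correctness of the inference under the stated transmission model, not
robustness to those real-data effects.

## Numerical and design choices

* Probabilities are exact rational arithmetic in double precision;
  distribution invariants are checked to $10^{-12}$. Percent reports round
  half-even to two decimals while retaining raw probabilities.
* One RNG stream per procedure run, seeded explicitly; child crosses draw
  in execution order, so whole procedures are bitwise reproducible. Seeds
  derived for fixture runs stay below $2^{31}$.
* Default brood sizes: 200 conceived per cross for the single-transgene
  scheme, 400 for the double-transgene scheme (per-cross totals in such
  studies run to a few hundred). With tight linkage (8.31 cM) the F9
  double-recombinant selection has expectation $n(r/2)^2 \approx 0.0017n$,
  so realistic broods abort — reproducing the practical difficulty of the
  linked case rather than hiding it.
* Test problem sizes: chi-square agreement uses $10^5$ draws over seeds
  0–9 per canonical cross and a single-seed $10^6$-draw total-variation
  check; linkage recovery uses 3 repetitions × 700–1000 progeny at
  $r \in \{0.02, 0.0831, 0.2\}$; bias recovery uses $10^4$ F4 progeny.
* The single-transgene procedure requires the dual-marker construct on an
  autosome (the helper occupies the X); the double-transgene procedure
  requires the second construct autosomal, the first free to be X-linked.
* Coordinates are 1-based inclusive throughout; physical distances report
  in Mbp to two decimals (`locus_distance_mbp(8613308, 10781551)` is
  `r locus_distance_mbp(8613308, 10781551)`).

## Known limitations

Two-point model only (no three-locus chromosomes, no interference); binary
lethality (no partial fitness costs); no maternal effects; eye markers
only (expression-cassette fluorophores are ignored for genotyping);
mosaicism carried as an annotation rather than a detection channel; the
probabilistic (EM-style) alternative to parsimony recombination scoring is
out of scope.
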