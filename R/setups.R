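# Canonical breeding setups and stage crosses --------------------------------

#' Single dual-marker construct plus X-linked Cre helper
#'
#' The standard single-transgene configuration: an autosomal excisable
#' construct carrying mCe/mVe (the homozygosing target) and an X-linked
#' fixed-marker helper carrying mC and expressing Cre in the germline.
#'
#' @param homozygous_lethal Is the dual-marker construct homozygous lethal?
#' @param chromosome Autosome carrying the construct.
#' @param position 1-based TTAA coordinate of the construct.
#' @return List with `genome`, `acos` and `helper` construct ids.
#' @export
setup_acos_fire <- function(homozygous_lethal = FALSE, chromosome = "ChLG2",
                            position = 5e6) {
  genome <- lx_genome(
    list(lx_chromosome(chromosome, "autosome"),
         lx_chromosome("ChLGX", "X")),
    list(lx_construct("ACOS", chromosome, position, c("mCe", "mVe"),
                      homozygous_lethal = homozygous_lethal),
         lx_construct("FIRE", "ChLGX", 1e6, "mC", expresses_cre = TRUE)))
  list(genome = genome, acos = "ACOS", helper = "FIRE")
}

#' Two post-recombination constructs for the double-transgene scheme
#'
#' An mO/mC construct (AGOC) and an mCe/mVe construct (ACOS), used in their
#' single-marker post-recombination states. The default puts them on
#' different autosomes (independent assortment); placing both on the same
#' chromosome gives the linked special case (set the recombination fraction
#' via `linkage_cM`), and `agoc_chromosome = "ChLGX"` gives the X-allosome
#' special case. The linked default uses the two ChLG9 TTAA coordinates
#' 8,613,308 and 10,781,551 (about 2.17 Mbp apart).
#'
#' @param agoc_chromosome Chromosome of the AGOC construct (`"ChLGX"` for
#'   the X-linked case).
#' @param acos_chromosome Chromosome of the ACOS construct (autosome).
#' @param linkage_cM Genetic distance in cM when both constructs share a
#'   chromosome; ignored otherwise.
#' @param homozygous_lethal Length-2 logical: lethality of AGOC and ACOS.
#' @return List with `genome`, `agoc`, `acos` and `params` (a [lx_params()]
#'   carrying the linkage entry when applicable).
#' @export
setup_agoc_acos <- function(agoc_chromosome = "ChLG2",
                            acos_chromosome = "ChLG9",
                            linkage_cM = 8.31,
                            homozygous_lethal = c(FALSE, FALSE)) {
  linked <- identical(agoc_chromosome, acos_chromosome)
  chroms <- list(lx_chromosome("ChLGX", "X"))
  for (ch in unique(c(agoc_chromosome, acos_chromosome)))
    if (ch != "ChLGX") chroms <- c(chroms, list(lx_chromosome(ch, "autosome")))
  agoc_pos <- if (linked) 8613308 else 5e6
  acos_pos <- if (linked) 10781551 else 5e6
  genome <- lx_genome(
    chroms,
    list(lx_construct("AGOC", agoc_chromosome, agoc_pos, c("mO", "mC"),
                      homozygous_lethal = homozygous_lethal[1]),
         lx_construct("ACOS", acos_chromosome, acos_pos, c("mCe", "mVe"),
                      homozygous_lethal = homozygous_lethal[2])))
  linkage <- list()
  if (linked)
    linkage[[acos_chromosome]] <- recombination_fraction(linkage_cM)
  list(genome = genome, agoc = "AGOC", acos = "ACOS",
       params = lx_params(linkage = linkage))
}

#' Canonical crosses of the single-transgene scheme
#'
#' Builds the idealized parents of a stage of the F3-to-F7 procedure (the
#' genotypes the procedure would have selected) and returns the cross:
#' `"F3"` DUAL_PRE hemizygous female x helper male; `"F4"` double-hemizygous
#' female x wild-type male (germline excision happens here); `"F5"`
#' first-flavor female x second-flavor male; `"F6"` trans-heterozygous
#' siblings.
#'
#' @param setup A [setup_acos_fire()] list.
#' @param stage One of `"F3"`, `"F4"`, `"F5"`, `"F6"`.
#' @param params A [lx_params()].
#' @return A [lx_cross()].
#' @export
acos_cross <- function(setup, stage = c("F3", "F4", "F5", "F6"),
                       params = lx_params()) {
  stage <- match.arg(stage)
  g <- setup$genome
  a <- setup$acos
  h <- setup$helper
  al <- function(construct, state, homolog)
    list(construct = construct, state = state, homolog = homolog)
  cross <- switch(stage,
    F3 = lx_cross(g,
                  lx_genotype(g, "XX", list(al(a, "DUAL_PRE", 1))),
                  lx_genotype(g, "XY", list(al(h, "FIXED", 1))),
                  params, id = "F3"),
    F4 = lx_cross(g,
                  lx_genotype(g, "XX", list(al(a, "DUAL_PRE", 1),
                                            al(h, "FIXED", 2))),
                  lx_genotype(g, "XY"), params, id = "F4"),
    F5 = lx_cross(g,
                  lx_genotype(g, "XX", list(al(a, "FIRST_ONLY", 1))),
                  lx_genotype(g, "XY", list(al(a, "SECOND_ONLY", 1))),
                  params, id = "F5"),
    F6 = lx_cross(g,
                  lx_genotype(g, "XX", list(al(a, "FIRST_ONLY", 1),
                                            al(a, "SECOND_ONLY", 2))),
                  lx_genotype(g, "XY", list(al(a, "FIRST_ONLY", 1),
                                            al(a, "SECOND_ONLY", 2))),
                  params, id = "F6"))
  cross
}

#' Canonical crosses of the double-transgene scheme
#'
#' Idealized parents of a stage of the F7-to-F10 procedure (autosomal
#' variant): `"F7a"`/`"F7b"` the parallel single-flavor homozygote crosses;
#' `"F8"` the cross of the two complementary double hemizygotes (for linked
#' loci the transgenes sit in trans, so a double-heterozygous child needs
#' maternal and paternal recombination); `"F9"` the double-heterozygous
#' sibling cross (for linked loci the parents carry the two transgenes in
#' cis, as produced by the double-recombinant F8 selection).
#'
#' @param setup A [setup_agoc_acos()] list (autosomal AGOC).
#' @param stage One of `"F7a"`, `"F7b"`, `"F8"`, `"F9"`.
#' @param params A [lx_params()]; defaults to the setup's params (which
#'   carry the linkage entry for same-chromosome loci).
#' @return A [lx_cross()].
#' @export
agoc_acos_cross <- function(setup, stage = c("F7a", "F7b", "F8", "F9"),
                            params = setup$params) {
  stage <- match.arg(stage)
  g <- setup$genome
  a <- setup$agoc
  cns <- setup$acos
  al <- function(construct, state, homolog)
    list(construct = construct, state = state, homolog = homolog)
  switch(stage,
    F7a = lx_cross(g,
                   lx_genotype(g, "XX", list(al(a, "FIRST_ONLY", 1),
                                             al(a, "FIRST_ONLY", 2))),
                   lx_genotype(g, "XY", list(al(cns, "FIRST_ONLY", 1),
                                             al(cns, "FIRST_ONLY", 2))),
                   params, id = "F7a"),
    F7b = lx_cross(g,
                   lx_genotype(g, "XX", list(al(a, "SECOND_ONLY", 1),
                                             al(a, "SECOND_ONLY", 2))),
                   lx_genotype(g, "XY", list(al(cns, "SECOND_ONLY", 1),
                                             al(cns, "SECOND_ONLY", 2))),
                   params, id = "F7b"),
    F8 = lx_cross(g,
                  lx_genotype(g, "XX", list(al(a, "FIRST_ONLY", 1),
                                            al(cns, "FIRST_ONLY", 2))),
                  lx_genotype(g, "XY", list(al(a, "SECOND_ONLY", 1),
                                            al(cns, "SECOND_ONLY", 2))),
                  params, id = "F8"),
    F9 = {
      linked <- identical(g$constructs[[a]]$chromosome,
                          g$constructs[[cns]]$chromosome)
      mk <- function(sex) {
        if (linked)
          # cis: both first-flavor alleles on homolog 1, both second-flavor
          # on homolog 2 (the arrangement the double-recombinant F8
          # selection produces)
          lx_genotype(g, sex, list(al(a, "FIRST_ONLY", 1),
                                   al(cns, "FIRST_ONLY", 1),
                                   al(a, "SECOND_ONLY", 2),
                                   al(cns, "SECOND_ONLY", 2)))
        else
          lx_genotype(g, sex, list(al(a, "FIRST_ONLY", 1),
                                   al(a, "SECOND_ONLY", 2),
                                   al(cns, "FIRST_ONLY", 1),
                                   al(cns, "SECOND_ONLY", 2)))
      }
      lx_cross(g, mk("XX"), mk("XY"), params, id = "F9")
    })
}

#' Hemizygote sibling cross at a single locus
#'
#' The standard viability-assay cross: two siblings hemizygous for the same
#' construct state. With a viable construct, 75% of the progeny display the
#' marker; with a homozygous-lethal construct, 66.7% of the survivors do.
#'
#' @param genome A [lx_genome()].
#' @param construct Construct id.
#' @param state Allele state of both parents (default `"DUAL_PRE"`).
#' @param params A [lx_params()].
#' @return A [lx_cross()].
#' @export
hemizygote_sibling_cross <- function(genome, construct, state = "DUAL_PRE",
                                     params = lx_params()) {
  al <- list(list(construct = construct, state = state, homolog = 1))
  lx_cross(genome,
           lx_genotype(genome, "XX", al),
           lx_genotype(genome, "XY", al),
           params, id = "hemizygote_sibling")
}
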