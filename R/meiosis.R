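# Gamete formation: germline Cre excision, two-point linkage, assortment -----

#' Transmission-model parameters
#'
#' @param beta Cre excision bias: probability that excision removes the
#'   second-slot marker and leaves the first-slot marker (`FIRST_ONLY`), in
#'   \[0, 1\]. 0.5 is the unbiased ("theoretical") value; interweaved Lox
#'   pairs of similar spacing are expected to recombine with almost equal
#'   probability, but an empirical bias towards one site can be supplied.
#' @param completeness Probability that a `DUAL_PRE` allele is recombined at
#'   all in a Cre-carrying germline, in \[0, 1\]; default 1 (effectively
#'   complete germline excision).
#' @param linkage Named list/vector: per chromosome the recombination
#'   fraction r in \[0, 0.5\] between its (at most two) transgene loci. Use
#'   [recombination_fraction()] to convert a centimorgan distance. Loci on a
#'   chromosome without an entry assort independently (r = 0.5).
#' @return A `lx_params` list.
#' @export
lx_params <- function(beta = 0.5, completeness = 1, linkage = list()) {
  stopifnot(is.numeric(beta), length(beta) == 1L, beta >= 0, beta <= 1)
  stopifnot(is.numeric(completeness), length(completeness) == 1L,
            completeness >= 0, completeness <= 1)
  linkage <- as.list(linkage)
  for (nm in names(linkage)) {
    r <- linkage[[nm]]
    if (!is.numeric(r) || length(r) != 1L || r < 0 || r > 0.5)
      stop("linkage['", nm, "']: recombination fraction must be in [0, 0.5]")
  }
  structure(list(beta = beta, completeness = completeness, linkage = linkage),
            class = "lx_params")
}

#' Convert map distance in centimorgan to a recombination fraction
#'
#' Map distance is identified with recombination percentage (1 cM = 1%
#' recombinant gametes); no Haldane/Kosambi map-function correction is
#' applied, matching schemes where cM is computed directly as the scored
#' recombination frequency. Values above 50 cM cap at r = 0.5 (independent
#' assortment). The inverse is [centimorgan()].
#'
#' @param cM Non-negative map distance in centimorgan.
#' @return Recombination fraction r in \[0, 0.5\].
#' @examples
#' recombination_fraction(8.31)  # 0.0831
#' @export
recombination_fraction <- function(cM) {
  if (any(!is.finite(cM)) || any(cM < 0)) stop("cM must be >= 0")
  pmin(cM / 100, 0.5)
}

#' Convert a recombination fraction to centimorgan
#'
#' @param r Recombination fraction in \[0, 0.5\].
#' @return Map distance in cM (`100 * r`).
#' @export
centimorgan <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r > 0.5))
    stop("r must be in [0, 0.5]")
  100 * r
}

chrom_r <- function(params, chrom) {
  r <- params$linkage[[chrom]]
  if (is.null(r)) 0.5 else r
}

#' Germline fate of one construct state under Cre
#'
#' Non-`DUAL_PRE` states are absorbing and map to themselves: after one
#' excision the remaining single LoxP and LoxN sites are incompatible, so no
#' further recombination is possible. A `DUAL_PRE` allele in a Cre-carrying
#' germline resolves to `FIRST_ONLY` with probability `completeness * beta`,
#' to `SECOND_ONLY` with `completeness * (1 - beta)`, and stays `DUAL_PRE`
#' with `1 - completeness`. Without Cre it is inert.
#'
#' @param state One of [CONSTRUCT_STATES].
#' @param cre_present Logical; is any Cre-expressing allele present in the
#'   parent's genotype?
#' @param params A [lx_params()].
#' @return Named numeric vector: probability over resulting states (zero
#'   entries dropped).
#' @export
germline_state <- function(state, cre_present, params = lx_params()) {
  if (!state %in% CONSTRUCT_STATES)
    stop("unknown construct state '", state, "'")
  if (state != "DUAL_PRE" || !isTRUE(cre_present))
    return(stats::setNames(1, state))
  cc <- params$completeness
  b <- params$beta
  out <- c(DUAL_PRE = 1 - cc, FIRST_ONLY = cc * b, SECOND_ONLY = cc * (1 - b))
  out[out > 0]
}

# Expand one haplotype into a distribution over germline-resolved haplotypes:
# every DUAL_PRE allele resolves independently. Returns list of
# list(hap=, prob=).
resolve_haplotype <- function(genome, hap, cre, params) {
  if (is_y_hap(hap) || !length(hap))
    return(list(list(hap = hap, prob = 1)))
  out <- list(list(hap = character(0), prob = 1))
  for (tok in hap) {
    p <- split_token(tok)
    d <- germline_state(p$state, cre, params)
    nxt <- list()
    for (o in out) for (i in seq_along(d)) {
      nxt[[length(nxt) + 1L]] <- list(
        hap = c(o$hap, allele_token(p$construct, names(d)[i])),
        prob = o$prob * d[[i]])
    }
    out <- nxt
  }
  out
}

# Two-point meiosis for one resolved homolog pair on one (non-Y) chromosome.
# Returns list of list(hap=, prob=, recomb=0/1). `loci` are the construct ids
# on the chromosome in position order.
meiosis_pair <- function(genome, h1, h2, loci, r) {
  if (length(loci) > 2L)
    stop("unsupported configuration: more than two transgene loci on one ",
         "chromosome (two-point model)")
  if (length(loci) <= 1L || r == 0) {
    return(list(list(hap = h1, prob = 0.5, recomb = 0L),
                list(hap = h2, prob = 0.5, recomb = 0L)))
  }
  at <- function(h, cid) {
    for (t in h) if (split_token(t)$construct == cid) return(t)
    character(0)
  }
  g_ab <- sort_hap(genome, c(at(h1, loci[1]), at(h2, loci[2])))
  g_ba <- sort_hap(genome, c(at(h2, loci[1]), at(h1, loci[2])))
  list(list(hap = h1, prob = (1 - r) / 2, recomb = 0L),
       list(hap = h2, prob = (1 - r) / 2, recomb = 0L),
       list(hap = g_ab, prob = r / 2, recomb = 1L),
       list(hap = g_ba, prob = r / 2, recomb = 1L))
}

# Per-chromosome gamete options for one parent, germline excision applied.
# Returns list of list(hap=, prob=, recomb=).
chrom_gametes <- function(genome, genotype, chrom, cre, params) {
  pr <- genotype$chrs[[chrom]]
  loci <- constructs_on(genome, chrom)
  r <- chrom_r(params, chrom)
  if (is_y_hap(pr[[2]])) {
    # XY parent's sex-chromosome pair: X and Y segregate 1/2 each, the single
    # X does not recombine.
    res1 <- resolve_haplotype(genome, pr[[1]], cre, params)
    out <- lapply(res1, function(o)
      list(hap = o$hap, prob = o$prob / 2, recomb = 0L))
    out[[length(out) + 1L]] <- list(hap = Y_HAP, prob = 0.5, recomb = 0L)
    return(out)
  }
  res1 <- resolve_haplotype(genome, pr[[1]], cre, params)
  res2 <- resolve_haplotype(genome, pr[[2]], cre, params)
  out <- list()
  for (o1 in res1) for (o2 in res2) {
    w <- o1$prob * o2$prob
    if (w == 0) next
    for (g in meiosis_pair(genome, o1$hap, o2$hap, loci, r)) {
      if (g$prob == 0) next
      g$prob <- g$prob * w
      out[[length(out) + 1L]] <- g
    }
  }
  out
}

# Full gamete enumeration across chromosomes. Returns a list of gametes:
# list(chrs = named list of haplotypes, prob =, recomb = total crossovers).
# No merging: the same haploid content may appear with different recomb
# labels (needed for parsimony recombination scoring).
enumerate_gametes <- function(genome, genotype, params) {
  cre <- carries_cre(genome, genotype)
  gam <- list(list(chrs = list(), prob = 1, recomb = 0L))
  for (ch in names(genome$chromosomes)) {
    opts <- chrom_gametes(genome, genotype, ch, cre, params)
    nxt <- vector("list", length(gam) * length(opts))
    k <- 0L
    for (g in gam) for (o in opts) {
      k <- k + 1L
      chrs <- g$chrs
      chrs[[ch]] <- o$hap
      nxt[[k]] <- list(chrs = chrs, prob = g$prob * o$prob,
                       recomb = g$recomb + o$recomb)
    }
    gam <- nxt
  }
  gam
}

gamete_key <- function(genome, gam) {
  parts <- vapply(names(genome$chromosomes), function(ch) {
    paste0(ch, "=", hap_string(genome, gam$chrs[[ch]], use_markers = FALSE))
  }, character(1))
  paste(parts, collapse = "; ")
}

#' Gamete distribution of one parent
#'
#' Enumerates the exact probability mass over haploid gamete classes emitted
#' by a parent: germline Cre excision is applied to every `DUAL_PRE` allele
#' first, then each chromosome pair segregates (two-point recombination at
#' fraction r for two linked loci; the four gamete classes have probabilities
#' (1-r)/2, (1-r)/2 parental and r/2, r/2 recombinant), chromosomes assort
#' independently, and an XY parent emits X- and Y-bearing gametes with
#' probability 1/2 each.
#'
#' @param parent A [lx_genotype()].
#' @param genome The matching [lx_genome()].
#' @param params A [lx_params()].
#' @return A data frame with columns `gamete` (canonical class string) and
#'   `prob`, summing to 1; the per-class haploid content is attached as
#'   attribute `"content"` (a named list).
#' @export
gamete_distribution <- function(parent, genome, params = lx_params()) {
  stopifnot(inherits(parent, "lx_genotype"), inherits(genome, "lx_genome"))
  gam <- enumerate_gametes(genome, parent, params)
  keys <- vapply(gam, function(g) gamete_key(genome, g), character(1))
  probs <- vapply(gam, `[[`, numeric(1), "prob")
  agg <- tapply(probs, keys, sum)
  ord <- order(names(agg))
  df <- data.frame(gamete = names(agg)[ord], prob = as.numeric(agg)[ord],
                   stringsAsFactors = FALSE, row.names = NULL)
  content <- list()
  for (i in seq_along(gam)) {
    k <- keys[i]
    if (is.null(content[[k]])) content[[k]] <- gam[[i]]$chrs
  }
  attr(df, "content") <- content[df$gamete]
  df
}
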