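# Diploid genotypes, haplotypes and marker phenotypes ------------------------

# A haplotype is a character vector of "construct:STATE" tokens sorted by
# insertion position; the Y "haplotype" is the sentinel below (no loci).
Y_HAP <- "<Y>"

is_y_hap <- function(h) identical(h, Y_HAP)

allele_token <- function(construct, state) paste(construct, state, sep = ":")

split_token <- function(tok) {
  parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
  list(construct = parts[1], state = parts[2])
}

# Sort a haplotype's allele tokens by construct position.
sort_hap <- function(genome, hap) {
  if (is_y_hap(hap) || !length(hap)) return(hap)
  cons <- vapply(hap, function(t) split_token(t)$construct, character(1))
  pos <- vapply(cons, function(cid) genome$constructs[[cid]]$position, numeric(1))
  unname(hap[order(pos)])
}

#' Construct a diploid genotype
#'
#' A genotype is a sex (XX or XY) plus, for every chromosome of the genome, an
#' ordered pair of haplotypes (homolog 1 = maternally inherited, homolog 2 =
#' paternally inherited). For an XY individual the second X-chromosome slot is
#' the Y sentinel, which never carries transgene alleles.
#'
#' @param genome A [lx_genome()].
#' @param sex `"XX"` or `"XY"`.
#' @param alleles List of allele placements; each element is a list or named
#'   character vector with fields `construct` (a construct id of the genome),
#'   `state` (one of [CONSTRUCT_STATES]) and `homolog` (1 or 2).
#' @return A `lx_genotype`.
#' @examples
#' g <- lx_genome(list(lx_chromosome("ChLG2")),
#'                list(lx_construct("ACOS", "ChLG2", 100, c("mCe", "mVe"))))
#' het <- lx_genotype(g, "XX", list(
#'   list(construct = "ACOS", state = "FIRST_ONLY", homolog = 1),
#'   list(construct = "ACOS", state = "SECOND_ONLY", homolog = 2)))
#' @export
lx_genotype <- function(genome, sex = c("XX", "XY"), alleles = list()) {
  stopifnot(inherits(genome, "lx_genome"))
  sex <- match.arg(sex)
  xchr <- x_chromosome(genome)
  chrs <- lapply(genome$chromosomes, function(ch) {
    if (ch$kind == "X" && sex == "XY") list(character(0), Y_HAP)
    else list(character(0), character(0))
  })
  for (al in alleles) {
    al <- as.list(al)
    cid <- al$construct
    if (is.null(genome$constructs[[cid]]))
      stop("unknown construct '", cid, "'")
    st <- al$state
    if (!st %in% CONSTRUCT_STATES)
      stop("unknown construct state '", st, "'")
    co <- genome$constructs[[cid]]
    if ((co$type == "fixed") != (st == "FIXED"))
      stop("construct '", cid, "' cannot take state ", st)
    hom <- as.integer(al$homolog)
    if (!hom %in% c(1L, 2L)) stop("homolog must be 1 or 2")
    ch <- co$chromosome
    if (identical(ch, xchr) && sex == "XY" && hom == 2L)
      stop("the Y sentinel cannot carry transgene alleles (construct '",
           cid, "')")
    prev <- chrs[[ch]][[hom]]
    if (any(vapply(prev, function(t) split_token(t)$construct, character(1)) == cid))
      stop("construct '", cid, "' placed twice on homolog ", hom)
    chrs[[ch]][[hom]] <- c(prev, allele_token(cid, st))
  }
  for (ch in names(chrs)) {
    chrs[[ch]][[1]] <- sort_hap(genome, chrs[[ch]][[1]])
    chrs[[ch]][[2]] <- sort_hap(genome, chrs[[ch]][[2]])
  }
  structure(list(sex = sex, chrs = chrs), class = "lx_genotype")
}

# Build a genotype directly from per-chromosome haplotype pairs (internal).
genotype_from_haps <- function(genome, sex, chrs) {
  chrs <- lapply(chrs, function(pr)
    list(sort_hap(genome, pr[[1]]), sort_hap(genome, pr[[2]])))
  structure(list(sex = sex, chrs = chrs), class = "lx_genotype")
}

# All allele tokens carried by a genotype.
all_tokens <- function(genotype) {
  unlist(lapply(genotype$chrs, function(pr) {
    c(if (!is_y_hap(pr[[1]])) pr[[1]], if (!is_y_hap(pr[[2]])) pr[[2]])
  }), use.names = FALSE)
}

carries_cre <- function(genome, genotype) {
  toks <- all_tokens(genotype)
  if (!length(toks)) return(FALSE)
  any(vapply(toks, function(t)
    genome$constructs[[split_token(t)$construct]]$expresses_cre, logical(1)))
}

# States of `construct` on each homolog: character(0)/state per slot, "Y" for
# the Y sentinel.
construct_slot_states <- function(genotype, construct) {
  lapply(seq_len(2L), function(hom) {
    found <- character(0)
    for (pr in genotype$chrs) {
      h <- pr[[hom]]
      if (is_y_hap(h)) { if (!length(found)) found <- "Y"; next }
      for (t in h) {
        p <- split_token(t)
        if (p$construct == construct) found <- p$state
      }
    }
    found
  })
}

#' Zygosity of a genotype at a construct's locus
#'
#' Classifies the allele configuration at one insertion locus: `absent` (no
#' allele), `hemizygous` (one allele, the other homolog empty -- including a
#' single X-borne allele in an XY male), `heterozygous` (two alleles with
#' different states, the "trans two-flavor" configuration) or `homozygous`
#' (two alleles with the same state).
#'
#' @param genotype A [lx_genotype()].
#' @param construct Construct id identifying the locus.
#' @param genome The [lx_genome()] the genotype was built against.
#' @return List with `class` (one of the four labels) and `states`
#'   (character vector of the allele states found, length 0, 1 or 2).
#' @export
zygosity <- function(genotype, construct, genome) {
  stopifnot(inherits(genotype, "lx_genotype"))
  if (is.null(genome$constructs[[construct]]))
    stop("unknown locus/construct '", construct, "'")
  slots <- construct_slot_states(genotype, construct)
  xchr <- x_chromosome(genome)
  on_x <- identical(genome$constructs[[construct]]$chromosome, xchr)
  s1 <- slots[[1]]
  s2 <- if (on_x && genotype$sex == "XY") character(0) else slots[[2]]
  s2 <- setdiff(s2, "Y")
  states <- c(s1[s1 != "Y"], s2)
  cls <- if (length(states) == 0L) "absent"
  else if (length(states) == 1L) "hemizygous"
  else if (states[1] == states[2]) "homozygous"
  else "heterozygous"
  list(class = cls, states = sort(states))
}

# Phenotypes ------------------------------------------------------------------

#' Marker phenotype of a genotype
#'
#' The visible set is the union of all markers encoded by all allele states
#' (a `DUAL_PRE` allele contributes both of its markers). The mosaic set is
#' the pair of excisable markers of any `DUAL_PRE` allele that co-occurs with
#' a Cre-expressing allele in the same individual: somatic Cre recombination
#' then gives patchy marker expression (e.g. within the compound eyes).
#' Mosaic markers remain visible; mosaicism is an annotation.
#'
#' @param genotype A [lx_genotype()].
#' @param genome The matching [lx_genome()].
#' @return A `lx_phenotype` list with sorted character vectors `visible` and
#'   `mosaic` (`mosaic` is always a subset of `visible`).
#' @export
phenotype_of <- function(genotype, genome) {
  toks <- all_tokens(genotype)
  vis <- character(0)
  mos <- character(0)
  cre <- carries_cre(genome, genotype)
  for (t in toks) {
    p <- split_token(t)
    co <- genome$constructs[[p$construct]]
    mk <- state_markers(co, p$state)
    vis <- union(vis, mk)
    if (p$state == "DUAL_PRE" && cre) mos <- union(mos, mk)
  }
  structure(list(visible = sort(vis), mosaic = sort(mos)),
            class = "lx_phenotype")
}

#' Serialize a marker set as a phenotype string
#'
#' Phenotypes are serialized as sorted comma-joined marker lists (e.g.
#' `"mC,mCe,mVe"`); the empty set is `"-"`.
#'
#' @param x A `lx_phenotype`, or a character vector of marker ids.
#' @return A single string.
#' @export
phenotype_string <- function(x) {
  if (inherits(x, "lx_phenotype")) x <- x$visible
  if (!length(x) || identical(x, "-") || identical(x, "")) return("-")
  paste(sort(unique(x)), collapse = ",")
}

parse_phenotype <- function(s) {
  if (inherits(s, "lx_phenotype")) return(sort(s$visible))
  if (length(s) == 1L && (s == "-" || s == "")) return(character(0))
  if (length(s) == 1L && grepl(",", s)) s <- strsplit(s, ",", fixed = TRUE)[[1]]
  sort(unique(trimws(s)))
}

#' @export
print.lx_phenotype <- function(x, ...) {
  cat("<phenotype> visible: ", phenotype_string(x), sep = "")
  if (length(x$mosaic))
    cat("  (mosaic: ", paste(x$mosaic, collapse = ","), ")", sep = "")
  cat("\n")
  invisible(x)
}

# Class labels ----------------------------------------------------------------

hap_string <- function(genome, hap, use_markers = TRUE) {
  if (is_y_hap(hap)) return("Y")
  if (!length(hap)) return("-")
  paste(vapply(hap, function(t) {
    p <- split_token(t)
    if (use_markers) state_flavor(genome$constructs[[p$construct]], p$state)
    else t
  }, character(1)), collapse = "+")
}

# Arrangement-level canonical label: per chromosome the unordered pair of full
# haplotype strings (order of homologs, i.e. parental origin, is dropped --
# but cis/trans differences persist because they change the strings).
# Chromosomes carrying no construct in the genome are omitted, except the X
# pair of an XY genotype when the genome defines an X with loci.
arrangement_label <- function(genome, genotype) {
  parts <- character(0)
  for (ch in names(genome$chromosomes)) {
    if (!length(constructs_on(genome, ch))) next
    pr <- genotype$chrs[[ch]]
    s1 <- hap_string(genome, pr[[1]])
    s2 <- hap_string(genome, pr[[2]])
    pair <- if (s2 == "Y") c(s1, s2) else sort(c(s1, s2))
    if (pair[1] == "-" && pair[2] %in% c("-", "Y")) next
    parts <- c(parts, paste0(ch, "[", pair[1], "/", pair[2], "]"))
  }
  if (!length(parts)) return("wildtype")
  paste(parts, collapse = "; ")
}

# Flavor-level label: per construct the unordered multiset of its states
# across homologs, written via marker names, ignoring cis/trans arrangement.
# Constructs absent from the genotype are omitted; a single X-borne allele in
# an XY male is marked "/Y".
flavor_label <- function(genome, genotype) {
  xchr <- x_chromosome(genome)
  parts <- character(0)
  for (ch in names(genome$chromosomes)) {
    for (cid in constructs_on(genome, ch)) {
      co <- genome$constructs[[cid]]
      slots <- construct_slot_states(genotype, cid)
      st <- unlist(lapply(slots, function(s) s[s != "Y"]))
      if (!length(st)) next
      flav <- sort(vapply(st, function(s) state_flavor(co, s), character(1)))
      on_x_male <- identical(ch, xchr) && genotype$sex == "XY"
      lab <- if (on_x_male) paste0(flav[1], "/Y")
      else if (length(flav) == 2L) paste(flav, collapse = "/")
      else flav[1]
      parts <- c(parts, paste0(cid, "(", lab, ")"))
    }
  }
  if (!length(parts)) return("wildtype")
  paste(parts, collapse = "; ")
}

# TRUE if the genotype is homozygous for any homozygous-lethal construct
# (two alleles of the construct with the same state).
is_lethal <- function(genome, genotype) {
  for (cid in names(genome$constructs)) {
    if (!genome$constructs[[cid]]$homozygous_lethal) next
    z <- zygosity(genotype, cid, genome)
    if (z$class == "homozygous") return(TRUE)
  }
  FALSE
}

#' @export
print.lx_genotype <- function(x, ...) {
  cat("<lx_genotype> ", x$sex, "\n", sep = "")
  for (ch in names(x$chrs)) {
    pr <- x$chrs[[ch]]
    cat("  ", ch, ": ", paste(vapply(pr, function(h) {
      if (is_y_hap(h)) "Y" else if (!length(h)) "-" else paste(h, collapse = "+")
    }, character(1)), collapse = " / "), "\n", sep = "")
  }
  invisible(x)
}
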