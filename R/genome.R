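# Genome and construct definitions ------------------------------------------

#' Transgene construct states
#'
#' A dual-marker Cre-Lox construct carries two eye markers between interweaved
#' LoxP/LoxN pairs. Germline Cre excises exactly one of them; afterwards the
#' remaining single LoxP + LoxN pair is inert, so the single-marker states are
#' absorbing. Helper constructs carry one fixed, non-excisable marker.
#'
#' @format Character vector of the four recognised states:
#'   `DUAL_PRE` (both markers, cis, pre-recombination), `FIRST_ONLY`
#'   (second-slot marker excised), `SECOND_ONLY` (first-slot marker excised),
#'   `FIXED` (single non-excisable marker).
#' @export
CONSTRUCT_STATES <- c("DUAL_PRE", "FIRST_ONLY", "SECOND_ONLY", "FIXED")

#' Recognised transformation-marker identifiers
#'
#' The four phenotypically distinguishable eye-specific fluorescent markers,
#' each detected under its own filter set: mO (mOrange-based), mC
#' (mCherry-based), mCe (mCerulean-based) and mVe (mVenus-based).
#'
#' @export
MARKER_IDS <- c("mO", "mC", "mCe", "mVe")

#' Define a chromosome
#'
#' @param name Chromosome identifier (e.g. `"ChLG9"`, `"ChLGX"`).
#' @param kind Either `"autosome"` or `"X"`. The Y chromosome is implicit and
#'   carries no loci.
#' @return A `lx_chromosome` list with elements `name` and `kind`.
#' @export
lx_chromosome <- function(name, kind = c("autosome", "X")) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, kind = kind), class = "lx_chromosome")
}

#' Define a transgene construct at a fixed insertion locus
#'
#' A construct occupies one TTAA insertion site (1-based start coordinate) on
#' one chromosome. Excisable constructs name two markers (first and second
#' slot); fixed constructs name one marker and may express Cre (helper lines).
#'
#' @param id Construct identifier (e.g. `"ACOS"`, `"AGOC"`, `"FIRE"`).
#' @param chromosome Name of the chromosome carrying the insertion.
#' @param position 1-based start coordinate of the TTAA insertion site.
#' @param markers Character vector of marker ids: length 2 (first, second
#'   excisable slots) or length 1 (fixed marker).
#' @param expresses_cre Logical; `TRUE` only for fixed helper constructs.
#' @param homozygous_lethal Logical; two same-state doses are not viable.
#' @return A `lx_construct` list.
#' @export
lx_construct <- function(id, chromosome, position, markers,
                         expresses_cre = FALSE, homozygous_lethal = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(chromosome), length(chromosome) == 1L)
  position <- as.numeric(position)
  if (length(position) != 1L || is.na(position) || position < 1)
    stop("construct '", id, "': position must be a 1-based coordinate >= 1")
  if (!all(markers %in% MARKER_IDS))
    stop("construct '", id, "': unknown marker(s) ",
         paste(setdiff(markers, MARKER_IDS), collapse = ", "),
         " (recognised: ", paste(MARKER_IDS, collapse = ", "), ")")
  if (!length(markers) %in% c(1L, 2L))
    stop("construct '", id, "': markers must have length 1 (fixed) or 2 (excisable)")
  if (length(markers) == 2L && markers[1] == markers[2])
    stop("construct '", id, "': the two excisable markers must differ")
  if (expresses_cre && length(markers) != 1L)
    stop("construct '", id, "': only fixed helper constructs may express Cre")
  structure(list(id = id, chromosome = chromosome, position = position,
                 markers = unname(markers),
                 type = if (length(markers) == 2L) "excisable" else "fixed",
                 expresses_cre = isTRUE(expresses_cre),
                 homozygous_lethal = isTRUE(homozygous_lethal)),
            class = "lx_construct")
}

#' Assemble a genome definition
#'
#' @param chromosomes List of [lx_chromosome()] objects. At most one may have
#'   kind `"X"`.
#' @param constructs List of [lx_construct()] objects; each must sit on a
#'   declared chromosome and two constructs on the same chromosome must occupy
#'   distinct positions. At most two constructs per chromosome are supported
#'   downstream (two-point model).
#' @return A `lx_genome` with named lists `chromosomes` and `constructs`.
#' @export
lx_genome <- function(chromosomes, constructs = list()) {
  if (inherits(chromosomes, "lx_chromosome")) chromosomes <- list(chromosomes)
  if (inherits(constructs, "lx_construct")) constructs <- list(constructs)
  stopifnot(all(vapply(chromosomes, inherits, logical(1), "lx_chromosome")))
  stopifnot(all(vapply(constructs, inherits, logical(1), "lx_construct")))
  cn <- vapply(chromosomes, `[[`, character(1), "name")
  if (anyDuplicated(cn))
    stop("duplicate chromosome name: ", cn[duplicated(cn)][1])
  if (sum(vapply(chromosomes, `[[`, character(1), "kind") == "X") > 1L)
    stop("at most one chromosome may have kind 'X'")
  names(chromosomes) <- cn
  ids <- vapply(constructs, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate construct id: ", ids[duplicated(ids)][1])
  names(constructs) <- ids
  for (co in constructs) {
    if (!co$chromosome %in% cn)
      stop("construct '", co$id, "' references unknown chromosome '",
           co$chromosome, "'")
  }
  for (ch in cn) {
    on_ch <- constructs[vapply(constructs, `[[`, character(1), "chromosome") == ch]
    pos <- vapply(on_ch, `[[`, numeric(1), "position")
    if (anyDuplicated(pos))
      stop("two constructs on ", ch, " share position ", pos[duplicated(pos)][1])
  }
  structure(list(chromosomes = chromosomes, constructs = constructs),
            class = "lx_genome")
}

# Construct ids on a chromosome, sorted by insertion position.
constructs_on <- function(genome, chrom) {
  keep <- vapply(genome$constructs, `[[`, character(1), "chromosome") == chrom
  on_ch <- genome$constructs[keep]
  pos <- vapply(on_ch, `[[`, numeric(1), "position")
  names(on_ch)[order(pos)]
}

x_chromosome <- function(genome) {
  kinds <- vapply(genome$chromosomes, `[[`, character(1), "kind")
  nm <- names(kinds)[kinds == "X"]
  if (length(nm)) nm else NA_character_
}

#' Chromosomal distance between two insertion sites in Mbp
#'
#' Coordinates are 1-based TTAA start positions; the distance is reported in
#' megabase pairs rounded to two decimals, the convention used when comparing
#' physical with genetic distance.
#'
#' @param pos1,pos2 1-based coordinates on the same chromosome.
#' @return Distance in Mbp, rounded to two decimals.
#' @examples
#' locus_distance_mbp(8613308, 10781551)  # 2.17
#' @export
locus_distance_mbp <- function(pos1, pos2) {
  stopifnot(is.numeric(pos1), is.numeric(pos2), pos1 >= 1, pos2 >= 1)
  round(abs(pos2 - pos1) / 1e6, 2)
}

# Markers visible for a construct in a given state.
state_markers <- function(construct, state) {
  switch(state,
         DUAL_PRE = construct$markers,
         FIRST_ONLY = construct$markers[1],
         SECOND_ONLY = construct$markers[2],
         FIXED = construct$markers[1],
         stop("unknown construct state '", state, "'"))
}

# Human-readable flavor of a construct state, e.g. "mCe-mVe" or "mVe".
state_flavor <- function(construct, state) {
  paste(state_markers(construct, state), collapse = "-")
}

#' @export
print.lx_genome <- function(x, ...) {
  cat("<lx_genome> ", length(x$chromosomes), " chromosome(s), ",
      length(x$constructs), " construct(s)\n", sep = "")
  for (ch in x$chromosomes) {
    ids <- constructs_on(x, ch$name)
    cat("  ", ch$name, " [", ch$kind, "]", sep = "")
    if (length(ids)) {
      for (id in ids) {
        co <- x$constructs[[id]]
        cat("  ", id, "@", format(co$position, big.mark = ",", scientific = FALSE),
            " (", paste(co$markers, collapse = "/"), ")",
            if (co$expresses_cre) " Cre" else "",
            if (co$homozygous_lethal) " lethal" else "", sep = "")
      }
    }
    cat("\n")
  }
  invisible(x)
}
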