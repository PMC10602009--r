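# Exact progeny enumeration for a cross --------------------------------------

#' Specify a cross
#'
#' @param genome A [lx_genome()].
#' @param mother An XX [lx_genotype()].
#' @param father An XY [lx_genotype()].
#' @param params A [lx_params()].
#' @param id Optional cross identifier used in reports.
#' @return A `lx_cross` list.
#' @export
lx_cross <- function(genome, mother, father, params = lx_params(),
                     id = "cross") {
  stopifnot(inherits(genome, "lx_genome"),
            inherits(mother, "lx_genotype"),
            inherits(father, "lx_genotype"),
            inherits(params, "lx_params"))
  if (mother$sex != "XX") stop("mother must be XX")
  if (father$sex != "XY") stop("father must be XY")
  structure(list(genome = genome, mother = mother, father = father,
                 params = params, id = id), class = "lx_cross")
}

# Fuse one maternal and one paternal gamete into a zygote genotype.
# Sex: if the genome defines an X chromosome, the paternal sex chromosome
# decides; otherwise the zygote is returned for both sexes with half weight
# by the caller.
fuse_gametes <- function(genome, gm, gf) {
  xchr <- x_chromosome(genome)
  sex <- if (!is.na(xchr) && is_y_hap(gf[[xchr]])) "XY" else "XX"
  chrs <- list()
  for (ch in names(genome$chromosomes)) {
    h1 <- gm[[ch]]
    h2 <- gf[[ch]]
    if (is.null(h1)) h1 <- character(0)
    if (is.null(h2)) h2 <- if (identical(ch, xchr) && sex == "XY") Y_HAP else character(0)
    chrs[[ch]] <- list(h1, h2)
  }
  genotype_from_haps(genome, sex, chrs)
}

#' Exact progeny distribution of a cross
#'
#' Outer product of the maternal and paternal gamete distributions, fused
#' into diploid genotype classes (maternal gamete becomes homolog 1; a
#' paternal X makes a daughter, a paternal Y a son) and merged by canonical
#' class. With `apply_lethality = TRUE`, classes homozygous for any
#' homozygous-lethal construct are removed and the survivors renormalized --
#' the distribution seen when scoring surviving progeny.
#'
#' @param cross A [lx_cross()].
#' @param apply_lethality Remove homozygous-lethal classes and renormalize.
#' @return A data frame with columns `sex`, `genotype` (arrangement-level
#'   canonical label, cis/trans preserved), `flavor` (marker-flavor label,
#'   arrangement and parental origin collapsed), `phenotype` (visible marker
#'   string) and `prob`. Representative [lx_genotype()] objects are attached
#'   as attribute `"genotypes"`, keyed by `sex` and `genotype` label.
#' @export
progeny_distribution <- function(cross, apply_lethality = FALSE) {
  stopifnot(inherits(cross, "lx_cross"))
  genome <- cross$genome
  gm <- gamete_distribution(cross$mother, genome, cross$params)
  gf <- gamete_distribution(cross$father, genome, cross$params)
  cm <- attr(gm, "content")
  cf <- attr(gf, "content")
  has_x <- !is.na(x_chromosome(genome))

  keys <- character(0)
  probs <- numeric(0)
  sexes <- character(0)
  labels <- character(0)
  reps <- list()
  add <- function(g, p) {
    lab <- arrangement_label(genome, g)
    key <- paste(g$sex, lab, sep = "|")
    i <- match(key, keys)
    if (is.na(i)) {
      keys[[length(keys) + 1L]] <<- key
      probs[[length(probs) + 1L]] <<- p
      sexes[[length(sexes) + 1L]] <<- g$sex
      labels[[length(labels) + 1L]] <<- lab
      reps[[key]] <<- g
    } else probs[[i]] <<- probs[[i]] + p
  }
  for (i in seq_len(nrow(gm))) for (j in seq_len(nrow(gf))) {
    p <- gm$prob[i] * gf$prob[j]
    if (p == 0) next
    z <- fuse_gametes(genome, cm[[i]], cf[[j]])
    if (has_x) add(z, p)
    else {
      # no X chromosome defined: sexes are equally likely and independent
      z$sex <- "XX"; add(z, p / 2)
      z$sex <- "XY"; add(z, p / 2)
    }
  }

  geno <- reps[keys]
  if (apply_lethality) {
    dead <- vapply(geno, function(g) is_lethal(genome, g), logical(1))
    keep <- !dead
    if (!any(keep)) stop("no surviving progeny class under lethality")
    keys <- keys[keep]; probs <- probs[keep]
    sexes <- sexes[keep]; labels <- labels[keep]
    geno <- geno[keys]
    probs <- probs / sum(probs)
  }
  flavors <- vapply(geno, function(g) flavor_label(genome, g), character(1))
  phenos <- vapply(geno, function(g)
    phenotype_string(phenotype_of(g, genome)), character(1))
  ord <- order(labels, sexes)
  df <- data.frame(sex = sexes[ord], genotype = labels[ord],
                   flavor = unname(flavors)[ord], phenotype = unname(phenos)[ord],
                   prob = probs[ord], stringsAsFactors = FALSE, row.names = NULL)
  attr(df, "genotypes") <- geno[ord]
  attr(df, "cross_id") <- cross$id
  df
}

#' Phenotype distribution of a cross
#'
#' Pushforward of [progeny_distribution()] through [phenotype_of()].
#'
#' @inheritParams progeny_distribution
#' @return Data frame with columns `phenotype` and `prob`, summing to 1.
#' @export
phenotype_distribution <- function(cross, apply_lethality = FALSE) {
  d <- progeny_distribution(cross, apply_lethality)
  agg <- tapply(d$prob, d$phenotype, sum)
  data.frame(phenotype = names(agg), prob = as.numeric(agg),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Probability of a progeny class defined by a predicate
#'
#' @param cross A [lx_cross()].
#' @param predicate Function taking a [lx_genotype()] and returning `TRUE` or
#'   `FALSE`; must be total over the progeny classes.
#' @param apply_lethality Evaluate over survivors instead of conceptions.
#' @return The summed probability of the classes satisfying the predicate.
#' @export
class_probability <- function(cross, predicate, apply_lethality = FALSE) {
  d <- progeny_distribution(cross, apply_lethality)
  geno <- attr(d, "genotypes")
  sel <- vapply(seq_len(nrow(d)), function(i) isTRUE(predicate(geno[[i]])),
                logical(1))
  sum(d$prob[sel])
}

#' Number of distinct progeny genotype classes
#'
#' Counts classes with positive probability. The default `"flavor"`
#' granularity counts presence/state of each transgene by marker flavor,
#' collapsing cis/trans arrangement, parental origin and (for autosomal
#' content) sex -- the granularity at which a cross of two double
#' hemizygotes for unlinked transgenes yields sixteen different genotypes.
#' `"arrangement"` keeps cis/trans-distinct classes separate.
#'
#' @param cross A [lx_cross()].
#' @param granularity `"flavor"` (default) or `"arrangement"`.
#' @param apply_lethality Count surviving classes only.
#' @return Integer count.
#' @export
distinct_genotype_count <- function(cross,
                                    granularity = c("flavor", "arrangement"),
                                    apply_lethality = FALSE) {
  granularity <- match.arg(granularity)
  d <- progeny_distribution(cross, apply_lethality)
  d <- d[d$prob > 0, ]
  length(unique(d[[if (granularity == "flavor") "flavor" else "genotype"]]))
}

#' Theoretical ratio table for a cross
#'
#' Machine-readable table of the expected ("theoretical") progeny ratios of a
#' cross, at phenotype or genotype granularity. Percentages are rounded to
#' two decimals with half-even rounding; the unrounded probabilities are
#' retained in the `prob` column.
#'
#' @param cross A [lx_cross()].
#' @param level `"phenotype"` (default) or `"genotype"` (flavor granularity).
#' @param apply_lethality Report ratios among survivors.
#' @return Data frame with columns `cross_id`, `class`, `theoretical_percent`,
#'   `granularity`, `prob` and, at phenotype level, `genotype_classes` (the
#'   contributing flavor classes, comma-joined).
#' @export
expected_ratio_table <- function(cross, level = c("phenotype", "genotype"),
                                 apply_lethality = FALSE) {
  level <- match.arg(level)
  d <- progeny_distribution(cross, apply_lethality)
  d <- d[d$prob > 0, ]
  if (level == "phenotype") {
    agg <- tapply(d$prob, d$phenotype, sum)
    contrib <- tapply(d$flavor, d$phenotype, function(x)
      paste(sort(unique(x)), collapse = " | "))
    out <- data.frame(cross_id = cross$id, class = names(agg),
                      theoretical_percent = round(100 * as.numeric(agg), 2),
                      granularity = "phenotype",
                      prob = as.numeric(agg),
                      genotype_classes = as.character(contrib),
                      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    agg <- tapply(d$prob, d$flavor, sum)
    out <- data.frame(cross_id = cross$id, class = names(agg),
                      theoretical_percent = round(100 * as.numeric(agg), 2),
                      granularity = "flavor",
                      prob = as.numeric(agg),
                      stringsAsFactors = FALSE, row.names = NULL)
  }
  out[order(-out$prob, out$class), , drop = FALSE]
}

#' Resolve an observed phenotype to progeny genotype classes
#'
#' Returns the progeny genotype classes of a cross that are compatible with
#' an observed marker phenotype: exactly the classes with positive survivor
#' probability whose visible marker set equals the observation (mosaicism is
#' an annotation and does not enter the comparison). Because some genotypes
#' share a phenotype in isolation (a hemizygote and a homozygote of the same
#' flavor, for instance), resolution always requires the cross context; this
#' is what makes phenotype-only genotyping unambiguous at the right steps of
#' the breeding procedures.
#'
#' @param observed A `lx_phenotype`, a character vector of marker ids, or a
#'   phenotype string such as `"mC,mCe"` (`"-"` for no marker).
#' @param cross A [lx_cross()].
#' @param sex Optional: restrict to `"XX"` or `"XY"` progeny.
#' @param granularity Granularity at which uniqueness is judged: `"flavor"`
#'   (default; cis/trans arrangements of the same flavor count once) or
#'   `"arrangement"`.
#' @return List with `classes` (the matching rows of
#'   [progeny_distribution()]), `unique` (logical: exactly one class at the
#'   chosen granularity) and `flavors` (the distinct flavor labels).
#'   An observation impossible under the cross raises an error of class
#'   `"lx_inconsistent_observation"`.
#' @export
resolve_genotypes <- function(observed, cross, sex = NULL,
                              granularity = c("flavor", "arrangement")) {
  granularity <- match.arg(granularity)
  obs <- parse_phenotype(observed)
  d <- progeny_distribution(cross, apply_lethality = TRUE)
  keep <- d$prob > 0 & d$phenotype == phenotype_string(obs)
  if (!is.null(sex)) keep <- keep & d$sex == sex
  sub <- d[keep, , drop = FALSE]
  if (!nrow(sub)) {
    stop(structure(class = c("lx_inconsistent_observation", "error",
                             "condition"),
                   list(message = paste0(
                     "inconsistent observation: phenotype '",
                     phenotype_string(obs), "'",
                     if (!is.null(sex)) paste0(" (", sex, ")"),
                     " is impossible under cross '", cross$id, "'"),
                     call = sys.call(-1))))
  }
  attr(sub, "genotypes") <- attr(d, "genotypes")[keep]
  n_classes <- length(unique(
    sub[[if (granularity == "flavor") "flavor" else "genotype"]]))
  list(classes = sub, unique = n_classes == 1L,
       flavors = sort(unique(sub$flavor)))
}

# Warn when two constructs entering a cross share a marker id: phenotype
# resolution may then be non-unique.
check_marker_collisions <- function(cross) {
  toks <- unique(c(all_tokens(cross$mother), all_tokens(cross$father)))
  cons <- unique(vapply(toks, function(t) split_token(t)$construct,
                        character(1)))
  if (length(cons) < 2L) return(invisible(NULL))
  mk <- lapply(cons, function(cid) cross$genome$constructs[[cid]]$markers)
  all_mk <- unlist(mk)
  dup <- unique(all_mk[duplicated(all_mk)])
  if (length(dup))
    warning("constructs in cross '", cross$id, "' share marker(s) ",
            paste(dup, collapse = ", "),
            ": phenotype resolution may be non-unique", call. = FALSE)
  invisible(dup)
}

#' @export
print.lx_cross <- function(x, ...) {
  cat("<lx_cross> ", x$id, "\n  mother: ",
      flavor_label(x$genome, x$mother), "\n  father: ",
      flavor_label(x$genome, x$father), "\n", sep = "")
  invisible(x)
}
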