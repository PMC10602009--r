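# Stochastic progeny sampling and mating-procedure orchestration -------------

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Multinomial draw of n conceived progeny over the raw (unfiltered) progeny
# distribution, then removal of homozygous-lethal classes. Uses the current
# RNG stream. Returns the survivor distribution rows with a `count` column;
# attribute "n_conceived" and "n_scored".
sample_genotype_counts <- function(cross, n_conceived) {
  d <- progeny_distribution(cross, apply_lethality = FALSE)
  counts <- if (n_conceived > 0)
    as.integer(stats::rmultinom(1, n_conceived, d$prob))
  else integer(nrow(d))
  geno <- attr(d, "genotypes")
  dead <- vapply(geno, function(g) is_lethal(cross$genome, g), logical(1))
  d$count <- counts
  surv <- d[!dead, , drop = FALSE]
  attr(surv, "genotypes") <- geno[!dead]
  attr(surv, "lethal_classes") <- d[dead, , drop = FALSE]
  attr(surv, "n_conceived") <- n_conceived
  attr(surv, "n_scored") <- sum(surv$count)
  surv
}

#' Sample a progeny score table for one cross
#'
#' Draws `n_conceived` progeny from the exact progeny distribution
#' (multinomial), removes individuals homozygous for a homozygous-lethal
#' construct before scoring (conceived-then-filter semantics), and tabulates
#' the surviving progeny by visible marker phenotype. Identical
#' `(cross, n_conceived, seed)` inputs reproduce identical tables.
#'
#' @param cross A [lx_cross()].
#' @param n_conceived Number of conceived progeny (before lethality).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param generation Generation label recorded in the table (e.g. `"F6"`).
#' @return A score table: data frame with columns `cross_id`, `generation`,
#'   `mother_class`, `father_class`, `phenotype`, `count` (survivors only).
#'   The per-genotype-class survivor counts are attached as attribute
#'   `"genotype_counts"`; `"n_conceived"` and `"n_scored"` record totals.
#' @export
sample_progeny <- function(cross, n_conceived, seed = NULL, generation = "") {
  stopifnot(inherits(cross, "lx_cross"), n_conceived >= 0)
  surv <- with_seed(seed, sample_genotype_counts(cross, n_conceived))
  keep <- surv$count > 0
  tab <- surv[keep, , drop = FALSE]
  agg <- if (nrow(tab)) tapply(tab$count, tab$phenotype, sum) else
    integer(0)
  out <- data.frame(
    cross_id = rep(cross$id, length(agg)),
    generation = rep(generation, length(agg)),
    mother_class = rep(flavor_label(cross$genome, cross$mother), length(agg)),
    father_class = rep(flavor_label(cross$genome, cross$father), length(agg)),
    phenotype = as.character(if (length(agg)) names(agg) else character(0)),
    count = as.integer(agg),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$phenotype), , drop = FALSE]
  row.names(out) <- NULL
  attr(out, "genotype_counts") <- surv
  attr(out, "n_conceived") <- attr(surv, "n_conceived")
  attr(out, "n_scored") <- attr(surv, "n_scored")
  out
}

# Select one individual of the required (sex, phenotype) observation from the
# sampled survivors. Selection is phenotype-only: the candidate genotype
# classes come from resolve-style matching on the enumerated survivor
# distribution, never from the hidden truth. Returns
# list(ok, genotype, flavor, reason).
select_individual <- function(cross, sampled, sex, markers) {
  ph <- phenotype_string(markers)
  cand <- sampled$sex == sex & sampled$phenotype == ph
  enum_cand <- sampled[cand & sampled$prob > 0, , drop = FALSE]
  if (!nrow(enum_cand)) {
    dead <- attr(sampled, "lethal_classes")
    lethal_only <- !is.null(dead) && nrow(dead) &&
      any(dead$sex == sex & dead$phenotype == ph & dead$prob > 0)
    return(list(ok = FALSE,
                reason = if (lethal_only)
                  paste0("lack of suitable progeny: all '", ph, "' (", sex,
                         ") classes of cross '", cross$id,
                         "' are homozygous-lethal")
                else
                  paste0("phenotype '", ph, "' (", sex,
                         ") impossible under cross '", cross$id, "'")))
  }
  flavors <- unique(enum_cand$flavor)
  if (length(flavors) > 1L)
    return(list(ok = FALSE,
                reason = paste0("phenotype '", ph, "' (", sex,
                                ") does not resolve uniquely in cross '",
                                cross$id, "': ",
                                paste(flavors, collapse = " vs "))))
  hit <- cand & sampled$count > 0
  if (!any(hit))
    return(list(ok = FALSE,
                reason = paste0("no '", ph, "' (", sex,
                                ") individuals among scored progeny of cross '",
                                cross$id, "'")))
  idx <- which(hit)
  pick <- if (length(idx) == 1L) idx else
    idx[sample.int(length(idx), 1L, prob = sampled$count[idx])]
  list(ok = TRUE, genotype = attr(sampled, "genotypes")[[pick]],
       flavor = sampled$flavor[pick])
}

# Run one cross of a procedure: sample progeny and perform the requested
# selections. `targets` is a named list of list(sex=, markers=, generation=).
run_step <- function(genome, params, id, generation, mother, father,
                     n_per_cross, targets) {
  cross <- lx_cross(genome, mother, father, params, id = id)
  tab <- sample_progeny(cross, n_per_cross, generation = generation)
  sampled <- attr(tab, "genotype_counts")
  selected <- list()
  for (nm in names(targets)) {
    tg <- targets[[nm]]
    res <- select_individual(cross, sampled, tg$sex, tg$markers)
    if (!res$ok)
      return(list(ok = FALSE, table = tab, failed_target = nm,
                  target_generation = tg$generation, reason = res$reason))
    selected[[nm]] <- res
  }
  list(ok = TRUE, table = tab, selected = selected)
}

new_procedure_result <- function(scheme, steps, status, aborted_step = NULL,
                                 reason = NULL, cultures = list(),
                                 seed = NULL, params = NULL) {
  structure(list(scheme = scheme, status = status, aborted_step = aborted_step,
                 reason = reason, steps = steps, cultures = cultures,
                 seed = seed, params = params),
            class = "lx_procedure_result")
}

#' Run the single-transgene homozygosing procedure (F3 to F7)
#'
#' In-silico execution of the four-cross scheme that takes a dual-marker
#' pre-recombination hemizygote to both single-marker homozygous cultures:
#' F3 pre-recombination hemizygous females x X-linked Cre-helper males; F4
#' double-hemizygous females x wild-type males (germline excision splits the
#' construct into its two flavors); F5 first-flavor females x second-flavor
#' male siblings; F6 trans-heterozygous siblings inter se, from which both
#' F7 homozygous flavors are established. At every step individuals are
#' selected by sex and visible marker phenotype only, and only where the
#' phenotype resolves to a unique genotype class under the cross -- the true
#' sampled genotypes are never consulted. A step lacking a required
#' individual (for instance because the construct is homozygous lethal, so
#' no F7 homozygote survives) aborts the procedure with a step-labelled
#' status.
#'
#' @param genome A [lx_genome()] containing the two constructs.
#' @param acos Id of the excisable dual-marker construct (autosomal, started
#'   in `DUAL_PRE` state).
#' @param helper Id of the X-linked fixed-marker construct with
#'   `expresses_cre = TRUE`.
#' @param params A [lx_params()].
#' @param n_per_cross Conceived progeny sampled per cross.
#' @param seed Integer seed for the procedure's single RNG stream.
#' @return A `lx_procedure_result`: `status` (`"completed"` or `"aborted"`),
#'   `aborted_step`/`reason` when aborted, per-cross score tables in
#'   `steps`, and the established `cultures` (flavor labels) when completed.
#' @export
run_acos_procedure <- function(genome, acos, helper, params = lx_params(),
                               n_per_cross = 200, seed = 1) {
  co <- genome$constructs[[acos]]
  he <- genome$constructs[[helper]]
  if (is.null(co) || is.null(he))
    stop("unknown construct id(s)")
  xchr <- x_chromosome(genome)
  if (is.na(xchr) || !identical(he$chromosome, xchr) || !he$expresses_cre)
    stop("configuration error: helper must be X-linked and express Cre")
  if (co$type != "excisable")
    stop("configuration error: '", acos, "' must be an excisable dual-marker construct")
  if (identical(co$chromosome, xchr))
    stop("configuration error: '", acos, "' must be autosomal")
  m1 <- co$markers[1]; m2 <- co$markers[2]; hm <- he$markers[1]

  gt <- function(sex, ...) lx_genotype(genome, sex, list(...))
  al <- function(construct, state, homolog)
    list(construct = construct, state = state, homolog = homolog)

  with_seed(seed, {
    steps <- list()
    fail <- function(st, step_label) new_procedure_result(
      "acos", steps, "aborted", aborted_step = step_label,
      reason = st$reason, seed = seed, params = params)

    # F3: DUAL_PRE hemizygous female x helper male
    st <- run_step(genome, params, "F3", "F4",
                   gt("XX", al(acos, "DUAL_PRE", 1)),
                   gt("XY", al(helper, "FIXED", 1)),
                   n_per_cross,
                   list(f4_female = list(sex = "XX", markers = c(hm, m1, m2),
                                         generation = "F4")))
    steps$F3 <- st$table
    if (!st$ok) return(fail(st, "F4"))
    f4f <- st$selected$f4_female$genotype

    # F4: double-hemizygous female x wild-type male (germline Cre acts here)
    st <- run_step(genome, params, "F4", "F5",
                   f4f, gt("XY"), n_per_cross,
                   list(f5_female = list(sex = "XX", markers = m1,
                                         generation = "F5"),
                        f5_male = list(sex = "XY", markers = m2,
                                       generation = "F5")))
    steps$F4 <- st$table
    if (!st$ok) return(fail(st, "F5"))

    # F5: first-flavor female x second-flavor male sibling
    st <- run_step(genome, params, "F5", "F6",
                   st$selected$f5_female$genotype,
                   st$selected$f5_male$genotype, n_per_cross,
                   list(f6_female = list(sex = "XX", markers = c(m1, m2),
                                         generation = "F6"),
                        f6_male = list(sex = "XY", markers = c(m1, m2),
                                       generation = "F6")))
    steps$F5 <- st$table
    if (!st$ok) return(fail(st, "F6"))

    # F6: trans-heterozygous siblings inter se; establish both F7 flavors
    st <- run_step(genome, params, "F6", "F7",
                   st$selected$f6_female$genotype,
                   st$selected$f6_male$genotype, n_per_cross,
                   list(f7_first_female = list(sex = "XX", markers = m1,
                                               generation = "F7"),
                        f7_first_male = list(sex = "XY", markers = m1,
                                             generation = "F7"),
                        f7_second_female = list(sex = "XX", markers = m2,
                                                generation = "F7"),
                        f7_second_male = list(sex = "XY", markers = m2,
                                              generation = "F7")))
    steps$F6 <- st$table
    if (!st$ok) return(fail(st, "F7"))

    new_procedure_result("acos", steps, "completed",
                         cultures = list(first = st$selected$f7_first_female$flavor,
                                         second = st$selected$f7_second_female$flavor),
                         seed = seed, params = params)
  })
}

#' Run the double-transgene homozygosing procedure (F7 to F10)
#'
#' In-silico execution of the three-step scheme that combines two
#' single-marker (post-recombination) constructs into all four flavors of
#' double homozygotes: parallel F7 crosses of single-flavor homozygous
#' cultures produce the two complementary double hemizygotes, the F8 cross
#' of those yields four-marker double heterozygotes, and the F9 sibling
#' cross yields the four double-homozygous flavors. When the first construct
#' sits on the X chromosome the scheme switches automatically to the
#' X-allosome variant (reciprocal F8 crosses, hemi-heterozygous males, and
#' F10 females double homozygous next to hemi-homozygous males). For two
#' loci on the same autosome the recombination fraction from `params`
#' governs how often the required double-recombinant classes arise; with
#' tight linkage and a modest `n_per_cross` the procedure will typically
#' abort at the F9 selection. Selection is by sex and visible phenotype
#' only, exactly as in [run_acos_procedure()].
#'
#' @param genome A [lx_genome()] containing both constructs.
#' @param agoc Id of the first excisable construct (autosomal or X-linked);
#'   its `FIRST_ONLY`/`SECOND_ONLY` flavors seed the F7 female cultures.
#' @param acos Id of the second excisable construct (autosomal); its flavors
#'   seed the F7 male cultures.
#' @param params A [lx_params()] (set `linkage` for same-chromosome loci).
#' @param n_per_cross Conceived progeny sampled per cross.
#' @param seed Integer seed.
#' @return A `lx_procedure_result`; on completion `cultures` holds the four
#'   double-homozygous flavor labels.
#' @export
run_agoc_acos_procedure <- function(genome, agoc, acos, params = lx_params(),
                                    n_per_cross = 400, seed = 1) {
  ca <- genome$constructs[[agoc]]
  cc <- genome$constructs[[acos]]
  if (is.null(ca) || is.null(cc)) stop("unknown construct id(s)")
  if (ca$type != "excisable" || cc$type != "excisable")
    stop("configuration error: both constructs must be excisable dual-marker ",
         "constructs in single-marker (post-recombination) use")
  xchr <- x_chromosome(genome)
  if (identical(cc$chromosome, xchr))
    stop("configuration error: '", acos, "' must be autosomal")
  x_variant <- identical(ca$chromosome, xchr)
  a1 <- ca$markers[1]; a2 <- ca$markers[2]
  c1 <- cc$markers[1]; c2 <- cc$markers[2]

  gt <- function(sex, ...) lx_genotype(genome, sex, list(...))
  al <- function(construct, state, homolog)
    list(construct = construct, state = state, homolog = homolog)
  # F7 culture parents: single-flavor homozygotes (X-linked males are
  # hemizygous on their single X).
  agoc_female <- function(state) gt("XX", al(agoc, state, 1), al(agoc, state, 2))
  acos_male <- function(state) gt("XY", al(acos, state, 1), al(acos, state, 2))

  with_seed(seed, {
    steps <- list()
    fail <- function(st, step_label) new_procedure_result(
      "agoc_acos", steps, "aborted", aborted_step = step_label,
      reason = st$reason, seed = seed, params = params)

    if (!x_variant) {
      st <- run_step(genome, params, "F7a", "F8",
                     agoc_female("FIRST_ONLY"), acos_male("FIRST_ONLY"),
                     n_per_cross,
                     list(f8_female = list(sex = "XX", markers = c(a1, c1),
                                           generation = "F8")))
      steps$F7a <- st$table
      if (!st$ok) return(fail(st, "F8"))
      f8f <- st$selected$f8_female$genotype

      st <- run_step(genome, params, "F7b", "F8",
                     agoc_female("SECOND_ONLY"), acos_male("SECOND_ONLY"),
                     n_per_cross,
                     list(f8_male = list(sex = "XY", markers = c(a2, c2),
                                         generation = "F8")))
      steps$F7b <- st$table
      if (!st$ok) return(fail(st, "F8"))
      f8m <- st$selected$f8_male$genotype

      st <- run_step(genome, params, "F8", "F9", f8f, f8m, n_per_cross,
                     list(f9_female = list(sex = "XX",
                                           markers = c(a1, a2, c1, c2),
                                           generation = "F9"),
                          f9_male = list(sex = "XY",
                                         markers = c(a1, a2, c1, c2),
                                         generation = "F9")))
      steps$F8 <- st$table
      if (!st$ok) return(fail(st, "F9"))

      targets <- list()
      for (am in c(a1, a2)) for (cm in c(c1, c2)) {
        targets[[paste0("f10_", am, "_", cm, "_female")]] <-
          list(sex = "XX", markers = c(am, cm), generation = "F10")
        targets[[paste0("f10_", am, "_", cm, "_male")]] <-
          list(sex = "XY", markers = c(am, cm), generation = "F10")
      }
      st <- run_step(genome, params, "F9", "F10",
                     st$selected$f9_female$genotype,
                     st$selected$f9_male$genotype, n_per_cross, targets)
      steps$F9 <- st$table
      if (!st$ok) return(fail(st, "F10"))
      cultures <- lapply(st$selected[grep("_female$", names(st$selected))],
                         `[[`, "flavor")
      names(cultures) <- sub("^f10_(.*)_female$", "\\1", names(cultures))
      return(new_procedure_result("agoc_acos", steps, "completed",
                                  cultures = cultures, seed = seed,
                                  params = params))
    }

    # X-allosome variant: AGOC on the X, reciprocal F8 and parallel F9 crosses
    st <- run_step(genome, params, "F7a", "F8",
                   agoc_female("FIRST_ONLY"), acos_male("FIRST_ONLY"),
                   n_per_cross,
                   list(f8a_female = list(sex = "XX", markers = c(a1, c1),
                                          generation = "F8"),
                        f8a_male = list(sex = "XY", markers = c(a1, c1),
                                        generation = "F8")))
    steps$F7a <- st$table
    if (!st$ok) return(fail(st, "F8"))
    f8a_f <- st$selected$f8a_female$genotype
    f8a_m <- st$selected$f8a_male$genotype

    st <- run_step(genome, params, "F7b", "F8",
                   agoc_female("SECOND_ONLY"), acos_male("SECOND_ONLY"),
                   n_per_cross,
                   list(f8b_female = list(sex = "XX", markers = c(a2, c2),
                                          generation = "F8"),
                        f8b_male = list(sex = "XY", markers = c(a2, c2),
                                        generation = "F8")))
    steps$F7b <- st$table
    if (!st$ok) return(fail(st, "F8"))
    f8b_f <- st$selected$f8b_female$genotype
    f8b_m <- st$selected$f8b_male$genotype

    st <- run_step(genome, params, "F8a", "F9", f8a_f, f8b_m, n_per_cross,
                   list(f9_female = list(sex = "XX",
                                         markers = c(a1, a2, c1, c2),
                                         generation = "F9"),
                        f9a_male = list(sex = "XY", markers = c(a1, c1, c2),
                                        generation = "F9")))
    steps$F8a <- st$table
    if (!st$ok) return(fail(st, "F9"))
    f9_f <- st$selected$f9_female$genotype
    f9a_m <- st$selected$f9a_male$genotype

    st <- run_step(genome, params, "F8b", "F9", f8b_f, f8a_m, n_per_cross,
                   list(f9b_male = list(sex = "XY", markers = c(a2, c1, c2),
                                        generation = "F9")))
    steps$F8b <- st$table
    if (!st$ok) return(fail(st, "F9"))
    f9b_m <- st$selected$f9b_male$genotype

    f10_targets <- function(am) {
      tg <- list()
      for (cm in c(c1, c2)) {
        tg[[paste0("f10_", am, "_", cm, "_female")]] <-
          list(sex = "XX", markers = c(am, cm), generation = "F10")
        tg[[paste0("f10_", am, "_", cm, "_male")]] <-
          list(sex = "XY", markers = c(am, cm), generation = "F10")
      }
      tg
    }
    st <- run_step(genome, params, "F9a", "F10", f9_f, f9a_m, n_per_cross,
                   f10_targets(a1))
    steps$F9a <- st$table
    if (!st$ok) return(fail(st, "F10"))
    cult_a <- lapply(st$selected[grep("_female$", names(st$selected))],
                     `[[`, "flavor")

    st <- run_step(genome, params, "F9b", "F10", f9_f, f9b_m, n_per_cross,
                   f10_targets(a2))
    steps$F9b <- st$table
    if (!st$ok) return(fail(st, "F10"))
    cult_b <- lapply(st$selected[grep("_female$", names(st$selected))],
                     `[[`, "flavor")

    cultures <- c(cult_a, cult_b)
    names(cultures) <- sub("^f10_(.*)_female$", "\\1", names(cultures))
    new_procedure_result("agoc_acos", steps, "completed", cultures = cultures,
                         seed = seed, params = params)
  })
}

#' @export
print.lx_procedure_result <- function(x, ...) {
  cat("<lx_procedure_result> scheme: ", x$scheme, ", status: ", x$status,
      "\n", sep = "")
  if (x$status == "aborted")
    cat("  aborted at step ", x$aborted_step, ": ", x$reason, "\n", sep = "")
  cat("  crosses executed: ", paste(names(x$steps), collapse = ", "), "\n",
      sep = "")
  if (length(x$cultures)) {
    cat("  cultures established:\n")
    for (nm in names(x$cultures))
      cat("    ", nm, ": ", x$cultures[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' Bind the per-step score tables of a procedure into one data frame
#'
#' @param result A `lx_procedure_result`.
#' @return One score table covering every executed cross.
#' @export
procedure_score_tables <- function(result) {
  stopifnot(inherits(result, "lx_procedure_result"))
  tabs <- lapply(result$steps, function(t)
    t[, c("cross_id", "generation", "mother_class", "father_class",
          "phenotype", "count"), drop = FALSE])
  out <- do.call(rbind, c(tabs, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(cross_id = character(0), generation = character(0),
                      mother_class = character(0), father_class = character(0),
                      phenotype = character(0), count = integer(0))
  out
}
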