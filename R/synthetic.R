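# Synthetic study fixtures with known ground truth ---------------------------

#' Configuration for a synthetic multi-subline study fixture
#'
#' Describes a set of transgenic sublines, each put through the appropriate
#' mating procedure in silico, so that every pipeline stage can be tested
#' against known truth. Each subline spec is a list with fields `name`,
#' `scheme` (`"acos"` or `"agoc_acos"`), and optionally `homozygous_lethal`
#' (default `FALSE`), `agoc_chromosome` (`"ChLG2"`, `"ChLG9"` for the
#' linked case, or `"ChLGX"`; agoc_acos scheme only) and `linkage_cM`.
#'
#' @param sublines List of subline specs (see Details).
#' @param beta,completeness Cre model parameters, see [lx_params()].
#' @param n_per_cross Conceived progeny per cross.
#' @param repetitions Independent procedure repetitions per subline.
#' @param seed Master seed; per-run seeds are derived deterministically.
#' @return A `lx_fixture_config` list.
#' @export
fixture_config <- function(sublines, beta = 0.5, completeness = 1,
                           n_per_cross = 200, repetitions = 1, seed = 1) {
  stopifnot(is.list(sublines), length(sublines) >= 1)
  for (i in seq_along(sublines)) {
    sl <- sublines[[i]]
    if (is.null(sl$name)) stop("subline ", i, ": missing 'name'")
    if (is.null(sl$scheme) || !sl$scheme %in% c("acos", "agoc_acos"))
      stop("subline '", sl$name, "': scheme must be 'acos' or 'agoc_acos'")
  }
  structure(list(sublines = sublines, beta = beta,
                 completeness = completeness, n_per_cross = n_per_cross,
                 repetitions = repetitions, seed = as.integer(seed)),
            class = "lx_fixture_config")
}

# Deterministic per-run seed derived from the master seed; kept well below
# 2^31.
derive_seed <- function(master, i, rep) {
  (as.integer(master) * 1009L + i * 101L + rep) %% 1000000007L
}

#' Generate a study-shaped fixture of score tables with known truth
#'
#' Runs the configured mating procedure for every subline and repetition,
#' producing one score table per executed cross (the shape of a per-subline,
#' per-generation raw-score spreadsheet) together with truth metadata that
#' records every parameter and seed. Regeneration from the same
#' configuration is bit-identical.
#'
#' @param config A [fixture_config()].
#' @param dir Optional directory; when given, one TSV per subline and
#'   repetition plus a `truth.json` file are written there.
#' @return Invisibly, a list with `scores` (one combined data frame with
#'   `subline` and `repetition` columns), `results` (the
#'   `lx_procedure_result` objects) and `truth` (metadata list).
#' @export
generate_study_fixture <- function(config, dir = NULL) {
  stopifnot(inherits(config, "lx_fixture_config"))
  all_scores <- list()
  results <- list()
  truth_sublines <- list()
  for (i in seq_along(config$sublines)) {
    sl <- config$sublines[[i]]
    lethal <- isTRUE(sl$homozygous_lethal)
    for (rep in seq_len(config$repetitions)) {
      run_seed <- derive_seed(config$seed, i, rep)
      if (sl$scheme == "acos") {
        su <- setup_acos_fire(homozygous_lethal = lethal)
        params <- lx_params(beta = config$beta,
                            completeness = config$completeness)
        res <- run_acos_procedure(su$genome, su$acos, su$helper, params,
                                  n_per_cross = config$n_per_cross,
                                  seed = run_seed)
      } else {
        agoc_ch <- if (is.null(sl$agoc_chromosome)) "ChLG2" else
          sl$agoc_chromosome
        cM <- if (is.null(sl$linkage_cM)) 8.31 else sl$linkage_cM
        su <- setup_agoc_acos(agoc_chromosome = agoc_ch, linkage_cM = cM,
                              homozygous_lethal = c(lethal, lethal))
        params <- lx_params(beta = config$beta,
                            completeness = config$completeness,
                            linkage = su$params$linkage)
        res <- run_agoc_acos_procedure(su$genome, su$agoc, su$acos, params,
                                       n_per_cross = config$n_per_cross,
                                       seed = run_seed)
      }
      key <- paste0(sl$name, "_rep", rep)
      results[[key]] <- res
      sc <- procedure_score_tables(res)
      if (nrow(sc)) {
        sc <- cbind(subline = sl$name, repetition = rep, sc,
                    stringsAsFactors = FALSE)
        all_scores[[key]] <- sc
      }
      truth_sublines[[key]] <- list(
        subline = sl$name, repetition = rep, scheme = sl$scheme,
        homozygous_lethal = lethal, seed = run_seed, status = res$status,
        aborted_step = res$aborted_step)
    }
  }
  scores <- do.call(rbind, c(all_scores, list(make.row.names = FALSE)))
  truth <- list(master_seed = config$seed, beta = config$beta,
                completeness = config$completeness,
                n_per_cross = config$n_per_cross,
                repetitions = config$repetitions, runs = truth_sublines)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (key in names(all_scores))
      write_score_table(all_scores[[key]],
                        file.path(dir, paste0(key, ".tsv")))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(scores = scores, results = results, truth = truth))
}

#' Generate a linked-locus recombination-scoring experiment
#'
#' Simulates independent repetitions of the sibling cross used for two-point
#' linkage estimation: both parents are double heterozygotes carrying the
#' two transgene flavors in cis on a shared chromosome, with true
#' recombination fraction `r_true`. Each repetition yields one progeny score
#' table; feeding the tables through [score_recombination()] and
#' [estimate_linkage()] recovers the linkage end to end.
#'
#' @param r_true True recombination fraction in \[0, 0.5\].
#' @param n_progeny_per_rep Progeny scored per repetition.
#' @param repetitions Number of independent repetitions.
#' @param seed Integer seed.
#' @return List with `tables` (score tables, one per repetition), `cross`
#'   (the [lx_cross()] shared by all repetitions) and `truth`
#'   (`r_true`, `cM_true`, seeds).
#' @export
generate_linkage_experiment <- function(r_true, n_progeny_per_rep = 700,
                                        repetitions = 3, seed = 1) {
  stopifnot(r_true >= 0, r_true <= 0.5)
  su <- setup_agoc_acos(agoc_chromosome = "ChLG9", acos_chromosome = "ChLG9",
                        linkage_cM = centimorgan(r_true))
  cross <- agoc_acos_cross(su, "F9")
  tables <- with_seed(seed, lapply(seq_len(repetitions), function(rep)
    sample_progeny(cross, n_progeny_per_rep, generation = "F10")))
  list(tables = tables, cross = cross,
       truth = list(r_true = r_true, cM_true = centimorgan(r_true),
                    n_progeny_per_rep = n_progeny_per_rep,
                    repetitions = repetitions, seed = seed))
}
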