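# Score-table and configuration I/O ------------------------------------------

SCORE_COLUMNS <- c("cross_id", "generation", "mother_class", "father_class",
                   "phenotype", "count")

#' Write a progeny score table as TSV
#'
#' @param table A score table data frame containing at least the columns
#'   `cross_id`, `generation`, `mother_class`, `father_class`, `phenotype`,
#'   `count`; extra columns (e.g. `subline`) are preserved.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_score_table <- function(table, path) {
  missing <- setdiff(SCORE_COLUMNS, names(table))
  if (length(missing))
    stop("score table is missing column(s): ", paste(missing, collapse = ", "))
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a progeny score table from TSV
#'
#' Header-checked TSV reader for per-cross phenotype-class count tables.
#' Counts must parse as non-negative integers; violations are reported with
#' the file line number. Round-trips with [write_score_table()].
#'
#' @param path Path to a TSV file.
#' @return A data frame with the score-table columns; `count` is integer.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = TRUE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(SCORE_COLUMNS, names(df))
  if (length(missing))
    stop("malformed score table '", path, "': missing column(s) ",
         paste(missing, collapse = ", "))
  counts <- suppressWarnings(as.numeric(df$count))
  bad <- which(is.na(counts) | counts < 0 | counts != floor(counts))
  if (length(bad))
    stop("malformed score table '", path, "': invalid count '",
         df$count[bad[1]], "' at line ", bad[1] + 1L,
         " (counts must be non-negative integers)")
  df$count <- as.integer(counts)
  df
}

# Configuration ---------------------------------------------------------------

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown configuration key '", unknown[1], "' in ", where,
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  invisible(x)
}

#' Read a run configuration from YAML
#'
#' Parses and validates a structured configuration describing the genome
#' (chromosomes and constructs), model parameters, and optional simulation
#' and cross sections. Unknown keys are rejected with a message naming the
#' key. Linkage entries may give either a recombination fraction `r` or a
#' distance `cM`.
#'
#' @param path Path to a YAML file.
#' @return List with `genome` ([lx_genome()]), `params` ([lx_params()]),
#'   `simulation` (list: `n_per_cross`, `seed`, `repetitions`) and `cross`
#'   (list: `scheme`, `stage`, `homozygous_lethal`, ... or `NULL`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, c("genome", "params", "simulation", "cross", "sublines"),
             "top level")
  genome <- NULL
  if (!is.null(cfg$genome)) {
    check_keys(cfg$genome, c("chromosomes", "constructs"), "genome")
    chroms <- lapply(cfg$genome$chromosomes, function(ch) {
      check_keys(ch, c("name", "kind"), "genome/chromosomes")
      lx_chromosome(ch$name, if (is.null(ch$kind)) "autosome" else ch$kind)
    })
    cons <- lapply(cfg$genome$constructs, function(co) {
      check_keys(co, c("id", "chromosome", "position", "markers",
                       "expresses_cre", "homozygous_lethal"),
                 "genome/constructs")
      lx_construct(co$id, co$chromosome, co$position,
                   unlist(co$markers),
                   expresses_cre = isTRUE(co$expresses_cre),
                   homozygous_lethal = isTRUE(co$homozygous_lethal))
    })
    genome <- lx_genome(chroms, cons)
  }
  params <- lx_params()
  if (!is.null(cfg$params)) {
    check_keys(cfg$params, c("beta", "completeness", "linkage"), "params")
    linkage <- list()
    for (nm in names(cfg$params$linkage)) {
      entry <- cfg$params$linkage[[nm]]
      if (is.numeric(entry)) linkage[[nm]] <- entry
      else {
        check_keys(entry, c("r", "cM"), paste0("params/linkage/", nm))
        linkage[[nm]] <- if (!is.null(entry$r)) entry$r
        else recombination_fraction(entry$cM)
      }
    }
    params <- lx_params(
      beta = if (is.null(cfg$params$beta)) 0.5 else cfg$params$beta,
      completeness = if (is.null(cfg$params$completeness)) 1
      else cfg$params$completeness,
      linkage = linkage)
  }
  sim <- list(n_per_cross = 200L, seed = 1L, repetitions = 1L)
  if (!is.null(cfg$simulation)) {
    check_keys(cfg$simulation, c("n_per_cross", "seed", "repetitions"),
               "simulation")
    for (nm in names(cfg$simulation)) sim[[nm]] <- cfg$simulation[[nm]]
  }
  crs <- NULL
  if (!is.null(cfg$cross)) {
    check_keys(cfg$cross, c("scheme", "stage", "homozygous_lethal",
                            "agoc_chromosome", "linkage_cM"), "cross")
    crs <- cfg$cross
  }
  subl <- NULL
  if (!is.null(cfg$sublines)) {
    subl <- lapply(cfg$sublines, function(sl) {
      check_keys(sl, c("name", "scheme", "homozygous_lethal",
                       "agoc_chromosome", "linkage_cM"), "sublines")
      sl
    })
  }
  list(genome = genome, params = params, simulation = sim, cross = crs,
       sublines = subl)
}

# Build the cross described by a config's `cross` section (falling back on
# the canonical setups when no explicit genome is given).
config_cross <- function(cfg) {
  if (is.null(cfg$cross))
    stop("the configuration has no 'cross' section")
  sch <- cfg$cross$scheme
  stage <- cfg$cross$stage
  lethal <- isTRUE(cfg$cross$homozygous_lethal)
  if (identical(sch, "acos")) {
    su <- setup_acos_fire(homozygous_lethal = lethal)
    acos_cross(su, stage, cfg$params)
  } else if (identical(sch, "agoc_acos")) {
    agoc_ch <- if (is.null(cfg$cross$agoc_chromosome)) "ChLG2" else
      cfg$cross$agoc_chromosome
    cM <- if (is.null(cfg$cross$linkage_cM)) 8.31 else cfg$cross$linkage_cM
    su <- setup_agoc_acos(agoc_chromosome = agoc_ch, linkage_cM = cM,
                          homozygous_lethal = c(lethal, lethal))
    params <- if (length(cfg$params$linkage)) cfg$params else
      lx_params(beta = cfg$params$beta,
                completeness = cfg$params$completeness,
                linkage = su$params$linkage)
    agoc_acos_cross(su, stage, params)
  } else if (identical(sch, "hemizygote_sibling")) {
    su <- setup_acos_fire(homozygous_lethal = lethal)
    hemizygote_sibling_cross(su$genome, su$acos, params = cfg$params)
  } else {
    stop("unknown cross scheme '", sch,
         "' (expected acos, agoc_acos or hemizygote_sibling)")
  }
}
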