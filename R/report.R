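#' Carrier summary of a cohort at a qualification rule
#'
#' Counts qualifying carriers per arm and reports the carrier
#' percentages both at full precision and rounded to one decimal, the
#' reporting style of case/control screens ("2.1% versus 1.0%").
#'
#' @param cohort A cohort.
#' @param rule A [qualification_rule()].
#' @return List with the qualifying variant ids, the dominant 2x2 table,
#'   carrier fractions and one-decimal percentages per arm.
#' @export
carrier_summary <- function(cohort, rule = qualification_rule()) {
  qual <- qualify_variants(cohort, rule)
  tab <- carrier_table(cohort, qual, model = "dominant")
  n_ca <- tab[["a"]] + tab[["b"]]; n_co <- tab[["c"]] + tab[["d"]]
  list(qualifying = qual,
       table = tab,
       case_carriers = tab[["a"]], n_cases = n_ca,
       control_carriers = tab[["c"]], n_controls = n_co,
       case_fraction = tab[["a"]] / n_ca,
       control_fraction = tab[["c"]] / n_co,
       case_percent = round(100 * tab[["a"]] / n_ca, 1),
       control_percent = round(100 * tab[["c"]] / n_co, 1))
}

report_as_list <- function(report) {
  lapply(report, function(cell) {
    r <- cell$result
    list(plan = cell$plan,
         package_version = cell$package_version,
         config = list(thresholds = cell$config$thresholds,
                       model = cell$config$model,
                       classes_included = cell$config$classes_included,
                       region = cell$config$region,
                       maf_reference = cell$config$maf_reference,
                       n_permutations = cell$config$n_permutations,
                       seed = cell$config$seed,
                       control_subset = cell$config$control_subset,
                       bmi_cutoff = cell$config$bmi_cutoff),
         n_cases = r$n_cases, n_controls = r$n_controls,
         per_threshold = r$per_threshold,
         min_p = r$min_p, min_p_threshold = r$min_p_threshold,
         adjusted_p = r$adjusted_p,
         n_permutations_used = r$n_permutations_used)
  })
}

#' Write a burden report as JSON
#'
#' Serialises every analysis cell of a [run_analysis()] report —
#' resolved configuration, seed, arm sizes, per-threshold tables and
#' p-values at full precision — into a versioned JSON document
#' (`schema_version` 1).
#'
#' @param report A `"burden_report"`.
#' @param path Output path (`result.json` convention).
#' @return `path`, invisibly.
#' @export
write_burden_json <- function(report, path) {
  stopifnot(inherits(report, "burden_report"))
  doc <- list(schema_version = 1L,
              package = "vtburden",
              package_version =
                as.character(utils::packageVersion("vtburden")),
              cells = report_as_list(report))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a burden report as a flat per-threshold TSV
#'
#' One row per analysis cell and MAF threshold; p-values are printed to
#' four significant figures (full precision lives in the JSON report).
#'
#' @param report A `"burden_report"`.
#' @param path Output path (`result.tsv` convention).
#' @return `path`, invisibly.
#' @export
write_burden_tsv <- function(report, path) {
  stopifnot(inherits(report, "burden_report"))
  rows <- lapply(names(report), function(nm) {
    cell <- report[[nm]]
    pt <- cell$result$per_threshold
    data.frame(cell = nm,
               sample = cell$plan$sample,
               control_set = cell$plan$control_set,
               scope = cell$plan$scope,
               model = cell$plan$model,
               n_cases = cell$result$n_cases,
               n_controls = cell$result$n_controls,
               threshold = pt$threshold,
               n_qualifying = pt$n_qualifying,
               a = pt$a, b = pt$b, c = pt$c, d = pt$d,
               fisher_p = signif(pt$fisher_p, 4),
               min_p = signif(cell$result$min_p, 4),
               adjusted_p = signif(cell$result$adjusted_p, 4),
               n_permutations = cell$result$n_permutations_used,
               seed = if (is.null(cell$config$seed)) NA_integer_
                      else cell$config$seed)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an analysis configuration from YAML
#'
#' The YAML schema mirrors the function arguments: a `burden` block for
#' [burden_config()] (`thresholds`, `model`, `classes_included`,
#' `maf_reference`, `n_permutations`, `seed`, `control_subset`,
#' `bmi_cutoff`), an optional `plan` block (parallel lists `sample`,
#' `control_set`, `scope`, `model` for [analysis_plan()]), and an
#' optional `sim` block for [sim_config()] (`n_cases`, `n_controls`,
#' `n_sites`, `odds_ratio`, `seed`, and `maf_spectrum` with `type` and
#' the matching fields).
#'
#' @param path YAML file.
#' @return List with elements `burden`, `plan` (or `NULL`), `sim` (or
#'   `NULL`).
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  bc <- do.call(burden_config, c(y$burden, list()))
  plan <- if (!is.null(y$plan)) do.call(analysis_plan, y$plan) else NULL
  sim <- NULL
  if (!is.null(y$sim)) {
    args <- y$sim
    if (!is.null(args$maf_spectrum)) {
      ms <- args$maf_spectrum
      args$maf_spectrum <- switch(
        ms$type,
        fixed = maf_fixed(ms$value),
        uniform = maf_uniform(ms$lo, ms$hi),
        point_mixture = maf_mixture(unlist(ms$mafs), unlist(ms$weights)),
        stop("unknown maf_spectrum type in config: ", ms$type,
             call. = FALSE))
    }
    sim <- do.call(sim_config, args)
  }
  list(burden = bc, plan = plan, sim = sim)
}
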