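#' Build an analysis plan
#'
#' A plan is a table of analysis cells, each a combination of sample
#' (original, replication, or the merged combined sample), control set
#' (all controls or the normal-weight subset), scope (whole gene or a
#' named protein region) and genetic model. [run_analysis()] executes
#' one permutation-adjusted variable-threshold scan per cell.
#'
#' @param sample,control_set,scope,model Character vectors, recycled to
#'   a common length. `sample` in `original`/`replication`/`combined`;
#'   `control_set` in `all`/`normal_weight`; `scope` either
#'   `"whole_gene"` or the name of a region in the regions table passed
#'   to [run_analysis()]; `model` in `dominant`/`additive`.
#' @return data.frame of class `"analysis_plan"`.
#' @export
analysis_plan <- function(sample = "original", control_set = "all",
                          scope = "whole_gene", model = "dominant") {
  n <- max(length(sample), length(control_set), length(scope),
           length(model))
  plan <- data.frame(sample = rep_len(sample, n),
                     control_set = rep_len(control_set, n),
                     scope = rep_len(scope, n),
                     model = rep_len(model, n))
  bad <- setdiff(unique(plan$sample),
                 c("original", "replication", "combined"))
  if (length(bad)) stop("unknown plan sample: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(unique(plan$control_set), c("all", "normal_weight"))
  if (length(bad)) stop("unknown plan control_set: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(plan$model), c("dominant", "additive"))
  if (length(bad)) stop("unknown plan model: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  class(plan) <- c("analysis_plan", "data.frame")
  plan
}

select_sample <- function(cohorts, sample) {
  labels <- c("original", "replication")
  pick <- function(lab) {
    if (!is.null(cohorts[[lab]])) return(cohorts[[lab]])
    stop("analysis plan requests the '", lab, "' sample but no cohort ",
         "with that label was supplied", call. = FALSE)
  }
  if (sample == "combined") {
    merge_cohorts(pick("original"), pick("replication"))
  } else {
    pick(sample)
  }
}

#' Run a plan of burden analyses
#'
#' Executes one [permutation_adjusted_p()] scan per plan cell and
#' returns the results with full provenance (resolved configuration,
#' seed, arm sizes, package version). The combined sample is formed by
#' [merge_cohorts()], after which all sample MAFs are recomputed on the
#' merged individual set by the qualification step itself.
#'
#' @param cohorts Either a single cohort (treated as `original`) or a
#'   named list with elements `original` and/or `replication`.
#' @param plan An [analysis_plan()].
#' @param config A [burden_config()] template; each cell overrides its
#'   `model`, `control_subset` and `region` fields.
#' @param regions data.frame from [read_regions()]; required when any
#'   plan cell names a region scope.
#' @return List of class `"burden_report"`: one element per plan cell,
#'   each holding `plan` (the cell), `config` (resolved) and `result`
#'   (the `burden_result`).
#' @export
run_analysis <- function(cohorts, plan = analysis_plan(),
                         config = burden_config(), regions = NULL) {
  stopifnot(inherits(plan, "analysis_plan"),
            inherits(config, "burden_config"))
  if (inherits(cohorts, "cohort")) cohorts <- list(original = cohorts)
  out <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    cell <- plan[i, ]
    cfg <- config
    cfg$model <- cell$model
    cfg$control_subset <- cell$control_set
    if (cell$scope != "whole_gene") {
      if (is.null(regions)) {
        stop("plan cell ", i, " requests region '", cell$scope,
             "' but no regions table was supplied", call. = FALSE)
      }
      cfg$region <- lookup_region(regions, cell$scope)
    } else {
      cfg$region <- NULL
    }
    res <- permutation_adjusted_p(select_sample(cohorts, cell$sample), cfg)
    out[[i]] <- list(plan = as.list(cell), config = cfg, result = res,
                     package_version =
                       as.character(utils::packageVersion("vtburden")))
  }
  names(out) <- sprintf("%s.%s.%s.%s", plan$sample, plan$control_set,
                        plan$scope, plan$model)
  class(out) <- "burden_report"
  out
}

#' @export
print.burden_report <- function(x, ...) {
  cat(sprintf("<burden_report> %d analysis cell(s)\n", length(x)))
  for (nm in names(x)) {
    r <- x[[nm]]$result
    cat(sprintf("  %-45s min p = %.4g, adjusted p = %.4g\n",
                nm, r$min_p, r$adjusted_p))
  }
  invisible(x)
}
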