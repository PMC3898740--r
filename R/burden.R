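#' Configuration of a variable-threshold burden analysis
#'
#' Bundles the MAF threshold ladder, the genetic model, the
#' qualification template (classes, optional region, MAF reference), the
#' permutation count and seed, and the control-arm subset rule.
#'
#' @param thresholds Strictly decreasing MAF thresholds in (0, 0.5];
#'   default `c(0.005, 0.001, 0.0005)`, the ladder scanned by the
#'   variable-threshold statistic.
#' @param model `"dominant"` (carrier counting: an individual with at
#'   least one qualifying alternate allele counts once) or `"additive"`
#'   (allele counting: heterozygote 1, homozygote 2, summed over
#'   qualifying variants).
#' @param classes_included Functional classes that qualify; default
#'   frameshift, nonsense, missense.
#' @param region Optional protein region `list(region_name, start, end)`
#'   restricting qualification; `NULL` = whole gene.
#' @param maf_reference `"pooled"` (default) or `"controls_only"`; see
#'   [qualification_rule()].
#' @param n_permutations Number of case/control label permutations used
#'   to adjust the minimum p-value for threshold selection; default 10000.
#' @param seed Integer RNG seed for the permutations (`NULL` = current
#'   RNG state).
#' @param control_subset `"all"` or `"normal_weight"` (drop controls with
#'   BMI above `bmi_cutoff` before analysis).
#' @param bmi_cutoff BMI cutoff (kg/m^2) for the normal-weight control
#'   subset; default 30.
#' @return A `"burden_config"` list.
#' @export
burden_config <- function(thresholds = c(0.005, 0.001, 0.0005),
                          model = c("dominant", "additive"),
                          classes_included = c("frameshift", "nonsense",
                                               "missense"),
                          region = NULL,
                          maf_reference = c("pooled", "controls_only"),
                          n_permutations = 10000L,
                          seed = NULL,
                          control_subset = c("all", "normal_weight"),
                          bmi_cutoff = 30) {
  model <- match.arg(model)
  maf_reference <- match.arg(maf_reference)
  control_subset <- match.arg(control_subset)
  stopifnot(is.numeric(thresholds), length(thresholds) >= 1,
            all(thresholds > 0), all(thresholds <= 0.5))
  if (length(thresholds) > 1 && any(diff(thresholds) >= 0)) {
    stop("thresholds must be strictly decreasing", call. = FALSE)
  }
  n_permutations <- as.integer(n_permutations)
  stopifnot(n_permutations >= 1L)
  # reuse the rule constructor for class/region validation
  qualification_rule(classes_included, maf_threshold = thresholds[1],
                     region = region, maf_reference = maf_reference)
  structure(list(thresholds = thresholds, model = model,
                 classes_included = classes_included, region = region,
                 maf_reference = maf_reference,
                 n_permutations = n_permutations, seed = seed,
                 control_subset = control_subset, bmi_cutoff = bmi_cutoff),
            class = "burden_config")
}

apply_control_subset <- function(cohort, config) {
  if (config$control_subset == "normal_weight") {
    normal_weight_controls(cohort, config$bmi_cutoff)
  } else {
    cohort
  }
}

check_arms <- function(cohort) {
  if (n_cases(cohort) < 1L || n_controls(cohort) < 1L) {
    stop("degenerate cohort: need at least 1 case and 1 control ",
         "(after any control-subset filtering)", call. = FALSE)
  }
}

#' Collapse qualifying variants into a carrier 2x2 table
#'
#' Under the dominant model the units are individuals: `a` is the number
#' of distinct cases carrying at least one qualifying variant (an
#' individual with several qualifying variants, or a homozygous genotype,
#' counts once). Under the additive model the units are alleles: `a` is
#' the total qualifying allele count over cases and the case margin is
#' `2 * n_cases`.
#'
#' @param cohort A cohort.
#' @param qualifying Character vector of qualifying variant ids (subset
#'   of the cohort's variants).
#' @param model `"dominant"` or `"additive"`.
#' @param control_subset `"all"` or `"normal_weight"`.
#' @param bmi_cutoff BMI cutoff for the normal-weight subset.
#' @return Named integer vector `c(a, b, c, d)` with attribute `model`.
#' @export
carrier_table <- function(cohort, qualifying,
                          model = c("dominant", "additive"),
                          control_subset = c("all", "normal_weight"),
                          bmi_cutoff = 30) {
  model <- match.arg(model)
  control_subset <- match.arg(control_subset)
  stopifnot(inherits(cohort, "cohort"))
  unknown <- setdiff(qualifying, cohort$variants$variant_id)
  if (length(unknown)) {
    stop("qualifying set contains unknown variant_id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  if (control_subset == "normal_weight") {
    cohort <- normal_weight_controls(cohort, bmi_cutoff)
  }
  check_arms(cohort)
  M <- unit_matrix(cohort, list(qualifying), model)
  table_from_units(M[, 1], cohort$individuals$status == "case", model)
}

# N x T matrix of per-individual units per qualification set:
# dominant -> 0/1 carrier indicator; additive -> summed allele counts.
unit_matrix <- function(cohort, qual_sets, model) {
  ids <- cohort$individuals$individual_id
  gt <- cohort$genotypes
  gi <- match(gt$individual_id, ids)
  M <- matrix(0L, nrow = length(ids), ncol = length(qual_sets))
  for (t in seq_along(qual_sets)) {
    sel <- gt$variant_id %in% qual_sets[[t]]
    if (!any(sel)) next
    cnt <- tabulate(rep.int(gi[sel], gt$allele_count[sel]),
                    nbins = length(ids))
    M[, t] <- if (model == "dominant") as.integer(cnt > 0L) else cnt
  }
  M
}

table_from_units <- function(units, is_case, model) {
  nc <- sum(is_case); nk <- sum(!is_case)
  mult <- if (model == "dominant") 1L else 2L
  a <- if (model == "dominant") sum(units[is_case] > 0L) else
    sum(units[is_case])
  cc <- if (model == "dominant") sum(units[!is_case] > 0L) else
    sum(units[!is_case])
  if (a > mult * nc || cc > mult * nk) {
    stop("additive allele count exceeds the 2N allele margin ",
         "(too many multi-variant carriers for the allele-table model)",
         call. = FALSE)
  }
  out <- c(a = as.integer(a), b = as.integer(mult * nc - a),
           c = as.integer(cc), d = as.integer(mult * nk - cc))
  attr(out, "model") <- model
  out
}

# Shared machinery of vt_scan and permutation_adjusted_p: the analysed
# cohort, per-threshold qualifying sets, the unit matrix, the Fisher
# p-value lookup tables keyed by the case-unit count a, and the observed
# per-threshold results.
vt_machine <- function(cohort, config) {
  analyzed <- apply_control_subset(cohort, config)
  check_arms(analyzed)
  qual_sets <- lapply(config$thresholds, function(th) {
    qualify_variants(analyzed,
                     qualification_rule(config$classes_included,
                                        maf_threshold = th,
                                        region = config$region,
                                        maf_reference = config$maf_reference))
  })
  M <- unit_matrix(analyzed, qual_sets, config$model)
  is_case <- analyzed$individuals$status == "case"
  mult <- if (config$model == "dominant") 1L else 2L
  N_units <- mult * nrow(M)
  k_units <- mult * sum(is_case)
  K <- if (config$model == "dominant") colSums(M > 0L) else colSums(M)
  luts <- lapply(K, function(Kt) fisher_margin_pvals(N_units, Kt, k_units))
  obs <- vapply(seq_along(qual_sets), function(t) {
    tab <- table_from_units(M[, t], is_case, config$model)
    c(tab, p = luts[[t]]$p[tab[["a"]] - luts[[t]]$lo + 1L])
  }, numeric(5))
  per_threshold <- data.frame(threshold = config$thresholds,
                              n_qualifying = lengths(qual_sets),
                              a = as.integer(obs[1, ]),
                              b = as.integer(obs[2, ]),
                              c = as.integer(obs[3, ]),
                              d = as.integer(obs[4, ]),
                              fisher_p = obs[5, ])
  list(analyzed = analyzed, qual_sets = qual_sets, M = M,
       is_case = is_case, luts = luts, per_threshold = per_threshold)
}

new_burden_result <- function(machine, config, adjusted_p = NA_real_,
                              n_permutations_used = 0L) {
  pt <- machine$per_threshold
  i <- which.min(pt$fisher_p)  # ties break toward the largest threshold
  structure(list(per_threshold = pt,
                 min_p = pt$fisher_p[i],
                 min_p_threshold = pt$threshold[i],
                 adjusted_p = adjusted_p,
                 n_permutations_used = n_permutations_used,
                 seed = config$seed,
                 model = config$model,
                 control_subset = config$control_subset,
                 maf_reference = config$maf_reference,
                 region = config$region,
                 n_cases = sum(machine$is_case),
                 n_controls = sum(!machine$is_case)),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("<burden_result> %s model, %d cases / %d controls%s\n",
              x$model, x$n_cases, x$n_controls,
              if (!is.null(x$region))
                paste0(", region ", x$region$region_name) else ""))
  print(x$per_threshold, row.names = FALSE)
  cat(sprintf("min p = %.4g at threshold %g", x$min_p, x$min_p_threshold))
  if (!is.na(x$adjusted_p)) {
    cat(sprintf("; permutation-adjusted p = %.4g (B = %d)",
                x$adjusted_p, x$n_permutations_used))
  }
  cat("\n")
  invisible(x)
}

#' Variable-threshold scan: minimum Fisher p over a MAF ladder
#'
#' For each MAF threshold in the ladder, qualifies variants on the
#' analysed sample, collapses them into the carrier (or allele) 2x2
#' table, and computes the exact two-sided Fisher p-value; the smallest
#' of the per-threshold p-values is the variable-threshold statistic.
#' A threshold with no qualifying variants yields the degenerate table
#' `(0, cases, 0, controls)` and p = 1. Ties in the minimum are broken
#' toward the largest (first) threshold.
#'
#' Because the best threshold is chosen after seeing the data, `min_p`
#' is not a valid p-value on its own; see [permutation_adjusted_p()].
#'
#' @param cohort A cohort.
#' @param config A [burden_config()].
#' @return A `"burden_result"` with `adjusted_p = NA`.
#' @export
vt_scan <- function(cohort, config = burden_config()) {
  stopifnot(inherits(cohort, "cohort"), inherits(config, "burden_config"))
  new_burden_result(vt_machine(cohort, config), config)
}

#' Permutation adjustment of the variable-threshold statistic
#'
#' Recomputes the full threshold scan under `B` uniform random
#' case/control relabelings (preserving the numbers of cases and
#' controls within the analysed individual set) and reports
#' `adjusted_p = (1 + #\{permuted min_p <= observed min_p\}) / (1 + B)`,
#' the standard estimator that includes the observed labeling and
#' counts ties as extreme; its floor is `1 / (B + 1)`.
#'
#' With the default pooled MAF reference the qualifying sets are
#' invariant under relabeling, so each permutation only redistributes
#' carrier units between the arms and the per-threshold p-values come
#' from precomputed hypergeometric lookup tables. With
#' `maf_reference = "controls_only"` qualification depends on the labels
#' and is recomputed inside every permutation.
#'
#' @param cohort A cohort with at least one case and one control.
#' @param config A [burden_config()]; `n_permutations` and `seed` control
#'   the Monte-Carlo sampling.
#' @return A `"burden_result"` with `adjusted_p` set.
#' @export
permutation_adjusted_p <- function(cohort, config = burden_config()) {
  stopifnot(inherits(cohort, "cohort"), inherits(config, "burden_config"))
  machine <- vt_machine(cohort, config)
  obs <- new_burden_result(machine, config)
  B <- config$n_permutations
  if (!is.null(config$seed)) set.seed(config$seed)
  N <- nrow(machine$M)
  ncase <- sum(machine$is_case)
  # ties at the observed statistic count as extreme; a hair of relative
  # slack guards against float noise between identical computations
  cut <- obs$min_p * (1 + 1e-12)
  if (config$maf_reference == "pooled") {
    luts <- machine$luts
    M <- machine$M
    model <- config$model
    r <- 0L
    for (b in seq_len(B)) {
      idx <- sample.int(N, ncase)
      a <- if (model == "dominant") colSums(M[idx, , drop = FALSE] > 0L)
           else colSums(M[idx, , drop = FALSE])
      pm <- min(vapply(seq_along(luts), function(t)
        luts[[t]]$p[a[t] - luts[[t]]$lo + 1L], numeric(1)))
      if (pm <= cut) r <- r + 1L
    }
  } else {
    # labels are permuted within the analysed set (after any BMI
    # exclusion), so the inner scans must not re-apply the subset rule
    analyzed <- machine$analyzed
    inner <- config
    inner$control_subset <- "all"
    r <- 0L
    for (b in seq_len(B)) {
      perm <- analyzed
      perm$individuals$status <- sample(perm$individuals$status)
      pm <- min(vt_machine(perm, inner)$per_threshold$fisher_p)
      if (pm <= cut) r <- r + 1L
    }
  }
  obs$adjusted_p <- (1 + r) / (1 + B)
  obs$n_permutations_used <- B
  obs
}
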