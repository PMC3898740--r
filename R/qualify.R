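#' Qualification rule for rare coding variants
#'
#' A variant qualifies when its functional class is in
#' `classes_included`, its protein position falls inside `region` (when a
#' region is set; inclusive on both ends), and its sample minor-allele
#' frequency is strictly below `maf_threshold`. The MAF is computed on
#' the sample being analysed: pooled cases + controls by default (which
#' makes qualification invariant under case/control label permutation),
#' or on controls only.
#'
#' @param classes_included Character vector of functional classes; default
#'   the protein-altering classes frameshift, nonsense, missense.
#' @param maf_threshold Frequency threshold in (0, 0.5]; strict `<`.
#' @param region Optional `list(region_name, start, end)` (see
#'   [read_regions()]); `NULL` for whole-gene analysis.
#' @param maf_reference `"pooled"` or `"controls_only"`.
#' @return A `"qualification_rule"` list.
#' @export
qualification_rule <- function(classes_included = c("frameshift", "nonsense",
                                                    "missense"),
                               maf_threshold = 0.005,
                               region = NULL,
                               maf_reference = c("pooled", "controls_only")) {
  maf_reference <- match.arg(maf_reference)
  classes_included <- match.arg(classes_included, FUNC_CLASSES,
                                several.ok = TRUE)
  if (!length(classes_included)) {
    stop("classes_included must be non-empty", call. = FALSE)
  }
  stopifnot(is.numeric(maf_threshold), length(maf_threshold) == 1,
            maf_threshold > 0, maf_threshold <= 0.5)
  if (!is.null(region)) {
    stopifnot(is.list(region), all(c("start", "end") %in% names(region)))
  }
  structure(list(classes_included = classes_included,
                 maf_threshold = maf_threshold,
                 region = region,
                 maf_reference = maf_reference),
            class = "qualification_rule")
}

maf_reference_ids <- function(cohort, reference) {
  ind <- cohort$individuals
  if (reference == "controls_only") {
    ind$individual_id[ind$status == "control"]
  } else {
    ind$individual_id
  }
}

# Alternate-allele frequency of every variant in one pass:
# sum(allele_count over reference individuals) / (2 * n_reference).
variant_mafs <- function(cohort, reference = "pooled") {
  ids <- maf_reference_ids(cohort, reference)
  if (!length(ids)) {
    stop("MAF reference set is empty (no ",
         if (reference == "controls_only") "controls" else "individuals",
         " in cohort)", call. = FALSE)
  }
  gt <- cohort$genotypes
  gt <- gt[gt$individual_id %in% ids, , drop = FALSE]
  counts <- integer(nrow(cohort$variants))
  if (nrow(gt)) {
    vi <- match(gt$variant_id, cohort$variants$variant_id)
    counts <- tabulate(rep.int(vi, gt$allele_count),
                       nbins = nrow(cohort$variants))
  }
  stats::setNames(counts / (2 * length(ids)), cohort$variants$variant_id)
}

#' Sample minor-allele frequency of one variant
#'
#' Computed as the alternate-allele count over `2 * N` reference
#' chromosomes, where the reference set is the pooled analysed sample or
#' its control arm. With a pooled reference the value does not depend on
#' how case/control labels are assigned within the same individuals.
#'
#' @param cohort A cohort.
#' @param variant_id Variant identifier present in the cohort.
#' @param reference `"pooled"` (default) or `"controls_only"`.
#' @return Frequency in `[0, 1]`.
#' @examples
#' # 1 het carrier among 1000 pooled individuals -> 1/2000
#' @export
compute_sample_maf <- function(cohort, variant_id,
                               reference = c("pooled", "controls_only")) {
  reference <- match.arg(reference)
  stopifnot(inherits(cohort, "cohort"))
  if (!variant_id %in% cohort$variants$variant_id) {
    stop("unknown variant_id: ", variant_id, call. = FALSE)
  }
  unname(variant_mafs(cohort, reference)[variant_id])
}

#' Select the qualifying variants of a cohort under a rule
#'
#' Applies the three filters of [qualification_rule()] — functional
#' class, optional protein region (inclusive bounds), and strict sample
#' MAF threshold — and returns the ids of the variants passing all of
#' them.
#'
#' @param cohort A cohort.
#' @param rule A [qualification_rule()].
#' @return Character vector of qualifying `variant_id`s (possibly empty).
#' @export
qualify_variants <- function(cohort, rule) {
  stopifnot(inherits(cohort, "cohort"), inherits(rule, "qualification_rule"))
  var <- cohort$variants
  keep <- var$func_class %in% rule$classes_included
  if (!is.null(rule$region)) {
    keep <- keep & var$protein_pos >= rule$region$start &
      var$protein_pos <= rule$region$end
  }
  mafs <- variant_mafs(cohort, rule$maf_reference)
  keep <- keep & mafs < rule$maf_threshold
  var$variant_id[keep]
}
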