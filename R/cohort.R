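#' @keywords internal
"_PACKAGE"

FUNC_CLASSES <- c("frameshift", "nonsense", "missense", "synonymous", "other")

#' Construct a case/control cohort
#'
#' A cohort bundles three tables: one row per individual (case/control
#' status, cohort label, optional BMI), one row per coding variant
#' (protein position on the 950-aa isoform, functional class), and one row
#' per non-reference genotype (allele count 1 = heterozygous, 2 =
#' homozygous alternate; absence of a row means zero copies). Individuals
#' with no genotype rows are ordinary non-carriers and are retained.
#'
#' @param individuals data.frame with columns `individual_id`, `status`
#'   (`"case"`/`"control"`), `cohort_label` (`"original"`/`"replication"`),
#'   and optionally `bmi` (kg/m^2, `NA` allowed).
#' @param variants data.frame with columns `variant_id`, `protein_pos`
#'   (1-based residue index, >= 1), `func_class` (one of `"frameshift"`,
#'   `"nonsense"`, `"missense"`, `"synonymous"`, `"other"`), optionally
#'   `notes`.
#' @param genotypes data.frame with columns `individual_id`, `variant_id`,
#'   `allele_count` (1 or 2). May have zero rows.
#' @return An object of class `"cohort"`.
#' @examples
#' ind <- data.frame(individual_id = c("a", "b"),
#'                   status = c("case", "control"),
#'                   cohort_label = "original", bmi = c(45, 24))
#' var <- data.frame(variant_id = "R684C", protein_pos = 684,
#'                   func_class = "missense")
#' gt <- data.frame(individual_id = "a", variant_id = "R684C",
#'                  allele_count = 1L)
#' cohort(ind, var, gt)
#' @export
cohort <- function(individuals, variants, genotypes) {
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  genotypes <- as.data.frame(genotypes, stringsAsFactors = FALSE)
  if (!"bmi" %in% names(individuals)) individuals$bmi <- NA_real_
  if (!"notes" %in% names(variants)) variants$notes <- ""
  individuals$bmi <- as.numeric(individuals$bmi)
  variants$protein_pos <- as.integer(variants$protein_pos)
  if (nrow(genotypes)) {
    genotypes$allele_count <- as.integer(genotypes$allele_count)
  } else {
    genotypes <- data.frame(individual_id = character(),
                            variant_id = character(),
                            allele_count = integer())
  }
  obj <- structure(list(individuals = individuals,
                        variants = variants,
                        genotypes = genotypes),
                   class = "cohort")
  validate_cohort(obj)
}

#' Validate a cohort object
#'
#' Checks every structural invariant of the data model: required columns,
#' unique identifiers, status/cohort/functional-class enums, protein
#' positions >= 1, allele counts in \{1, 2\}, unique
#' (individual, variant) genotype pairs, and referential integrity of
#' genotype rows against the individual and variant tables.
#'
#' @param x A `"cohort"` object.
#' @return `x`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  ind <- x$individuals; var <- x$variants; gt <- x$genotypes
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s table is missing column(s): %s",
                   what, paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  need(ind, c("individual_id", "status", "cohort_label"), "individuals")
  need(var, c("variant_id", "protein_pos", "func_class"), "variants")
  need(gt, c("individual_id", "variant_id", "allele_count"), "genotypes")

  if (anyDuplicated(ind$individual_id)) {
    stop("duplicate individual_id in individuals table", call. = FALSE)
  }
  bad <- setdiff(unique(ind$status), c("case", "control"))
  if (length(bad)) {
    stop("invalid status value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(ind$cohort_label), c("original", "replication"))
  if (length(bad)) {
    stop("invalid cohort_label value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(ind$bmi) & ind$bmi < 0)) {
    stop("negative bmi in individuals table", call. = FALSE)
  }

  if (anyDuplicated(var$variant_id)) {
    stop("duplicate variant_id in variants table", call. = FALSE)
  }
  if (any(is.na(var$protein_pos) | var$protein_pos < 1L)) {
    stop("protein_pos must be an integer >= 1", call. = FALSE)
  }
  bad <- setdiff(unique(var$func_class), FUNC_CLASSES)
  if (length(bad)) {
    stop("invalid func_class value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  if (nrow(gt)) {
    if (!all(gt$allele_count %in% c(1L, 2L))) {
      stop("allele_count must be 1 (het) or 2 (hom); absence means 0",
           call. = FALSE)
    }
    if (anyDuplicated(gt[c("individual_id", "variant_id")])) {
      stop("duplicate (individual_id, variant_id) genotype entry",
           call. = FALSE)
    }
    unk <- setdiff(gt$individual_id, ind$individual_id)
    if (length(unk)) {
      stop("genotype references unknown individual_id: ",
           paste(utils::head(unk, 5), collapse = ", "), call. = FALSE)
    }
    unk <- setdiff(gt$variant_id, var$variant_id)
    if (length(unk)) {
      stop("genotype references unknown variant_id: ",
           paste(utils::head(unk, 5), collapse = ", "), call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  n_case <- sum(x$individuals$status == "case")
  n_ctrl <- sum(x$individuals$status == "control")
  cat(sprintf("<cohort> %d cases / %d controls; %d variants; %d genotype entries\n",
              n_case, n_ctrl, nrow(x$variants), nrow(x$genotypes)))
  cat("  cohort labels:",
      paste(sort(unique(x$individuals$cohort_label)), collapse = ", "), "\n")
  invisible(x)
}

#' Arm sizes of a cohort
#'
#' @param x A cohort.
#' @return Integer count of case (resp. control) individuals.
#' @export
n_cases <- function(x) sum(x$individuals$status == "case")

#' @rdname n_cases
#' @export
n_controls <- function(x) sum(x$individuals$status == "control")

#' Restrict a cohort to a subset of individuals
#'
#' Drops genotype rows of removed individuals; the variant table is kept
#' intact (a variant with no remaining carriers simply has sample MAF 0).
#'
#' @param x A cohort.
#' @param keep Logical vector along `x$individuals`, or character vector of
#'   individual ids to keep.
#' @return A cohort.
#' @export
subset_cohort <- function(x, keep) {
  stopifnot(inherits(x, "cohort"))
  if (is.character(keep)) keep <- x$individuals$individual_id %in% keep
  stopifnot(is.logical(keep), length(keep) == nrow(x$individuals))
  ind <- x$individuals[keep, , drop = FALSE]
  gt <- x$genotypes[x$genotypes$individual_id %in% ind$individual_id, ,
                    drop = FALSE]
  rownames(ind) <- NULL; rownames(gt) <- NULL
  cohort(ind, x$variants, gt)
}

#' Restrict the control arm to normal-weight individuals
#'
#' Removes controls whose BMI exceeds `bmi_cutoff` (population controls
#' with BMI > 30 in the default analysis), mirroring the exclusion of
#' obese population controls from the comparison arm. Overweight controls
#' (25-30 kg/m^2) remain. Controls with missing BMI are removed because
#' the condition cannot be verified. Cases are always kept.
#'
#' @param x A cohort.
#' @param bmi_cutoff Controls with `bmi > bmi_cutoff` (kg/m^2) are dropped;
#'   default 30.
#' @return A cohort.
#' @export
normal_weight_controls <- function(x, bmi_cutoff = 30) {
  stopifnot(inherits(x, "cohort"))
  ind <- x$individuals
  keep <- ind$status == "case" |
    (!is.na(ind$bmi) & ind$bmi <= bmi_cutoff)
  subset_cohort(x, keep)
}

#' Classify BMI into weight classes
#'
#' @param bmi Numeric vector of BMI values (kg/m^2); `NA` allowed.
#' @return Character vector: `"normal"` (< 25), `"overweight"` (25-30),
#'   `"obese"` (> 30), `NA` where BMI is missing.
#' @export
weight_class <- function(bmi) {
  out <- ifelse(bmi > 30, "obese", ifelse(bmi >= 25, "overweight", "normal"))
  out[is.na(bmi)] <- NA_character_
  out
}

#' Merge two cohorts
#'
#' Forms the union cohort for a combined analysis. Individual ids must be
#' disjoint; variants colliding on `variant_id` must agree on
#' `protein_pos` and `func_class`. Sample MAFs are a property of the
#' sample being tested, so any qualification run on the merged cohort
#' recomputes them on the merged individual set.
#'
#' @param a,b Cohorts.
#' @return The merged cohort.
#' @export
merge_cohorts <- function(a, b) {
  stopifnot(inherits(a, "cohort"), inherits(b, "cohort"))
  if (nrow(b$individuals) == 0 && nrow(b$genotypes) == 0) {
    # merging in an empty cohort: identity up to new variant annotations
    return(merge_variant_tables_only(a, b))
  }
  clash <- intersect(a$individuals$individual_id, b$individuals$individual_id)
  if (length(clash)) {
    stop("cannot merge cohorts: individual_id collision(s): ",
         paste(utils::head(clash, 5), collapse = ", "), call. = FALSE)
  }
  var <- merge_variant_tables(a$variants, b$variants)
  ind <- rbind(a$individuals[names(a$individuals)],
               b$individuals[names(a$individuals)])
  gt <- rbind(a$genotypes, b$genotypes)
  rownames(ind) <- NULL; rownames(gt) <- NULL
  cohort(ind, var, gt)
}

merge_variant_tables_only <- function(a, b) {
  cohort(a$individuals, merge_variant_tables(a$variants, b$variants),
         a$genotypes)
}

merge_variant_tables <- function(va, vb) {
  shared <- intersect(va$variant_id, vb$variant_id)
  if (length(shared)) {
    ia <- va[match(shared, va$variant_id), ]
    ib <- vb[match(shared, vb$variant_id), ]
    bad <- shared[ia$protein_pos != ib$protein_pos |
                    ia$func_class != ib$func_class]
    if (length(bad)) {
      stop("cannot merge cohorts: conflicting annotation for variant(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  out <- rbind(va, vb[!vb$variant_id %in% shared, names(va), drop = FALSE])
  rownames(out) <- NULL
  out
}
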