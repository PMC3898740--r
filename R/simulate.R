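#' MAF spectrum specifications for the cohort simulator
#'
#' `maf_fixed(q)` gives every site the same baseline frequency;
#' `maf_uniform(lo, hi)` draws each site's frequency uniformly;
#' `maf_mixture(mafs, weights)` draws from a discrete set of
#' frequencies. All frequencies must lie in (0, 0.5).
#'
#' @param q,lo,hi,mafs Baseline alternate-allele frequencies.
#' @param weights Mixture weights; normalised to sum to 1.
#' @return A `"maf_spectrum"` list.
#' @export
maf_fixed <- function(q) {
  stopifnot(q > 0, q < 0.5)
  structure(list(type = "fixed", value = q), class = "maf_spectrum")
}

#' @rdname maf_fixed
#' @export
maf_uniform <- function(lo, hi) {
  stopifnot(lo > 0, hi < 0.5, lo <= hi)
  structure(list(type = "uniform", lo = lo, hi = hi),
            class = "maf_spectrum")
}

#' @rdname maf_fixed
#' @export
maf_mixture <- function(mafs, weights = rep(1, length(mafs))) {
  stopifnot(length(mafs) == length(weights), all(mafs > 0), all(mafs < 0.5),
            all(weights >= 0), sum(weights) > 0)
  structure(list(type = "point_mixture", mafs = mafs,
                 weights = weights / sum(weights)),
            class = "maf_spectrum")
}

draw_site_mafs <- function(spectrum, n) {
  switch(spectrum$type,
         fixed = rep(spectrum$value, n),
         uniform = stats::runif(n, spectrum$lo, spectrum$hi),
         point_mixture = sample(spectrum$mafs, n, replace = TRUE,
                                prob = spectrum$weights),
         stop("unknown maf_spectrum type: ", spectrum$type, call. = FALSE))
}

#' Configuration of the synthetic case/control cohort generator
#'
#' Defaults emulate the study design the analysis targets: a single-gene
#' screen of 2,101 severely obese cases against 1,536 population
#' controls, ~30 rare coding sites whose baseline frequencies straddle
#' the qualification ladder \{0.005, 0.001, 0.0005\}, a
#' missense-dominated class mix, and a per-site allele-scale
#' case-enrichment odds ratio of 2 (matching the roughly twofold
#' case/control carrier-rate contrast of such screens).
#'
#' @param n_cases,n_controls Arm sizes.
#' @param n_sites Number of variant sites.
#' @param maf_spectrum A [maf_fixed()]/[maf_uniform()]/[maf_mixture()]
#'   object; the default mixture puts most mass on very rare sites with
#'   a small common tail so every threshold of the ladder is populated.
#' @param class_probs Named probability vector over functional classes
#'   (must sum to 1 within 1e-12).
#' @param region_layout data.frame with columns `region_name`, `start`,
#'   `end`, `weight`: protein intervals and the probability of placing a
#'   site in each. Default: one 950-residue gene body.
#' @param odds_ratio Case enrichment applied to each site's allele odds:
#'   the case allele frequency solves
#'   `q'/(1-q') = odds_ratio * q/(1-q)`.
#' @param bmi_mean_controls,bmi_sd_controls Control BMI distribution
#'   (normal, truncated to \[15, 45\] kg/m^2); cases are drawn obese
#'   (truncated normal above the BMI-30 cutoff).
#' @param cohort_label Label stamped on every simulated individual.
#' @param seed Integer seed making the draw reproducible.
#' @return A `"sim_config"` list.
#' @export
sim_config <- function(n_cases = 2101L, n_controls = 1536L, n_sites = 30L,
                       maf_spectrum = maf_mixture(
                         c(2e-4, 5e-4, 1e-3, 5e-3),
                         c(0.60, 0.20, 0.15, 0.05)),
                       class_probs = c(frameshift = 0.05, nonsense = 0.05,
                                       missense = 0.70, synonymous = 0.20),
                       region_layout = data.frame(region_name = "gene",
                                                  start = 1L, end = 950L,
                                                  weight = 1),
                       odds_ratio = 2,
                       bmi_mean_controls = 26, bmi_sd_controls = 4,
                       cohort_label = "original",
                       seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1, n_sites >= 1,
            inherits(maf_spectrum, "maf_spectrum"), odds_ratio > 0)
  if (is.null(names(class_probs)) ||
      !all(names(class_probs) %in% FUNC_CLASSES)) {
    stop("class_probs must be named with functional classes", call. = FALSE)
  }
  if (abs(sum(class_probs) - 1) > 1e-12) {
    stop("class_probs must sum to 1", call. = FALSE)
  }
  stopifnot(all(c("region_name", "start", "end", "weight") %in%
                  names(region_layout)),
            all(region_layout$start >= 1),
            all(region_layout$end >= region_layout$start),
            all(region_layout$weight >= 0), sum(region_layout$weight) > 0)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_sites = as.integer(n_sites),
                 maf_spectrum = maf_spectrum,
                 class_probs = class_probs,
                 region_layout = region_layout,
                 odds_ratio = odds_ratio,
                 bmi_mean_controls = bmi_mean_controls,
                 bmi_sd_controls = bmi_sd_controls,
                 cohort_label = cohort_label,
                 seed = as.integer(seed)),
            class = "sim_config")
}

enriched_maf <- function(q, odds_ratio) {
  odds_ratio * q / (1 + (odds_ratio - 1) * q)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Simulate a case/control cohort of independent rare variant sites
#'
#' Each site gets a baseline alternate-allele frequency `q` from the
#' configured spectrum. Control genotypes are drawn under
#' Hardy-Weinberg equilibrium (hom-ref `(1-q)^2`, het `2q(1-q)`,
#' hom-alt `q^2`, i.e. Binomial(2, q) copies); case genotypes use the
#' enriched frequency `q'` with allele odds `odds_ratio` times the
#' baseline odds. Sites are independent (no linkage disequilibrium).
#' Functional classes and protein positions follow the configured
#' probabilities and region layout; controls get a truncated-normal BMI
#' and cases an obese-range BMI so the normal-weight-control subset path
#' is exercisable. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A [cohort()].
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_ca <- config$n_cases; n_co <- config$n_controls; S <- config$n_sites
  q <- draw_site_mafs(config$maf_spectrum, S)
  q_case <- enriched_maf(q, config$odds_ratio)
  if (any(q_case >= 0.5)) {
    stop("enriched case allele frequency reaches 0.5; lower odds_ratio ",
         "or the MAF spectrum", call. = FALSE)
  }
  rl <- config$region_layout
  reg <- sample.int(nrow(rl), S, replace = TRUE,
                    prob = rl$weight / sum(rl$weight))
  pos <- rl$start[reg] +
    floor(stats::runif(S) * (rl$end[reg] - rl$start[reg] + 1L))
  cls <- sample(names(config$class_probs), S, replace = TRUE,
                prob = config$class_probs)
  variants <- data.frame(variant_id = sprintf("V%03d", seq_len(S)),
                         protein_pos = as.integer(pos),
                         func_class = cls)
  ids <- c(sprintf("case_%05d", seq_len(n_ca)),
           sprintf("ctrl_%05d", seq_len(n_co)))
  individuals <- data.frame(
    individual_id = ids,
    status = rep(c("case", "control"), c(n_ca, n_co)),
    cohort_label = config$cohort_label,
    bmi = c(rtruncnorm1(n_ca, 42, 6, 30.5, 70),
            rtruncnorm1(n_co, config$bmi_mean_controls,
                        config$bmi_sd_controls, 15, 45)))
  # genotype copies per individual x site, cases first
  g_case <- matrix(stats::rbinom(n_ca * S, 2L, rep(q_case, each = n_ca)),
                   nrow = n_ca)
  g_ctrl <- matrix(stats::rbinom(n_co * S, 2L, rep(q, each = n_co)),
                   nrow = n_co)
  g <- rbind(g_case, g_ctrl)
  nz <- which(g > 0L, arr.ind = TRUE)
  genotypes <- data.frame(individual_id = ids[nz[, 1]],
                          variant_id = variants$variant_id[nz[, 2]],
                          allele_count = g[nz])
  genotypes <- genotypes[order(genotypes$variant_id,
                               genotypes$individual_id), ]
  rownames(genotypes) <- NULL
  cohort(individuals, variants, genotypes)
}

#' Deterministic fixture cohort matching the published marginal counts
#'
#' Builds, without any random draw, a 2,101-case / 1,536-control cohort
#' in which exactly 45 cases and 16 controls carry at least one
#' qualifying rare variant, with 27 distinct case-observed and 7
#' distinct control-observed variants (4 shared between arms), one case
#' homozygous for two variants, one case heterozygous for two variants,
#' and every pooled MAF below 0.005. Of the 16 control carriers, 14 are
#' normal weight, so the normal-weight control subset has 1,353 controls
#' with 14 carriers. Variant identities, positions and the carrier
#' layout are synthetic: only the published marginal counts are matched
#' (the per-variant table of the source screen is not reproduced).
#'
#' @return A [cohort()].
#' @export
make_paper_fixture <- function() {
  n_ca <- 2101L; n_co <- 1536L
  case_ids <- sprintf("case_%04d", seq_len(n_ca))
  ctrl_ids <- sprintf("ctrl_%04d", seq_len(n_co))
  individuals <- data.frame(
    individual_id = c(case_ids, ctrl_ids),
    status = rep(c("case", "control"), c(n_ca, n_co)),
    cohort_label = "original",
    bmi = c(rep(42, n_ca),                      # cases: severely obese
            rep(c(23, 35), c(1353L, 183L))))    # 1353 normal-weight controls
  # 30 variants: V01..V27 case-observed; V24..V27 shared with controls;
  # C28..C30 control-only. Positions spread over the 950-aa isoform with
  # a block inside the C-terminal kinase domain.
  vid <- c(sprintf("V%02d", 1:27), sprintf("C%02d", 28:30))
  pos <- c(253L, 323L, 400L, 410L,                      # V01..V04
           as.integer(seq(640L, 930L, length.out = 17)), # V05..V21 (kinase)
           180L, 210L, 260L, 300L, 350L, 500L,          # V22..V27
           150L, 220L, 560L)                            # C28..C30
  cls <- rep("missense", 30L)
  cls[c(5, 6)] <- "frameshift"; cls[7] <- "nonsense"
  variants <- data.frame(variant_id = vid, protein_pos = pos,
                         func_class = cls)
  gt <- list()
  # case 1: homozygous for two variants; case 2: two heterozygous variants
  gt[[1]] <- data.frame(individual_id = case_ids[1],
                        variant_id = c("V01", "V02"), allele_count = 2L)
  gt[[2]] <- data.frame(individual_id = case_ids[2],
                        variant_id = c("V03", "V04"), allele_count = 1L)
  # cases 3..25: one het each, covering V05..V27 once
  gt[[3]] <- data.frame(individual_id = case_ids[3:25],
                        variant_id = sprintf("V%02d", 5:27),
                        allele_count = 1L)
  # cases 26..45: twenty more het carriers cycling the recurrent variants
  gt[[4]] <- data.frame(individual_id = case_ids[26:45],
                        variant_id = sprintf("V%02d", rep(22:27,
                                                          length.out = 20)),
                        allele_count = 1L)
  # 16 control carriers: 14 normal-weight, 2 obese; variants V24..V27 and
  # C28..C30 cycled so each control-observed variant appears
  ctrl_carriers <- c(ctrl_ids[1:14], ctrl_ids[1354:1355])
  gt[[5]] <- data.frame(individual_id = ctrl_carriers,
                        variant_id = c(sprintf("V%02d", rep(24:27,
                                                            length.out = 9)),
                                       sprintf("C%02d", rep(28:30,
                                                            length.out = 7))),
                        allele_count = 1L)
  cohort(individuals, variants, do.call(rbind, gt))
}

#' Synthetic replication cohort with the published arm sizes
#'
#' A deterministic 238-case / 1,117-control cohort labelled
#' `"replication"`, for exercising merged-cohort analyses. Arm sizes
#' match the published replication sample; the carrier layout (a few
#' carriers of two variants shared with [make_paper_fixture()] plus one
#' replication-only variant) is entirely synthetic because the source
#' screen does not print its replication carrier table.
#'
#' @return A [cohort()].
#' @export
make_replication_fixture <- function() {
  n_ca <- 238L; n_co <- 1117L
  case_ids <- sprintf("rep_case_%04d", seq_len(n_ca))
  ctrl_ids <- sprintf("rep_ctrl_%04d", seq_len(n_co))
  individuals <- data.frame(
    individual_id = c(case_ids, ctrl_ids),
    status = rep(c("case", "control"), c(n_ca, n_co)),
    cohort_label = "replication",
    bmi = c(rep(41, n_ca), rep(c(24, 33), c(1000L, 117L))))
  # V22/V24 carry the same annotation as in the original fixture so the
  # merged variant tables reconcile; R31 is replication-only
  variants <- data.frame(variant_id = c("V22", "V24", "R31"),
                         protein_pos = c(180L, 260L, 720L),
                         func_class = c("missense", "missense", "missense"))
  genotypes <- data.frame(
    individual_id = c(case_ids[1:5], ctrl_ids[1:6]),
    variant_id = c("V22", "V24", "R31", "R31", "V24",
                   "V22", "V22", "V24", "R31", "R31", "R31"),
    allele_count = 1L)
  cohort(individuals, variants, genotypes)
}

#' Size/power calibration of the permutation-adjusted burden test
#'
#' For every simulation configuration in `grid`, draws `n_reps`
#' independent cohorts, runs the full variable-threshold scan with
#' permutation adjustment on each, and tabulates the fraction of
#' adjusted p-values at or below each significance level with exact
#' (Clopper-Pearson) binomial confidence intervals. Per-replicate seeds
#' are derived deterministically from `seed`.
#'
#' @param grid A single [sim_config()] or a list of them (one row of the
#'   output per config and level).
#' @param burden A [burden_config()]; its `seed` is overridden per
#'   replicate.
#' @param n_reps Replicates per grid point.
#' @param alpha Significance levels; default `c(0.05, 0.01)`.
#' @param seed Master seed.
#' @return data.frame with columns `grid_point`, `odds_ratio`, `n_cases`,
#'   `n_controls`, `n_sites`, `alpha`, `n_reps`, `n_reject`, `rate`,
#'   `ci_lo`, `ci_hi`.
#' @export
calibration_study <- function(grid, burden = burden_config(),
                              n_reps = 100L, alpha = c(0.05, 0.01),
                              seed = 1L) {
  if (inherits(grid, "sim_config")) grid <- list(grid)
  stopifnot(length(grid) >= 1, all(vapply(grid, inherits, TRUE,
                                          "sim_config")),
            n_reps >= 1)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 length(grid) * n_reps),
                      nrow = n_reps)
  rows <- list()
  for (gidx in seq_along(grid)) {
    sc <- grid[[gidx]]
    adj <- vapply(seq_len(n_reps), function(r) {
      sc$seed <- rep_seeds[r, gidx]
      bc <- burden
      bc$seed <- rep_seeds[r, gidx] %% 1000003L + 1L
      permutation_adjusted_p(simulate_cohort(sc), bc)$adjusted_p
    }, numeric(1))
    for (al in alpha) {
      x <- sum(adj <= al)
      ci <- stats::binom.test(x, n_reps)$conf.int
      rows[[length(rows) + 1L]] <-
        data.frame(grid_point = gidx, odds_ratio = sc$odds_ratio,
                   n_cases = sc$n_cases, n_controls = sc$n_controls,
                   n_sites = sc$n_sites, alpha = al, n_reps = n_reps,
                   n_reject = x, rate = x / n_reps,
                   ci_lo = ci[1], ci_hi = ci[2])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
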