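# Independent oracles used to check the package's statistics.
# These deliberately use different algorithms from the implementation:
# the Fisher oracle works from lchoose log-binomials with a sort/cumsum
# accumulation, and the permutation oracle enumerates every case/control
# label assignment and rebuilds tables from the raw allele matrix.

# Exact two-sided Fisher p by the minimum-likelihood convention,
# accumulated over the sorted point masses.
fisher_oracle <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c
  k <- a + b
  if (N == 0) stop("empty table")
  x <- max(0, k - (N - K)):min(k, K)
  pr <- exp(lchoose(K, x) + lchoose(N - K, k - x) - lchoose(N, k))
  ord <- order(pr)
  srt <- pr[ord]
  cum <- cumsum(srt)
  obs <- pr[match(a, x)]
  min(1, cum[findInterval(obs * (1 + 1e-7), srt)])
}

# Dominant-model min-p over a threshold ladder, computed from the raw
# per-individual allele-count matrix (individuals x variants) with a
# pooled-MAF qualification.
oracle_min_p <- function(allele_mat, is_case, thresholds) {
  N <- nrow(allele_mat)
  maf <- colSums(allele_mat) / (2 * N)
  n_case <- sum(is_case)
  n_ctrl <- N - n_case
  ps <- vapply(thresholds, function(th) {
    qual <- maf < th
    carrier <- rowSums(allele_mat[, qual, drop = FALSE]) > 0
    a <- sum(carrier & is_case)
    cc <- sum(carrier & !is_case)
    fisher_oracle(a, n_case - a, cc, n_ctrl - cc)
  }, numeric(1))
  min(ps)
}

# Exact adjusted p by exhaustive enumeration of all case-label
# assignments; rows 1..n_case of allele_mat are the observed cases.
oracle_exhaustive_adjusted_p <- function(allele_mat, n_case, thresholds) {
  N <- nrow(allele_mat)
  obs <- oracle_min_p(allele_mat, seq_len(N) <= n_case, thresholds)
  combos <- utils::combn(N, n_case)
  minps <- apply(combos, 2, function(idx) {
    oracle_min_p(allele_mat, seq_len(N) %in% idx, thresholds)
  })
  list(observed_min_p = obs,
       adjusted_p = mean(minps <= obs * (1 + 1e-12)))
}

# Build a cohort from a raw allele-count matrix (rows = individuals,
# cases first; columns = variants). Positions/classes default to
# qualifying missense so only the MAF filter is active.
toy_cohort <- function(allele_mat, n_case,
                       classes = rep("missense", ncol(allele_mat)),
                       positions = seq_len(ncol(allele_mat)),
                       bmi = NULL) {
  N <- nrow(allele_mat)
  ids <- sprintf("i%03d", seq_len(N))
  vids <- sprintf("v%02d", seq_len(ncol(allele_mat)))
  nz <- which(allele_mat > 0, arr.ind = TRUE)
  gt <- data.frame(individual_id = ids[nz[, 1]],
                   variant_id = vids[nz[, 2]],
                   allele_count = allele_mat[nz])
  cohort(data.frame(individual_id = ids,
                    status = rep(c("case", "control"),
                                 c(n_case, N - n_case)),
                    cohort_label = "original",
                    bmi = if (is.null(bmi)) NA_real_ else bmi),
         data.frame(variant_id = vids, protein_pos = positions,
                    func_class = classes),
         gt)
}
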