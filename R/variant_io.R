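#' Read a cohort from the variant-table TSV format
#'
#' The on-disk format holds the three cohort tables either as three
#' stanzas in one UTF-8 TSV file, each introduced by a marker line
#' (`#table: individuals`, `#table: variants`, `#table: genotypes`, each
#' followed by a header row), or as three plain TSV files
#' (`individuals.tsv`, `variants.tsv`, `genotypes.tsv`) inside a
#' directory. A missing BMI is encoded as an empty field. Individuals
#' without genotype rows are non-carriers and are retained.
#'
#' @param path Path to a stanza file or to a directory holding the three
#'   TSV files.
#' @return A [cohort()].
#' @seealso [write_variant_table()]
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("no such file or directory: ", path,
                               call. = FALSE)
  if (dir.exists(path)) {
    tabs <- lapply(c(individuals = "individuals.tsv",
                     variants = "variants.tsv",
                     genotypes = "genotypes.tsv"), function(f) {
      fp <- file.path(path, f)
      if (!file.exists(fp)) stop("missing table file: ", fp, call. = FALSE)
      parse_tsv_lines(readLines(fp, encoding = "UTF-8"), fp, offset = 0L)
    })
  } else {
    tabs <- parse_stanza_file(path)
  }
  build_cohort_from_tables(tabs$individuals, tabs$variants, tabs$genotypes)
}

parse_stanza_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  marks <- grep("^#table:", lines)
  if (!length(marks)) {
    stop(sprintf("%s: no '#table:' stanza markers found", path),
         call. = FALSE)
  }
  names_ <- trimws(sub("^#table:", "", lines[marks]))
  ends <- c(marks[-1] - 1L, length(lines))
  tabs <- list()
  for (i in seq_along(marks)) {
    body <- lines[seq(marks[i] + 1L, ends[i])]
    keep <- nzchar(trimws(body))
    tabs[[names_[i]]] <- parse_tsv_lines(body[keep], path,
                                         offset = marks[i])
  }
  need <- c("individuals", "variants", "genotypes")
  miss <- setdiff(need, names(tabs))
  if (length(miss)) {
    stop(sprintf("%s: missing stanza(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  tabs
}

# Parse header + data lines, reporting 1-based file line numbers on error.
parse_tsv_lines <- function(lines, path, offset = 0L) {
  if (!length(lines)) stop(sprintf("%s: empty table", path), call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  ncol <- length(header)
  body <- lines[-1]
  if (!length(body)) {
    out <- as.data.frame(setNames(rep(list(character()), ncol), header))
    return(out)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  # a trailing empty field (e.g. missing bmi) drops off strsplit; restore it
  short1 <- nf == ncol - 1L & endsWith(body, "\t")
  parts[short1] <- lapply(parts[short1], function(p) c(p, ""))
  nf[short1] <- ncol
  if (any(nf != ncol)) {
    bad <- which(nf != ncol)[1]
    stop(sprintf("%s: line %d has %d field(s), expected %d",
                 path, offset + 1L + bad, nf[bad], ncol), call. = FALSE)
  }
  mat <- matrix(unlist(parts), ncol = ncol, byrow = TRUE)
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- header
  out
}

build_cohort_from_tables <- function(ind, var, gt) {
  if ("bmi" %in% names(ind)) {
    ind$bmi <- suppressWarnings(as.numeric(ifelse(nzchar(ind$bmi),
                                                  ind$bmi, NA)))
  }
  if (nrow(var)) {
    pos <- suppressWarnings(as.integer(var$protein_pos))
    if (anyNA(pos)) {
      stop("non-integer protein_pos in variants table: ",
           var$protein_pos[which(is.na(pos))[1]], call. = FALSE)
    }
    var$protein_pos <- pos
  }
  if (nrow(gt)) {
    ac <- suppressWarnings(as.integer(gt$allele_count))
    if (anyNA(ac) || !all(ac %in% c(1L, 2L))) {
      bad <- gt$allele_count[which(is.na(ac) | !ac %in% c(1L, 2L))[1]]
      stop("invalid allele_count in genotypes table: ", bad,
           " (must be 1 or 2)", call. = FALSE)
    }
    gt$allele_count <- ac
  }
  cohort(ind, var, gt)
}

#' Write a cohort to the variant-table TSV format
#'
#' @param x A cohort.
#' @param path Output file (single stanza file) or, with
#'   `as_dir = TRUE`, a directory receiving `individuals.tsv`,
#'   `variants.tsv`, `genotypes.tsv`.
#' @param as_dir Write the three-file layout instead of one stanza file.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path, as_dir = FALSE) {
  stopifnot(inherits(x, "cohort"))
  ind <- x$individuals[c("individual_id", "status", "cohort_label", "bmi")]
  ind$bmi <- ifelse(is.na(ind$bmi),
                    "", format(ind$bmi, trim = TRUE, digits = 15,
                               scientific = FALSE))
  var <- x$variants[c("variant_id", "protein_pos", "func_class")]
  gt <- x$genotypes[c("individual_id", "variant_id", "allele_count")]
  fmt <- function(df) {
    c(paste(names(df), collapse = "\t"),
      if (nrow(df)) do.call(paste, c(lapply(df, as.character), sep = "\t")))
  }
  if (as_dir) {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    writeLines(fmt(ind), file.path(path, "individuals.tsv"))
    writeLines(fmt(var), file.path(path, "variants.tsv"))
    writeLines(fmt(gt), file.path(path, "genotypes.tsv"))
  } else {
    writeLines(c("#table: individuals", fmt(ind),
                 "#table: variants", fmt(var),
                 "#table: genotypes", fmt(gt)), path)
  }
  invisible(path)
}

#' Read a protein-region annotation file
#'
#' TSV with header `region_name`, `start`, `end`; residue coordinates are
#' 1-based and inclusive on both ends.
#'
#' @param path Path to the regions TSV.
#' @return data.frame with columns `region_name`, `start`, `end`.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- parse_tsv_lines(readLines(path, encoding = "UTF-8"), path)
  need <- c("region_name", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(path, ": regions file missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(is.na(df$start) | is.na(df$end) | df$start < 1L |
            df$end < df$start)) {
    stop(path, ": regions must satisfy 1 <= start <= end", call. = FALSE)
  }
  df[need]
}

region <- function(region_name, start, end) {
  stopifnot(start >= 1, start <= end)
  list(region_name = region_name, start = as.integer(start),
       end = as.integer(end))
}

lookup_region <- function(regions, name) {
  i <- match(name, regions$region_name)
  if (is.na(i)) {
    stop("unknown region name: ", name, call. = FALSE)
  }
  region(regions$region_name[i], regions$start[i], regions$end[i])
}

#' Read a minimal single-gene VCF into a cohort
#'
#' Accepts a VCF restricted to one gene with per-sample `GT` fields and
#' two INFO keys carrying the protein-level annotation: `FCLASS`
#' (functional class) and `PPOS` (1-based residue position). Multi-allelic
#' sites are rejected. Case/control status and cohort labels are not part
#' of VCF, so a matching `individuals` table must be supplied.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param individuals data.frame as for [cohort()]; its `individual_id`
#'   values must cover all VCF sample names.
#' @return A [cohort()].
#' @export
read_vcf_cohort <- function(path, individuals) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf_cohort requires the 'vcfR' package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix  # fixed-field matrix keeps its dimensions for 1-row VCFs
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE))) {
    stop("multi-allelic VCF site(s) are not supported; split them first",
         call. = FALSE)
  }
  info_field <- function(key) {
    val <- vcfR::extract.info(v, element = key)
    if (all(is.na(val))) {
      stop("VCF INFO key '", key, "' absent; required for protein-level ",
           "annotation", call. = FALSE)
    }
    val
  }
  vid <- fix[, "ID"]
  if (any(is.na(vid) | vid == ".")) {
    vid <- paste0(fix[, "CHROM"], ":", fix[, "POS"], "_", fix[, "REF"],
                  ">", alt)
  }
  var <- data.frame(variant_id = vid,
                    protein_pos = as.integer(info_field("PPOS")),
                    func_class = info_field("FCLASS"))
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  miss <- setdiff(samples, individuals$individual_id)
  if (length(miss)) {
    stop("VCF sample(s) absent from individuals table: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  ac <- matrix(0L, nrow(gt), ncol(gt))
  ok <- !is.na(gt)
  ac[ok] <- vapply(strsplit(gt[ok], "[/|]"),
                   function(g) sum(g == "1"), 0L)
  carrier <- which(ac > 0L, arr.ind = TRUE)
  geno <- data.frame(individual_id = samples[carrier[, 2]],
                     variant_id = vid[carrier[, 1]],
                     allele_count = ac[carrier])
  cohort(individuals, var, geno)
}
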