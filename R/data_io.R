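#' Genotype tables
#'
#' A genotype table is an ordinary tibble with one row per individual: an
#' `individual_id` character column, an optional `status` column
#' (`"case"`/`"control"`), and one integer column per SNP holding the additive
#' genotype code — 0 for major-allele homozygotes, 1 for heterozygotes, 2 for
#' minor-allele homozygotes, `NA` for a missing call. All functions in the
#' package take and return this shape, so analyses chain with the pipe.
#'
#' @param geno A genotype tibble.
#' @return `snp_cols()` returns the SNP column names; `geno_matrix()` the
#'   integer genotype matrix (individuals x SNPs, rownames = individual ids).
#' @examples
#' g <- tibble::tibble(individual_id = c("a", "b"), rs1 = c(0L, 2L), rs2 = c(1L, NA))
#' snp_cols(g)
#' geno_matrix(g)
#' @export
snp_cols <- function(geno) {
  setdiff(names(geno), c("individual_id", "status"))
}

#' @rdname snp_cols
#' @export
geno_matrix <- function(geno) {
  snps <- snp_cols(geno)
  m <- as.matrix(geno[snps])
  storage.mode(m) <- "integer"
  rownames(m) <- geno$individual_id
  m
}

validate_genotypes <- function(geno, call = rlang::caller_env()) {
  if (!"individual_id" %in% names(geno)) {
    abort("genotype table must have an `individual_id` column", call = call)
  }
  if (anyDuplicated(geno$individual_id)) {
    abort("individual ids must be unique", call = call)
  }
  m <- geno_matrix(geno)
  if (ncol(m) == 0) abort("genotype table has no SNP columns", call = call)
  bad <- which(!is.na(m) & !(m %in% 0:2))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(m))
    abort(sprintf(
      "genotype value %s at individual '%s', SNP '%s' is not in {0,1,2,NA}",
      m[bad[1]], rownames(m)[ij[1]], colnames(m)[ij[2]]), call = call)
  }
  invisible(geno)
}

MISSING_TOKENS <- c("NA", "", ".")

#' Read a delimited genotype file
#'
#' Expects a header row `individual_id,<snp ids...>` (an optional `status`
#' column is kept) and one row per individual with cells in `{0,1,2}` or one of
#' the missing tokens `"NA"`, `""`, `"."`. Input row order is preserved.
#'
#' @param path Path to the file.
#' @param delim Field delimiter, default comma.
#' @return A genotype tibble (see [snp_cols()]).
#' @seealso [write_genotypes()], [read_genotypes_vcf()]
#' @export
read_genotypes <- function(path, delim = ",") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) abort(sprintf("parse error: %s is empty", path))
  # pad with a sentinel so trailing empty cells survive strsplit
  fields <- lapply(strsplit(paste0(lines, delim, "\r"), delim, fixed = TRUE),
                   function(f) f[-length(f)])
  header <- trimws(fields[[1]])
  if (header[1] != "individual_id") {
    abort("parse error: first header field must be `individual_id`")
  }
  n_field <- length(header)
  rows <- fields[-1]
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != n_field) {
      abort(sprintf("parse error at line %d: expected %d fields, found %d",
                    i + 1L, n_field, length(rows[[i]])))
    }
  }
  cells <- matrix(trimws(unlist(rows)), nrow = length(rows), byrow = TRUE)
  out <- tibble(individual_id = cells[, 1])
  for (j in seq_len(n_field - 1L)) {
    col <- cells[, j + 1L]
    name <- header[j + 1L]
    if (name == "status") { out$status <- col; next }
    col[col %in% MISSING_TOKENS] <- NA
    bad <- which(!is.na(col) & !(col %in% c("0", "1", "2")))
    if (length(bad)) {
      abort(sprintf(
        "value error at line %d, column '%s': token '%s' is not in {0,1,2,NA}",
        bad[1] + 1L, name, col[bad[1]]))
    }
    out[[name]] <- as.integer(col)
  }
  validate_genotypes(out)
}

#' @rdname read_genotypes
#' @param geno A genotype tibble.
#' @export
write_genotypes <- function(geno, path, delim = ",") {
  validate_genotypes(geno)
  m <- as.data.frame(geno)
  m[is.na(m)] <- "NA"
  lines <- c(paste(names(m), collapse = delim),
             apply(m, 1, paste, collapse = delim))
  writeLines(lines, path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Ingests GT fields of biallelic records: `0/0 -> 0`, `0/1`/`1/0 -> 1`,
#' `1/1 -> 2`; `./.` and half-calls become `NA`. Multi-allelic records are
#' rejected. The ALT allele is taken as the counted allele; orient afterwards
#' with [orient_to_control_minor()].
#'
#' @inheritParams read_genotypes
#' @return A genotype tibble.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("VCF ingestion requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt))) {
    abort("value error: multi-allelic VCF records are not supported")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  code_one <- function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2 || any(al == ".")) return(NA_integer_)
    sum(as.integer(al))
  }
  coded <- apply(gt, c(1, 2), code_one)
  ids <- colnames(gt)
  out <- tibble(individual_id = ids)
  snp_ids <- rownames(gt)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(nrow(gt)))
  for (j in seq_len(nrow(coded))) out[[snp_ids[j]]] <- as.integer(coded[j, ])
  validate_genotypes(out)
}

#' Orient genotype coding to the control minor allele
#'
#' The additive code counts copies of the minor allele, defined as the less
#' frequent allele in the control group. For every SNP where the currently
#' counted allele has control frequency above 0.5, all individuals are recoded
#' `g -> 2 - g`. A 50/50 tie keeps the input orientation. SNPs with no observed
#' control genotypes are left unoriented with a warning. Missing entries are
#' never touched.
#'
#' @param geno A genotype tibble (cases and controls together or separate).
#' @param control_ids Character vector of control individual ids, or `NULL` to
#'   use rows with `status == "control"`.
#' @return The re-oriented genotype tibble, with a `flipped` attribute naming
#'   the recoded SNPs.
#' @export
orient_to_control_minor <- function(geno, control_ids = NULL) {
  validate_genotypes(geno)
  if (is.null(control_ids)) {
    if (!"status" %in% names(geno)) {
      abort("supply `control_ids` or a `status` column")
    }
    control_ids <- geno$individual_id[geno$status == "control"]
  }
  if (!length(control_ids)) abort("control subset is empty")
  m <- geno_matrix(geno)
  ctrl <- m[rownames(m) %in% control_ids, , drop = FALSE]
  if (!nrow(ctrl)) abort("no control individuals found in the genotype table")
  n_obs <- colSums(!is.na(ctrl))
  freq <- colSums(ctrl, na.rm = TRUE) / (2 * n_obs)
  unobserved <- n_obs == 0
  if (any(unobserved)) {
    warn(sprintf("SNP(s) with all control genotypes missing left unoriented: %s",
                 paste(colnames(m)[unobserved], collapse = ", ")))
  }
  flip <- !unobserved & freq > 0.5
  out <- geno
  for (s in colnames(m)[flip]) out[[s]] <- 2L - out[[s]]
  attr(out, "flipped") <- colnames(m)[flip]
  out
}

PHENOTYPE_COLS <- c("gender", "age_at_diagnosis", "location", "anal",
                    "inflammatory", "stenosing", "non_perianal_fistulae",
                    "perianal_fistulae", "surgery")
LOCATION_LEVELS <- c("colon", "ileum", "ileocolonic")

#' Read a clinical phenotype table
#'
#' Delimited file with columns `individual_id`, `gender` (male/female),
#' `age_at_diagnosis` (years), `location` (colon/ileum/ileocolonic — mutually
#' exclusive), and the 0/1 flags `anal`, `inflammatory`, `stenosing`,
#' `non_perianal_fistulae`, `perianal_fistulae`, `surgery`. Anal disease is
#' recorded independently of location. Missing cells: `NA`, empty, or `.`.
#'
#' @inheritParams read_genotypes
#' @return A typed phenotype tibble; `attr(, "missing_report")` counts missing
#'   values per column (see [phenotype_missing_report()]).
#' @export
read_phenotypes <- function(path, delim = ",") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- read.csv(path, sep = delim, colClasses = "character",
                  na.strings = MISSING_TOKENS, check.names = FALSE)
  if (!"individual_id" %in% names(raw)) {
    abort("phenotype file must have an `individual_id` column")
  }
  out <- tibble(individual_id = as.character(raw$individual_id))
  if ("gender" %in% names(raw)) {
    bad <- setdiff(stats::na.omit(unique(raw$gender)), c("male", "female"))
    if (length(bad)) abort(sprintf("value error: gender '%s'", bad[1]))
    out$gender <- raw$gender
  }
  if ("age_at_diagnosis" %in% names(raw)) {
    out$age_at_diagnosis <- as.numeric(raw$age_at_diagnosis)
  }
  if ("location" %in% names(raw)) {
    bad <- setdiff(stats::na.omit(unique(raw$location)), LOCATION_LEVELS)
    if (length(bad)) {
      abort(sprintf("value error: location '%s' not in {%s}",
                    bad[1], paste(LOCATION_LEVELS, collapse = ", ")))
    }
    out$location <- raw$location
  }
  for (b in c("anal", "inflammatory", "stenosing", "non_perianal_fistulae",
              "perianal_fistulae", "surgery")) {
    if (!b %in% names(raw)) next
    v <- raw[[b]]
    bad <- setdiff(stats::na.omit(unique(v)), c("0", "1"))
    if (length(bad)) abort(sprintf("value error: %s '%s' is not 0/1/NA", b, bad[1]))
    out[[b]] <- as.integer(v) == 1L
  }
  attr(out, "missing_report") <- phenotype_missing_report(out)
  out
}

#' @rdname read_phenotypes
#' @param phen A phenotype tibble.
#' @return `phenotype_missing_report()`: a tibble with `variable` and
#'   `n_missing`.
#' @export
phenotype_missing_report <- function(phen) {
  cols <- setdiff(names(phen), "individual_id")
  tibble(variable = cols,
         n_missing = vapply(cols, function(c) sum(is.na(phen[[c]])), integer(1),
                            USE.NAMES = FALSE))
}

#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(phen, path, delim = ",") {
  df <- as.data.frame(phen)
  for (j in seq_along(df)) {
    if (is.logical(df[[j]])) df[[j]] <- as.integer(df[[j]])
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Per-SNP missingness rates
#'
#' @param geno A genotype tibble.
#' @return A named numeric vector, fraction of missing calls per SNP.
#' @export
missingness_rates <- function(geno) {
  m <- geno_matrix(geno)
  colMeans(is.na(m))
}

#' Per-SNP panel summary
#'
#' Counted-allele frequency in the control group (after
#' [orient_to_control_minor()] this is the control minor-allele frequency,
#' `<= 0.5`) and the missingness rate per SNP.
#'
#' @param geno A genotype tibble.
#' @param control_ids Control individual ids; `NULL` uses
#'   `status == "control"`.
#' @return A tibble: `snp_id`, `control_minor_freq` (`NaN` when no control
#'   genotype is observed), `missing_rate`.
#' @export
snp_summary <- function(geno, control_ids = NULL) {
  validate_genotypes(geno)
  if (is.null(control_ids)) {
    if (!"status" %in% names(geno)) {
      abort("supply `control_ids` or a `status` column")
    }
    control_ids <- geno$individual_id[geno$status == "control"]
  }
  m <- geno_matrix(geno)
  ctrl <- m[rownames(m) %in% control_ids, , drop = FALSE]
  n_obs <- colSums(!is.na(ctrl))
  tibble(snp_id = colnames(m),
         control_minor_freq = unname(colSums(ctrl, na.rm = TRUE) / (2 * n_obs)),
         missing_rate = unname(colMeans(is.na(m))))
}
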