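#' Specify a synthetic case/control cohort design
#'
#' Defines a two-group cohort with planted latent-class structure: each group is
#' a finite mixture of classes, each class has its own per-SNP genotype-category
#' distribution, genotype calls are missing completely at random at per-SNP
#' rates, and binary clinical phenotypes have class-conditional prevalences in
#' the case group.
#'
#' Class profiles are `k x m x 3` arrays of genotype-category probabilities
#' (each `[k, j, ]` a 3-simplex), most conveniently built from per-class
#' minor-allele frequencies with [profiles_from_mafs()].
#'
#' @param n_cases,n_controls Group sizes.
#' @param profiles_cases,profiles_controls Class profile arrays (`k x m x 3`).
#' @param mixing_cases,mixing_controls Mixing proportions (simplex vectors, one
#'   per class; default uniform).
#' @param missing_rate Per-SNP missing-call probability: scalar or length-`m`
#'   vector.
#' @param phenotype_model Optional tibble of class-conditional prevalences for
#'   the case group: column `class` plus one column in `[0,1]` per binary
#'   phenotype.
#' @return A `sim_design` object.
#' @seealso [simulate_cohort()], [paper_scale_design()]
#' @export
simulation_design <- function(n_cases, n_controls,
                              profiles_cases, profiles_controls,
                              mixing_cases = NULL, mixing_controls = NULL,
                              missing_rate = 0,
                              phenotype_model = NULL) {
  check_profiles <- function(p, what) {
    if (length(dim(p)) != 3 || dim(p)[3] != 3) {
      abort(sprintf("%s must be a k x m x 3 array", what))
    }
    sums <- apply(p, c(1, 2), sum)
    if (any(abs(sums - 1) > 1e-12) || any(p < 0)) {
      abort(sprintf("design error: %s rows must be probability 3-simplexes", what))
    }
  }
  check_simplex <- function(v, k, what) {
    if (is.null(v)) return(rep(1 / k, k))
    if (length(v) != k || any(v < 0) || abs(sum(v) - 1) > 1e-12) {
      abort(sprintf("design error: %s must be a %d-simplex", what, k))
    }
    v
  }
  if (n_cases < 1 || n_controls < 1) abort("design error: group sizes must be positive")
  check_profiles(profiles_cases, "profiles_cases")
  check_profiles(profiles_controls, "profiles_controls")
  m <- dim(profiles_cases)[2]
  if (dim(profiles_controls)[2] != m) {
    abort("design error: case and control profiles must cover the same SNP panel")
  }
  if (length(missing_rate) == 1) missing_rate <- rep(missing_rate, m)
  if (length(missing_rate) != m) abort("design error: missing_rate length must be 1 or m")
  if (any(missing_rate < 0 | missing_rate > 1)) {
    abort("design error: missing rates must lie in [0,1]")
  }
  if (!is.null(phenotype_model)) {
    prev <- as.matrix(phenotype_model[setdiff(names(phenotype_model), "class")])
    if (any(prev < 0 | prev > 1)) abort("design error: prevalences must lie in [0,1]")
    if (nrow(phenotype_model) != dim(profiles_cases)[1]) {
      abort("design error: phenotype_model needs one row per case class")
    }
  }
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    m_snps = m,
    profiles_cases = profiles_cases, profiles_controls = profiles_controls,
    mixing_cases = check_simplex(mixing_cases, dim(profiles_cases)[1], "mixing_cases"),
    mixing_controls = check_simplex(mixing_controls, dim(profiles_controls)[1],
                                    "mixing_controls"),
    missing_rate = missing_rate,
    phenotype_model = phenotype_model
  ), class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic cohort design: %d cases (%d classes), %d controls (%d classes), ",
    "%d SNPs\nmean per-SNP missing rate %.3f\n"),
    x$n_cases, length(x$mixing_cases), x$n_controls, length(x$mixing_controls),
    x$m_snps, mean(x$missing_rate)))
  invisible(x)
}

#' Genotype-category profiles from minor-allele frequencies
#'
#' Converts per-class per-SNP minor-allele frequencies `p` into genotype
#' probabilities under Hardy-Weinberg proportions:
#' `((1-p)^2, 2p(1-p), p^2)`.
#'
#' @param mafs A `k x m` matrix of frequencies in `[0,1]`.
#' @return A `k x m x 3` profile array.
#' @export
profiles_from_mafs <- function(mafs) {
  mafs <- as.matrix(mafs)
  if (any(mafs < 0 | mafs > 1)) abort("allele frequencies must lie in [0,1]")
  k <- nrow(mafs); m <- ncol(mafs)
  out <- array(0, dim = c(k, m, 3))
  out[, , 1] <- (1 - mafs)^2
  out[, , 2] <- 2 * mafs * (1 - mafs)
  out[, , 3] <- mafs^2
  out
}

sample_group <- function(n, profiles, mixing, id_prefix) {
  k <- dim(profiles)[1]; m <- dim(profiles)[2]
  cls <- sample.int(k, n, replace = TRUE, prob = mixing)
  g <- matrix(NA_integer_, n, m)
  u <- matrix(runif(n * m), n, m)
  for (kk in seq_len(k)) {
    rows <- which(cls == kk)
    if (!length(rows)) next
    p1 <- matrix(profiles[kk, , 1], length(rows), m, byrow = TRUE)
    p12 <- matrix(profiles[kk, , 1] + profiles[kk, , 2], length(rows), m, byrow = TRUE)
    g[rows, ] <- ifelse(u[rows, , drop = FALSE] < p1, 0L,
                        ifelse(u[rows, , drop = FALSE] < p12, 1L, 2L))
  }
  list(ids = sprintf("%s%0*d", id_prefix, nchar(n) + 1L, seq_len(n)),
       genotypes = g, classes = cls)
}

#' Simulate a case/control cohort with planted latent classes
#'
#' Draws each individual's latent class from the group's mixing proportions,
#' genotypes independently per SNP from that class's category profile, masks
#' entries missing-completely-at-random at the design's per-SNP rates, and (for
#' cases) draws binary phenotypes from class-conditional prevalences. Fully
#' reproducible given `seed`.
#'
#' @param design A [simulation_design()].
#' @param seed Integer seed.
#' @return A list: `genotypes` (genotype tibble for cases and controls, with
#'   `status`), `true_labels` (tibble of `individual_id`, `status`,
#'   `true_class`), and `phenotypes` (tibble, `NULL` when the design has no
#'   phenotype model).
#' @export
simulate_cohort <- function(design, seed = 1L) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(seed)
  snp_ids <- sprintf("snp%02d", seq_len(design$m_snps))
  cases <- sample_group(design$n_cases, design$profiles_cases,
                        design$mixing_cases, "case")
  ctrls <- sample_group(design$n_controls, design$profiles_controls,
                        design$mixing_controls, "ctrl")
  g <- rbind(cases$genotypes, ctrls$genotypes)
  n <- nrow(g)
  mask <- matrix(runif(n * design$m_snps), n, design$m_snps) <
    matrix(design$missing_rate, n, design$m_snps, byrow = TRUE)
  g[mask] <- NA_integer_
  geno <- tibble(individual_id = c(cases$ids, ctrls$ids),
                 status = rep(c("case", "control"),
                              c(design$n_cases, design$n_controls)))
  for (j in seq_along(snp_ids)) geno[[snp_ids[j]]] <- g[, j]

  labels <- tibble(individual_id = geno$individual_id, status = geno$status,
                   true_class = c(cases$classes, ctrls$classes))

  phen <- NULL
  if (!is.null(design$phenotype_model)) {
    pm <- design$phenotype_model
    vars <- setdiff(names(pm), "class")
    phen <- tibble(individual_id = cases$ids)
    for (v in vars) {
      prev <- pm[[v]][cases$classes]
      phen[[v]] <- runif(design$n_cases) < prev
    }
  }
  list(genotypes = geno, true_labels = labels, phenotypes = phen)
}

#' Mask genotype calls missing-completely-at-random
#'
#' Re-imposes per-SNP missingness on a complete (or partially complete)
#' genotype table, e.g. to give bootstrap replicates the same per-SNP missing
#' percentages as an observed sample.
#'
#' @param geno A genotype tibble.
#' @param rates Per-SNP missing probabilities (length = number of SNPs).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return The masked genotype tibble.
#' @export
apply_missingness <- function(geno, rates, seed = NULL) {
  snps <- snp_cols(geno)
  if (length(rates) == 1) rates <- rep(rates, length(snps))
  if (length(rates) != length(snps)) {
    abort(sprintf("dimension error: %d rates for %d SNPs", length(rates), length(snps)))
  }
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0,1]")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(geno)
  for (j in seq_along(snps)) {
    if (rates[j] == 0) next
    hit <- runif(n) < rates[j]
    geno[[snps[j]]][hit] <- NA_integer_
  }
  geno
}

#' Cohort-scale preset design
#'
#' A named preset mirroring the scale of a CD case/control reclassification
#' study: 875 cases in 6 latent classes, 367 controls in 5 classes, 46 SNPs,
#' 2% missing calls per SNP. Each class carries an elevated minor-allele
#' frequency (0.45 vs a 0.10 background) on its own block of SNPs, giving
#' well-separated but overlapping genotype profiles; case mixing proportions
#' follow the cluster sizes 302/96/62/117/59/239. Case phenotype prevalences
#' vary moderately by class. The genotype profiles are synthetic: they do not
#' reproduce any real SNP panel.
#'
#' @return A [simulation_design()].
#' @export
paper_scale_design <- function() {
  m <- 46
  block <- function(k, m, maf_in = 0.45, maf_out = 0.10) {
    # class c owns SNPs ((c-1)*w+1) .. c*w, w = floor(m/k)
    w <- floor(m / k)
    mafs <- matrix(maf_out, k, m)
    for (c in seq_len(k)) mafs[c, ((c - 1) * w + 1):(c * w)] <- maf_in
    mafs
  }
  phen <- tibble(
    class = 1:6,
    anal = c(0.39, 0.34, 0.42, 0.44, 0.25, 0.37),
    inflammatory = c(0.48, 0.59, 0.37, 0.51, 0.51, 0.49),
    stenosing = c(0.38, 0.34, 0.50, 0.31, 0.31, 0.40),
    non_perianal_fistulae = c(0.27, 0.17, 0.29, 0.28, 0.27, 0.26),
    perianal_fistulae = c(0.29, 0.32, 0.42, 0.29, 0.29, 0.31),
    surgery = c(0.57, 0.56, 0.73, 0.53, 0.53, 0.54))
  simulation_design(
    n_cases = 875, n_controls = 367,
    profiles_cases = profiles_from_mafs(block(6, m)),
    profiles_controls = profiles_from_mafs(block(5, m)),
    mixing_cases = c(302, 96, 62, 117, 59, 239) / 875,
    mixing_controls = rep(1 / 5, 5),
    missing_rate = 0.02,
    phenotype_model = phen)
}
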