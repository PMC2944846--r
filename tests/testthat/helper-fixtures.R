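# Shared fixture builders and independent oracles. Every oracle here is a
# deliberately naive re-derivation (enumeration / closed form) kept separate
# from the package's own computation paths.

# genotype tibble from a plain matrix (rows = individuals)
make_geno <- function(mat, ids = NULL, status = NULL) {
  n <- nrow(mat)
  ids <- ids %||% sprintf("ind%02d", seq_len(n))
  out <- tibble::tibble(individual_id = ids)
  if (!is.null(status)) out$status <- status
  snps <- colnames(mat) %||% sprintf("snp%02d", seq_len(ncol(mat)))
  for (j in seq_len(ncol(mat))) out[[snps[j]]] <- as.integer(mat[, j])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force mixture log-likelihood: explicit sum over classes per individual
oracle_loglik <- function(pi, theta, gm) {
  # theta: k x m x 3
  total <- 0
  for (i in seq_len(nrow(gm))) {
    li <- 0
    for (k in seq_along(pi)) {
      f <- pi[k]
      for (j in seq_len(ncol(gm))) {
        g <- gm[i, j]
        if (!is.na(g)) f <- f * theta[k, j, g + 1]
      }
      li <- li + f
    }
    total <- total + log(li)
  }
  total
}

# exhaustive best first split: all (SNP, category-subset) pairs by Gini decrease
oracle_best_split <- function(gm, labels) {
  classes <- sort(unique(labels))
  gini <- function(y) { p <- table(factor(y, classes)) / length(y); 1 - sum(p^2) }
  best <- list(decrease = -Inf)
  for (j in seq_len(ncol(gm))) {
    obs <- !is.na(gm[, j])
    gj <- gm[obs, j]; yj <- labels[obs]
    for (subset in list(0L, 1L, 2L)) {
      left <- gj %in% subset
      if (!any(left) || all(left)) next
      dec <- length(gj) * gini(yj) -
        sum(left) * gini(yj[left]) - sum(!left) * gini(yj[!left])
      if (dec > best$decrease + 1e-12) {
        best <- list(decrease = dec, snp = j, left_set = subset)
      }
    }
  }
  best
}

# the 3-class recovery experiment: each class nearly fixed for the counted
# allele at its own pair of SNPs (within-class frequency 0.9 vs background
# 0.05 -> pooled frequency 1/3, still the minor allele overall), equal mixing,
# n = 2000 cases. Extreme within-class frequencies keep every category
# probability far from 1/2, so class assignment is near-certain and category
# estimates concentrate well inside a 0.05 sup-norm at this sample size.
recovery_design <- function() {
  mafs <- rbind(c(0.9, 0.9, 0.05, 0.05, 0.05, 0.05),
                c(0.05, 0.05, 0.9, 0.9, 0.05, 0.05),
                c(0.05, 0.05, 0.05, 0.05, 0.9, 0.9))
  prof <- profiles_from_mafs(mafs)
  simulation_design(2000, 10, prof, profiles_from_mafs(mafs[1:2, ]),
                    mixing_cases = rep(1 / 3, 3), missing_rate = 0.02)
}

# two-sided Fisher exact p by full enumeration over the hypergeometric support
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, function(x)
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)), numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pearson chi-square via the expected-count definition
oracle_chi2 <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  sum((obs - expd)^2 / expd)
}

# align fitted classes to planted classes by best sup-norm over permutations
best_permutation <- function(fit_theta, true_theta) {
  k <- dim(fit_theta)[1]
  perms <- combinat_perms(k)
  errs <- vapply(perms, function(p)
    max(abs(fit_theta[p, , , drop = FALSE] - true_theta)), numeric(1))
  perms[[which.min(errs)]]
}

combinat_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest_vals <- setdiff(seq_len(k), i)
    for (rest in combinat_perms(k - 1)) {
      out[[length(out) + 1]] <- c(i, rest_vals[rest])
    }
  }
  out
}
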