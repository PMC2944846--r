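#' Canonical discriminant analysis of coded genotypes
#'
#' Finds linear combinations of the (additively coded, quantitative) genotype
#' columns that maximise between-cluster relative to within-cluster variation:
#' the generalized eigenproblem of the between-group scatter `B` against the
#' within-group scatter `W`. Missing genotypes are mean-imputed per SNP before
#' the analysis (and the same imputation values are reused when projecting new
#' samples). Scores are centered at the derivation-sample mean — so each
#' canonical variable has derivation mean 0 to floating-point precision — and
#' scaled to unit pooled within-group variance; between-group spread then adds
#' variance on top, so informative axes have total SD above 1. If `W` is
#' (near-)singular a ridge of `1e-8 * trace(W)/m` is added with a warning.
#'
#' @param geno A genotype tibble (or any data frame of numeric columns plus
#'   `individual_id`).
#' @param labels Cluster assignment per row; at least 2 groups of at least 2.
#' @param n_axes Number of canonical axes kept, default `min(k - 1, m)`.
#' @return A `cda_fit`: `coefficients` (m x r), `eigenvalues` (of
#'   `W^{-1} B`, non-increasing), `centering`, `impute_means`, `scores`
#'   (tibble: `individual_id`, `cluster`, `can1`, `can2`, ...), and canonical
#'   group means.
#' @seealso [project_cda()], [manova_wilks()]
#' @export
fit_cda <- function(geno, labels, n_axes = NULL) {
  x <- cda_numeric(geno)
  if (length(labels) != nrow(x)) {
    abort(sprintf("dimension error: %d labels for %d rows", length(labels), nrow(x)))
  }
  groups <- sort(unique(labels))
  if (length(groups) < 2) abort("need at least 2 groups")
  if (any(table(labels) < 2)) abort("every group needs at least 2 members")

  impute_means <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- impute_means[j]

  n <- nrow(x); p <- ncol(x); g <- length(groups)
  xbar <- colMeans(x)
  W <- matrix(0, p, p)
  group_means <- matrix(0, g, p, dimnames = list(groups, colnames(x)))
  for (i in seq_len(g)) {
    xi <- x[labels == groups[i], , drop = FALSE]
    group_means[i, ] <- colMeans(xi)
    cen <- sweep(xi, 2, group_means[i, ])
    W <- W + crossprod(cen)
  }
  cen_all <- sweep(x, 2, xbar)
  B <- crossprod(cen_all) - W

  L <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(L) || min(diag(L)) < sqrt(.Machine$double.eps * sum(diag(W)))) {
    warn("within-group scatter is (near-)singular; adding ridge 1e-8 * trace/m")
    W <- W + diag(1e-8 * sum(diag(W)) / p, p)
    L <- chol(W)
  }
  # W^{-1} B via the symmetric form L'^{-1} -> orthonormal eigenvectors
  Linv <- backsolve(L, diag(p))           # L^{-1}' actually: chol gives upper U, W = U'U
  M <- t(Linv) %*% B %*% Linv             # U'^{-1} B U^{-1}
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  r <- min(g - 1, p)
  if (!is.null(n_axes)) r <- min(r, n_axes)
  evals <- pmax(eig$values[seq_len(r)], 0)
  # a = U^{-1} v scaled so pooled within-group variance a' (W/(n-g)) a = 1
  A <- Linv %*% eig$vectors[, seq_len(r), drop = FALSE] * sqrt(n - g)
  dimnames(A) <- list(colnames(x), paste0("can", seq_len(r)))

  scores <- cen_all %*% A
  ids <- if ("individual_id" %in% names(geno)) geno$individual_id else
    as.character(seq_len(n))
  score_tbl <- as_tibble(as.data.frame(scores))
  score_tbl <- dplyr::bind_cols(tibble(individual_id = ids, cluster = labels),
                                score_tbl)
  can_means <- aggregate(as.data.frame(scores), by = list(cluster = labels),
                         FUN = mean)

  structure(list(coefficients = A, eigenvalues = evals,
                 centering = xbar, impute_means = impute_means,
                 group_means_canonical = as_tibble(can_means),
                 scores = score_tbl, n = n, n_groups = g,
                 snp_ids = colnames(x)),
            class = "cda_fit")
}

cda_numeric <- function(geno) {
  df <- as.data.frame(geno)
  df <- df[setdiff(names(df), c("individual_id", "status"))]
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  m
}

#' @export
print.cda_fit <- function(x, ...) {
  cat(sprintf("Canonical discriminant analysis: %d groups, %d variables, %d axes\n",
              x$n_groups, length(x$snp_ids), ncol(x$coefficients)))
  cat("eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = " "), "\n")
  invisible(x)
}

#' @describeIn fit_cda `tidy()` returns the canonical coefficients in long
#'   form (`variable`, `axis`, `coefficient`).
#' @param x A `cda_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cda_fit <- function(x, ...) {
  df <- as.data.frame(x$coefficients)
  df$variable <- rownames(x$coefficients)
  tidyr::pivot_longer(as_tibble(df), -"variable", names_to = "axis",
                      values_to = "coefficient")
}

#' @describeIn fit_cda `glance()` eigenvalue summary.
#' @exportS3Method generics::glance
glance.cda_fit <- function(x, ...) {
  tibble(n = x$n, n_groups = x$n_groups, n_axes = ncol(x$coefficients),
         eigenvalue1 = x$eigenvalues[1],
         eigenvalue2 = if (length(x$eigenvalues) > 1) x$eigenvalues[2] else NA_real_)
}

#' Project a sample through a fitted discriminant rule
#'
#' Applies the derivation sample's imputation values, centering and canonical
#' coefficients unchanged to another sample on the same SNP panel — e.g.
#' computing case-derived canonical variables for the controls. Projected
#' scores need not have mean zero.
#'
#' @param cda A `cda_fit`.
#' @param geno A genotype tibble on the same panel.
#' @param labels Optional cluster labels carried into the output.
#' @return A tibble of canonical scores (`individual_id`, optional `cluster`,
#'   `can1`, ...).
#' @export
project_cda <- function(cda, geno, labels = NULL) {
  x <- cda_numeric(geno)
  if (!identical(colnames(x), cda$snp_ids)) {
    if (!all(cda$snp_ids %in% colnames(x))) {
      abort("dimension error: sample panel does not match the derivation panel")
    }
    x <- x[, cda$snp_ids, drop = FALSE]
  }
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- cda$impute_means[j]
  scores <- sweep(x, 2, cda$centering) %*% cda$coefficients
  ids <- if ("individual_id" %in% names(geno)) geno$individual_id else
    as.character(seq_len(nrow(x)))
  out <- tibble(individual_id = ids)
  if (!is.null(labels)) out$cluster <- labels
  dplyr::bind_cols(out, as_tibble(as.data.frame(scores)))
}

#' MANOVA comparison of canonical means between two samples
#'
#' Compares the mean vector of the canonical variables (typically the first
#' two) between two groups — e.g. cases' own scores vs controls projected
#' through the cases' discriminant rule — by Wilks' lambda with Rao's F
#' approximation (exact for two groups).
#'
#' @param scores_a,scores_b Data frames of the same score columns (any
#'   `individual_id`/`cluster` columns are dropped); each group needs at least
#'   3 rows and at least 2 score columns.
#' @return A `manova_result`: `wilks_lambda`, `f_stat`, `df1`, `df2`,
#'   `p_value`.
#' @export
manova_wilks <- function(scores_a, scores_b) {
  a <- score_matrix(scores_a); b <- score_matrix(scores_b)
  if (ncol(a) < 2 || ncol(b) < 2) {
    abort("dimension error: need at least 2 response columns")
  }
  if (!identical(colnames(a), colnames(b))) {
    abort("dimension error: score columns differ between groups")
  }
  if (nrow(a) < 3 || nrow(b) < 3) abort("each group needs at least 3 rows")
  y <- rbind(a, b)
  grp <- factor(rep(c("a", "b"), c(nrow(a), nrow(b))))
  fit <- stats::manova(y ~ grp)
  if (isTRUE(all.equal(colMeans(a), colMeans(b), tolerance = 1e-12))) {
    # degenerate equal-means case: summary.manova's F is 0/0
    res <- c(lambda = 1, f = 0, df1 = ncol(a), df2 = nrow(y) - 1 - ncol(a), p = 1)
  } else {
    s <- summary(fit, test = "Wilks")$stats
    res <- c(lambda = s["grp", "Wilks"], f = s["grp", "approx F"],
             df1 = s["grp", "num Df"], df2 = s["grp", "den Df"],
             p = s["grp", "Pr(>F)"])
  }
  structure(list(wilks_lambda = unname(res["lambda"]),
                 f_stat = unname(res["f"]),
                 df1 = unname(res["df1"]), df2 = unname(res["df2"]),
                 p_value = unname(res["p"])),
            class = "manova_result")
}

score_matrix <- function(scores) {
  df <- as.data.frame(scores)
  df <- df[setdiff(names(df), c("individual_id", "cluster", "status"))]
  as.matrix(df)
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf("Wilks' lambda = %.4f, F(%g, %g) = %.3f, p = %.3g\n",
              x$wilks_lambda, x$df1, x$df2, x$f_stat, x$p_value))
  invisible(x)
}

#' @describeIn manova_wilks `glance()` one-row summary.
#' @param x A `manova_result`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.manova_result <- function(x, ...) {
  tibble(wilks_lambda = x$wilks_lambda, f_stat = x$f_stat,
         df1 = x$df1, df2 = x$df2, p_value = x$p_value)
}
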