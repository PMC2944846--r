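#' Odds ratio with Woolf confidence interval
#'
#' For a 2x2 table with cells `a` (exposed, trait), `b` (exposed, no trait),
#' `c` (unexposed, trait), `d` (unexposed, no trait): `OR = ad / bc` and the
#' Woolf (log-normal) interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell triggers
#' the Haldane-Anscombe correction (+0.5 to every cell), flagged in the
#' output.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @param conf_level Confidence level, default 0.95.
#' @return A one-row tibble: `odds_ratio`, `ci_low`, `ci_high`,
#'   `haldane_corrected`.
#' @export
odds_ratio_woolf <- function(a, b, c, d, conf_level = 0.95) {
  if (any(c(a, b, c, d) < 0)) abort("counts must be non-negative")
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(odds_ratio = or,
         ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se),
         haldane_corrected = corrected)
}

#' Pearson chi-square test for a 2x2 table
#'
#' `X^2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on 1 df, with no continuity
#' correction.
#'
#' @inheritParams odds_ratio_woolf
#' @return A one-row tibble: `chi2_stat`, `chi2_p`.
#' @export
pearson_chi2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("counts must be non-negative")
  tab <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("undefined-result error: a table margin is zero")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(chi2_stat = unname(ct$statistic), chi2_p = unname(ct$p.value))
}

#' Fisher exact test for a 2x2 table (two-sided)
#'
#' Hypergeometric two-sided p: the sum of probabilities of all tables with the
#' observed margins whose probability does not exceed the observed table's.
#'
#' @inheritParams odds_ratio_woolf
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("counts must be non-negative")
  fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
}

#' Cluster-membership vs phenotype 2x2 association
#'
#' Tests one cluster against all other clusters for a binary phenotype.
#' Individuals with a missing phenotype are excluded (and counted). Reports
#' the 2x2 counts, odds ratio with Woolf CI, Pearson chi-square (no continuity
#' correction), and — whenever any expected cell count is below 5 — the Fisher
#' exact p as well.
#'
#' @param labels Cluster assignment per individual.
#' @param cluster_id The cluster tested against the rest.
#' @param phenotype Logical vector (may contain `NA`), same length.
#' @return A one-row `contingency_result` tibble: `a`, `b`, `c`, `d` (cluster
#'   with / without trait, others with / without), `odds_ratio`, `ci_low`,
#'   `ci_high`, `chi2_stat`, `chi2_p`, `fisher_p` (`NA` when not needed),
#'   `n_missing_excluded`.
#' @export
two_by_two <- function(labels, cluster_id, phenotype) {
  if (length(labels) != length(phenotype)) {
    abort("dimension error: labels and phenotype differ in length")
  }
  if (!any(labels == cluster_id)) {
    abort(sprintf("undefined-result error: cluster '%s' is empty", cluster_id))
  }
  keep <- !is.na(phenotype)
  n_missing <- sum(!keep)
  lab <- labels[keep]; ph <- as.logical(phenotype[keep])
  in_cl <- lab == cluster_id
  a <- sum(in_cl & ph); b <- sum(in_cl & !ph)
  c <- sum(!in_cl & ph); d <- sum(!in_cl & !ph)
  or <- odds_ratio_woolf(a, b, c, d)
  chi <- pearson_chi2(a, b, c, d)
  expected <- outer(c(a + b, c + d), c(a + c, b + d)) / (a + b + c + d)
  fis <- if (any(expected < 5)) fisher_exact(a, b, c, d) else NA_real_
  out <- tibble(cluster = cluster_id, a = a, b = b, c = c, d = d,
                odds_ratio = or$odds_ratio, ci_low = or$ci_low,
                ci_high = or$ci_high,
                chi2_stat = chi$chi2_stat, chi2_p = chi$chi2_p,
                fisher_p = fis, n_missing_excluded = n_missing)
  class(out) <- c("contingency_result", class(out))
  out
}

#' Association table over all clusters and binary phenotypes
#'
#' Runs [two_by_two()] for every (cluster, phenotype) pair.
#'
#' @param labels Cluster assignment per individual.
#' @param phenotypes A phenotype tibble aligned with `labels` (logical
#'   columns are used; others ignored).
#' @param phenotype_cols Optional subset of column names to test.
#' @return A tibble with one row per cluster x phenotype.
#' @export
cluster_phenotype_table <- function(labels, phenotypes,
                                    phenotype_cols = NULL) {
  if (nrow(phenotypes) != length(labels)) {
    abort("dimension error: phenotype table and labels differ in length")
  }
  if (is.null(phenotype_cols)) {
    phenotype_cols <- names(phenotypes)[vapply(phenotypes, is.logical, logical(1))]
  }
  rows <- list()
  for (cl in sort(unique(labels))) {
    for (ph in phenotype_cols) {
      r <- two_by_two(labels, cl, phenotypes[[ph]])
      r <- dplyr::mutate(r, phenotype = ph, .after = "cluster")
      rows[[length(rows) + 1]] <- r
    }
  }
  bind_rows(rows)
}

#' Backward-selection logistic regression
#'
#' Maximum-likelihood logistic regression (via `glm`) of a binary outcome on
#' binary/numeric predictors, with automated backward elimination: at each
#' step the predictor with the largest Wald p-value above `p_remove` is
#' dropped, until every remaining predictor's p is at or below the threshold
#' (or the model is empty). Aliased (collinear) predictors and
#' quasi-separation abort with the offending predictor named.
#'
#' @param data A data frame holding outcome and predictors.
#' @param outcome Name of the logical/0-1 outcome column.
#' @param predictors Character vector of predictor column names.
#' @param p_remove Removal threshold on the Wald p, default 0.10.
#' @return A `logistic_fit`: `tidy()` gives retained predictors with
#'   coefficient, Wald `odds_ratio`, 95% CI and p; `$trace` records each
#'   elimination (`removed`, `p_at_removal`).
#' @export
logistic_backward <- function(data, outcome, predictors, p_remove = 0.10) {
  df <- as.data.frame(data)[c(outcome, predictors)]
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) <= length(predictors) + 1) {
    abort("n must exceed the number of predictors")
  }
  y <- as.numeric(df[[outcome]])
  if (!all(y %in% 0:1)) abort("outcome must be binary (logical or 0/1)")

  mf <- df
  mf$..y <- y
  fit_one <- function(preds) {
    if (!length(preds)) return(glm(..y ~ 1, data = mf, family = binomial()))
    f <- stats::reformulate(preds, response = "..y")
    fit <- suppressWarnings(glm(f, data = mf, family = binomial()))
    cf <- coef(fit)
    if (anyNA(cf)) {
      abort(sprintf("collinearity error: predictor '%s' is aliased",
                    names(cf)[which(is.na(cf))[1]]))
    }
    big <- which(abs(cf[-1]) > 15)
    if (length(big)) {
      abort(sprintf("separation error: predictor '%s' separates the outcome",
                    names(cf[-1])[big[1]]))
    }
    fit
  }

  preds <- predictors
  trace <- tibble(removed = character(), p_at_removal = numeric())
  repeat {
    fit <- fit_one(preds)
    if (!length(preds)) break
    p_wald <- summary(fit)$coefficients[-1, "Pr(>|z|)", drop = TRUE]
    names(p_wald) <- preds
    worst <- which.max(p_wald)
    if (p_wald[worst] <= p_remove) break
    trace <- bind_rows(trace, tibble(removed = preds[worst],
                                     p_at_removal = unname(p_wald[worst])))
    preds <- preds[-worst]
  }

  est <- if (length(preds)) {
    s <- summary(fit)$coefficients[-1, , drop = FALSE]
    z <- qnorm(0.975)
    tibble(term = preds, estimate = s[, "Estimate"],
           std_error = s[, "Std. Error"],
           odds_ratio = exp(s[, "Estimate"]),
           ci_low = exp(s[, "Estimate"] - z * s[, "Std. Error"]),
           ci_high = exp(s[, "Estimate"] + z * s[, "Std. Error"]),
           p_value = s[, "Pr(>|z|)"])
  } else {
    tibble(term = character(), estimate = numeric(), std_error = numeric(),
           odds_ratio = numeric(), ci_low = numeric(), ci_high = numeric(),
           p_value = numeric())
  }
  structure(list(retained = est, trace = trace, p_remove = p_remove,
                 n = nrow(df), fit = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Backward logistic regression (p_remove = %g, n = %d)\n",
              x$p_remove, x$n))
  if (nrow(x$retained)) print(x$retained) else cat("no predictors retained\n")
  if (nrow(x$trace)) { cat("eliminated:\n"); print(x$trace) }
  invisible(x)
}

#' @describeIn logistic_backward `tidy()` retained-predictor table.
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.logistic_fit <- function(x, ...) x$retained

#' @describeIn logistic_backward `glance()` one-row summary.
#' @exportS3Method generics::glance
glance.logistic_fit <- function(x, ...) {
  tibble(n = x$n, n_retained = nrow(x$retained),
         n_removed = nrow(x$trace), p_remove = x$p_remove)
}
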