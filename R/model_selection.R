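#' Parametric bootstrap likelihood-ratio test for the number of classes
#'
#' Tests the null hypothesis that `k_null` latent classes explain the sample
#' against the alternative of `k_null + 1`. Both models are fitted to the data
#' to give the observed statistic `2 * (ll_alt - ll_null)`. Each of the `B`
#' bootstrap replicates then simulates `n` individuals from the fitted null
#' model, re-imposes missing calls per SNP at the original sample's per-SNP
#' rates, refits both models, and records its likelihood-ratio statistic. The
#' p-value is `(1 + #{bootstrap LR >= observed LR}) / (B + 1)`.
#'
#' The replicates are parametric draws under the null hypothesis — that is
#' what gives the test its calibration. By default each replicate's generating
#' parameters are themselves drawn from the Dirichlet posterior implied by the
#' fitted null model's responsibility-weighted counts
#' (`replicate_params = "posterior"`) rather than fixed at the point estimate.
#' With many parameters relative to the sample (a 5-class model on 46 SNPs has
#' ~460 parameters), plug-in replicates understate the estimation uncertainty
#' in the fitted model and their LR distribution sits systematically below the
#' statistic's true null distribution, inflating the rejection rate; the
#' posterior draw restores that missing variability.
#' `replicate_params = "plugin"` gives the classical plug-in bootstrap.
#'
#' @param geno A genotype tibble (one group: cases or controls).
#' @param k_null Null number of classes (`>= 1`).
#' @param B Bootstrap replicates, default 20.
#' @param seed Integer seed controlling fits and replicates.
#' @param n_starts Multi-starts for the two fits on the observed data.
#' @param boot_n_starts Multi-starts for each replicate refit. Defaults to
#'   `n_starts`: the test is calibrated only when observed and replicate data
#'   are fitted with the same optimization budget, because the extra-class
#'   improvement found by a harder multi-start is systematically larger.
#'   Lowering this buys speed at the cost of anti-conservative p-values.
#' @param tol,max_iter EM settings (see [lca_fit()]).
#' @param replicate_params `"posterior"` (default) draws each replicate's
#'   generating parameters from the fitted null's Dirichlet posterior;
#'   `"plugin"` fixes them at the point estimate (see Details).
#' @return A `boot_lrt` object: `k_null`, `k_alt`, `observed_lr`,
#'   `bootstrap_lrs` (length `B`), `p_value`, the two fitted models, and the
#'   per-SNP missing rates used for the replicates.
#' @seealso [select_num_classes()]
#' @export
bootstrap_lrt <- function(geno, k_null, B = 20, seed = 1L,
                          n_starts = 20, boot_n_starts = n_starts,
                          tol = 1e-8, max_iter = 2000,
                          replicate_params = c("posterior", "plugin")) {
  replicate_params <- match.arg(replicate_params)
  if (B < 1) abort("parameter error: B must be >= 1")
  if (k_null < 1) abort("parameter error: k_null must be >= 1")
  # canonical order: the test outcome must not depend on how rows/columns of
  # the input happen to be sorted
  geno <- geno[order(geno$individual_id),
               c(intersect(c("individual_id", "status"), names(geno)),
                 sort(snp_cols(geno)))]
  set.seed(seed)
  rates <- missingness_rates(geno)
  n <- nrow(geno)
  boot_tol <- max(tol, 1e-7)  # replicate refits need less resolution

  fit0 <- lca_fit(geno, k_null, n_starts = n_starts, tol = tol,
                  max_iter = max_iter)
  fit1 <- lca_fit(geno, k_null + 1L, n_starts = n_starts, tol = tol,
                  max_iter = max_iter, split_init = fit0)
  observed_lr <- 2 * (fit1$loglik - fit0$loglik)
  if (any(fit0$pi < 1 / n)) {
    warn("fitted null model has a near-empty class (pi < 1/n); replicates drawn anyway")
  }

  boot_lrs <- vapply(seq_len(B), function(b) {
    gen_model <- if (replicate_params == "posterior") {
      draw_posterior_params(fit0, geno)
    } else fit0
    rep_geno <- apply_missingness(simulate_from_model(gen_model, n), rates)
    b0 <- lca_fit(rep_geno, k_null, n_starts = boot_n_starts, tol = boot_tol,
                  max_iter = max_iter)
    # an MLE can never fall below the replicate's own generating parameters;
    # if the refit did, it is provably stuck — rescue it with a warm start
    # (the rescue never fires on a healthy fit, so typical replicates are
    # untouched and no systematic optimism is introduced)
    if (b0$loglik < lca_loglik(gen_model, rep_geno)) {
      b0 <- lca_fit(rep_geno, k_null, n_starts = boot_n_starts,
                    tol = boot_tol, max_iter = max_iter,
                    warm_start = gen_model)
    }
    b1 <- lca_fit(rep_geno, k_null + 1L, n_starts = boot_n_starts,
                  tol = boot_tol, max_iter = max_iter, split_init = b0)
    2 * (b1$loglik - b0$loglik)
  }, numeric(1))

  structure(list(k_null = as.integer(k_null), k_alt = k_null + 1L,
                 observed_lr = observed_lr, bootstrap_lrs = boot_lrs,
                 p_value = boot_lrt_pvalue(observed_lr, boot_lrs),
                 B = as.integer(B), seed = seed,
                 fit_null = fit0, fit_alt = fit1,
                 missing_rates = rates),
            class = "boot_lrt")
}

#' @rdname bootstrap_lrt
#' @param observed_lr Observed likelihood-ratio statistic.
#' @param bootstrap_lrs Replicate statistics.
#' @return `boot_lrt_pvalue()`: the add-one bootstrap p-value
#'   `(1 + #{replicate >= observed}) / (B + 1)`, always in `(0, 1]`.
#' @export
boot_lrt_pvalue <- function(observed_lr, bootstrap_lrs) {
  (1 + sum(bootstrap_lrs >= observed_lr)) / (length(bootstrap_lrs) + 1)
}

#' @export
print.boot_lrt <- function(x, ...) {
  cat(sprintf("Bootstrap LRT: %d vs %d classes\nobserved LR = %.3f, B = %d, p = %.3f\n",
              x$k_null, x$k_alt, x$observed_lr, x$B, x$p_value))
  invisible(x)
}

#' @describeIn bootstrap_lrt `glance()` one-row summary of a test.
#' @param x A `boot_lrt`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.boot_lrt <- function(x, ...) {
  tibble(k_null = x$k_null, k_alt = x$k_alt, observed_lr = x$observed_lr,
         p_value = x$p_value, B = x$B)
}

#' Select the number of latent classes
#'
#' Steps k = 1, 2, ... and tests k against k+1 with [bootstrap_lrt()]; stops at
#' the first k whose test is non-significant at `alpha` and returns that k. If
#' every test up to `k_max` is significant, returns `k_max` with a warning.
#'
#' @inheritParams bootstrap_lrt
#' @param alpha Significance level, default 0.05.
#' @param k_max Largest k considered.
#' @return A `class_selection` object: `k` (the chosen number), `tests` (list
#'   of `boot_lrt`), and `path` (tibble of k, observed LR, p per step).
#' @export
select_num_classes <- function(geno, alpha = 0.05, k_max = 10, B = 20,
                               seed = 1L, n_starts = 20,
                               boot_n_starts = n_starts,
                               tol = 1e-8, max_iter = 2000) {
  if (k_max < 1) abort("parameter error: k_max must be >= 1")
  tests <- list()
  chosen <- k_max
  exhausted <- TRUE
  for (k in seq_len(k_max)) {
    if (alpha >= 1) { chosen <- k; exhausted <- FALSE; break }
    t_k <- bootstrap_lrt(geno, k, B = B, seed = seed + k, n_starts = n_starts,
                         boot_n_starts = boot_n_starts, tol = tol,
                         max_iter = max_iter)
    tests[[k]] <- t_k
    if (t_k$p_value >= alpha) { chosen <- k; exhausted <- FALSE; break }
  }
  if (exhausted) {
    warn(sprintf("every test up to k_max = %d was significant; returning k_max", k_max))
  }
  path <- if (length(tests)) dplyr::bind_rows(lapply(tests, glance)) else
    tibble(k_null = integer(), k_alt = integer(), observed_lr = numeric(),
           p_value = numeric(), B = integer())
  structure(list(k = as.integer(chosen), tests = tests, path = path,
                 alpha = alpha, seed = seed),
            class = "class_selection")
}

#' @export
print.class_selection <- function(x, ...) {
  cat(sprintf("Selected k = %d latent classes (alpha = %g)\n", x$k, x$alpha))
  if (nrow(x$path)) print(x$path)
  invisible(x)
}

#' @describeIn select_num_classes `tidy()` returns the per-step test table.
#' @param x A `class_selection`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.class_selection <- function(x, ...) x$path

#' Cross-tabulate cluster assignments of successive models
#'
#' Counts how individuals "flow" from the clusters of a model with `k` classes
#' to those of the next model with `k + 1` (or any other labelling). Row sums
#' reproduce the first model's cluster sizes, column sums the second's.
#'
#' @param labels_i,labels_i1 Equal-length assignment vectors.
#' @return A `cluster_flow` object wrapping the count matrix; `tidy()` gives
#'   the long tibble (`from`, `to`, `n`), [autoplot()] a band diagram.
#' @export
cluster_flow <- function(labels_i, labels_i1) {
  if (length(labels_i) != length(labels_i1)) {
    abort(sprintf("dimension error: label vectors differ in length (%d vs %d)",
                  length(labels_i), length(labels_i1)))
  }
  counts <- as.matrix(table(from = labels_i, to = labels_i1))
  structure(list(counts = counts, n = length(labels_i)), class = "cluster_flow")
}

#' @export
print.cluster_flow <- function(x, ...) {
  cat(sprintf("Cluster flow, n = %d\n", x$n)); print(x$counts); invisible(x)
}

#' @describeIn cluster_flow `tidy()` long counts.
#' @param x A `cluster_flow`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cluster_flow <- function(x, ...) {
  df <- as.data.frame(x$counts, stringsAsFactors = FALSE)
  names(df) <- c("from", "to", "n")
  as_tibble(df)
}
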