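#' @section Model:
#' The latent class model treats the cohort as a finite mixture of `k` classes.
#' Within a class, the `m` SNPs are independent and each genotype (0/1/2) has a
#' class-specific multinomial probability. Missing genotypes contribute no
#' factor to an individual's likelihood (missing-at-random marginalisation), so
#' every individual — including those with missing calls — enters the fit.
#' @name lca_model
NULL

row_max <- function(m) {
  do.call(pmax, c(lapply(seq_len(ncol(m)), function(j) m[, j])))
}

geno_indicators <- function(gm) {
  # three n x m 0/1 matrices; a missing entry is 0 in all three
  list(I0 = matrix(as.numeric(!is.na(gm) & gm == 0L), nrow(gm)),
       I1 = matrix(as.numeric(!is.na(gm) & gm == 1L), nrow(gm)),
       I2 = matrix(as.numeric(!is.na(gm) & gm == 2L), nrow(gm)))
}

theta_stack <- function(theta) {
  # k x m x 3 array -> list of m x k matrices as the C++ core expects
  k <- dim(theta)[1]; m <- dim(theta)[2]
  lapply(1:3, function(g) t(matrix(theta[, , g], k, m)))
}

new_lca_model <- function(k, pi, theta, snp_ids, loglik, converged,
                          n_iterations, ll_trace, n, seed, settings) {
  structure(list(
    k = k, pi = as.numeric(pi), theta = theta, snp_ids = snp_ids,
    loglik = loglik, n_params = (k - 1L) + k * length(snp_ids) * 2L,
    converged = converged, n_iterations = n_iterations, ll_trace = ll_trace,
    n = n, seed = seed, settings = settings), class = "lca_model")
}

#' Fit a latent class model to SNP genotypes
#'
#' Fits a `k`-class mixture of independent per-SNP multinomials by EM.
#' Individuals with missing genotypes are included: the E-step uses only their
#' observed entries, and the M-step weights each SNP's category frequencies by
#' the responsibilities of the individuals observed at that SNP. Multi-start:
#' half the `n_starts` starts are random responsibility matrices
#' (Dirichlet(1,...,1) rows), half are genotype-exemplar starts (soft
#' assignment by agreement with `k` individuals picked by a farthest-point
#' rule); every start runs `short_iter` EM iterations and the most promising
#' of each family are run to convergence, the best final log-likelihood
#' winning. Category probabilities are smoothed by `eps` in the M-step so no
#' fitted probability is exactly zero. Reproducible given `seed`.
#'
#' @param geno A genotype tibble (see [snp_cols()]); a `status` column, if
#'   present, is ignored — fit case and control groups separately.
#' @param k Number of latent classes (`k >= 1`).
#' @param n_starts Number of random starts.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Iteration cap per start.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param short_iter,n_deep Multi-start schedule (see Details).
#' @param eps M-step smoothing added to category counts.
#' @param split_init Optional fitted `lca_model` with `k - 1` classes. Adds a
#'   third start family: for each class of that model, a candidate start that
#'   splits the class's posterior mass in two at random. Used when stepping
#'   from a k-class to a (k+1)-class fit so the larger model can never miss
#'   structure the smaller one found.
#' @param warm_start Optional `lca_model` with the same `k`: its posterior on
#'   this data is added as one more start, so the fit can never end below it.
#'   Used for bootstrap replicates, whose generating model is known.
#' @return An `lca_model` object: mixing proportions `pi`, category
#'   probabilities `theta` (`k x m x 3`), `loglik`, `n_params`
#'   (`k-1 + 2km`), convergence diagnostics, and the fitted posterior
#'   memberships (retrieve with [lca_memberships()]).
#' @examples
#' d <- simulation_design(60, 40, profiles_from_mafs(rbind(0.05, 0.45)),
#'                        profiles_from_mafs(rbind(0.2)))
#' sim <- simulate_cohort(d, seed = 7)
#' fit <- lca_fit(dplyr::filter(sim$genotypes, status == "case"), k = 2, seed = 1)
#' glance(fit)
#' @export
lca_fit <- function(geno, k, n_starts = 20, tol = 1e-8, max_iter = 2000,
                    seed = NULL, short_iter = 25, n_deep = 3, eps = 1e-10,
                    split_init = NULL, warm_start = NULL) {
  if (!is.null(split_init) && split_init$k != k - 1) {
    abort("split_init must have exactly k - 1 classes")
  }
  if (!is.null(warm_start) && warm_start$k != k) {
    abort("warm_start must have exactly k classes")
  }
  base_post <- if (is.null(split_init)) NULL else
    posterior_memberships(split_init, geno)$posterior
  warm_post <- if (is.null(warm_start) || k == 1L) NULL else
    posterior_memberships(warm_start, geno)$posterior
  gm <- geno_matrix(geno)
  # canonical row/column order so the fit (and its random starts) cannot
  # depend on how the input happens to be sorted; mapped back on return
  row_ord <- order(rownames(gm))
  col_ord <- order(colnames(gm))
  input_snps <- colnames(gm)
  input_ids <- rownames(gm)
  gm <- gm[row_ord, col_ord, drop = FALSE]
  n <- nrow(gm); m <- ncol(gm)
  if (k < 1) abort("parameter error: k must be >= 1")
  n_informative <- sum(rowSums(!is.na(gm)) > 0)
  if (k > n) abort(sprintf("parameter error: k = %d exceeds n = %d", k, n))
  if (n_informative < k) {
    abort(sprintf("parameter error: only %d individuals have any observed genotype",
                  n_informative))
  }
  if (!is.null(seed)) set.seed(seed)
  ind <- geno_indicators(gm)

  rand_resp <- function() {
    r <- matrix(stats::rexp(n * k), n, k)  # Dirichlet(1,..,1) rows
    r / rowSums(r)
  }
  # exemplar start: soft-assign everyone by genotype agreement with k seed
  # individuals chosen by a farthest-point (k-means++-like) rule, so the seeds
  # tend to land in distinct classes; finds block-structured classes far more
  # reliably than purely random responsibilities, so half the starts use it
  informative <- which(rowSums(!is.na(gm)) > 0)
  obs_ind <- ind$I0 + ind$I1 + ind$I2
  agree_with <- function(e) {
    # per-individual fraction of co-observed SNPs agreeing with individual e
    co <- obs_ind %*% obs_ind[e, ]
    ag <- ind$I0 %*% ind$I0[e, ] + ind$I1 %*% ind$I1[e, ] +
      ind$I2 %*% ind$I2[e, ]
    as.numeric(ag) / pmax(as.numeric(co), 1)
  }
  exemplar_resp <- function() {
    ex <- sample(informative, 1)
    sim <- matrix(agree_with(ex), ncol = 1)
    while (length(ex) < k) {
      w <- (1 - row_max(sim))^2
      w[ex] <- 0
      nxt <- if (sum(w[informative]) > 0) {
        sample(informative, 1, prob = w[informative])
      } else sample(setdiff(informative, ex), 1)
      ex <- c(ex, nxt)
      sim <- cbind(sim, agree_with(nxt))
    }
    r <- exp(0.5 * m * (sim - row_max(sim)))
    r / rowSums(r)
  }
  if (k == 1L) {
    runs <- list(cpp_em(ind$I0, ind$I1, ind$I2, matrix(1, n, 1),
                        tol, max_iter, eps))
  } else {
    family <- rep(c("dirichlet", "exemplar"), length.out = n_starts)
    starts <- lapply(seq_len(n_starts), function(s)
      if (family[s] == "exemplar") exemplar_resp() else rand_resp())
    if (!is.null(base_post)) {
      base_resp <- base_post[row_ord, , drop = FALSE]
      splits <- lapply(seq_len(k - 1), function(cl) {
        u <- runif(n)
        cbind(base_resp[, -cl, drop = FALSE],
              base_resp[, cl] * u, base_resp[, cl] * (1 - u))
      })
      starts <- c(starts, splits)
      family <- c(family, rep("split", k - 1))
    }
    if (!is.null(warm_post)) {
      starts <- c(starts, list(warm_post[row_ord, , drop = FALSE]))
      family <- c(family, "warm")
    }
    shorts <- lapply(starts, function(r)
      cpp_em(ind$I0, ind$I1, ind$I2, r, tol, as.integer(short_iter), eps))
    lls <- vapply(shorts, `[[`, numeric(1), "loglik")
    # pick survivors per start family: exemplar and split starts converge much
    # faster, so an unstratified short-run comparison would always favour them
    # even when a (slower) random start is heading to a better basin
    fams <- unique(family)
    quota <- max(1, ceiling(n_deep / length(fams)))
    keep <- unlist(lapply(fams, function(f) {
      idx <- which(family == f)
      idx[order(lls[idx], decreasing = TRUE)][seq_len(min(quota, length(idx)))]
    }))
    runs <- lapply(shorts[keep], function(s) {
      if (isTRUE(s$converged)) s else
        cpp_em(ind$I0, ind$I1, ind$I2, s$resp, tol, max_iter, eps)
    })
  }
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "loglik"))]]

  theta <- array(0, dim = c(k, m, 3))
  theta[, , 1] <- t(best$theta0); theta[, , 2] <- t(best$theta1)
  theta[, , 3] <- t(best$theta2)
  # back to input SNP and individual order
  theta <- theta[, match(input_snps, colnames(gm)), , drop = FALSE]
  resp <- best$resp[match(input_ids, rownames(gm)), , drop = FALSE]
  model <- new_lca_model(
    k = as.integer(k), pi = best$pi, theta = theta, snp_ids = input_snps,
    loglik = best$loglik, converged = isTRUE(best$converged),
    n_iterations = best$n_iterations, ll_trace = as.numeric(best$ll_trace),
    n = n, seed = seed,
    settings = list(n_starts = n_starts, tol = tol, max_iter = max_iter,
                    short_iter = short_iter, n_deep = n_deep, eps = eps))
  model$membership <- make_membership(resp, model$pi, input_ids)
  model
}

make_membership <- function(resp, pi, ids) {
  bad <- !is.finite(rowSums(resp))
  if (any(bad)) {
    warn(sprintf("%d individual(s) had zero likelihood under every class; posterior set to the prior",
                 sum(bad)))
    resp[bad, ] <- matrix(pi, sum(bad), length(pi), byrow = TRUE)
  }
  structure(list(posterior = resp,
                 assignment = max.col(resp, ties.method = "first"),
                 max_posterior = apply(resp, 1, max),
                 individual_id = ids),
            class = "lca_membership")
}

#' Posterior class memberships
#'
#' `posterior_memberships()` computes, for each individual, the posterior
#' probability of belonging to each latent class (`posterior[i,k] ~ pi_k *
#' prod_{j observed} theta[k,j,g_ij]`, rows normalised) and the hard assignment
#' (argmax; ties broken toward the lowest class index). An individual with all
#' genotypes missing gets the prior `pi`. `lca_memberships()` returns the
#' memberships of the fitting sample as a tibble.
#'
#' @param model An `lca_model`.
#' @param geno A genotype tibble on the model's SNP panel.
#' @return `posterior_memberships()`: an `lca_membership` object;
#'   `lca_memberships()`: a tibble with `individual_id`, `assignment`,
#'   `max_posterior` and one `p_class<k>` column per class.
#' @export
posterior_memberships <- function(model, geno) {
  gm <- align_panel(model, geno)
  ind <- geno_indicators(gm)
  th <- theta_stack(model$theta)
  res <- cpp_loglik(ind$I0, ind$I1, ind$I2, model$pi, th[[1]], th[[2]], th[[3]])
  make_membership(res$resp, model$pi, rownames(gm))
}

#' @rdname posterior_memberships
#' @param x An `lca_model` or `lca_membership`.
#' @export
lca_memberships <- function(x) {
  mem <- if (inherits(x, "lca_model")) x$membership else x
  stopifnot(inherits(mem, "lca_membership"))
  out <- tibble(individual_id = mem$individual_id,
                assignment = mem$assignment,
                max_posterior = mem$max_posterior)
  for (kk in seq_len(ncol(mem$posterior))) {
    out[[paste0("p_class", kk)]] <- mem$posterior[, kk]
  }
  out
}

align_panel <- function(model, geno, call = rlang::caller_env()) {
  gm <- geno_matrix(geno)
  if (!identical(colnames(gm), model$snp_ids)) {
    if (!all(model$snp_ids %in% colnames(gm))) {
      abort("dimension error: data SNP panel does not match the model's", call = call)
    }
    gm <- gm[, model$snp_ids, drop = FALSE]
  }
  gm
}

#' Log-likelihood of a latent class model on data
#'
#' `sum_i log sum_k pi_k prod_{j observed for i} theta[k, j, g_ij]`. Missing
#' entries are marginalised out; an all-missing individual contributes
#' `log sum_k pi_k = 0`. If some individual's observed genotypes have zero
#' probability under every class, `-Inf` is returned with a warning.
#'
#' @inheritParams posterior_memberships
#' @return A scalar log-likelihood.
#' @export
lca_loglik <- function(model, geno) {
  gm <- align_panel(model, geno)
  ind <- geno_indicators(gm)
  th <- theta_stack(model$theta)
  res <- cpp_loglik(ind$I0, ind$I1, ind$I2, model$pi, th[[1]], th[[2]], th[[3]])
  if (!is.finite(res$loglik)) {
    warn("an observed genotype has zero probability under every class; log-likelihood is -Inf")
  }
  res$loglik
}

#' Relabel the classes of a fitted model
#'
#' Class labels in a mixture are arbitrary; this applies a permutation to
#' `pi`, `theta` and the stored memberships. Used when comparing a fit against
#' a planted design.
#'
#' @param model An `lca_model`.
#' @param perm A permutation of `1:k`; new class `i` is old class `perm[i]`.
#' @export
permute_classes <- function(model, perm) {
  stopifnot(inherits(model, "lca_model"), sort(perm) == seq_len(model$k))
  model$pi <- model$pi[perm]
  model$theta <- model$theta[perm, , , drop = FALSE]
  if (!is.null(model$membership)) {
    mem <- model$membership
    mem$posterior <- mem$posterior[, perm, drop = FALSE]
    mem$assignment <- order(perm)[mem$assignment]
    model$membership <- mem
  }
  model
}

#' Summarise membership certainty
#'
#' Counts individuals whose highest membership probability exceeds `high`
#' (clear membership) or falls below `low` (uncertain membership).
#'
#' @param mem An `lca_membership`, `lca_model`, or the tibble from
#'   [lca_memberships()].
#' @param high,low Thresholds, defaults 0.9 and 0.6.
#' @return A one-row tibble: `n`, `n_above_high`, `frac_above_high`,
#'   `n_below_low`, `frac_below_low`.
#' @export
membership_summary <- function(mem, high = 0.9, low = 0.6) {
  if (!(low >= 0 && low <= high && high <= 1)) {
    abort("thresholds must satisfy 0 <= low <= high <= 1")
  }
  mp <- if (is.data.frame(mem)) mem$max_posterior
        else if (inherits(mem, "lca_model")) mem$membership$max_posterior
        else mem$max_posterior
  n <- length(mp)
  tibble(n = n,
         n_above_high = sum(mp > high), frac_above_high = mean(mp > high),
         n_below_low = sum(mp < low), frac_below_low = mean(mp < low))
}

# Draw mixture parameters from the Dirichlet posterior implied by the fitted
# model's responsibility-weighted counts (Jeffreys 1/2 prior): pi* from the
# class masses, theta*[k,j,] from the per-class per-SNP observed-category
# masses. Used to give bootstrap replicates the estimation uncertainty that a
# plug-in theta-hat ignores.
draw_posterior_params <- function(model, geno) {
  gm <- geno_matrix(geno)
  if (!identical(colnames(gm), model$snp_ids)) {
    gm <- gm[, model$snp_ids, drop = FALSE]
  }
  resp <- model$membership$posterior
  resp <- resp[match(rownames(gm), model$membership$individual_id), ,
               drop = FALSE]
  ind <- geno_indicators(gm)
  k <- model$k; m <- ncol(gm)
  cnt <- vapply(list(ind$I0, ind$I1, ind$I2),
                function(I) t(resp) %*% I, matrix(0, k, m))  # k x m x 3
  draw <- array(rgamma(length(cnt), shape = cnt + 0.5), dim = dim(cnt))
  model$theta <- draw / array(rep(apply(draw, c(1, 2), sum), 3), dim = dim(cnt))
  pi_draw <- rgamma(k, shape = colSums(resp) + 0.5)
  model$pi <- pi_draw / sum(pi_draw)
  model
}

#' Simulate genotypes from a fitted latent class model
#'
#' Draws `n` individuals: a class from `pi`, then each SNP's genotype from the
#' class's category probabilities. No missingness is imposed; layer it on with
#' [apply_missingness()].
#'
#' @param model An `lca_model`.
#' @param n Number of individuals.
#' @param seed Optional integer seed.
#' @return A genotype tibble.
#' @export
simulate_from_model <- function(model, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- model$k; m <- length(model$snp_ids)
  cls <- sample.int(k, n, replace = TRUE, prob = model$pi)
  g <- matrix(NA_integer_, n, m)
  u <- matrix(runif(n * m), n, m)
  for (kk in seq_len(k)) {
    rows <- which(cls == kk)
    if (!length(rows)) next
    p1 <- matrix(model$theta[kk, , 1], length(rows), m, byrow = TRUE)
    p12 <- p1 + matrix(model$theta[kk, , 2], length(rows), m, byrow = TRUE)
    g[rows, ] <- ifelse(u[rows, , drop = FALSE] < p1, 0L,
                        ifelse(u[rows, , drop = FALSE] < p12, 1L, 2L))
  }
  out <- tibble(individual_id = sprintf("sim%0*d", nchar(n) + 1L, seq_len(n)))
  for (j in seq_len(m)) out[[model$snp_ids[j]]] <- g[, j]
  out
}

#' @export
print.lca_model <- function(x, ...) {
  cat(sprintf("Latent class model: k = %d classes, %d SNPs, n = %d\n",
              x$k, length(x$snp_ids), x$n))
  cat(sprintf("log-likelihood %.3f (%d parameters), %s in %d iterations\n",
              x$loglik, x$n_params,
              if (x$converged) "converged" else "NOT converged", x$n_iterations))
  cat("mixing proportions:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  invisible(x)
}

#' @describeIn lca_fit `tidy()` returns the fitted category probabilities,
#'   one row per (class, SNP, genotype).
#' @param x An `lca_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.lca_model <- function(x, ...) {
  grid <- expand.grid(genotype = 0:2, snp_id = x$snp_ids, class = seq_len(x$k),
                      stringsAsFactors = FALSE)
  grid$estimate <- as.numeric(aperm(x$theta, c(3, 2, 1)))
  as_tibble(grid[c("class", "snp_id", "genotype", "estimate")])
}

#' @describeIn lca_fit `glance()` returns a one-row model summary.
#' @exportS3Method generics::glance
glance.lca_model <- function(x, ...) {
  tibble(k = x$k, loglik = x$loglik, n_params = x$n_params, n = x$n,
         converged = x$converged, n_iterations = x$n_iterations)
}
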