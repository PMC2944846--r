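# helper: hand-built model
toy_model <- function(pi, theta, snp_ids = NULL) {
  k <- length(pi); m <- dim(theta)[2]
  snp_ids <- snp_ids %||% sprintf("snp%02d", seq_len(m))
  structure(list(k = k, pi = pi, theta = theta, snp_ids = snp_ids,
                 loglik = NA_real_, n_params = (k - 1) + k * m * 2,
                 converged = TRUE, n_iterations = 0L, n = 0L),
            class = "lca_model")
}

test_that("log-likelihood matches hand arithmetic and handles all-missing rows", {
  th <- array(0, dim = c(1, 1, 3)); th[1, 1, ] <- c(0.5, 0.3, 0.2)
  mod <- toy_model(1, th, "snp01")
  g <- make_geno(matrix(c(0L, 1L), 2, 1))
  expect_equal(lca_loglik(mod, g), log(0.5) + log(0.3), tolerance = 1e-12)

  g_na <- make_geno(matrix(NA_integer_, 3, 1))
  expect_equal(lca_loglik(mod, g_na), 0)
})

test_that("zero-probability observations give -Inf with a warning, not an error", {
  th <- array(0, dim = c(1, 1, 3)); th[1, 1, ] <- c(1, 0, 0)
  mod <- toy_model(1, th, "snp01")
  g <- make_geno(matrix(2L, 1, 1))
  expect_warning(ll <- lca_loglik(mod, g), "zero probability")
  expect_identical(ll, -Inf)
})

test_that("log-likelihood equals the brute-force class-enumeration oracle", {
  set.seed(4)
  for (k in 1:2) {
    gm <- matrix(sample(c(0:2, NA), 15, replace = TRUE), 5, 3)
    pi <- as.numeric(rmultinom(1, 50, rep(1, k))) / 50
    pi <- pi + 0.01; pi <- pi / sum(pi)
    theta <- array(runif(k * 3 * 3), dim = c(k, 3, 3))
    for (kk in 1:k) for (j in 1:3) {
      theta[kk, j, ] <- theta[kk, j, ] / sum(theta[kk, j, ])
    }
    mod <- toy_model(pi, theta)
    g <- make_geno(gm)
    expect_equal(lca_loglik(mod, g), oracle_loglik(pi, theta, gm),
                 tolerance = 1e-6)
  }
})

test_that("k = 1 fit recovers observed category frequencies and its closed-form loglik", {
  set.seed(2)
  gm <- matrix(sample(c(0:2, NA), 200, replace = TRUE,
                      prob = c(0.5, 0.3, 0.15, 0.05)), 50, 4)
  fit <- lca_fit(make_geno(gm), k = 1)
  closed <- 0
  for (j in 1:4) {
    njg <- tabulate(gm[, j] + 1L, 3)
    nobs <- sum(njg)
    expect_equal(as.numeric(fit$theta[1, j, ]), njg / nobs, tolerance = 1e-6)
    closed <- closed + sum(njg[njg > 0] * log(njg[njg > 0] / nobs))
  }
  expect_equal(fit$loglik, closed, tolerance = 1e-6)
  expect_equal(fit$pi, 1)
})

test_that("EM log-likelihood is monotone non-decreasing on every fit", {
  set.seed(7)
  gm <- matrix(sample(c(0:2, NA), 300, replace = TRUE), 60, 5)
  for (k in 1:3) {
    fit <- lca_fit(make_geno(gm), k, n_starts = 5, seed = k)
    expect_true(all(diff(fit$ll_trace) >= -1e-8))
  }
})

test_that("fitted log-likelihood attains the direct-maximization oracle on tiny instances", {
  # k=2 on a 6x2 matrix: compare against a dense grid over (pi, theta)
  gm <- rbind(c(0L, 0L), c(0L, 0L), c(0L, 1L),
              c(2L, 2L), c(2L, 2L), c(2L, 1L))
  g <- make_geno(gm)
  fit <- lca_fit(g, 2, n_starts = 30, seed = 1)
  grid_best <- -Inf
  probs <- seq(0.05, 0.95, by = 0.15)
  for (pi1 in seq(0.2, 0.8, by = 0.1)) {
    for (t10 in probs) for (t12 in probs) for (t20 in probs) for (t22 in probs) {
      if (t10 + t12 >= 1 || t20 + t22 >= 1) next
      th <- array(0, dim = c(2, 2, 3))
      th[1, 1, ] <- c(t10, 1 - t10 - t12, t12)
      th[1, 2, ] <- th[1, 1, ]
      th[2, 1, ] <- c(t20, 1 - t20 - t22, t22)
      th[2, 2, ] <- th[2, 1, ]
      ll <- oracle_loglik(c(pi1, 1 - pi1), th, gm)
      grid_best <- max(grid_best, ll)
    }
  }
  expect_gte(fit$loglik, grid_best - 1e-6)
})

test_that("posterior memberships follow Bayes' rule and degenerate cases", {
  # hand Bayes: pi=(.5,.5), theta1=(.9,.05,.05), theta2=(.1,.45,.45), g=0
  th <- array(0, dim = c(2, 1, 3))
  th[1, 1, ] <- c(0.9, 0.05, 0.05); th[2, 1, ] <- c(0.1, 0.45, 0.45)
  mod <- toy_model(c(0.5, 0.5), th, "snp01")
  mem <- posterior_memberships(mod, make_geno(matrix(0L, 1, 1), "a"))
  expect_equal(mem$posterior[1, 1], 0.9, tolerance = 1e-12)

  # all-missing individual gets the prior
  mod2 <- toy_model(c(0.3, 0.7), th, "snp01")
  mem2 <- posterior_memberships(mod2, make_geno(matrix(NA_integer_, 1, 1)))
  expect_equal(as.numeric(mem2$posterior), c(0.3, 0.7))

  # k=1: posterior exactly 1
  th1 <- array(0, dim = c(1, 1, 3)); th1[1, 1, ] <- c(0.5, 0.3, 0.2)
  mem1 <- posterior_memberships(toy_model(1, th1, "snp01"),
                                make_geno(matrix(1L, 4, 1)))
  expect_true(all(mem1$posterior == 1))
  # rows sum to 1, assignment attains the max
  expect_equal(rowSums(mem$posterior), 1, tolerance = 1e-10)
  expect_equal(mem$max_posterior[1], mem$posterior[1, mem$assignment[1]])
})

test_that("argmax ties break toward the lowest class index", {
  th <- array(1 / 3, dim = c(2, 1, 3))
  mod <- toy_model(c(0.5, 0.5), th, "snp01")
  mem <- posterior_memberships(mod, make_geno(matrix(1L, 3, 1)))
  expect_true(all(mem$assignment == 1L))
})

test_that("class relabeling leaves the likelihood invariant and permutes posteriors", {
  set.seed(11)
  gm <- matrix(sample(c(0:2, NA), 120, replace = TRUE), 30, 4)
  g <- make_geno(gm)
  fit <- lca_fit(g, 3, n_starts = 5, seed = 2)
  perm <- c(3L, 1L, 2L)
  fit_p <- permute_classes(fit, perm)
  expect_equal(lca_loglik(fit_p, g), lca_loglik(fit, g), tolerance = 1e-10)
  expect_equal(fit_p$membership$posterior, fit$membership$posterior[, perm])
})

test_that("a fully missing SNP column changes no likelihood or posterior", {
  set.seed(13)
  gm <- matrix(sample(0:2, 60, replace = TRUE), 20, 3)
  gm_ext <- cbind(gm, NA_integer_)
  fit <- lca_fit(make_geno(gm), 2, n_starts = 8, seed = 3)
  fit_ext <- lca_fit(make_geno(gm_ext), 2, n_starts = 8, seed = 3)
  expect_equal(fit_ext$loglik, fit$loglik, tolerance = 1e-6)
  perm <- if (sum(abs(fit_ext$pi - fit$pi)) <
              sum(abs(fit_ext$pi - rev(fit$pi)))) 1:2 else 2:1
  expect_equal(fit_ext$membership$posterior[, perm],
               fit$membership$posterior, tolerance = 1e-4)
})

test_that("model invariants hold after fitting", {
  set.seed(17)
  gm <- matrix(sample(c(0:2, NA), 200, replace = TRUE), 50, 4)
  fit <- lca_fit(make_geno(gm), 3, n_starts = 5, seed = 5)
  expect_equal(sum(fit$pi), 1, tolerance = 1e-10)
  sums <- apply(fit$theta, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-10))
  expect_identical(fit$n_params, (3L - 1L) + 3L * 4L * 2L)
  expect_true(is.finite(fit$loglik))
})

test_that("membership summary counts certainty bands correctly", {
  mem <- structure(list(posterior = rbind(c(0.95, 0.05), c(0.7, 0.3),
                                          c(0.5, 0.5)),
                        assignment = c(1L, 1L, 1L),
                        max_posterior = c(0.95, 0.7, 0.5),
                        individual_id = c("a", "b", "c")),
                   class = "lca_membership")
  s <- membership_summary(mem)
  expect_equal(s$n_above_high, 1); expect_equal(s$frac_above_high, 1 / 3)
  expect_equal(s$n_below_low, 1); expect_equal(s$frac_below_low, 1 / 3)

  all_sure <- membership_summary(
    structure(list(max_posterior = rep(1, 5)), class = "lca_membership"))
  expect_equal(all_sure$n_above_high, 5); expect_equal(all_sure$n_below_low, 0)

  uniform6 <- membership_summary(
    structure(list(max_posterior = rep(1 / 6, 10)), class = "lca_membership"))
  expect_equal(uniform6$n_below_low, 10)
  expect_error(membership_summary(mem, high = 0.5, low = 0.9), "thresholds")
})

test_that("parameter recovery on a well-separated 3-class cohort", {
  d <- recovery_design()
  sim <- simulate_cohort(d, seed = 21)
  cases <- dplyr::filter(sim$genotypes, status == "case")
  fit <- lca_fit(cases, 3, n_starts = 20, seed = 6)
  prof <- d$profiles_cases
  perm <- best_permutation(fit$theta, prof)
  aligned <- permute_classes(fit, perm)
  expect_lt(max(abs(aligned$theta - prof)), 0.05)
  expect_lt(max(abs(aligned$pi - d$mixing_cases)), 0.05)
})

test_that("tidy and glance expose the fitted model as tibbles", {
  gm <- matrix(sample(0:2, 60, replace = TRUE), 20, 3)
  fit <- lca_fit(make_geno(gm), 2, n_starts = 5, seed = 1)
  td <- tidy(fit)
  expect_identical(nrow(td), 2L * 3L * 3L)
  one <- td[td$class == 2 & td$snp_id == "snp02", ]
  expect_equal(one$estimate, as.numeric(fit$theta[2, 2, ]))
  gl <- glance(fit)
  expect_identical(gl$k, 2L)
  expect_identical(gl$n, 20L)
})
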