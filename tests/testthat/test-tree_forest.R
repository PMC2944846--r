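test_that("a perfectly separating SNP yields a one-split tree with zero error", {
  gm <- cbind(snpA = c(0, 0, 0, 1, 2, 1, 2, 1), snpB = c(0, 1, 2, 0, 1, 2, 0, 1))
  labels <- c(1, 1, 1, 2, 2, 2, 2, 2)
  g <- make_geno(gm)
  tr <- grow_tree(g, labels, min_split = 2, cp = 0.01)
  expect_identical(tr$root$type, "split")
  expect_identical(tr$root$snp, "snpA")
  expect_identical(tr$root$left_set, 0L)
  expect_identical(tr$root$left$type, "leaf")
  expect_identical(tr$root$right$type, "leaf")
  rep <- drop_down_report(tr, g, labels)
  expect_identical(rep$n_misclassified, 0L)
  expect_identical(rep$n_unallocated, 0L)
  expect_identical(rep$n_correct, 8L)
})

test_that("the root split matches the exhaustive (SNP, subset) oracle", {
  set.seed(12)
  for (rep in 1:20) {
    gm <- matrix(sample(c(0:2, NA), 30, replace = TRUE,
                        prob = c(0.35, 0.3, 0.25, 0.1)), 10, 3)
    labels <- sample(1:2, 10, replace = TRUE)
    if (length(unique(labels)) < 2) next
    want <- oracle_best_split(gm, labels)
    tr <- grow_tree(make_geno(gm), labels, min_split = 2, cp = 1e-9)
    if (!is.finite(want$decrease) || want$decrease <= 1e-9 * tr$root_measure) {
      expect_identical(tr$root$type, "leaf")
    } else {
      expect_identical(tr$root$snp, sprintf("snp%02d", want$snp))
      expect_identical(tr$root$left_set, want$left_set)
      expect_equal(tr$root$decrease, want$decrease, tolerance = 1e-10)
    }
  }
})

test_that("single-class input gives a single leaf", {
  gm <- matrix(sample(0:2, 20, replace = TRUE), 10, 2)
  tr <- grow_tree(make_geno(gm), rep("A", 10), min_split = 2)
  expect_identical(tr$root$type, "leaf")
  expect_identical(tr$root$class, "A")
  dd <- drop_down(tr, make_geno(gm))
  expect_true(all(dd$predicted == "A"))
})

test_that("every accepted split meets the cp impurity-decrease contract", {
  set.seed(14)
  gm <- matrix(sample(c(0:2, NA), 600, replace = TRUE,
                      prob = c(0.4, 0.3, 0.2, 0.1)), 200, 3)
  # labels partly driven by snp01 so the tree certainly splits
  labels <- ifelse(!is.na(gm[, 1]) & gm[, 1] > 0 & runif(200) < 0.8, 2, 1)
  tr <- grow_tree(make_geno(gm), labels, min_split = 10, cp = 0.02)
  expect_identical(tr$root$type, "split")
  n_checked <- 0
  check <- function(node) {
    if (node$type == "leaf") return(invisible())
    n_checked <<- n_checked + 1
    expect_gte(node$decrease, 0.02 * tr$root_measure)
    check(node$left); check(node$right)
  }
  check(tr$root)
  expect_gte(n_checked, 1)
})

test_that("drop-down returns UNALLOCATED exactly when a decision SNP is missing", {
  gm <- cbind(snpA = c(0, 0, 1, 1, 2, 2), snpB = c(0, 1, 0, 1, 0, 1))
  labels <- c(1, 1, 2, 2, 2, 2)
  g <- make_geno(gm)
  tr <- grow_tree(g, labels, min_split = 2)
  # missing at the root SNP -> unallocated; missing at an unused SNP -> fine
  probe <- make_geno(cbind(snpA = c(NA, 0), snpB = c(0, NA)))
  dd <- drop_down(tr, probe)
  expect_true(dd$unallocated[1])
  expect_false(dd$unallocated[2])
  expect_identical(dd$predicted[2], 1)
})

test_that("drop-down report counts partition n and match a confusion oracle", {
  set.seed(15)
  gm <- matrix(sample(c(0:2, NA), 300, replace = TRUE,
                      prob = c(0.35, 0.3, 0.25, 0.1)), 100, 3)
  labels <- sample(1:2, 100, replace = TRUE)
  g <- make_geno(gm)
  tr <- grow_tree(g, labels, min_split = 10, cp = 0.005)
  ref <- sample(1:2, 100, replace = TRUE)   # arbitrary reference labeling
  rep <- drop_down_report(tr, g, ref)
  expect_identical(rep$n_correct + rep$n_misclassified + rep$n_unallocated,
                   rep$n_total)
  dd <- drop_down(tr, g)
  expect_identical(rep$n_correct, sum(!dd$unallocated & dd$predicted == ref))
  expect_identical(rep$n_misclassified, sum(!dd$unallocated & dd$predicted != ref))
  expect_identical(rep$n_unallocated, sum(dd$unallocated))
  expect_error(drop_down_report(tr, g, ref[-1]), "dimension")
})

test_that("tree growth is deterministic given data and settings", {
  set.seed(16)
  gm <- matrix(sample(c(0:2, NA), 240, replace = TRUE), 80, 3)
  labels <- sample(1:3, 80, replace = TRUE)
  t1 <- grow_tree(make_geno(gm), labels, min_split = 10, cp = 0.005)
  t2 <- grow_tree(make_geno(gm), labels, min_split = 10, cp = 0.005)
  expect_identical(t1, t2)
})

test_that("forest finds a planted perfectly informative feature", {
  set.seed(17)
  n <- 500
  f1 <- sample(0:1, n, replace = TRUE)
  feats <- data.frame(f1 = f1,
                      noise1 = rnorm(n), noise2 = sample(0:2, n, TRUE),
                      noise3 = rnorm(n))
  fr <- fit_forest(feats, labels = f1, n_trees = 200, seed = 4)
  expect_lt(fr$oob_error_rate, 0.05)
  imp <- fr$importance
  expect_identical(imp$feature[which.max(imp$mda)], "f1")
  expect_identical(imp$feature[which.max(imp$gini)], "f1")
})

test_that("forest OOB error sits at chance on pure-noise features", {
  set.seed(18)
  n <- 1000; k <- 4
  feats <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  labels <- rep(1:k, length.out = n)
  fr <- fit_forest(feats, labels, n_trees = 200, seed = 5)
  expect_lt(abs(fr$oob_error_rate - (k - 1) / k), 0.05)
})

test_that("a constant feature is warned about and gets zero permutation importance", {
  set.seed(19)
  feats <- data.frame(x = rnorm(100), flat = rep(1, 100))
  labels <- rep(1:2, 50)
  expect_warning(fr <- fit_forest(feats, labels, n_trees = 50, seed = 6),
                 "zero-variance")
  expect_identical(fr$importance$mda[fr$importance$feature == "flat"], 0)
})

test_that("forest is reproducible given a seed and honours NA policy", {
  set.seed(20)
  feats <- data.frame(x = rnorm(60), y = rnorm(60))
  labels <- rep(1:2, 30)
  a <- fit_forest(feats, labels, n_trees = 50, seed = 9)
  b <- fit_forest(feats, labels, n_trees = 50, seed = 9)
  expect_equal(a$oob_error_rate, b$oob_error_rate)
  expect_equal(a$importance, b$importance)
  feats$x[1] <- NA
  expect_error(fit_forest(feats, labels, n_trees = 10, seed = 1), "NA")
  expect_s3_class(fit_forest(feats, labels, n_trees = 10, seed = 1,
                             na_action = "roughfix"), "forest_report")
})
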