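#' Grow a genotype-subset classification tree explaining cluster labels
#'
#' CART-style recursive binary partitioning with the cluster assignment as the
#' categorical response and SNPs as candidate explanatory variables. Genotypes
#' are treated as unordered categories: every candidate split sends a proper
#' nonempty subset of \{0,1,2\} left, and all `2^(c-1) - 1` partitions of the
#' categories present are searched exhaustively. The split maximising the
#' decrease in count-weighted Gini impurity wins; individuals missing at a
#' candidate SNP are excluded from that split's evaluation, and individuals
#' missing at the chosen SNP take no further part in growing that branch
#' (there are no surrogate splits). Growth stops at purity, below `min_split`
#' individuals, or when the best impurity decrease falls below `cp` times the
#' root impurity.
#'
#' @param geno A genotype tibble.
#' @param labels Cluster assignment per individual (length `n`).
#' @param min_split Minimum node size eligible for splitting, default 20.
#' @param cp Complexity threshold: a split must reduce the count-weighted Gini
#'   impurity by at least `cp * n * gini(root)`, default 0.01.
#' @return An `snp_tree`; print it for an indented rule display, or use
#'   [drop_down()] / [drop_down_report()].
#' @export
grow_tree <- function(geno, labels, min_split = 20, cp = 0.01) {
  gm <- geno_matrix(geno)
  if (length(labels) != nrow(gm)) {
    abort(sprintf("dimension error: %d labels for %d individuals",
                  length(labels), nrow(gm)))
  }
  classes <- sort(unique(labels))
  y <- as.integer(factor(labels, levels = classes))
  gini <- function(counts) 1 - sum((counts / sum(counts))^2)
  count_y <- function(idx) tabulate(y[idx], nbins = length(classes))

  root_counts <- count_y(seq_along(y))
  root_measure <- length(y) * gini(root_counts)  # impurity units for cp
  partitions <- list(0L, 1L, 2L)                 # subset sent left; complement right

  best_split <- function(idx) {
    best <- list(decrease = -Inf)
    for (j in seq_len(ncol(gm))) {
      gj <- gm[idx, j]
      obs <- !is.na(gj)
      if (sum(obs) < 2) next
      gj <- gj[obs]; yj <- y[idx][obs]
      node_counts <- tabulate(yj, nbins = length(classes))
      node_imp <- sum(node_counts) * gini(node_counts)
      for (p in partitions) {
        left <- gj %in% p
        nl <- sum(left)
        if (nl == 0 || nl == length(gj)) next
        cl <- tabulate(yj[left], nbins = length(classes))
        cr <- node_counts - cl
        dec <- node_imp - sum(cl) * gini(cl) - sum(cr) * gini(cr)
        if (dec > best$decrease + 1e-12) {
          best <- list(decrease = dec, snp = j, left_set = p)
        }
      }
    }
    best
  }

  build <- function(idx) {
    counts <- count_y(idx)
    majority <- classes[which.max(counts)]    # ties -> lowest class
    leaf <- list(type = "leaf", class = majority, counts = counts,
                 n = length(idx))
    if (sum(counts > 0) <= 1 || length(idx) < min_split) return(leaf)
    b <- best_split(idx)
    if (!is.finite(b$decrease) || b$decrease < cp * root_measure) return(leaf)
    gj <- gm[idx, b$snp]
    obs <- !is.na(gj)
    go_left <- obs & gj %in% b$left_set
    go_right <- obs & !gj %in% b$left_set
    list(type = "split", snp = colnames(gm)[b$snp], left_set = b$left_set,
         right_set = setdiff(0:2, b$left_set), decrease = b$decrease,
         counts = counts, n = length(idx),
         left = build(idx[go_left]), right = build(idx[go_right]))
  }

  structure(list(root = build(seq_along(y)), classes = classes,
                 snp_ids = colnames(gm), min_split = min_split, cp = cp,
                 root_measure = root_measure),
            class = "snp_tree")
}

tree_depth <- function(node) {
  if (node$type == "leaf") return(0L)
  1L + max(tree_depth(node$left), tree_depth(node$right))
}

#' @export
print.snp_tree <- function(x, ...) {
  cat(sprintf("Genotype classification tree (depth %d, cp = %g)\n",
              tree_depth(x$root), x$cp))
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(sprintf("%s=> cluster %s  [%s] n=%d\n", pad, node$class,
                  paste(node$counts, collapse = "/"), node$n))
    } else {
      cat(sprintf("%s%s genotype in {%s}?\n", pad, node$snp,
                  paste(node$left_set, collapse = ",")))
      show(node$left, indent + 1)
      cat(sprintf("%selse (in {%s}):\n", pad,
                  paste(node$right_set, collapse = ",")))
      show(node$right, indent + 1)
    }
  }
  show(x$root, 0)
  invisible(x)
}

#' Drop individuals down a classification tree
#'
#' Follows each individual's genotypes through the tree's subset decisions to a
#' leaf. An individual missing the genotype at any decision SNP on its path is
#' *unallocated* (there are no surrogate splits): `predicted` is `NA`.
#'
#' @param tree An `snp_tree`.
#' @param geno A genotype tibble covering the tree's SNPs.
#' @return A tibble: `individual_id`, `predicted`, `unallocated`.
#' @export
drop_down <- function(tree, geno) {
  gm <- geno_matrix(geno)
  missing_snp <- setdiff(used_snps(tree$root), colnames(gm))
  if (length(missing_snp)) {
    abort(sprintf("genotype table lacks decision SNP(s): %s",
                  paste(missing_snp, collapse = ", ")))
  }
  classify <- function(i) {
    node <- tree$root
    while (node$type == "split") {
      g <- gm[i, node$snp]
      if (is.na(g)) return(NA_integer_)
      node <- if (g %in% node$left_set) node$left else node$right
    }
    match(node$class, tree$classes)
  }
  idx <- vapply(seq_len(nrow(gm)), classify, integer(1))
  tibble(individual_id = rownames(gm), predicted = tree$classes[idx],
         unallocated = is.na(idx))
}

used_snps <- function(node) {
  if (node$type == "leaf") return(character())
  unique(c(node$snp, used_snps(node$left), used_snps(node$right)))
}

#' Goodness-of-fit of a tree against reference cluster labels
#'
#' Drops every individual down the tree and compares the tree-based class to
#' the reference (model-based) assignment: correct, misclassified, or
#' unallocated because of a missing genotype at a decision SNP. The three
#' counts always partition `n`.
#'
#' @inheritParams drop_down
#' @param labels Reference assignments, length `n`.
#' @return A `drop_down_report`: counts, rates, and the per-cluster confusion
#'   tibble (`reference`, `predicted`, `n`; unallocated rows have
#'   `predicted = NA`).
#' @export
drop_down_report <- function(tree, geno, labels) {
  if (length(labels) != nrow(geno)) {
    abort(sprintf("dimension error: %d labels for %d individuals",
                  length(labels), nrow(geno)))
  }
  dd <- drop_down(tree, geno)
  ok <- !dd$unallocated & dd$predicted == labels
  mis <- !dd$unallocated & dd$predicted != labels
  conf <- tibble(reference = labels, predicted = dd$predicted) %>%
    group_by(.data$reference, .data$predicted) %>%
    summarise(n = dplyr::n(), .groups = "drop")
  structure(list(n_total = nrow(dd), n_correct = sum(ok),
                 n_misclassified = sum(mis),
                 n_unallocated = sum(dd$unallocated),
                 confusion = conf),
            class = "drop_down_report")
}

#' @export
print.drop_down_report <- function(x, ...) {
  cat(sprintf(
    "Drop-down report: n = %d\ncorrect %d (%.1f%%), misclassified %d (%.1f%%), unallocated %d (%.1f%%)\n",
    x$n_total, x$n_correct, 100 * x$n_correct / x$n_total,
    x$n_misclassified, 100 * x$n_misclassified / x$n_total,
    x$n_unallocated, 100 * x$n_unallocated / x$n_total))
  invisible(x)
}

#' @describeIn drop_down_report `glance()` one-row counts and rates.
#' @param x A `drop_down_report`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.drop_down_report <- function(x, ...) {
  tibble(n_total = x$n_total, n_correct = x$n_correct,
         n_misclassified = x$n_misclassified, n_unallocated = x$n_unallocated,
         misclassified_rate = x$n_misclassified / x$n_total,
         unallocated_rate = x$n_unallocated / x$n_total)
}

#' Random forest of cluster labels on features
#'
#' Bagged classification forest (Breiman-Cutler, via the randomForest package)
#' predicting cluster membership from SNPs or numerically coded clinical
#' variables. Reports the out-of-bag (OOB) misclassification rate and two
#' variable-importance measures that need not agree: permutation mean decrease
#' in accuracy (raw, unscaled) and mean decrease in Gini impurity.
#'
#' @param features A data frame / tibble of predictors (no id columns).
#' @param labels Class labels, length `nrow(features)`.
#' @param n_trees Number of trees, default 500.
#' @param mtry Candidate features per split; default `floor(sqrt(m))`.
#' @param seed Integer seed.
#' @param na_action `"fail"` (default) or `"roughfix"` (median/mode fill).
#' @return A `forest_report`: `oob_error_rate`, importance tibble (`tidy()`),
#'   and the underlying `randomForest` fit.
#' @export
fit_forest <- function(features, labels, n_trees = 500, mtry = NULL,
                       seed = 1L, na_action = c("fail", "roughfix")) {
  na_action <- match.arg(na_action)
  features <- as.data.frame(features)
  if (nrow(features) < 2) abort("need at least 2 individuals")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(features))))
  if (mtry > ncol(features)) abort("mtry exceeds the number of features")
  const <- vapply(features, function(v) length(unique(v[!is.na(v)])) <= 1,
                  logical(1))
  if (any(const)) {
    warn(sprintf("zero-variance feature(s): %s (importance will be 0)",
                 paste(names(features)[const], collapse = ", ")))
  }
  if (anyNA(features)) {
    if (na_action == "fail") {
      abort("features contain NA; use na_action = 'roughfix' or complete cases")
    }
    features <- randomForest::na.roughfix(features)
  }
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = features, y = factor(labels), ntree = n_trees, mtry = mtry,
    importance = TRUE)
  imp_mda <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  imp_gini <- randomForest::importance(rf, type = 2)[, 1]
  structure(list(
    n_trees = n_trees, mtry = mtry,
    oob_error_rate = unname(rf$err.rate[n_trees, "OOB"]),
    importance = tibble(feature = names(features),
                        mda = unname(imp_mda[names(features)]),
                        gini = unname(imp_gini[names(features)])),
    seed = seed, fit = rf), class = "forest_report")
}

#' @export
print.forest_report <- function(x, ...) {
  cat(sprintf("Random forest: %d trees, mtry = %d, OOB error %.2f%%\n",
              x$n_trees, x$mtry, 100 * x$oob_error_rate))
  print(dplyr::arrange(x$importance, dplyr::desc(.data$mda)))
  invisible(x)
}

#' @describeIn fit_forest `tidy()` per-feature importance.
#' @param x A `forest_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.forest_report <- function(x, ...) x$importance

#' @describeIn fit_forest `glance()` one-row fit summary.
#' @exportS3Method generics::glance
glance.forest_report <- function(x, ...) {
  tibble(n_trees = x$n_trees, mtry = x$mtry,
         oob_error_rate = x$oob_error_rate)
}
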