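#' Configure a full reclassification analysis
#'
#' Bundles everything [run_pipeline()] needs: either a simulation design or
#' paths/tibbles for genotype + phenotype input, the class-selection settings,
#' EM settings, tree settings, and the seed. Exactly one of `design` or
#' `genotypes` must be given.
#'
#' @param design A [simulation_design()] (synthetic cohort), or `NULL`.
#' @param genotypes A genotype tibble with a `status` column, or a file path
#'   readable by [read_genotypes()].
#' @param phenotypes A phenotype tibble aligned to the case individuals, or a
#'   file path; optional.
#' @param alpha Class-selection significance level, default 0.05.
#' @param B Bootstrap replicates per test, default 20.
#' @param k_max Largest number of classes considered per group.
#' @param k_cases,k_controls Optional forced class counts (skip selection).
#' @param n_starts,boot_n_starts,tol,max_iter EM settings (see [lca_fit()] and
#'   [bootstrap_lrt()]).
#' @param min_split,cp Tree settings (see [grow_tree()]).
#' @param seed Integer master seed.
#' @param outdir Optional directory for report artifacts.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(design = NULL, genotypes = NULL, phenotypes = NULL,
                            alpha = 0.05, B = 20, k_max = 8,
                            k_cases = NULL, k_controls = NULL,
                            n_starts = 20, boot_n_starts = n_starts,
                            tol = 1e-8, max_iter = 2000,
                            min_split = 20, cp = 0.01,
                            seed = 1L, outdir = NULL) {
  if (is.null(design) == is.null(genotypes)) {
    abort("exactly one of `design` or `genotypes` must be supplied")
  }
  if (is.character(genotypes) && !file.exists(genotypes)) {
    abort(sprintf("file not found: %s", genotypes))
  }
  if (is.character(phenotypes) && !file.exists(phenotypes)) {
    abort(sprintf("file not found: %s", phenotypes))
  }
  structure(list(design = design, genotypes = genotypes,
                 phenotypes = phenotypes,
                 alpha = alpha, B = B, k_max = k_max,
                 k_cases = k_cases, k_controls = k_controls,
                 n_starts = n_starts, boot_n_starts = boot_n_starts,
                 tol = tol, max_iter = max_iter,
                 min_split = min_split, cp = cp,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

analyse_group <- function(geno, cfg, k_forced, seed) {
  sel <- NULL
  if (is.null(k_forced)) {
    sel <- select_num_classes(geno, alpha = cfg$alpha, k_max = cfg$k_max,
                              B = cfg$B, seed = seed,
                              n_starts = cfg$n_starts,
                              boot_n_starts = cfg$boot_n_starts,
                              tol = cfg$tol, max_iter = cfg$max_iter)
    k <- sel$k
  } else k <- as.integer(k_forced)

  # one fit per step k' = 1..k so membership flow between successive models
  # can be tabulated; the final fit is the reported model
  fits <- lapply(seq_len(k), function(kk)
    lca_fit(geno, kk, n_starts = cfg$n_starts, tol = cfg$tol,
            max_iter = cfg$max_iter, seed = seed + 1000L + kk))
  model <- fits[[k]]
  mem <- lca_memberships(model)
  flows <- if (k > 1) {
    lapply(seq_len(k - 1), function(kk)
      cluster_flow(fits[[kk]]$membership$assignment,
                   fits[[kk + 1]]$membership$assignment))
  } else list()

  tree <- grow_tree(geno, mem$assignment, min_split = cfg$min_split,
                    cp = cfg$cp)
  dd <- drop_down_report(tree, geno, mem$assignment)

  list(k = k, selection = sel, model = model, membership = mem,
       membership_summary = membership_summary(model),
       flows = flows, tree = tree, drop_down = dd)
}

#' Run the reclassification pipeline end-to-end
#'
#' Per group (cases, controls, analysed separately after orienting the coding
#' to the control minor allele): selects the number of latent classes by
#' bootstrap LRT (unless forced), fits the latent class model, summarises
#' membership certainty, tabulates cluster flow across the stepwise models,
#' and grows + evaluates the explanatory SNP tree. Then compares the two
#' groups: canonical discriminant analysis within each group, projection of
#' the controls through the case-derived rule, and a Wilks-lambda MANOVA of
#' the first two canonical means. Finally, if phenotypes are available, the
#' cluster-vs-phenotype association table and a clinical random forest.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list with components `cases`, `controls`,
#'   `cda`, `association`, `clinical_forest`, `config`; reproducible
#'   bit-for-bit given the same config and seed.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e))))
  }

  phen <- NULL
  if (!is.null(cfg$design)) {
    sim <- stage("simulate", simulate_cohort(cfg$design, seed = cfg$seed))
    geno <- sim$genotypes
    phen <- sim$phenotypes
  } else {
    geno <- stage("load", {
      g <- if (is.character(cfg$genotypes)) read_genotypes(cfg$genotypes) else
        cfg$genotypes
      validate_genotypes(g)
    })
    if (!is.null(cfg$phenotypes)) {
      phen <- if (is.character(cfg$phenotypes)) read_phenotypes(cfg$phenotypes)
        else cfg$phenotypes
    }
  }
  if (!"status" %in% names(geno)) {
    abort("pipeline input needs a `status` column (case/control)")
  }

  geno <- stage("orient", orient_to_control_minor(geno))
  cases <- dplyr::filter(geno, .data$status == "case")
  controls <- dplyr::filter(geno, .data$status == "control")

  res_cases <- stage("cases", analyse_group(cases, cfg, cfg$k_cases, cfg$seed))
  res_controls <- stage("controls",
                        analyse_group(controls, cfg, cfg$k_controls,
                                      cfg$seed + 500000L))

  cda <- stage("cda", {
    rule_cases <- if (res_cases$k >= 3) {
      fit_cda(cases, res_cases$membership$assignment)
    } else pca_rule(cases, n_axes = 2)   # no 2-axis discriminant below k = 3
    cda_controls <- if (res_controls$k >= 2) {
      fit_cda(controls, res_controls$membership$assignment)
    } else NULL
    case_scores <- first_two_axes(score_of(rule_cases, cases,
                                           res_cases$membership$assignment))
    ctrl_proj <- first_two_axes(project_cda(rule_cases, controls,
                                            res_controls$membership$assignment))
    list(rule_cases = rule_cases, cda_controls = cda_controls,
         case_scores = case_scores, control_projected = ctrl_proj,
         manova = manova_wilks(case_scores, ctrl_proj))
  })

  association <- NULL
  clinical_forest <- NULL
  if (!is.null(phen) && res_cases$k >= 2) {
    stopifnot(nrow(phen) == nrow(cases))
    association <- stage("associate",
      cluster_phenotype_table(res_cases$membership$assignment, phen))
    feat <- as.data.frame(phen[setdiff(names(phen), "individual_id")])
    feat <- feat[vapply(feat, function(v) is.logical(v) || is.numeric(v),
                        logical(1))]
    clinical_forest <- stage("forest",
      fit_forest(feat, res_cases$membership$assignment,
                 seed = cfg$seed + 900000L, na_action = "roughfix"))
  }

  report <- structure(list(cases = res_cases, controls = res_controls,
                           cda = cda, association = association,
                           clinical_forest = clinical_forest,
                           config = cfg),
                      class = "pipeline_report")
  if (!is.null(cfg$outdir)) write_report(report, cfg$outdir)
  report
}

# Degenerate-path rule: with fewer than 3 case clusters CDA has under 2 axes,
# so the cross-group comparison falls back to the leading two principal
# components of the case genotypes (mean-imputed), wrapped in the same
# linear-rule shape project_cda() expects.
pca_rule <- function(geno, n_axes = 2) {
  x <- cda_numeric(geno)
  impute_means <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- impute_means[j]
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  A <- pc$rotation[, seq_len(n_axes), drop = FALSE]
  colnames(A) <- paste0("can", seq_len(n_axes))
  structure(list(coefficients = A, eigenvalues = pc$sdev[seq_len(n_axes)]^2,
                 centering = pc$center, impute_means = impute_means,
                 scores = NULL, n = nrow(x), n_groups = 1L,
                 snp_ids = colnames(x)),
            class = "cda_fit")
}

score_of <- function(rule, geno, labels) {
  if (!is.null(rule$scores)) rule$scores else project_cda(rule, geno, labels)
}

first_two_axes <- function(scores) {
  keep <- intersect(c("individual_id", "cluster", "can1", "can2"),
                    names(scores))
  scores[keep]
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("=== Genotype-driven reclassification report ===\n")
  for (grp in c("cases", "controls")) {
    r <- x[[grp]]
    ms <- r$membership_summary
    cat(sprintf("\n[%s] chosen k = %d\n", grp, r$k))
    if (!is.null(r$selection)) print(r$selection$path)
    cat(sprintf("membership: %.1f%% above 0.9, %.1f%% below 0.6\n",
                100 * ms$frac_above_high, 100 * ms$frac_below_low))
    print(r$drop_down)
  }
  cat("\n[case vs control geometry]\n")
  print(x$cda$manova)
  if (!is.null(x$association)) {
    cat("\n[cluster-phenotype associations] (rows with chi2 p < 0.05)\n")
    print(dplyr::filter(x$association, .data$chi2_p < 0.05))
  }
  if (!is.null(x$clinical_forest)) {
    cat(sprintf("\n[clinical forest] OOB error %.2f%%\n",
                100 * x$clinical_forest$oob_error_rate))
  }
  invisible(x)
}

#' @describeIn run_pipeline `glance()` one-row headline summary.
#' @param x A `pipeline_report`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.pipeline_report <- function(x, ...) {
  tibble(k_cases = x$cases$k, k_controls = x$controls$k,
         frac_above_high_cases = x$cases$membership_summary$frac_above_high,
         frac_below_low_cases = x$cases$membership_summary$frac_below_low,
         misclassified_rate_cases =
           x$cases$drop_down$n_misclassified / x$cases$drop_down$n_total,
         unallocated_rate_cases =
           x$cases$drop_down$n_unallocated / x$cases$drop_down$n_total,
         manova_p = x$cda$manova$p_value,
         clinical_oob_error = if (is.null(x$clinical_forest)) NA_real_ else
           x$clinical_forest$oob_error_rate)
}

#' Write pipeline report artifacts
#'
#' Persists the report as a human-readable text file plus delimited tables
#' (selection path, memberships, flows, association table, canonical scores)
#' under `dir`.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(utils::capture.output(print(report)),
             file.path(dir, "report.txt"))
  for (grp in c("cases", "controls")) {
    r <- report[[grp]]
    if (!is.null(r$selection)) {
      write.csv(r$selection$path,
                file.path(dir, paste0(grp, "_selection.csv")),
                row.names = FALSE)
    }
    write.csv(lca_memberships(r$model),
              file.path(dir, paste0(grp, "_memberships.csv")),
              row.names = FALSE)
  }
  write.csv(report$cda$case_scores, file.path(dir, "case_scores.csv"),
            row.names = FALSE)
  write.csv(report$cda$control_projected,
            file.path(dir, "control_projected_scores.csv"), row.names = FALSE)
  if (!is.null(report$association)) {
    write.csv(report$association, file.path(dir, "association.csv"),
              row.names = FALSE)
  }
  invisible(dir)
}
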