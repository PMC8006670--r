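# End-to-end orchestration: normalize -> contrasts -> calibrate -> label ->
# assess -> null models -> correlations -> perturbed-vs-unperturbed
# comparison, with an on-disk JSON report.

#' Run the full consistency analysis
#'
#' Executes every stage of the analysis on a network + compendium +
#' contrast-definition triple: per-dataset quantile normalization and
#' z-scoring (each optional), contrast computation, threshold calibration at
#' the target deregulated fraction, ternary labelling, sign-consistency
#' assessment, both empirical null models, regulator-target correlation
#' summaries, and the Mann-Whitney comparisons of perturbed vs unperturbed
#' contrasts. All randomness flows from `seed` through derived substreams;
#' reruns with the same inputs and seed are reproducible.
#'
#' @param net a [regulatory_network()].
#' @param comp an [expression_compendium()].
#' @param defs a [contrast_definitions()] table.
#' @param f target deregulated fraction for [calibrate_threshold()]
#'   (default 0.5; 1/3 and 2/3 are the usual sensitivity settings).
#' @param n_iter null-model iterations (default 200).
#' @param null_methods subset of `c("profile_shuffle", "edge_shuffle")`.
#' @param cor_methods subset of `c("pearson", "spearman")`.
#' @param quantile,zscore logical; apply the corresponding normalization
#'   stage. Disable both when the compendium is already normalized.
#' @param include_all_pairs compute the all-possible-pairs correlation
#'   category (quadratic; see [pair_correlations()]).
#' @param seed master seed.
#' @param out_dir optional directory; when given, writes `report.json`,
#'   `edges.tsv`, `contrasts.tsv`, `pairs_<method>.tsv` and
#'   `null_<method>.json` there.
#' @return List of class `grnsign_report` with elements `threshold`
#'   (a `threshold_calibration`), `report` (the [assess()] result), `nulls`
#'   (named list of [null_distribution()]s with observed percentiles),
#'   `correlations` (named list of [pair_correlations()] summaries),
#'   `group_comparisons` (see [summarize_contrast_groups()]), `overlap`
#'   (genes shared by network and compendium), `seed`, `f`.
#' @export
run_full_analysis <- function(net, comp, defs, f = 0.5, n_iter = 200L,
                              null_methods = c("profile_shuffle",
                                               "edge_shuffle"),
                              cor_methods = c("pearson", "spearman"),
                              quantile = TRUE, zscore = TRUE,
                              include_all_pairs = TRUE,
                              seed = 1L, out_dir = NULL) {
  stopifnot(inherits(net, "regulatory_network"),
            inherits(comp, "expression_compendium"),
            inherits(defs, "contrast_definitions"))
  null_methods <- match.arg(null_methods, several.ok = TRUE)
  cor_methods <- match.arg(cor_methods, several.ok = TRUE)
  overlap <- intersect(net$nodes, rownames(comp$values))
  if (length(overlap) == 0L) {
    stop("no gene id overlap between network and compendium")
  }

  if (quantile) comp <- quantile_normalize(comp)
  if (zscore) comp <- zscore_by_dataset(comp)
  cm <- compute_contrasts(comp, defs)
  cal <- calibrate_threshold(cm, f = f)
  labels <- label_genes(cm, cal)
  report <- assess(net, labels)

  null_seeds <- derive_seeds(seed, 2L)
  names(null_seeds) <- c("profile_shuffle", "edge_shuffle")
  nulls <- list()
  for (m in null_methods) {
    nd <- null_distribution(net, cm, cal, method = m, n_iter = n_iter,
                            seed = null_seeds[[m]])
    nd$observed <- report$global
    nd$observed_percentile <- null_percentile(nd, report$global)
    nulls[[m]] <- nd
  }

  correlations <- list()
  for (m in cor_methods) {
    correlations[[m]] <- pair_correlations(
      net, comp, method = m, include_all_pairs = include_all_pairs)
  }

  group_comparisons <- summarize_contrast_groups(report, defs)

  out <- structure(list(
    threshold = cal, report = report, nulls = nulls,
    correlations = correlations, group_comparisons = group_comparisons,
    overlap = length(overlap), seed = as.integer(seed), f = f
  ), class = "grnsign_report")
  if (!is.null(out_dir)) write_run_report(out, out_dir)
  out
}

#' Compare perturbed and unperturbed contrasts
#'
#' Two Mann-Whitney comparisons across the contrast columns: the per-contrast
#' inconsistency loads, and the per-contrast counts of deregulated
#' (up- or downregulated) genes, each split by the `perturbed` flag of the
#' contrast definitions.
#'
#' @param report an [assess()] report.
#' @param defs the matching [contrast_definitions()] table.
#' @return List with `inconsistency` and `deregulated`, each a
#'   [mann_whitney_u()] result augmented with the two group means
#'   (`mean_perturbed`, `mean_unperturbed`).
#' @export
summarize_contrast_groups <- function(report, defs) {
  stopifnot(inherits(report, "inconsistency_report"),
            inherits(defs, "contrast_definitions"))
  flag <- stats::setNames(defs$perturbed, defs$contrast)
  per_c <- report$per_contrast
  pert <- flag[per_c$contrast]
  if (anyNA(pert)) stop("report contrasts missing from the definitions")
  if (!any(pert) || all(pert)) {
    stop(sprintf(
      "need contrasts in both groups (perturbed: %d, unperturbed: %d)",
      sum(pert), sum(!pert)))
  }
  cmp_one <- function(vals) {
    x <- vals[pert]; y <- vals[!pert]
    out <- mann_whitney_u(x, y)
    out$mean_perturbed <- mean(x)
    out$mean_unperturbed <- mean(y)
    out
  }
  list(inconsistency = cmp_one(per_c$inconsistencies),
       deregulated = cmp_one(report$deregulated_per_contrast$deregulated))
}

#' Write a full-analysis report to disk
#'
#' `report.json` holds every summary quantity (threshold, achieved fraction,
#' global load, nPairs, mEdge, role splits, null mGlobals and observed
#' percentiles, per-category mean correlations, group comparisons, dropped
#' genes/edges); per-edge, per-contrast and per-pair tables go to TSV and
#' each null distribution to its own JSON.
#'
#' @param result a `grnsign_report` from [run_full_analysis()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(result, dir) {
  stopifnot(inherits(result, "grnsign_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep <- result$report
  summary <- list(
    seed = result$seed,
    target_fraction = result$f,
    threshold = result$threshold$t,
    achieved_fraction = result$threshold$achieved_fraction,
    global = rep$global,
    nPairs = rep$nPairs,
    mEdge = rep$mEdge,
    splits = as.list(rep$splits),
    dropped_genes = length(rep$dropped$genes),
    dropped_edges = nrow(rep$dropped$edges),
    overlap_genes = result$overlap,
    nulls = lapply(result$nulls, function(nd) {
      list(method = nd$method, n_iter = nd$n_iter, seed = nd$seed,
           mGlobal = nd$mGlobal, observed = nd$observed,
           observed_percentile = nd$observed_percentile, loads = nd$loads)
    }),
    mean_correlations = lapply(result$correlations, function(cs) {
      as.list(cs$mc)
    }),
    group_comparisons = lapply(result$group_comparisons, function(gc) {
      list(U = gc$U, p = gc$p, n_perturbed = gc$n1, n_unperturbed = gc$n2,
           mean_perturbed = gc$mean_perturbed,
           mean_unperturbed = gc$mean_unperturbed, method = gc$method)
    })
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_report_tables(rep, file.path(dir, "edges.tsv"),
                      file.path(dir, "contrasts.tsv"))
  for (m in names(result$correlations)) {
    utils::write.table(result$correlations[[m]]$pairs,
                       file.path(dir, sprintf("pairs_%s.tsv", m)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (m in names(result$nulls)) {
    nd <- result$nulls[[m]]
    jsonlite::write_json(
      list(method = nd$method, seed = nd$seed, n_iter = nd$n_iter,
           loads = nd$loads, mGlobal = nd$mGlobal, observed = nd$observed,
           observed_percentile = nd$observed_percentile),
      file.path(dir, sprintf("null_%s.json", m)),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @export
print.grnsign_report <- function(x, ...) {
  cat(sprintf("grnsign_report (seed %d, f = %.3f):\n", x$seed, x$f))
  cat(sprintf("  t = %.4g (achieved fraction %.3f)\n", x$threshold$t,
              x$threshold$achieved_fraction))
  cat(sprintf("  global = %d over %d edges (mEdge = %.3f)\n",
              x$report$global, x$report$nPairs, x$report$mEdge))
  for (m in names(x$nulls)) {
    cat(sprintf("  null %s: mGlobal = %.2f, observed at percentile %.1f\n",
                m, x$nulls[[m]]$mGlobal, x$nulls[[m]]$observed_percentile))
  }
  for (m in names(x$correlations)) {
    mc <- x$correlations[[m]]$mc
    cat(sprintf("  mc (%s): activation %.3f, repression %.3f\n", m,
                mc[["activation"]], mc[["repression"]]))
  }
  gc <- x$group_comparisons$inconsistency
  cat(sprintf(
    "  perturbed vs unperturbed load: %.2f vs %.2f (MW p = %.3g)\n",
    gc$mean_perturbed, gc$mean_unperturbed, gc$p))
  invisible(x)
}
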