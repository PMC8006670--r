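# Conservative sign-consistency model: per-edge verdicts and aggregated
# inconsistency reports.

#' Verdict of one edge under one pair of labels
#'
#' The conservative rule: an edge is *inconsistent* only when both endpoints
#' are labelled changed and the target's label contradicts
#' sign(edge) x label(regulator); it is *consistent* when both are changed
#' and agree; any "unchanged" (0) endpoint yields *indeterminate* and never
#' counts as an inconsistency. Under activation an upregulated regulator
#' should see an upregulated target; under repression, a downregulated one.
#'
#' @param label_u regulator label(s) in \{-1, 0, +1\} (vectorized).
#' @param sign edge sign(s), +1 activation / -1 repression.
#' @param label_v target label(s) in \{-1, 0, +1\}.
#' @return Character vector in
#'   \{"consistent", "inconsistent", "indeterminate"\}.
#' @examples
#' edge_consistency(1, 1, -1)   # inconsistent
#' edge_consistency(1, -1, -1)  # consistent
#' edge_consistency(0, 1, 1)    # indeterminate
#' @export
edge_consistency <- function(label_u, sign, label_v) {
  if (!all(label_u %in% c(-1, 0, 1)) || !all(label_v %in% c(-1, 0, 1))) {
    stop("labels must be -1, 0 or +1")
  }
  if (!all(sign %in% c(-1, 1))) stop("edge sign must be +1 or -1")
  n <- max(length(label_u), length(sign), length(label_v))
  label_u <- rep_len(label_u, n)
  sign <- rep_len(sign, n)
  label_v <- rep_len(label_v, n)
  out <- rep("indeterminate", n)
  both <- label_u != 0 & label_v != 0
  out[both & label_v == sign * label_u] <- "consistent"
  out[both & label_v != sign * label_u] <- "inconsistent"
  out
}

#' Assess the sign consistency of a network against a label matrix
#'
#' Applies the conservative sign-consistency rule to every (edge, contrast)
#' pair and aggregates: the global inconsistency load (total count of
#' inconsistent cases), per-edge counts (`nIncons`) and their mean `mEdge`
#' (global / number of assessed edges, `nPairs`), per-contrast counts, and
#' the counts split by interaction role and by single-regulator targets.
#' Each edge is assessed independently; no AND/OR combination across multiple
#' regulators of the same target is attempted. Edges whose regulator or
#' target has no row in the label matrix are excluded from `nPairs` and
#' reported in `dropped`.
#'
#' @param net a [regulatory_network()].
#' @param labels integer gene x contrast matrix in \{-1, 0, +1\} with gene
#'   rownames and contrast colnames, from [label_genes()].
#' @param single_only restrict assessment to edges whose target has a single
#'   regulator (in-degree 1 in `net`).
#' @param role_filter optional `"activation"` or `"repression"`: restrict
#'   assessment to edges of that role.
#' @return List of class `inconsistency_report` with fields `global`,
#'   `nPairs`, `mEdge`, `per_edge` (data.frame: regulator, target, sign,
#'   single_regulator, nIncons), `per_contrast` (data.frame: contrast,
#'   inconsistencies), `splits` (named counts: activation, repression,
#'   activation_single, repression_single), `deregulated_per_contrast`
#'   (data.frame: contrast, deregulated), `dropped` (list: `genes` in the
#'   network but absent from the labels, `edges` excluded for that reason,
#'   plus quarantined dual-role rows).
#' @export
assess <- function(net, labels, single_only = FALSE, role_filter = NULL) {
  stopifnot(inherits(net, "regulatory_network"))
  if (!is.matrix(labels) || nrow(labels) == 0L || ncol(labels) == 0L) {
    stop("label matrix is empty")
  }
  if (!all(labels %in% c(-1L, 0L, 1L))) stop("labels must be -1, 0 or +1")
  if (is.null(rownames(labels)) || is.null(colnames(labels))) {
    stop("label matrix needs gene rownames and contrast colnames")
  }

  edges <- net$edges
  single_set <- single_regulator_targets(net)
  if (nrow(edges) > 0L) {
    edges$single_regulator <- edges$target %in% single_set
  } else {
    edges$single_regulator <- logical(0)
  }
  if (!is.null(role_filter)) {
    role_filter <- match.arg(role_filter, c("activation", "repression"))
    keep_sign <- if (role_filter == "activation") 1L else -1L
    edges <- edges[edges$sign == keep_sign, , drop = FALSE]
  }
  if (single_only) {
    edges <- edges[edges$single_regulator, , drop = FALSE]
  }

  have <- rownames(labels)
  resolvable <- edges$regulator %in% have & edges$target %in% have
  dropped_edges <- edges[!resolvable, c("regulator", "target", "sign")]
  dropped_genes <- sort(setdiff(net$nodes, have))
  edges <- edges[resolvable, , drop = FALSE]

  contrasts <- colnames(labels)
  n_edge <- nrow(edges)
  if (n_edge > 0L) {
    lab_u <- labels[edges$regulator, , drop = FALSE]
    lab_v <- labels[edges$target, , drop = FALSE]
    incons <- (lab_u != 0L) & (lab_v != 0L) & (lab_v != edges$sign * lab_u)
    per_edge_count <- as.integer(rowSums(incons))
    per_contrast_count <- as.integer(colSums(incons))
  } else {
    incons <- matrix(FALSE, 0L, length(contrasts))
    per_edge_count <- integer(0)
    per_contrast_count <- rep(0L, length(contrasts))
  }
  global <- sum(per_edge_count)

  split_count <- function(mask) {
    if (n_edge == 0L || !any(mask)) 0L else sum(incons[mask, , drop = FALSE])
  }
  splits <- c(
    activation = split_count(edges$sign == 1L),
    repression = split_count(edges$sign == -1L),
    activation_single = split_count(edges$sign == 1L &
                                      edges$single_regulator),
    repression_single = split_count(edges$sign == -1L &
                                      edges$single_regulator)
  )

  per_edge <- data.frame(
    regulator = edges$regulator, target = edges$target, sign = edges$sign,
    single_regulator = edges$single_regulator, nIncons = per_edge_count,
    stringsAsFactors = FALSE)
  rownames(per_edge) <- NULL
  structure(list(
    global = global,
    nPairs = n_edge,
    mEdge = if (n_edge > 0L) global / n_edge else NA_real_,
    per_edge = per_edge,
    per_contrast = data.frame(contrast = contrasts,
                              inconsistencies = per_contrast_count,
                              stringsAsFactors = FALSE),
    splits = splits,
    deregulated_per_contrast = data.frame(
      contrast = contrasts,
      deregulated = as.integer(colSums(labels != 0L)),
      stringsAsFactors = FALSE),
    dropped = list(genes = dropped_genes, edges = dropped_edges,
                   quarantined = net$quarantined)
  ), class = "inconsistency_report")
}

#' @export
print.inconsistency_report <- function(x, ...) {
  cat(sprintf(
    "inconsistency_report: global = %d over %d edges x %d contrasts\n",
    x$global, x$nPairs, nrow(x$per_contrast)))
  cat(sprintf("  mEdge = %.4g; splits: activation %d, repression %d\n",
              x$mEdge, x$splits[["activation"]], x$splits[["repression"]]))
  if (length(x$dropped$genes) > 0L || nrow(x$dropped$edges) > 0L) {
    cat(sprintf("  dropped: %d genes without expression, %d edges\n",
                length(x$dropped$genes), nrow(x$dropped$edges)))
  }
  invisible(x)
}

#' Write the per-edge and per-contrast tables of a report to TSV
#'
#' @param report an [assess()] report.
#' @param edge_path,contrast_path output paths (either may be NULL to skip).
#' @return `report`, invisibly.
#' @export
write_report_tables <- function(report, edge_path = NULL,
                                contrast_path = NULL) {
  stopifnot(inherits(report, "inconsistency_report"))
  if (!is.null(edge_path)) {
    utils::write.table(report$per_edge, edge_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(contrast_path)) {
    tab <- merge(report$per_contrast, report$deregulated_per_contrast,
                 by = "contrast", sort = FALSE)
    utils::write.table(tab, contrast_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(report)
}
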