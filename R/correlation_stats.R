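# Regulator-target expression correlations summarized by interaction role,
# and the Mann-Whitney U comparison of contrast groups.

#' All possible regulator-target pairs
#'
#' The Cartesian product of the network's transcription factors (nodes with
#' out-degree >= 1) with every gene of the compendium, excluding self-pairs.
#' Pairs that are actual edges of the network are flagged `known`.
#'
#' @param net a [regulatory_network()].
#' @param comp an [expression_compendium()] (defines the gene universe).
#' @return data.frame with columns `regulator`, `target`, `known`.
#' @export
all_possible_pairs <- function(net, comp) {
  stopifnot(inherits(net, "regulatory_network"),
            inherits(comp, "expression_compendium"))
  tfs <- transcription_factors(net)
  genes <- rownames(comp$values)
  if (length(tfs) == 0L) {
    return(data.frame(regulator = character(), target = character(),
                      known = logical(), stringsAsFactors = FALSE))
  }
  pairs <- expand.grid(regulator = tfs, target = genes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, , drop = FALSE]
  known_key <- paste(net$edges$regulator, net$edges$target, sep = "\r")
  pairs$known <- paste(pairs$regulator, pairs$target, sep = "\r") %in%
    known_key
  rownames(pairs) <- NULL
  pairs
}

#' Regulator-target expression correlations by category
#'
#' Computes the correlation (`cPairs`) of each known regulator-target pair
#' across all samples of the compendium, and the mean correlation `mc`
#' (sum of cPairs / nPairs) per category: all known pairs, activation edges,
#' repression edges, and the two single-regulator restrictions; optionally
#' also all possible TF-gene pairs. Pairs involving a gene absent from the
#' compendium, or a gene whose profile is constant, are skipped and counted.
#' A category with no valid pair reports `mc = NA` (undefined), never 0.
#'
#' @param net a [regulatory_network()].
#' @param comp a normalized [expression_compendium()]; correlations pool all
#'   samples, which is defensible after per-dataset z-scoring.
#' @param method `"pearson"` or `"spearman"`.
#' @param include_all_pairs also compute `mc` over all possible TF-gene
#'   pairs (quadratic in network size; default TRUE).
#' @return List of class `correlation_summary`: `method`, `pairs`
#'   (data.frame: regulator, target, role, single_regulator, cPairs for the
#'   known pairs), `mc` (named numeric: all_possible_pairs, known_pairs,
#'   activation, repression, activation_single, repression_single),
#'   `n_pairs` (named integer, valid pairs per category), `skipped`
#'   (data.frame of pairs without a defined correlation and the reason).
#' @export
pair_correlations <- function(net, comp,
                              method = c("pearson", "spearman"),
                              include_all_pairs = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(net, "regulatory_network"),
            inherits(comp, "expression_compendium"))
  v <- comp$values
  if (ncol(v) < 3L) stop("need >= 3 samples for a defined correlation")
  genes <- rownames(v)
  sds <- apply(v, 1L, stats::sd)
  usable <- stats::setNames(sds > 0, genes)

  edges <- net$edges
  single_set <- single_regulator_targets(net)
  pair_ok <- edges$regulator %in% genes & edges$target %in% genes
  defined <- pair_ok
  defined[pair_ok] <- usable[edges$regulator[pair_ok]] &
    usable[edges$target[pair_ok]]
  skipped <- data.frame(
    regulator = edges$regulator[!defined], target = edges$target[!defined],
    reason = ifelse(!pair_ok[!defined], "absent_from_compendium",
                    "constant_profile"),
    stringsAsFactors = FALSE)

  keep <- edges[defined, , drop = FALSE]
  r <- numeric(nrow(keep))
  if (nrow(keep) > 0L) {
    for (i in seq_len(nrow(keep))) {
      r[i] <- stats::cor(v[keep$regulator[i], ], v[keep$target[i], ],
                         method = method)
    }
  }
  pairs <- data.frame(
    regulator = keep$regulator, target = keep$target,
    role = ifelse(keep$sign == 1L, "activation", "repression"),
    single_regulator = keep$target %in% single_set,
    cPairs = r, stringsAsFactors = FALSE)
  rownames(pairs) <- NULL

  cat_mask <- list(
    known_pairs = rep(TRUE, nrow(pairs)),
    activation = pairs$role == "activation",
    repression = pairs$role == "repression",
    activation_single = pairs$role == "activation" & pairs$single_regulator,
    repression_single = pairs$role == "repression" & pairs$single_regulator)
  mc <- vapply(cat_mask, function(m) {
    if (!any(m)) NA_real_ else mean(pairs$cPairs[m])
  }, 0)
  n_pairs <- vapply(cat_mask, sum, 0L)

  if (include_all_pairs) {
    ap <- all_possible_pairs(net, comp)
    ok <- usable[ap$regulator] & usable[ap$target]
    ap <- ap[ok, , drop = FALSE]
    if (nrow(ap) > 0L) {
      # correlate via the gene x gene correlation of the TF block,
      # restricted to non-constant genes
      tfs <- unique(ap$regulator)
      ug <- genes[usable[genes]]
      cmat <- stats::cor(t(v[tfs, , drop = FALSE]),
                         t(v[ug, , drop = FALSE]), method = method)
      r_all <- cmat[cbind(match(ap$regulator, tfs),
                          match(ap$target, ug))]
      mc <- c(all_possible_pairs = mean(r_all), mc)
      n_pairs <- c(all_possible_pairs = nrow(ap), n_pairs)
    } else {
      mc <- c(all_possible_pairs = NA_real_, mc)
      n_pairs <- c(all_possible_pairs = 0L, n_pairs)
    }
  }

  structure(list(method = method, pairs = pairs, mc = mc,
                 n_pairs = n_pairs, skipped = skipped),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf("correlation_summary (%s):\n", x$method))
  for (nm in names(x$mc)) {
    cat(sprintf("  mc[%s] = %s  (n = %d)\n", nm,
                ifelse(is.na(x$mc[[nm]]), "undefined",
                       sprintf("%.4f", x$mc[[nm]])), x$n_pairs[[nm]]))
  }
  invisible(x)
}

#' Mann-Whitney U test for two independent groups
#'
#' U is computed from rank sums with midranks for ties
#' (U = R1 - n1(n1+1)/2, the number of (x, y) pairs with x > y counting
#' ties one half). For combined n <= 16 the two-sided p-value is computed by
#' exact enumeration of all choose(n1+n2, n1) group assignments (counting
#' arrangements whose U is at least as far from n1*n2/2 as observed); above
#' that, by the normal approximation with tie-corrected variance and a 0.5
#' continuity correction.
#'
#' @param x,y numeric vectors (non-empty).
#' @param exact_max combined-size cutoff for exact enumeration (default 16).
#' @return List of class `group_comparison`: `U` (for the `x` side), `p`
#'   (two-sided), `n1`, `n2`, `method` ("exact" or "normal_approx").
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, exact_max = 16L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("missing values in groups")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  if (n <= exact_max) {
    method <- "exact"
    sets <- utils::combn(n, n1)
    u_all <- colSums(matrix(rk[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
  } else {
    method <- "normal_approx"
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * min(stats::pnorm(z),
                          stats::pnorm(z, lower.tail = FALSE)))
    }
  }
  structure(list(U = U, p = p, n1 = n1, n2 = n2, method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n1 = %d, n2 = %d), p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$p, x$method))
  invisible(x)
}
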