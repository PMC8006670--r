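# Randomized baselines: expression-profile shuffling (topology kept) and
# degree-preserving network rewiring (expression kept), plus the empirical
# null distribution of the global inconsistency load.

#' Shuffle the assignment of expression profiles to gene identities
#'
#' Permutes which gene id owns which row of values, uniformly at random. The
#' multiset of row vectors is untouched and the network is never modified:
#' this null keeps the marginal behaviour of the data while destroying gene
#' identity.
#'
#' @param x an [expression_compendium()], a `contrast_matrix`, or a plain
#'   matrix with gene rownames.
#' @param seed integer seed.
#' @return An object of the same class with rows reassigned to gene ids.
#' @export
shuffle_profiles <- function(x, seed) {
  permute_rows <- function(m) {
    if (nrow(m) < 2L) return(m)
    perm <- with_seed(seed, sample.int(nrow(m)))
    out <- m[perm, , drop = FALSE]
    rownames(out) <- rownames(m)
    out
  }
  if (inherits(x, "expression_compendium")) {
    x$values <- permute_rows(x$values)
    x
  } else if (inherits(x, "contrast_matrix")) {
    x$deltas <- permute_rows(x$deltas)
    x
  } else if (is.matrix(x)) {
    permute_rows(x)
  } else {
    stop("cannot shuffle profiles of a ", class(x)[1L])
  }
}

#' Degree-preserving rewiring by double edge swaps
#'
#' Randomizes the topology while keeping every node's in- and out-degree:
#' repeatedly picks two edges (a -> x) and (b -> y) and replaces them with
#' (a -> y) and (b -> x). Swaps that would create a duplicate
#' (regulator, target) pair — or a self-loop, unless `allow_self_loops` —
#' are rejected and do not count towards `n_swaps`. Edge signs (and any
#' extra edge columns such as weights) travel with the regulator's edge
#' slot, so each regulator's activation/repression out-profile is preserved.
#'
#' @param net a [regulatory_network()] with >= 2 edges.
#' @param seed integer seed.
#' @param n_swaps number of accepted swaps; default 10 x number of edges
#'   (standard burn-in for degree-preserving randomization).
#' @param allow_self_loops logical; permit swaps that create self-loops.
#' @param max_tries attempt budget before giving up (guards degenerate
#'   topologies, e.g. a single-regulator star where no swap changes
#'   anything); a warning is raised if the budget is exhausted early.
#' @return A rewired [regulatory_network()] with identical node set, degree
#'   profile and sign multiset.
#' @export
rewire_network <- function(net, seed, n_swaps = NULL,
                           allow_self_loops = FALSE,
                           max_tries = NULL) {
  stopifnot(inherits(net, "regulatory_network"))
  m <- nrow(net$edges)
  if (m < 2L) stop("rewiring needs at least 2 edges")
  if (is.null(n_swaps)) n_swaps <- 10L * m
  if (is.null(max_tries)) max_tries <- 100L * n_swaps
  edges <- net$edges
  with_seed(seed, {
    key <- paste(edges$regulator, edges$target, sep = "\r")
    accepted <- 0L
    tries <- 0L
    while (accepted < n_swaps && tries < max_tries) {
      tries <- tries + 1L
      ij <- sample.int(m, 2L)
      i <- ij[1L]; j <- ij[2L]
      a <- edges$regulator[i]; x <- edges$target[i]
      b <- edges$regulator[j]; y <- edges$target[j]
      if (!allow_self_loops && (a == y || b == x)) next
      new_i <- paste(a, y, sep = "\r")
      new_j <- paste(b, x, sep = "\r")
      # duplicate check against all other edges (and the partner slot)
      if (new_i == new_j) next
      other <- key[-c(i, j)]
      if (new_i %in% other || new_j %in% other) next
      edges$target[i] <- y
      edges$target[j] <- x
      key[i] <- new_i
      key[j] <- new_j
      accepted <- accepted + 1L
    }
    if (accepted < n_swaps) {
      warning(sprintf("rewiring stopped after %d/%d accepted swaps (%d tries)",
                      accepted, n_swaps, tries))
    }
  })
  edges$self_loop <- edges$regulator == edges$target
  out <- net
  out$edges <- edges
  out
}

#' Empirical null distribution of the global inconsistency load
#'
#' Repeats one of the two randomization schemes `n_iter` times, recomputes
#' the global inconsistency load each time, and summarizes the loads by
#' their mean (`mGlobal`). For `profile_shuffle`, the rows of the contrast
#' matrix are reassigned to gene ids and labels are recomputed with the
#' *original* threshold `t`; for `edge_shuffle`, the network is rewired and
#' the original labels are reused. Per-iteration seeds are derived from
#' `seed`, so results are bit-reproducible.
#'
#' @param net a [regulatory_network()].
#' @param cm a `contrast_matrix` from [compute_contrasts()].
#' @param t labelling threshold (or a `threshold_calibration`).
#' @param method `"profile_shuffle"` or `"edge_shuffle"`.
#' @param n_iter number of iterations (>= 1); default 200.
#' @param seed master integer seed.
#' @param n_swaps accepted swaps per rewiring iteration (default
#'   10 x edges).
#' @return List of class `null_distribution`: `method`, `n_iter`, `seed`,
#'   `loads` (integer vector of per-iteration global loads), `mGlobal`.
#' @export
null_distribution <- function(net, cm, t,
                              method = c("profile_shuffle", "edge_shuffle"),
                              n_iter = 200L, seed = 1L, n_swaps = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(net, "regulatory_network"),
            inherits(cm, "contrast_matrix"))
  if (inherits(t, "threshold_calibration")) t <- t$t
  if (n_iter < 1L) stop("n_iter must be >= 1")
  iter_seeds <- derive_seeds(seed, n_iter)
  base_labels <- label_genes(cm, t)
  loads <- integer(n_iter)
  for (i in seq_len(n_iter)) {
    if (method == "profile_shuffle") {
      labs <- shuffle_profiles(base_labels, iter_seeds[i])
      loads[i] <- assess(net, labs)$global
    } else {
      rnet <- rewire_network(net, iter_seeds[i], n_swaps = n_swaps)
      loads[i] <- assess(rnet, base_labels)$global
    }
  }
  structure(list(method = method, n_iter = as.integer(n_iter),
                 seed = as.integer(seed), loads = loads,
                 mGlobal = sum(loads) / n_iter),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution (%s): %d iterations, mGlobal = %.2f\n",
              x$method, x$n_iter, x$mGlobal))
  invisible(x)
}

#' Percentile of an observed load within a null distribution
#'
#' Midrank convention: ties between the observed value and null draws count
#' half.
#'
#' @param nd a [null_distribution()].
#' @param observed observed global inconsistency load.
#' @return Percentile in `[0, 100]`.
#' @export
null_percentile <- function(nd, observed) {
  stopifnot(inherits(nd, "null_distribution"))
  100 * (sum(nd$loads < observed) + 0.5 * sum(nd$loads == observed)) /
    length(nd$loads)
}
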