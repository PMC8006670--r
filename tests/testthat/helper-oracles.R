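# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, pair counting) so they share no code
# path with the package implementation they check.

# Exhaustive loop over every (edge, contrast) pair.
brute_force_counts <- function(edges, labels) {
  global <- 0L
  per_edge <- integer(nrow(edges))
  per_contrast <- integer(ncol(labels))
  for (i in seq_len(nrow(edges))) {
    for (j in seq_len(ncol(labels))) {
      lu <- labels[edges$regulator[i], j]
      lv <- labels[edges$target[i], j]
      if (lu != 0L && lv != 0L && lv != edges$sign[i] * lu) {
        global <- global + 1L
        per_edge[i] <- per_edge[i] + 1L
        per_contrast[j] <- per_contrast[j] + 1L
      }
    }
  }
  list(global = global, per_edge = per_edge, per_contrast = per_contrast)
}

# Random small network with distinct (regulator, target) pairs.
random_network <- function(n_nodes, n_edges) {
  nodes <- sprintf("g%02d", seq_len(n_nodes))
  pairs <- expand.grid(regulator = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pick <- pairs[sample.int(nrow(pairs), n_edges), ]
  pick$sign <- sample(c(-1L, 1L), n_edges, replace = TRUE)
  regulatory_network(pick, nodes = nodes)
}

random_labels <- function(nodes, n_contrasts) {
  m <- matrix(sample(c(-1L, 0L, 1L), length(nodes) * n_contrasts,
                     replace = TRUE),
              length(nodes), n_contrasts,
              dimnames = list(nodes, sprintf("c%d", seq_len(n_contrasts))))
  m
}

# Mann-Whitney by direct pair counting over all bitmask group assignments;
# no ranks involved.
brute_force_mw <- function(x, y) {
  u_pairs <- function(a, b) {
    u <- 0
    for (ai in a) for (bi in b) {
      u <- u + (ai > bi) + 0.5 * (ai == bi)
    }
    u
  }
  pooled <- c(x, y)
  n <- length(pooled)
  n1 <- length(x)
  mu <- n1 * (n - n1) / 2
  u_obs <- u_pairs(x, y)
  u_all <- numeric(0)
  for (mask in 0:(2^n - 1)) {
    sel <- as.logical(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L))
    if (sum(sel) != n1) next
    u_all <- c(u_all, u_pairs(pooled[sel], pooled[!sel]))
  }
  list(U = u_obs, p = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
}

# Small compendium built from an explicit matrix.
make_compendium <- function(values, datasets = NULL) {
  if (is.null(datasets)) datasets <- rep("d1", ncol(values))
  expression_compendium(values, data.frame(
    sample = colnames(values), dataset = datasets,
    platform = "microarray", stringsAsFactors = FALSE))
}

write_tmp_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
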