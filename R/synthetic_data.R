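# Synthetic worlds: signed DAG generation and a linear-Gaussian
# steady-state expression simulator with knockout / overexpression / stress
# conditions, multi-dataset structure, and exact noiseless ground truth.

#' Configuration for synthetic world generation
#'
#' Defaults describe a small bacterial-style regulatory module: 10
#' transcription factors over 20 target genes (~1.5 regulators per target),
#' a majority of activating edges, and a multi-dataset compendium mixing
#' wild-type references with single-gene perturbation conditions.
#'
#' @param n_tfs,n_targets node counts.
#' @param n_layers number of TF layers (layer-1 TFs are unregulated roots;
#'   deeper TFs get one upstream TF regulator each).
#' @param density mean number of regulators per target gene (in `[1, 4]`,
#'   realized as 1 + Binomial(3, (density-1)/3) per target, capped at
#'   `n_tfs`).
#' @param activation_fraction expected fraction of activating edges.
#' @param coherent_signs logical. If TRUE (default) every node receives a
#'   latent polarity in \{-1, +1\} and each edge's sign is the product of
#'   its endpoint polarities. All directed paths between two genes then
#'   carry the same sign, so single-gene clamp perturbations (knockout,
#'   overexpression) are exactly sign-consistent in the noiseless limit
#'   ("consistent world"). If FALSE,
#'   signs are i.i.d. Bernoulli(`activation_fraction`) and noiseless
#'   consistency is not guaranteed. Coherent mode requires
#'   `activation_fraction >= 0.5`.
#' @param weight_range range of (positive) regulatory weights, drawn
#'   uniformly per edge.
#' @param noise_sd standard deviation of the additive Gaussian noise on the
#'   z-like log-expression scale.
#' @param clamp magnitude of knockout/overexpression clamps: knockout fixes
#'   the gene at `-clamp`, overexpression at `+clamp` (z-units).
#' @param stress_magnitude,stress_fraction stress conditions shift the basal
#'   level of a random `stress_fraction` of genes by `stress_magnitude`,
#'   with an independent random sign per affected gene.
#' @param n_datasets number of datasets (independent per-gene basal offsets
#'   emulate platform/study effects; removed by per-dataset z-scoring).
#' @param n_knockout,n_overexpression,n_stress,n_wildtype_case per-dataset
#'   counts of case condition groups (wildtype_case groups give unperturbed
#'   wildtype-vs-wildtype contrasts).
#' @param ref_reps,case_reps replicate counts for the reference group and
#'   each case group.
#' @param perturbed_noise_mult noise multiplier applied to samples of
#'   perturbed conditions (1 = homoskedastic; >1 emulates noisier perturbed
#'   experiments).
#' @param schedule optional explicit condition schedule (data.frame with
#'   columns `dataset`, `condition`, `type`, `genes` (`;`-separated, may be
#'   empty for wildtype/stress), `n_reps`, `noise_mult`); overrides the
#'   per-dataset counts.
#' @param allow_cycles permit cyclic networks in [simulate_expression()] via
#'   damped fixed-point iteration.
#' @param seed master seed; all generation randomness derives from it.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_tfs = 10L, n_targets = 20L, n_layers = 2L,
                              density = 1.5, activation_fraction = 0.6,
                              coherent_signs = TRUE,
                              weight_range = c(0.5, 1.5), noise_sd = 0.3,
                              clamp = 2, stress_magnitude = 1.5,
                              stress_fraction = 0.2, n_datasets = 3L,
                              n_knockout = 2L, n_overexpression = 1L,
                              n_stress = 1L, n_wildtype_case = 2L,
                              ref_reps = 4L, case_reps = 3L,
                              perturbed_noise_mult = 1,
                              schedule = NULL, allow_cycles = FALSE,
                              seed = 1L) {
  stopifnot(n_tfs >= 1L, n_targets >= 1L, n_layers >= 1L,
            density >= 1, noise_sd >= 0, n_datasets >= 1L,
            ref_reps >= 1L, case_reps >= 1L,
            weight_range[1L] > 0, weight_range[2L] >= weight_range[1L],
            activation_fraction >= 0, activation_fraction <= 1)
  if (coherent_signs && activation_fraction < 0.5) {
    stop("coherent_signs requires activation_fraction >= 0.5")
  }
  if (density > min(4, n_tfs)) stop("density infeasible for n_tfs = ", n_tfs)
  structure(as.list(environment()), class = "simulation_config")
}

#' Generate a signed regulatory network
#'
#' Builds a directed acyclic signed network: TFs are assigned to layers
#' (deeper TFs regulated by one shallower TF), and each target gene is wired
#' to regulators drawn uniformly from the TF set until its drawn in-degree
#' is met. Each edge receives a positive weight drawn uniformly from
#' `config$weight_range` and a sign (see `coherent_signs` in
#' [simulation_config()]).
#'
#' If `degree_template` is given, its topology is copied verbatim (an
#' in-silico twin of the template network, the way an in-silico benchmark is
#' modelled on an experimental network) and only signs and weights are drawn
#' fresh, so the degree profile matches the template's exactly.
#'
#' @param config a [simulation_config()].
#' @param degree_template optional [regulatory_network()] whose topology is
#'   reused.
#' @return List of class `synthetic_network`: `network` (a
#'   [regulatory_network()] whose edge table carries a `weight` column),
#'   `polarity` (named vector, NULL unless coherent signs), `basal` (named
#'   numeric, all 0 by default), `tf_layers` (named integer).
#' @export
generate_network <- function(config, degree_template = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  seeds <- derive_seeds(config$seed, 4L)
  with_seed(seeds[1L], {
    if (is.null(degree_template)) {
      tfs <- sprintf("tf%02d", seq_len(config$n_tfs))
      tgs <- sprintf("tg%02d", seq_len(config$n_targets))
      layer <- rep(seq_len(config$n_layers), length.out = config$n_tfs)
      layer <- sort(layer)
      names(layer) <- tfs
      reg <- character(0); tgt <- character(0)
      for (i in seq_along(tfs)) {
        if (layer[i] > 1L) {
          upstream <- tfs[layer < layer[i]]
          reg <- c(reg, upstream[sample.int(length(upstream), 1L)])
          tgt <- c(tgt, tfs[i])
        }
      }
      p_extra <- (config$density - 1) / 3
      for (g in tgs) {
        k <- min(1L + stats::rbinom(1L, 3L, p_extra), config$n_tfs)
        reg <- c(reg, sample(tfs, k))
        tgt <- c(tgt, rep(g, k))
      }
      edges <- data.frame(regulator = reg, target = tgt,
                          stringsAsFactors = FALSE)
      nodes <- c(tfs, tgs)
    } else {
      stopifnot(inherits(degree_template, "regulatory_network"))
      edges <- degree_template$edges[c("regulator", "target")]
      nodes <- degree_template$nodes
      layer <- NULL
    }
    polarity <- NULL
    if (config$coherent_signs) {
      q <- 0.5 + sqrt(max(0, 2 * config$activation_fraction - 1)) / 2
      polarity <- stats::setNames(
        ifelse(stats::runif(length(nodes)) < q, 1L, -1L), nodes)
      edges$sign <- polarity[edges$regulator] * polarity[edges$target]
    } else {
      edges$sign <- ifelse(
        stats::runif(nrow(edges)) < config$activation_fraction, 1L, -1L)
    }
    edges$weight <- stats::runif(nrow(edges), config$weight_range[1L],
                                 config$weight_range[2L])
    net <- regulatory_network(edges, nodes = nodes)
    structure(list(network = net, polarity = polarity,
                   basal = stats::setNames(numeric(length(nodes)),
                                           sort(nodes)),
                   tf_layers = layer),
              class = "synthetic_network")
  })
}

# Topological order of the nodes; errors on cycles.
topological_order <- function(net) {
  nodes <- net$nodes
  edges <- net$edges[net$edges$regulator != net$edges$target, , drop = FALSE]
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(edges$target)
  indeg[names(tab)] <- as.integer(tab)
  out_adj <- split(edges$target, factor(edges$regulator, levels = nodes))
  order_ <- character(0)
  queue <- nodes[indeg == 0L]
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    order_ <- c(order_, v)
    for (w in out_adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order_) < length(nodes)) return(NULL)
  order_
}

# Deterministic + noise propagation for one condition group.
# clamp: named numeric of clamped values; shift: named basal shift;
# noise: genes x reps matrix (0 for the noiseless system).
propagate_expression <- function(gen, config, ds_offset, clamp, shift,
                                 noise) {
  net <- gen$network
  nodes <- net$nodes
  n_rep <- ncol(noise)
  X <- matrix(0, length(nodes), n_rep, dimnames = list(nodes, NULL))
  base <- gen$basal[nodes] + ds_offset[nodes]
  base[names(shift)] <- base[names(shift)] + shift
  e_by_target <- split(seq_len(nrow(net$edges)),
                       factor(net$edges$target, levels = nodes))
  topo <- topological_order(net)
  if (!is.null(topo)) {
    for (v in topo) {
      if (v %in% names(clamp)) {
        # the perturbation fixes the biological signal; measurement noise
        # still applies
        X[v, ] <- clamp[[v]] + noise[v, ]
        next
      }
      contrib <- 0
      for (e in e_by_target[[v]]) {
        contrib <- contrib + net$edges$sign[e] * net$edges$weight[e] *
          X[net$edges$regulator[e], ]
      }
      X[v, ] <- base[[v]] + contrib + noise[v, ]
    }
  } else {
    if (!config$allow_cycles) {
      stop("network is cyclic; set allow_cycles = TRUE for damped iteration")
    }
    # damped fixed-point iteration for cyclic networks
    damping <- 0.5
    free <- setdiff(nodes, names(clamp))
    X[names(clamp), ] <- matrix(rep(unlist(clamp), n_rep), ncol = n_rep) +
      noise[names(clamp), , drop = FALSE]
    for (it in seq_len(500L)) {
      X_new <- X
      for (v in free) {
        contrib <- 0
        for (e in e_by_target[[v]]) {
          contrib <- contrib + net$edges$sign[e] * net$edges$weight[e] *
            X[net$edges$regulator[e], ]
        }
        X_new[v, ] <- base[[v]] + contrib + noise[v, ]
      }
      X_new[free, ] <- damping * X_new[free, , drop = FALSE] +
        (1 - damping) * X[free, , drop = FALSE]
      delta <- max(abs(X_new - X))
      X <- X_new
      if (delta < 1e-8) break
    }
    if (delta >= 1e-8) stop("damped iteration did not converge")
  }
  X
}

# Build the default per-dataset condition schedule (RNG state: caller's).
build_schedule <- function(config, gen) {
  tfs <- transcription_factors(gen$network)
  rows <- list()
  add <- function(ds, cond, type, genes, n_reps, noise_mult) {
    rows[[length(rows) + 1L]] <<- data.frame(
      dataset = ds, condition = cond, type = type,
      genes = paste(genes, collapse = ";"), n_reps = n_reps,
      noise_mult = noise_mult, stringsAsFactors = FALSE)
  }
  pm <- config$perturbed_noise_mult
  for (ds in seq_len(config$n_datasets)) {
    add(ds, "wt_ref", "wildtype", character(0), config$ref_reps, 1)
    if (config$n_knockout > 0L) {
      ko_tfs <- sample(tfs, min(config$n_knockout, length(tfs)))
      for (i in seq_along(ko_tfs)) {
        add(ds, sprintf("ko%d", i), "knockout", ko_tfs[i],
            config$case_reps, pm)
      }
    }
    if (config$n_overexpression > 0L) {
      oe_tfs <- sample(tfs, min(config$n_overexpression, length(tfs)))
      for (i in seq_along(oe_tfs)) {
        add(ds, sprintf("oe%d", i), "overexpression", oe_tfs[i],
            config$case_reps, pm)
      }
    }
    for (i in seq_len(config$n_stress)) {
      add(ds, sprintf("st%d", i), "stress", character(0),
          config$case_reps, pm)
    }
    for (i in seq_len(config$n_wildtype_case)) {
      add(ds, sprintf("wt%d", i), "wildtype_case", character(0),
          config$case_reps, 1)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a GRN-driven expression compendium
#'
#' Steady-state log-scale expression is computed in topological order:
#' `x_v = basal_v + dataset_offset_v + sum over regulators u of
#' sign(u->v) * weight(u->v) * x_u + noise`. Condition semantics: knockout
#' clamps the affected gene(s)' biological signal at `-clamp` before
#' propagation, overexpression at `+clamp` (double knockouts clamp two
#' genes), in both cases keeping the additive measurement noise; stress
#' shifts the basal level of a random subset of genes; wildtype is
#' unclamped. One contrast is formed per non-reference condition group
#' against its dataset's wild-type reference, with the `perturbed` flag set
#' for every non-wildtype condition. The ground truth is the label sign of
#' the noiseless system.
#'
#' @param gen a `synthetic_network` from [generate_network()].
#' @param config the same [simulation_config()].
#' @param noise_seed optional override for the expression-noise substream
#'   (used by [decouple()]); condition parameters (stress targets,
#'   perturbation assignments) always derive from `config$seed` so the
#'   experimental design is unchanged.
#' @return List of class `synthetic_world`: `network`, `polarity`, `basal`,
#'   `compendium` (an [expression_compendium()]), `definitions`
#'   (a [contrast_definitions()] table), `ground_truth` (integer gene x
#'   contrast matrix of noiseless label signs), `delta0` (the noiseless
#'   contrast matrix), `min_delta0` (smallest nonzero |delta0|),
#'   `conditions` (realized schedule incl. stress targets), `config`.
#' @export
simulate_expression <- function(gen, config, noise_seed = NULL) {
  stopifnot(inherits(gen, "synthetic_network"),
            inherits(config, "simulation_config"))
  seeds <- derive_seeds(config$seed, 4L)
  if (is.null(noise_seed)) noise_seed <- seeds[3L]
  nodes <- gen$network$nodes
  n_gene <- length(nodes)

  # condition parameters (schedule, stress draws) — design substream
  design <- with_seed(seeds[2L], {
    sched <- config$schedule
    if (is.null(sched)) sched <- build_schedule(config, gen)
    sched$clamp <- vector("list", nrow(sched))
    sched$shift <- vector("list", nrow(sched))
    for (i in seq_len(nrow(sched))) {
      genes_i <- strsplit(sched$genes[i], ";", fixed = TRUE)[[1L]]
      genes_i <- genes_i[nzchar(genes_i)]
      type <- sched$type[i]
      if (type %in% c("knockout", "double_knockout")) {
        sched$clamp[[i]] <- stats::setNames(
          rep(-config$clamp, length(genes_i)), genes_i)
      } else if (type == "overexpression") {
        sched$clamp[[i]] <- stats::setNames(
          rep(config$clamp, length(genes_i)), genes_i)
      } else if (type == "stress") {
        n_aff <- max(1L, ceiling(config$stress_fraction * n_gene))
        aff <- sample(nodes, n_aff)
        mag <- sample(c(-1, 1), n_aff, replace = TRUE) *
          config$stress_magnitude
        sched$genes[i] <- paste(aff, collapse = ";")
        sched$shift[[i]] <- stats::setNames(as.numeric(mag), aff)
      }
    }
    sched
  })

  offsets <- with_seed(seeds[4L], {
    matrix(stats::rnorm(n_gene * config$n_datasets), n_gene,
           dimnames = list(nodes, NULL))
  })

  # per-sample noise, drawn once in schedule order — noise substream
  n_samples <- sum(design$n_reps)
  noise_all <- with_seed(noise_seed, {
    matrix(stats::rnorm(n_gene * n_samples, sd = max(config$noise_sd,
                                                     .Machine$double.xmin)),
           n_gene, n_samples, dimnames = list(nodes, NULL))
  })
  if (config$noise_sd == 0) noise_all[] <- 0

  values <- NULL
  meta <- NULL
  col_at <- 0L
  group_samples <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    ds <- design$dataset[i]
    n_rep <- design$n_reps[i]
    noise <- noise_all[, col_at + seq_len(n_rep), drop = FALSE] *
      design$noise_mult[i]
    col_at <- col_at + n_rep
    clamp <- design$clamp[[i]]
    shift <- design$shift[[i]]
    if (is.null(shift)) shift <- stats::setNames(numeric(0), character(0))
    if (is.null(clamp)) clamp <- stats::setNames(numeric(0), character(0))
    X <- propagate_expression(gen, config, offsets[, ds], clamp, shift,
                              noise)
    ids <- sprintf("d%d_%s_r%d", ds, design$condition[i], seq_len(n_rep))
    colnames(X) <- ids
    group_samples[[i]] <- ids
    values <- cbind(values, X)
    meta <- rbind(meta, data.frame(
      sample = ids, dataset = sprintf("d%d", ds),
      platform = if (ds %% 2L == 1L) "microarray" else "rnaseq",
      stringsAsFactors = FALSE))
  }
  comp <- expression_compendium(values, meta)

  # contrasts: each non-reference group vs its dataset's wildtype reference
  ref_idx <- which(design$condition == "wt_ref")
  names(ref_idx) <- design$dataset[ref_idx]
  case_idx <- which(design$condition != "wt_ref")
  defs <- contrast_definitions(
    contrast = sprintf("d%d_%s", design$dataset[case_idx],
                       design$condition[case_idx]),
    dataset = sprintf("d%d", design$dataset[case_idx]),
    reference = group_samples[ref_idx[as.character(design$dataset[case_idx])]],
    case = group_samples[case_idx],
    perturbed = !(design$type[case_idx] %in% c("wildtype", "wildtype_case")))

  # noiseless ground truth: propagate each group with zero noise
  zero_noise <- matrix(0, n_gene, 1L, dimnames = list(nodes, NULL))
  x0 <- matrix(0, n_gene, nrow(design), dimnames = list(nodes, NULL))
  for (i in seq_len(nrow(design))) {
    clamp <- design$clamp[[i]]
    shift <- design$shift[[i]]
    if (is.null(shift)) shift <- stats::setNames(numeric(0), character(0))
    if (is.null(clamp)) clamp <- stats::setNames(numeric(0), character(0))
    x0[, i] <- propagate_expression(gen, config, offsets[, design$dataset[i]],
                                    clamp, shift, zero_noise)[, 1L]
  }
  delta0 <- x0[, case_idx, drop = FALSE] -
    x0[, ref_idx[as.character(design$dataset[case_idx])], drop = FALSE]
  colnames(delta0) <- defs$contrast
  ground_truth <- sign(delta0)
  storage.mode(ground_truth) <- "integer"
  nz <- abs(delta0)[abs(delta0) > 0]

  structure(list(
    network = gen$network, polarity = gen$polarity, basal = gen$basal,
    compendium = comp, definitions = defs, ground_truth = ground_truth,
    delta0 = delta0, dataset_offsets = offsets,
    min_delta0 = if (length(nz) > 0L) min(nz) else NA_real_,
    conditions = design, config = config
  ), class = "synthetic_world")
}

#' Generate a complete synthetic world
#'
#' Convenience wrapper: [generate_network()] then [simulate_expression()].
#'
#' @param config a [simulation_config()].
#' @param degree_template passed to [generate_network()].
#' @return A `synthetic_world` (see [simulate_expression()]).
#' @export
synthetic_world <- function(config = simulation_config(),
                            degree_template = NULL) {
  gen <- generate_network(config, degree_template = degree_template)
  simulate_expression(gen, config)
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "synthetic_world: %d genes, %d edges, %d samples, %d contrasts (%d perturbed)\n",
    length(x$network$nodes), nrow(x$network$edges),
    ncol(x$compendium$values), nrow(x$definitions),
    sum(x$definitions$perturbed)))
  invisible(x)
}

#' Decouple a synthetic world's expression from its network
#'
#' Regenerates the expression compendium with every regulatory weight set to
#' 0, so expression is pure basal level (plus condition shifts/clamps and
#' noise) and the network has no influence on it. The negative control for
#' null-model calibration: the observed inconsistency load of a decoupled
#' world should be a typical draw from both null distributions.
#'
#' @param world a `synthetic_world`.
#' @param seed seed for the regenerated expression noise.
#' @return A `synthetic_world` with the same network topology/signs and the
#'   same experimental design, but network-independent expression.
#' @export
decouple <- function(world, seed) {
  stopifnot(inherits(world, "synthetic_world"))
  gen <- structure(list(network = world$network, polarity = world$polarity,
                        basal = world$basal, tf_layers = NULL),
                   class = "synthetic_network")
  gen$network$edges$weight <- 0
  simulate_expression(gen, world$config, noise_seed = seed)
}

#' Write a synthetic world's files to a directory
#'
#' Emits the exact formats the analysis consumes: `network.tsv` (edge list),
#' `expression.tsv`, `samples.tsv`, `contrasts.tsv`, plus
#' `ground_truth.tsv` (noiseless label signs) and `config.json`.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(world$network, file.path(dir, "network.tsv"))
  write_compendium(world$compendium, file.path(dir, "expression.tsv"),
                   file.path(dir, "samples.tsv"))
  write_contrasts(world$definitions, file.path(dir, "contrasts.tsv"))
  gt <- data.frame(gene = rownames(world$ground_truth), world$ground_truth,
                   check.names = FALSE)
  utils::write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- world$config
  cfg$schedule <- NULL
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
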