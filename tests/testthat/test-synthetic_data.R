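test_that("network generation honours forced topologies and sign settings", {
  # one TF, three targets, density 1: a star with all in-degrees 1
  cfg <- simulation_config(n_tfs = 1L, n_targets = 3L, n_layers = 1L,
                           density = 1, seed = 3)
  gen <- generate_network(cfg)
  expect_equal(nrow(gen$network$edges), 3L)
  expect_true(all(gen$network$edges$regulator == "tf01"))
  dp <- degree_profile(gen$network)
  expect_true(all(dp$in_degree[dp$node != "tf01"] == 1L))

  # activation fraction 1 forces all-positive signs in both modes
  for (coh in c(TRUE, FALSE)) {
    cfg1 <- simulation_config(activation_fraction = 1, coherent_signs = coh,
                              seed = 4)
    expect_true(all(generate_network(cfg1)$network$edges$sign == 1L))
  }

  # reproducibility by seed
  g1 <- generate_network(simulation_config(seed = 9))
  g2 <- generate_network(simulation_config(seed = 9))
  expect_identical(g1$network$edges, g2$network$edges)

  expect_error(simulation_config(n_tfs = 2L, density = 3.5), "infeasible")
})

test_that("a degree template is reproduced exactly", {
  withr::with_seed(61, {
    tmpl <- random_network(12, 30)
  })
  cfg <- simulation_config(seed = 5)
  gen <- generate_network(cfg, degree_template = tmpl)
  expect_equal(degree_profile(gen$network), degree_profile(tmpl))
  # signs and weights are freshly drawn, not copied
  expect_true(is.numeric(gen$network$edges$weight))
})

test_that("coherent signs make every path between two genes sign-unique", {
  cfg <- simulation_config(n_layers = 3L, density = 2.5, seed = 6)
  gen <- generate_network(cfg)
  p <- gen$polarity
  e <- gen$network$edges
  expect_equal(e$sign, unname(p[e$regulator] * p[e$target]))
})

test_that("noiseless propagation follows the linear chain rules", {
  # chain A -> B, activation, weight 1: knockout of A drops B by 2
  edges <- data.frame(regulator = "A", target = "B", sign = 1L, weight = 1)
  gen <- structure(list(network = regulatory_network(edges),
                        polarity = NULL,
                        basal = c(A = 0, B = 0), tf_layers = NULL),
                   class = "synthetic_network")
  cfg <- simulation_config(noise_sd = 0, n_datasets = 1L, n_knockout = 1L,
                           n_overexpression = 0L, n_stress = 0L,
                           n_wildtype_case = 0L, seed = 2)
  sched <- data.frame(dataset = 1L,
                      condition = c("wt_ref", "ko1"),
                      type = c("wildtype", "knockout"),
                      genes = c("", "A"), n_reps = c(2L, 2L),
                      noise_mult = 1)
  cfg$schedule <- sched
  w <- simulate_expression(gen, cfg)
  # offsets cancel in the contrast: delta_B = w * delta_A
  dA <- w$delta0["A", 1]
  expect_equal(unname(w$delta0["B", 1]), unname(dA))
  expect_equal(unname(w$ground_truth["B", 1]), unname(sign(dA)))

  # repression flips the sign under overexpression
  edges$sign <- -1L
  gen$network <- regulatory_network(edges)
  sched$type[2] <- "overexpression"
  sched$condition[2] <- "oe1"
  cfg$schedule <- sched
  w2 <- simulate_expression(gen, cfg)
  expect_equal(unname(w2$delta0["B", 1]), -unname(w2$delta0["A", 1]))
})

test_that("noiseless worlds reproduce their ground truth through the pipeline", {
  for (s in c(1, 23)) {
    # ground-truth recovery is exact for any schedule, stress included
    cfg <- simulation_config(noise_sd = 0, seed = s)
    w <- synthetic_world(cfg)
    cm <- compute_contrasts(w$compendium, w$definitions)
    expect_equal(cm$deltas, w$delta0, tolerance = 1e-12)
    lab <- label_genes(cm, w$min_delta0 / 2)
    expect_identical(lab, w$ground_truth)

    # under single-gene clamp perturbations a coherent-sign world is exactly
    # consistent in the noiseless limit (stress shifts genes independently,
    # so it carries no such guarantee)
    cfg2 <- simulation_config(noise_sd = 0, n_stress = 0L, seed = s)
    w2 <- synthetic_world(cfg2)
    cm2 <- compute_contrasts(w2$compendium, w2$definitions)
    lab2 <- label_genes(cm2, w2$min_delta0 / 2)
    expect_equal(assess(w2$network, lab2)$global, 0L)
  }
})

test_that("cyclic networks need the damped-iteration opt-in", {
  edges <- data.frame(regulator = c("A", "B"), target = c("B", "A"),
                      sign = c(1L, 1L), weight = c(0.4, 0.4))
  gen <- structure(list(network = regulatory_network(edges),
                        polarity = NULL, basal = c(A = 1, B = 0),
                        tf_layers = NULL),
                   class = "synthetic_network")
  sched <- data.frame(dataset = 1L, condition = c("wt_ref", "wt1"),
                      type = c("wildtype", "wildtype_case"),
                      genes = "", n_reps = 2L, noise_mult = 1)
  cfg <- simulation_config(noise_sd = 0, n_datasets = 1L, seed = 2)
  cfg$schedule <- sched
  expect_error(simulate_expression(gen, cfg), "cyclic")
  cfg$allow_cycles <- TRUE
  w <- simulate_expression(gen, cfg)
  # converged fixed point of x = b + offset + W x for the first sample
  x <- w$compendium$values[c("A", "B"), 1]
  off <- w$dataset_offsets[c("A", "B"), 1]
  expect_lt(abs(x[["A"]] - (1 + off[["A"]] + 0.4 * x[["B"]])), 1e-6)
  expect_lt(abs(x[["B"]] - (0 + off[["B"]] + 0.4 * x[["A"]])), 1e-6)
})

test_that("noise increases the inconsistency load at a fixed threshold", {
  # raw scale, fixed t: more noise can only add sign contradictions to a
  # coherent world (at sigma = 0 the load is exactly 0)
  loads <- vapply(c(0.05, 0.3, 0.8), function(sigma) {
    mean(vapply(1:8, function(s) {
      w <- synthetic_world(simulation_config(noise_sd = sigma, seed = s))
      cm <- compute_contrasts(w$compendium, w$definitions)
      as.numeric(assess(w$network, label_genes(cm, 0.3))$global)
    }, 0))
  }, 0)
  expect_true(all(diff(loads) > 0))
})

test_that("decoupled worlds sever the network-expression link", {
  cfg <- simulation_config(seed = 31)
  w <- synthetic_world(cfg)
  dw <- decouple(w, seed = 99)
  expect_true(all(dw$network$edges$weight == 0))
  expect_identical(dw$definitions$contrast, w$definitions$contrast)
  # sigma = 0 decoupled world: stress-free contrasts have delta exactly 0
  cfg0 <- simulation_config(seed = 31, noise_sd = 0, n_stress = 0L)
  dw0 <- decouple(synthetic_world(cfg0), seed = 99)
  expect_true(all(abs(dw0$delta0[, !grepl("ko|oe", colnames(dw0$delta0))])
                  == 0))
  # correlations collapse at >= 50 samples
  cs <- pair_correlations(dw$network, zscore_by_dataset(dw$compendium),
                          method = "pearson")
  expect_lt(abs(cs$mc[["activation"]]), 0.15)
  expect_lt(abs(cs$mc[["repression"]]), 0.15)
})

test_that("world files round-trip through the on-disk formats", {
  w <- synthetic_world(simulation_config(seed = 77))
  dir <- withr::local_tempdir()
  write_world(w, dir)
  net <- read_edge_list(file.path(dir, "network.tsv"))
  comp <- read_compendium(file.path(dir, "expression.tsv"),
                          file.path(dir, "samples.tsv"))
  defs <- read_contrasts(file.path(dir, "contrasts.tsv"))
  expect_equal(sort(net$nodes), sort(w$network$nodes))
  expect_equal(nrow(net$edges), nrow(w$network$edges))
  expect_equal(dim(comp$values), dim(w$compendium$values))
  expect_equal(comp$values, w$compendium$values, tolerance = 1e-6)
  expect_equal(defs$contrast, w$definitions$contrast)
  expect_equal(defs$perturbed, w$definitions$perturbed)
})
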