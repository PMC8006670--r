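test_that("profile shuffling permutes gene identity, nothing else", {
  v <- rbind(g1 = c(1, 2, 3), g2 = c(4, 5, 6))
  colnames(v) <- sprintf("s%d", 1:3)
  comp <- make_compendium(v)
  # with 2 genes, repeated draws must produce the swap; values stay intact
  swapped <- FALSE
  for (s in 1:20) {
    sh <- shuffle_profiles(comp, seed = s)
    expect_setequal(unname(apply(sh$values, 1, paste, collapse = ",")),
                    unname(apply(v, 1, paste, collapse = ",")))
    expect_equal(rownames(sh$values), rownames(v))
    if (all(sh$values["g1", ] == v["g2", ])) swapped <- TRUE
  }
  expect_true(swapped)

  withr::with_seed(41, {
    big <- matrix(rnorm(100 * 6), 100, 6,
                  dimnames = list(sprintf("g%03d", 1:100),
                                  sprintf("s%d", 1:6)))
  })
  sh <- shuffle_profiles(big, seed = 99)
  expect_equal(sort(unname(apply(sh, 1, paste, collapse = ","))),
               sort(unname(apply(big, 1, paste, collapse = ","))))
  expect_equal(rownames(sh), rownames(big))
})

test_that("a forced swap exchanges targets and carries signs along", {
  net <- regulatory_network(data.frame(
    regulator = c("A", "B"), target = c("X", "Y"), sign = c(1L, -1L)))
  # only one swap is possible; force it with n_swaps = 1
  rn <- rewire_network(net, seed = 5, n_swaps = 1)
  e <- rn$edges[order(rn$edges$regulator), ]
  expect_equal(e$target, c("Y", "X"))
  expect_equal(e$sign, c(1L, -1L))
  expect_equal(degree_profile(rn), degree_profile(net))

  expect_error(rewire_network(regulatory_network(data.frame(
    regulator = "A", target = "B", sign = 1L)), seed = 1), "at least 2")
})

test_that("a single-source star cannot change under rewiring", {
  net <- regulatory_network(data.frame(
    regulator = "A", target = c("X", "Y", "Z"), sign = c(1L, -1L, 1L)))
  # every swap exchanges two of A's own targets: a no-op on the edge set
  rn <- rewire_network(net, seed = 3, n_swaps = 5, max_tries = 200)
  expect_setequal(paste(rn$edges$regulator, rn$edges$target),
                  paste(net$edges$regulator, net$edges$target))
  expect_equal(degree_profile(rn), degree_profile(net))
})

test_that("rewiring preserves degrees, signs and nodes for every seed", {
  withr::with_seed(43, {
    net <- random_network(15, 50)
  })
  dp0 <- degree_profile(net)
  for (s in c(1, 17, 912)) {
    rn <- rewire_network(net, seed = s, n_swaps = 500)
    expect_equal(degree_profile(rn), dp0)
    expect_equal(sort(rn$edges$sign), sort(net$edges$sign))
    expect_equal(rn$nodes, net$nodes)
    expect_false(anyDuplicated(paste(rn$edges$regulator,
                                     rn$edges$target)) > 0)
    # rewiring with enough swaps actually moves edges around
    expect_true(any(paste(rn$edges$regulator, rn$edges$target) !=
                      paste(net$edges$regulator, net$edges$target)))
  }
})

test_that("null distributions are reproducible and average exactly", {
  withr::with_seed(44, {
    net <- random_network(10, 25)
    v <- matrix(rnorm(10 * 12), 10, 12,
                dimnames = list(net$nodes, sprintf("s%d", 1:12)))
  })
  comp <- make_compendium(v)
  defs <- contrast_definitions(
    sprintf("c%d", 1:3), "d1",
    list(c("s1", "s2"), c("s5", "s6"), c("s9", "s10")),
    list(c("s3", "s4"), c("s7", "s8"), c("s11", "s12")),
    c(TRUE, TRUE, FALSE))
  cm <- compute_contrasts(comp, defs)
  t <- calibrate_threshold(cm, 0.5)

  for (m in c("profile_shuffle", "edge_shuffle")) {
    nd1 <- null_distribution(net, cm, t, method = m, n_iter = 20, seed = 123)
    nd2 <- null_distribution(net, cm, t, method = m, n_iter = 20, seed = 123)
    expect_identical(nd1$loads, nd2$loads)
    expect_equal(nd1$mGlobal, sum(nd1$loads) / 20)
    expect_length(nd1$loads, 20)
    nd3 <- null_distribution(net, cm, t, method = m, n_iter = 20, seed = 124)
    expect_false(identical(nd1$loads, nd3$loads))
  }
  expect_error(null_distribution(net, cm, t, n_iter = 0, seed = 1), ">= 1")
})

test_that("an all-zero label matrix gives an all-zero null", {
  withr::with_seed(45, {
    net <- random_network(6, 10)
    v <- matrix(rnorm(6 * 4), 6, 4,
                dimnames = list(net$nodes, sprintf("s%d", 1:4)))
  })
  comp <- make_compendium(v)
  defs <- contrast_definitions("c1", "d1", list(c("s1", "s2")),
                               list(c("s3", "s4")), TRUE)
  cm <- compute_contrasts(comp, defs)
  # threshold above every |delta|: nothing is ever labelled
  nd <- null_distribution(net, cm, t = max(abs(cm$deltas)) + 1,
                          method = "profile_shuffle", n_iter = 10, seed = 9)
  expect_true(all(nd$loads == 0L))
  expect_equal(nd$mGlobal, 0)
})

test_that("percentile uses the midrank convention", {
  nd <- structure(list(method = "profile_shuffle", n_iter = 4L, seed = 1L,
                       loads = c(10L, 20L, 20L, 30L), mGlobal = 20),
                  class = "null_distribution")
  expect_equal(null_percentile(nd, 5), 0)
  expect_equal(null_percentile(nd, 20), 100 * (1 + 1) / 4)
  expect_equal(null_percentile(nd, 40), 100)
})
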