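test_that("pair correlations recover identity and antisymmetry", {
  v <- rbind(tf1 = c(1, 2, 3, 5),
             tgA = c(1, 2, 3, 5),
             tgB = -c(1, 2, 3, 5),
             tgC = c(0, 0, 0, 0))
  colnames(v) <- sprintf("s%d", 1:4)
  net <- regulatory_network(data.frame(
    regulator = "tf1", target = c("tgA", "tgB", "tgC", "tgZ"),
    sign = c(1L, -1L, 1L, 1L)))
  cs <- pair_correlations(net, make_compendium(v), method = "pearson")
  got <- setNames(cs$pairs$cPairs, cs$pairs$target)
  expect_equal(got[["tgA"]], 1.0)
  expect_equal(got[["tgB"]], -1.0)
  # constant and absent genes are skipped, not zeroed
  expect_setequal(cs$skipped$target, c("tgC", "tgZ"))
  expect_setequal(cs$skipped$reason,
                  c("constant_profile", "absent_from_compendium"))
  expect_equal(unname(cs$mc["known_pairs"]), 0)
  expect_equal(unname(cs$n_pairs["known_pairs"]), 2L)
})

test_that("mc is the plain mean per category, NA when empty", {
  v <- rbind(tf1 = c(1, 2, 4, 3),
             tgA = c(1, 2, 4, 3),
             tgB = c(2, 1, 4, 3))
  colnames(v) <- sprintf("s%d", 1:4)
  net <- regulatory_network(data.frame(
    regulator = "tf1", target = c("tgA", "tgB"), sign = c(1L, 1L)))
  cs <- pair_correlations(net, make_compendium(v), method = "pearson")
  expect_equal(unname(cs$mc["activation"]), mean(cs$pairs$cPairs))
  expect_true(is.na(cs$mc["repression"]))
  expect_equal(unname(cs$n_pairs["repression"]), 0L)
})

test_that("spearman equals pearson on rank-transformed data", {
  withr::with_seed(51, {
    net <- random_network(8, 20)
    v <- matrix(rnorm(8 * 15), 8, 15,
                dimnames = list(net$nodes, sprintf("s%d", 1:15)))
  })
  comp <- make_compendium(v)
  sp <- pair_correlations(net, comp, method = "spearman")
  ranked <- make_compendium(t(apply(v, 1, rank)))
  pe <- pair_correlations(net, ranked, method = "pearson")
  ord <- function(p) p[order(p$regulator, p$target), ]
  expect_equal(ord(sp$pairs)$cPairs, ord(pe$pairs)$cPairs,
               tolerance = 1e-12)
  # and both agree exactly on strictly monotone linear data
  lin <- rbind(a = 1:10, b = 2 * (1:10) + 3)
  colnames(lin) <- sprintf("s%d", 1:10)
  net2 <- regulatory_network(data.frame(regulator = "a", target = "b",
                                        sign = 1L))
  for (m in c("pearson", "spearman")) {
    expect_equal(pair_correlations(net2, make_compendium(lin),
                                   method = m)$pairs$cPairs, 1.0)
  }
})

test_that("all possible pairs are TFs x genes minus self-pairs", {
  v <- matrix(rnorm(16), 4, 4,
              dimnames = list(c("tf1", "tf2", "g3", "g4"),
                              sprintf("s%d", 1:4)))
  net <- regulatory_network(data.frame(
    regulator = c("tf1", "tf2"), target = c("g3", "g4"), sign = c(1L, 1L)))
  ap <- all_possible_pairs(net, make_compendium(v))
  expect_equal(nrow(ap), 2 * 4 - 2)
  expect_equal(sum(ap$known), 2L)

  empty_net <- regulatory_network(data.frame(
    regulator = character(), target = character(), sign = integer()))
  expect_equal(nrow(all_possible_pairs(empty_net, make_compendium(v))), 0L)

  withr::with_seed(52, {
    net3 <- random_network(9, 20)
    v3 <- matrix(rnorm(9 * 5), 9, 5,
                 dimnames = list(net3$nodes, sprintf("s%d", 1:5)))
  })
  ap3 <- all_possible_pairs(net3, make_compendium(v3))
  tfs <- unique(net3$edges$regulator)
  brute <- 0L
  for (tf in tfs) for (g in rownames(v3)) if (tf != g) brute <- brute + 1L
  expect_equal(nrow(ap3), brute)
})

test_that("mann-whitney matches the spec examples and symmetry", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)
  expect_equal(mw$method, "exact")

  same <- mann_whitney_u(c(2, 7, 7, 9), c(2, 7, 7, 9))
  expect_equal(same$U, 16 / 2)
  expect_equal(same$p, 1.0)

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")

  withr::with_seed(53, {
    for (trial in 1:20) {
      x <- sample(1:10, sample(2:5, 1), replace = TRUE)
      y <- sample(1:10, sample(2:5, 1), replace = TRUE)
      a <- mann_whitney_u(x, y)
      b <- mann_whitney_u(y, x)
      expect_equal(a$p, b$p)
      expect_equal(a$U + b$U, length(x) * length(y))
    }
  })
})

test_that("mann-whitney agrees with wilcox.test", {
  withr::with_seed(54, {
    # exact branch, tie-free: p must match wilcox.test exactly
    for (trial in 1:20) {
      x <- rnorm(sample(3:7, 1))
      y <- rnorm(sample(3:7, 1))
      got <- mann_whitney_u(x, y)
      ref <- wilcox.test(x, y, exact = TRUE)
      expect_equal(got$U, unname(ref$statistic))
      expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    }
    # large-sample branch with ties: same tie-corrected normal approximation
    for (trial in 1:10) {
      x <- sample(1:6, 15, replace = TRUE)
      y <- sample(1:6, 18, replace = TRUE)
      got <- mann_whitney_u(x, y)
      ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
      expect_equal(got$method, "normal_approx")
      expect_equal(got$p, ref$p.value, tolerance = 1e-9)
    }
  })
})

test_that("normal approximation is close to exact p for small samples", {
  withr::with_seed(55, {
    for (trial in 1:30) {
      x <- rnorm(sample(3:8, 1))
      y <- rnorm(sample(3:8, 1))
      exact <- mann_whitney_u(x, y)$p
      approx <- mann_whitney_u(x, y, exact_max = 0L)$p
      expect_lt(abs(exact - approx), 0.05)
    }
  })
})
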