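test_that("distance correlation matches the brute-force double loop", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.3 * x^2
    expect_equal(distance_correlation(x, y), bf_dcor(x, y), tolerance = 1e-12)
  }
})

test_that("distance correlation is symmetric, bounded and affine-saturating", {
  set.seed(5)
  x <- rnorm(20); y <- rexp(20)
  expect_equal(distance_correlation(x, y), distance_correlation(y, x),
               tolerance = 1e-12)
  expect_equal(distance_correlation(x, x), 1, tolerance = 1e-12)
  expect_equal(distance_correlation(x, 3 * x + 2), 1, tolerance = 1e-12)
  expect_equal(distance_correlation(x, rep(2, 20)), 0)
  expect_error(distance_correlation(x, y[1:10]), "equal length")
  expect_error(distance_correlation(c(1, NA, 2, 3), c(1, 2, 3, 4)), "missing")
})

test_that("independent samples give small distance correlation at n = 1000", {
  for (s in 1:20) {
    set.seed(500 + s)
    expect_lt(distance_correlation(rnorm(1000), rnorm(1000)), 0.15)
  }
})

test_that("signs come from Pearson and symmetric quadratics are ambiguous", {
  x <- c(-2, -1, -0.5, 0.5, 1, 2)
  set.seed(1)
  neg <- signed_association(x, -2 * x, B = 99)
  expect_equal(neg$d, 1, tolerance = 1e-12)
  expect_identical(neg$sign, "-")
  expect_equal(neg$p, 1 / 100)   # maximal statistic beats every permutation
  sq <- signed_association(c(-2, -1, 0, 1, 2), c(-2, -1, 0, 1, 2)^2, B = 99)
  expect_true(sq$ambiguous)
  expect_gt(sq$d, 0)
  const <- signed_association(x, rep(1, 6), B = 19)
  expect_equal(const$d, 0)
  expect_equal(const$p, 1)
  expect_true(const$ambiguous)
})

test_that("permutation p-values are super-uniform under the null", {
  set.seed(77)
  p <- replicate(200, signed_association(rnorm(20), rnorm(20), B = 199)$p)
  for (a in c(0.05, 0.1, 0.25)) {
    expect_lt(mean(p <= a), a + 3 * sqrt(a * (1 - a) / 200))
  }
})

test_that("edge retention follows the d and q thresholds", {
  set.seed(12)
  n <- 37
  z <- rnorm(n)
  metab <- cbind(perfect = 2 * z + 1,
                 noisy = z + rnorm(n, 0, 0.2),
                 null1 = rnorm(n), null2 = rnorm(n))
  params <- data.frame(par = z, other = rnorm(n))
  cls <- c(par = "PK", other = "trait")
  ed <- build_edges(metab, params, cls, B = 999, seed = 3)
  expect_equal(nrow(ed), 8)
  pp <- ed[ed$metabolite_id == "perfect" & ed$parameter == "par", ]
  expect_equal(pp$d, 1, tolerance = 1e-12)
  expect_true(pp$retained)
  expect_identical(pp$sign, "+")
  # strict d threshold: nothing survives d_min = 0.999 except exact dependence
  ed99 <- build_edges(metab, params, cls, d_min = 0.999, B = 199, seed = 3)
  expect_true(all(ed99$metabolite_id[ed99$retained] == "perfect"))
  # mismatched subjects
  expect_error(build_edges(metab[1:10, ], params, cls), "same subjects")
})

test_that("planted edges and only planted edges survive in a clean design", {
  set.seed(9)
  n <- 37
  z1 <- rnorm(n); z2 <- rexp(n)
  metab <- sapply(1:10, function(i) rnorm(n))
  colnames(metab) <- sprintf("M%02d", 1:10)
  metab[, 1] <- z1 + rnorm(n, 0, 0.1)      # planted +
  metab[, 2] <- -3 * z2 + rnorm(n, 0, 0.1) # planted -
  params <- data.frame(p1 = z1, p2 = z2, t1 = rnorm(n))
  cls <- c(p1 = "PK", p2 = "PK", t1 = "trait")
  ed <- build_edges(metab, params, cls, B = 999, seed = 21)
  got <- ed[ed$retained, c("metabolite_id", "parameter", "sign")]
  expect_equal(nrow(got), 2)
  expect_setequal(paste(got$metabolite_id, got$parameter, got$sign),
                  c("M01 p1 +", "M02 p2 -"))
})

test_that("the emitted graph is tripartite and violations are caught", {
  ed <- data.frame(metabolite_id = c("M1", "M2"), parameter = c("cmax", "ast"),
                   parameter_class = c("PK", "trait"), d = c(0.8, 0.7),
                   sign = c("+", "-"), ambiguous = FALSE,
                   p = c(0.001, 0.002), q = c(0.01, 0.01), retained = TRUE)
  g <- build_network(ed)
  expect_true(assert_tripartite(g))
  expect_equal(igraph::ecount(g), 2)
  bad <- igraph::make_graph(c("a", "b"), directed = FALSE)
  igraph::V(bad)$class <- c("PK", "trait")
  expect_error(assert_tripartite(bad), "tripartite")
})

test_that("Leiden attains the exhaustive modularity optimum on the two-clique graph", {
  g <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
  g <- igraph::add_edges(g, c(1, 5))
  igraph::E(g)$weight <- 1
  igraph::V(g)$name <- as.character(1:8)
  part <- leiden_partition(g, seed = 4)
  best_q <- max(vapply(all_partitions(8),
                       function(m) igraph::modularity(g, m), numeric(1)))
  expect_equal(part$modularity, best_q, tolerance = 1e-12)
  expect_equal(part$n_modules, 2)
  expect_equal(unname(part$membership[1:4]), rep(part$membership[["1"]], 4))
  expect_equal(unname(part$membership[5:8]), rep(part$membership[["5"]], 4))
})

test_that("a single-edge graph forms one module (the exhaustive optimum)", {
  g <- igraph::make_graph(c("a", "b"), directed = FALSE)
  igraph::E(g)$weight <- 1
  part <- leiden_partition(g, seed = 1)
  best_q <- max(vapply(all_partitions(2),
                       function(m) igraph::modularity(g, m), numeric(1)))
  expect_equal(part$n_modules, 1)
  expect_equal(part$modularity, best_q, tolerance = 1e-12)  # Q = 0 beats -1/2
})

test_that("modules never span disconnected components and seeds fix the result", {
  g <- igraph::make_full_graph(3) + igraph::make_full_graph(3)
  igraph::E(g)$weight <- runif(6) + 0.5
  igraph::V(g)$name <- letters[1:6]
  p1 <- leiden_partition(g, seed = 10)
  p2 <- leiden_partition(g, seed = 10)
  expect_identical(p1$membership, p2$membership)
  comp <- igraph::components(g)$membership
  for (m in unique(p1$membership)) {
    expect_equal(length(unique(comp[p1$membership == m])), 1)
  }
})

test_that("Leiden modularity dominates a single-pass greedy baseline", {
  set.seed(33)
  for (i in 1:50) {
    g <- igraph::sample_gnp(12, 0.3)
    if (igraph::ecount(g) == 0) next
    igraph::E(g)$weight <- runif(igraph::ecount(g), 0.2, 1)
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    part <- leiden_partition(g, seed = i)
    expect_gte(part$modularity + 1e-12, greedy_modularity(g))
  }
})

test_that("community report counts reconcile with the graph", {
  set.seed(2)
  n <- 30
  z <- rnorm(n)
  metab <- cbind(M1 = z + rnorm(n, 0, 0.1), M2 = -z + rnorm(n, 0, 0.1),
                 M3 = rnorm(n))
  params <- data.frame(cmax = z, ast = -z + rnorm(n, 0, 0.1))
  ed <- build_edges(metab, params, c(cmax = "PK", ast = "trait"),
                    B = 999, seed = 5)
  g <- build_network(ed)
  part <- leiden_partition(g)
  rep_ <- community_report(g, part)
  expect_equal(rep_$summary$n_edges, igraph::ecount(g))
  expect_equal(sum(rep_$modules$n_within_edges) + rep_$summary$n_cross_edges,
               rep_$summary$n_edges)
  expect_equal(nrow(rep_$members), igraph::vcount(g))
  # empty graph
  empty <- community_report(igraph::make_empty_graph(0, directed = FALSE),
                            list(membership = integer(0), n_modules = 0L))
  expect_equal(empty$summary$n_edges, 0L)
  expect_equal(empty$summary$n_modules, 0L)
})
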