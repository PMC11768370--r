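test_that("intercept-only paired fit recovers the mean difference exactly", {
  D <- matrix(1, 3, 4, dimnames = list(sprintf("F%03d", 1:3), NULL))
  fm <- make_diff_fm(D)
  fit <- paired_design_fit(fm, basic_traits(4), covariates = character(0))
  expect_equal(fit$estimate, rep(1, 3))
  expect_equal(fit$s2, rep(0, 3))
  expect_equal(fit$stdev_unscaled, 1 / 2)   # sqrt(1/n), n = 4
})

test_that("centered covariates leave the adjusted estimate at the mean difference", {
  set.seed(14)
  n <- 12
  D <- matrix(rnorm(15 * n), 15, n)
  fm <- make_diff_fm(D)
  tr <- basic_traits(n, seed = 2)
  fit <- paired_design_fit(fm, tr)
  expect_equal(fit$estimate, unname(rowMeans(D)), tolerance = 1e-10)
})

test_that("collinear covariates are reported by name", {
  n <- 8
  fm <- make_diff_fm(matrix(rnorm(12 * n), 12, n))
  tr <- basic_traits(n)
  tr$bmi2 <- tr$bmi * 2
  expect_error(paired_design_fit(fm, tr, covariates = c("bmi", "bmi2")),
               "collinear.*bmi2")
})

test_that("subjects missing a timepoint are dropped with a warning", {
  mat <- matrix(rlnorm(12 * 7), 12, 7)
  fm <- make_fm(mat, c("pre", "post", "pre", "post", "pre", "post", "pre"),
                subjects = c("S01", "S01", "S02", "S02", "S03", "S03", "S04"))
  expect_warning(fit <- paired_design_fit(fm, basic_traits(4),
                                          covariates = character(0)),
                 "S04")
  expect_equal(fit$n_pairs, 3)
})

test_that("moderation limits behave: no shrinkage and full shrinkage", {
  set.seed(31)
  n <- 10
  D <- matrix(rnorm(25 * n, 0, rep(runif(25, 0.5, 2), each = n)), 25, n,
              byrow = TRUE)
  fm <- make_diff_fm(D)
  fit <- paired_design_fit(fm, basic_traits(n), covariates = character(0))
  ord <- eb_moderate(fit, prior_df = 0)
  t_ord <- fit$estimate / sqrt(fit$s2 / n)
  expect_equal(ord$t_mod, t_ord, tolerance = 1e-12)
  # identical sample variances: posterior variances collapse to one common
  # value close to the shared s2 (log-scale bias correction of order 1/df)
  D2 <- matrix(rnorm(2000 * n), 2000, n)
  D2 <- D2 / sqrt(rowSums((D2 - rowMeans(D2))^2) / (n - 1))  # force s2 = 1
  fit2 <- paired_design_fit(make_diff_fm(D2), basic_traits(n),
                            covariates = character(0))
  res2 <- eb_moderate(fit2)
  expect_lt(diff(range(res2$s2_post)), 1e-10)
  expect_equal(res2$s2_post[1], 1, tolerance = 0.15)
})

test_that("moderated statistics match independent implementations", {
  set.seed(8)
  n <- 6
  D <- matrix(rnorm(20 * n, 0, rep(runif(20, 0.3, 3), each = n)), 20, n,
              byrow = TRUE)
  fm <- make_diff_fm(D)
  fit <- paired_design_fit(fm, basic_traits(n), covariates = character(0))
  res <- eb_moderate(fit)
  # brute-force moment estimator, written out from first principles
  d <- n - 1
  e <- log(fit$s2) - digamma(d / 2) + log(d / 2)
  evar <- var(e) - trigamma(d / 2)
  stopifnot(evar > 0)
  inv_tri <- function(y) uniroot(function(x) trigamma(x) - y,
                                 c(1e-8, 1e8), tol = 1e-14)$root
  d0 <- 2 * inv_tri(evar)
  s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  s2p <- (d0 * s0 + d * fit$s2) / (d0 + d)
  t_bf <- fit$estimate / sqrt(s2p / n)
  p_bf <- 2 * pt(-abs(t_bf), d0 + d)
  expect_equal(res$t_mod, t_bf, tolerance = 1e-8)
  expect_equal(res$p, p_bf, tolerance = 1e-8)
  expect_equal(attr(res, "d0"), d0, tolerance = 1e-6)
  # cross-check against the reference empirical-Bayes implementation
  X <- matrix(1, n, 1)
  lf <- limma::lmFit(D, X)
  eb <- limma::eBayes(lf)
  expect_equal(unname(res$t_mod), unname(eb$t[, 1]), tolerance = 1e-6)
  expect_equal(unname(res$p), unname(eb$p.value[, 1]), tolerance = 1e-6)
  expect_equal(attr(res, "d0"), eb$df.prior, tolerance = 1e-4)
})

test_that("null p-values are uniform and robust to within-subject label flips", {
  set.seed(55)
  n <- 20
  D <- matrix(rnorm(2000 * n, 0, rep(runif(2000, 0.5, 2), each = n)),
              2000, n, byrow = TRUE)
  tr <- basic_traits(n, seed = 5)
  res <- diff_abundance(make_diff_fm(D), tr)
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
  frac <- mean(res$p <= 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  # permuting timepoint labels within subjects flips difference signs
  flip <- sample(c(-1, 1), n, replace = TRUE)
  res_f <- diff_abundance(make_diff_fm(sweep(D, 2, flip, "*")), tr)
  expect_gt(ks.test(res_f$p, "punif")$p.value, 0.01)
})

test_that("BH adjustment matches hand-computed step-up and handles NA", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  q <- bh_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], c(0.02, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone non-decreasing in p-rank
  set.seed(2)
  p <- runif(100)
  q2 <- bh_adjust(p)
  expect_true(all(diff(q2[order(p)]) >= -1e-15))
})

test_that("selection respects the threshold and degenerate inputs", {
  expect_identical(select_features(data.frame(feature_id = character(0),
                                              q = numeric(0))),
                   character(0))
  res <- data.frame(feature_id = c("a", "b", "c"), q = c(0.01, 0.2, 0.04))
  expect_identical(select_features(res, 0.05), c("a", "c"))
  expect_identical(select_features(res, 0), character(0))
})

test_that("planted effects are recovered with coherent signs", {
  cfg <- sim_config(n_subjects = 37, n_features = 400, n_differential = 40,
                    n_planted_edges = 0, n_planted_edges_pre = 0,
                    planted_pathway_hits = 10, seed = 23)
  study <- simulate_study(cfg)
  prep <- preprocess(study$features)
  da <- diff_abundance(prep$matrix, study$traits)
  sel <- select_features(da)
  truth <- study$truth$differential
  hit <- intersect(sel, truth$feature_id)
  expect_gte(length(hit) / nrow(truth), 0.9)
  est <- da$estimate[match(hit, da$feature_id)]
  lfc <- truth$lfc[match(hit, truth$feature_id)]
  expect_gte(mean(sign(est) == sign(lfc)), 0.95)
})
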