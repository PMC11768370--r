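small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 12, n_features = 120, n_differential = 15,
         n_planted_edges = 3, n_planted_edges_pre = 2,
         n_pathways = 8, planted_pathway_size = 10,
         planted_pathway_hits = 8, seed = 11),
    list(...))
  do.call(sim_config, args)
}

test_that("identical configuration reproduces the study byte for byte", {
  s1 <- simulate_study(small_cfg())
  s2 <- simulate_study(small_cfg())
  expect_identical(s1$features$intensities, s2$features$intensities)
  expect_identical(s1$profiles, s2$profiles)
  expect_identical(s1$truth, s2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(s1, d1); write_study(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("analytic half-life follows the elimination rate", {
  cfg <- small_cfg(pk_population = list(ka = 1.3, ke = 0.0693, V = 11.5, F = 1),
                   pk_cv = list(ka = 0, ke = 0, V = 0, F = 0), noise_cv = 0)
  sim <- simulate_pk_profiles(cfg)
  expect_equal(sim$true_pk$t_half, rep(log(2) / 0.0693, cfg$n_subjects))
  expect_equal(sim$true_pk$t_half[1], 10.0, tolerance = 1e-2)
})

test_that("cohort elimination rate centers on the population value", {
  sim <- simulate_pk_profiles(sim_config(seed = 4))
  # 3 standard errors of the cohort mean at CV 22%
  expect_lt(abs(mean(sim$true_pk$ke) - 0.09), 3 * 0.09 * 0.22 / sqrt(37))
})

test_that("noiseless observed Tmax is the sampling time nearest the analytic one", {
  cfg <- sim_config(n_subjects = 5, n_features = 10, n_differential = 0,
                    n_planted_edges = 0, n_planted_edges_pre = 0,
                    planted_pathway_hits = 0, noise_cv = 0,
                    pk_population = list(ka = 1.0, ke = 0.1, V = 11.5, F = 1),
                    pk_cv = list(ka = 0, ke = 0, V = 0, F = 0), seed = 2)
  tmax_true <- log(1.0 / 0.1) / (1.0 - 0.1)
  expect_equal(tmax_true, 2.558, tolerance = 1e-3)
  pk <- compute_pk_table(simulate_pk_profiles(cfg)$profiles)
  grid <- cfg$sampling_times
  expect_equal(pk$tmax, rep(grid[which.min(abs(grid - tmax_true))], 5))
})

test_that("without effects, drift or noise, pre and post samples coincide", {
  cfg <- small_cfg(n_differential = 0, n_planted_edges = 0,
                   n_planted_edges_pre = 0, planted_pathway_hits = 0,
                   drift_magnitude = 0, noise_cv = 0)
  study <- simulate_study(cfg)
  fm <- study$features
  for (s in unique(na.omit(fm$meta$subject_id))) {
    pre <- fm$intensities[, fm$meta$subject_id %in% s & fm$meta$timepoint == "pre"]
    post <- fm$intensities[, fm$meta$subject_id %in% s & fm$meta$timepoint == "post"]
    expect_equal(pre, post, ignore_attr = TRUE)
  }
})

test_that("planted linear edges are exact without noise and strong at 5% noise", {
  cfg0 <- small_cfg(noise_cv = 0, drift_magnitude = 0,
                    edge_forms = "linear", n_planted_edges_pre = 0)
  study <- simulate_study(cfg0)
  pairs <- merge(study$true_pk, study$traits, by = "subject_id")
  for (k in seq_len(nrow(study$truth$edges))) {
    ed <- study$truth$edges[k, ]
    post_cols <- study$features$meta$timepoint == "post"
    subj <- study$features$meta$subject_id[post_cols]
    x <- study$features$intensities[ed$metabolite_id, post_cols]
    z <- pairs[[ed$parameter]][match(subj, pairs$subject_id)]
    r <- cor(x, z)
    expect_equal(abs(r), 1, tolerance = 1e-10)
    expect_equal(if (r < 0) "-" else "+", ed$sign)
  }
  # recoverability invariant at realistic cohort size and 5% noise
  cfg5 <- sim_config(n_subjects = 37, n_features = 150, n_differential = 15,
                     n_planted_edges = 5, n_planted_edges_pre = 0,
                     planted_pathway_hits = 8, edge_forms = "linear",
                     noise_cv = 0.05, drift_magnitude = 0, seed = 9)
  study5 <- simulate_study(cfg5)
  pairs5 <- merge(study5$true_pk, study5$traits, by = "subject_id")
  post_cols <- study5$features$meta$timepoint == "post"
  subj <- study5$features$meta$subject_id[post_cols]
  for (k in seq_len(nrow(study5$truth$edges))) {
    ed <- study5$truth$edges[k, ]
    x <- study5$features$intensities[ed$metabolite_id, post_cols]
    z <- pairs5[[ed$parameter]][match(subj, pairs5$subject_id)]
    expect_gt(abs(cor(x, z)), 0.9)
  }
})

test_that("injection-order drift inflates QC variability", {
  cfg0 <- small_cfg(drift_magnitude = 0, noise_cv = 0.05)
  cfg1 <- small_cfg(drift_magnitude = 0.3, noise_cv = 0.05)
  rsd0 <- qc_rsd(simulate_study(cfg0)$features)
  rsd1 <- qc_rsd(simulate_study(cfg1)$features)
  expect_gt(median(rsd1), median(rsd0))
})

test_that("pathway database respects the size window and plants one enriched set", {
  study <- simulate_study(small_cfg())
  sizes <- vapply(study$pathways, function(p) length(p$members), integer(1))
  expect_true(all(sizes >= 5 & sizes <= 150))
  planted <- study$pathways[[study$truth$enriched_pathway]]
  hits <- length(intersect(planted$members, study$truth$differential$feature_id))
  expect_gte(hits, 8)
  # the worked overlap from the study design: 10 hits in a 12-member pathway,
  # 70 selected out of 2000, is overwhelmingly unlikely by chance
  p <- hypergeom_test(10, 12, 70, 2000)
  expect_equal(p, bf_hyper_tail(10, 12, 70, 2000), tolerance = 1e-12)
  expect_lt(p, 1e-10)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(qc_interval = 1), "qc_interval")
  expect_error(sim_config(n_features = 10, n_differential = 20), "n_differential")
  expect_error(sim_config(pk_population = list(ka = 1, ke = -0.1, V = 10, F = 1)),
               "positive")
  expect_error(sim_config(sampling_times = c(1, 2, 30)), "start at 0")
  expect_error(sim_config(n_differential = 4, n_planted_edges = 3,
                          n_planted_edges_pre = 2, planted_pathway_hits = 4),
               "planted")
})
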