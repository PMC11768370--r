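#' Configure a synthetic single-dose pharmacometabolomics study
#'
#' Builds the configuration object consumed by [simulate_study()] and the
#' stage-level generators. Defaults describe a bioequivalence-style cohort of
#' 37 healthy adults receiving a single 500 mg oral dose, profiled by LC-MS at
#' baseline (pre-dose) and at the time of maximum drug concentration
#' (post-dose), with pooled QC injections every 10 study samples.
#'
#' The pharmacokinetic population is a one-compartment oral absorption model.
#' Default means (`ka` 1.3 1/h, `ke` 0.09 1/h, `V` 11.5 L, `F` 1) place the
#' cohort in a Cmax of roughly 35 ug/mL, Tmax near 2.2 h and terminal
#' half-life near 8 h. Between-subject variability is lognormal with the
#' coefficients of variation in `pk_cv`.
#'
#' @param n_subjects Number of subjects.
#' @param dose_mg Oral dose in mg.
#' @param sampling_times Blood sampling times in hours; strictly increasing,
#'   starting at 0, and covering at least three population half-lives.
#' @param pk_population Named list of population means: `ka`, `ke` (1/h),
#'   `V` (L), `F` (fraction absorbed).
#' @param pk_cv Named list of lognormal between-subject CVs for the same four
#'   parameters (fractions, >= 0).
#' @param n_features Number of LC-MS features.
#' @param n_differential Number of features given a pre/post effect.
#' @param effect_sizes Pool of absolute natural-log fold changes for
#'   differential features; signs are drawn at random.
#' @param n_planted_edges Number of post-dose metabolite-parameter
#'   associations planted in the ground truth.
#' @param n_planted_edges_pre Number of baseline metabolite-trait associations
#'   (present at both timepoints).
#' @param edge_forms Functional forms sampled for planted edges: `"linear"`
#'   and/or `"monotone"` (exponential in the standardized parameter).
#' @param edge_strength Strength of planted associations: the fractional
#'   intensity swing across the observed parameter range. The default makes
#'   planted edges unambiguously strong (distance correlation well above the
#'   0.5 retention threshold at cohort size 37 and 10% noise), so recovery
#'   tests exercise the pipeline rather than threshold luck.
#' @param drift_magnitude Magnitude of the multiplicative injection-order
#'   drift (0 disables drift).
#' @param qc_interval Number of study injections between pooled QC injections
#'   (>= 2).
#' @param noise_cv Multiplicative measurement noise CV applied to
#'   concentrations and feature intensities.
#' @param biological_cv Median between-subject biological CV of feature
#'   intensities (per-feature values vary around it).
#' @param n_pathways Number of pathways in the emitted database.
#' @param pathway_size_range Inclusive size range for random pathways.
#' @param planted_pathway_size,planted_pathway_hits Size of the planted
#'   enriched pathway and how many of its members are differential features.
#' @param trait_centers Named list of `c(mean, sd)` pairs for the clinical and
#'   laboratory traits.
#' @param seed Integer seed; all generator stages derive sub-seeds from it.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_subjects = 37,
                       dose_mg = 500,
                       sampling_times = c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4,
                                          5, 6, 8, 12, 16, 24, 36, 48),
                       pk_population = list(ka = 1.3, ke = 0.09, V = 11.5, F = 1),
                       pk_cv = list(ka = 0.35, ke = 0.22, V = 0.20, F = 0.05),
                       n_features = 2000,
                       n_differential = 70,
                       effect_sizes = c(0.5, 0.8, 1.2),
                       n_planted_edges = 10,
                       n_planted_edges_pre = 5,
                       edge_forms = c("linear", "monotone"),
                       edge_strength = 1.5,
                       drift_magnitude = 0.15,
                       qc_interval = 10,
                       noise_cv = 0.10,
                       biological_cv = 0.30,
                       n_pathways = 20,
                       pathway_size_range = c(5, 150),
                       planted_pathway_size = 12,
                       planted_pathway_hits = 10,
                       trait_centers = list(
                         systolic_bp     = c(118, 10),
                         diastolic_bp    = c(75, 8),
                         cholesterol     = c(180, 25),
                         creatinine      = c(0.9, 0.15),
                         glucose         = c(88, 8),
                         ast             = c(24, 7),
                         alt             = c(22, 9),
                         bilirubin_total = c(0.7, 0.2),
                         hemoglobin      = c(14.5, 1.2),
                         hematocrit      = c(43, 3)),
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), dose_mg = dose_mg,
              sampling_times = sampling_times, pk_population = pk_population,
              pk_cv = pk_cv, n_features = as.integer(n_features),
              n_differential = as.integer(n_differential),
              effect_sizes = effect_sizes,
              n_planted_edges = as.integer(n_planted_edges),
              n_planted_edges_pre = as.integer(n_planted_edges_pre),
              edge_forms = edge_forms, edge_strength = edge_strength,
              drift_magnitude = drift_magnitude,
              qc_interval = as.integer(qc_interval),
              noise_cv = noise_cv, biological_cv = biological_cv,
              n_pathways = as.integer(n_pathways),
              pathway_size_range = pathway_size_range,
              planted_pathway_size = as.integer(planted_pathway_size),
              planted_pathway_hits = as.integer(planted_pathway_hits),
              trait_centers = trait_centers, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 3, cfg$dose_mg > 0, cfg$n_features >= 1)
  if (cfg$n_differential > cfg$n_features)
    stop("n_differential must not exceed n_features")
  if (cfg$qc_interval < 2)
    stop("qc_interval must be >= 2")
  t <- cfg$sampling_times
  if (t[1] != 0 || any(diff(t) <= 0))
    stop("sampling_times must be strictly increasing and start at 0")
  pk <- cfg$pk_population
  if (any(unlist(pk[c("ka", "ke", "V", "F")]) <= 0))
    stop("population PK parameters must be strictly positive")
  if (any(unlist(cfg$pk_cv) < 0) || cfg$noise_cv < 0 || cfg$biological_cv < 0)
    stop("coefficients of variation must be >= 0")
  if (max(t) < 3 * log(2) / pk$ke)
    stop("sampling_times must cover at least 3 population half-lives")
  if (cfg$n_planted_edges + cfg$n_planted_edges_pre > cfg$n_differential)
    stop("more planted edges than differential features")
  if (cfg$planted_pathway_hits > min(cfg$planted_pathway_size, cfg$n_differential))
    stop("planted_pathway_hits exceeds planted pathway size or differential count")
  invisible(cfg)
}

# Independent RNG sub-stream per generator stage so that re-running one stage
# with the same config reproduces it exactly.
stage_seed <- function(cfg, stage) {
  (abs(cfg$seed) %% 2000000000L) + stage
}

# Lognormal draws parameterized by arithmetic mean and CV (cv = 0 -> constant).
rlnorm_mcv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# One-compartment oral concentration curve, conc in ug/mL for dose in mg and
# V in L.
conc_1cpt <- function(t, dose, ka, ke, V, F) {
  F * dose * ka / (V * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
}

subject_ids <- function(n) sprintf("S%02d", seq_len(n))

#' Simulate concentration-time profiles under a one-compartment oral model
#'
#' Draws per-subject absorption/elimination parameters from the lognormal
#' population in `cfg`, evaluates the one-compartment oral curve
#' \eqn{C(t) = F D k_a / (V (k_a - k_e)) (e^{-k_e t} - e^{-k_a t})} at the
#' sampling times, and applies multiplicative lognormal measurement noise
#' (mean-one, CV `noise_cv`). Subjects whose absorption and elimination rates
#' collide (`ka == ke`, where the curve is singular) are resampled.
#'
#' @param cfg A [sim_config()] object.
#' @return A list with `profiles` (data.frame `subject_id`, `time_h`,
#'   `conc_ug_per_ml`) and `true_pk`: the noise-free parameters computed
#'   analytically per subject (`auc0t` over the observed time span, `cmax`,
#'   `tmax`, `kel = ke`, `t_half = ln 2 / ke`, plus the generating
#'   `ka`, `ke`, `V`, `F`).
#' @export
simulate_pk_profiles <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg, 1L))
  n <- cfg$n_subjects
  pop <- cfg$pk_population; cv <- cfg$pk_cv
  ka <- rlnorm_mcv(n, pop$ka, cv$ka)
  ke <- rlnorm_mcv(n, pop$ke, cv$ke)
  V  <- rlnorm_mcv(n, pop$V,  cv$V)
  F_ <- rlnorm_mcv(n, pop$F,  cv$F)
  # resample on ka/ke collision: the model is singular at ka == ke
  bad <- abs(ka - ke) < 1e-6
  while (any(bad)) {
    ka[bad] <- rlnorm_mcv(sum(bad), pop$ka, cv$ka)
    bad <- abs(ka - ke) < 1e-6
  }
  ids <- subject_ids(n)
  tt <- cfg$sampling_times
  T_last <- max(tt)
  tmax <- log(ka / ke) / (ka - ke)
  cmax <- conc_1cpt(tmax, cfg$dose_mg, ka, ke, V, F_)
  # analytic integral of the curve over [0, T_last]
  auc0t <- F_ * cfg$dose_mg * ka / (V * (ka - ke)) *
    ((1 - exp(-ke * T_last)) / ke - (1 - exp(-ka * T_last)) / ka)
  true_pk <- data.frame(subject_id = ids, ka = ka, ke = ke, V = V, F = F_,
                        auc0t = auc0t, cmax = cmax, tmax = tmax,
                        kel = ke, t_half = log(2) / ke,
                        stringsAsFactors = FALSE)
  s_n <- sqrt(log1p(cfg$noise_cv^2))
  profiles <- do.call(rbind, lapply(seq_len(n), function(i) {
    conc <- conc_1cpt(tt, cfg$dose_mg, ka[i], ke[i], V[i], F_[i])
    conc[tt == 0] <- 0
    if (cfg$noise_cv > 0) {
      fac <- exp(stats::rnorm(length(tt), -s_n^2 / 2, s_n))
      conc <- conc * fac
    }
    data.frame(subject_id = ids[i], time_h = tt, conc_ug_per_ml = conc,
               stringsAsFactors = FALSE)
  }))
  rownames(profiles) <- NULL
  list(profiles = profiles, true_pk = true_pk)
}

#' Simulate subject traits
#'
#' Sex, age, BMI and bioequivalence period (the differential-abundance
#' covariates) plus independent normal clinical/laboratory traits drawn around
#' the plausible centers stored in the configuration.
#'
#' @param cfg A [sim_config()] object.
#' @return A data.frame with one row per subject.
#' @export
simulate_traits <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg, 2L))
  n <- cfg$n_subjects
  out <- data.frame(subject_id = subject_ids(n),
                    sex = sample(c("F", "M"), n, replace = TRUE),
                    age = pmin(pmax(round(stats::rnorm(n, 28, 6.8)), 18), 45),
                    bmi = round(pmin(pmax(stats::rnorm(n, 24.2, 2.7), 18.5), 29.9), 1),
                    period = sample(c("P1", "P2"), n, replace = TRUE),
                    stringsAsFactors = FALSE)
  for (nm in names(cfg$trait_centers)) {
    ms <- cfg$trait_centers[[nm]]
    out[[nm]] <- round(pmax(stats::rnorm(n, ms[1], ms[2]), ms[1] / 10), 2)
  }
  out
}

# rescale a parameter vector to [0, 1]
unit_scale <- function(z) {
  r <- range(z)
  if (diff(r) == 0) return(rep(0.5, length(z)))
  (z - r[1]) / diff(r)
}

#' Simulate an LC-MS feature matrix with known ground truth
#'
#' Generates lognormal feature intensities for paired pre/post study samples
#' plus pooled QC injections in a randomized injection sequence with QC
#' injections every `qc_interval` study samples. The ground truth embedded in
#' the matrix covers: differential features (multiplicative pre/post effect of
#' known log fold change), planted metabolite-parameter associations (linear
#' or rank-monotone in the target PK parameter or trait), and a smooth
#' feature-specific multiplicative injection-order drift shared by QC and
#' study samples. QC injections measure the per-feature mean of all study
#' samples before drift and noise, so drift-correction quality is directly
#' measurable.
#'
#' @param cfg A [sim_config()] object.
#' @param true_pk `true_pk` table from [simulate_pk_profiles()].
#' @param traits Trait table from [simulate_traits()]; must cover the same
#'   subjects.
#' @return A list with `matrix` (a [feature_matrix()]) and `truth`, a list
#'   holding `differential` (feature_id, lfc), `edges` (metabolite_id,
#'   parameter, parameter_class, sign, form, timepoint) and, once pathways are
#'   simulated, the planted pathway id.
#' @export
simulate_feature_matrix <- function(cfg, true_pk, traits) {
  validate_sim_config(cfg)
  if (!identical(sort(true_pk$subject_id), sort(traits$subject_id)))
    stop("true_pk and traits must cover identical subject ids")
  if (cfg$n_planted_edges + cfg$n_planted_edges_pre > cfg$n_features)
    stop("more planted edges than features")
  set.seed(stage_seed(cfg, 3L))
  n_sub <- cfg$n_subjects
  n_feat <- cfg$n_features
  ids <- true_pk$subject_id
  feat_ids <- sprintf("M%04d", seq_len(n_feat))

  # feature-level baselines and biological variability (natural-log scale)
  mu <- stats::runif(n_feat, log(1e4), log(1e6))
  sb0 <- sqrt(log1p(cfg$biological_cv^2))
  sb <- sb0 * exp(stats::rnorm(n_feat, 0, 0.35))

  # differential features: planted away from the lowest-abundance floor,
  # where absolute-scale variance filtering removes features by design and
  # ground-truth recovery would be undefined
  plantable <- which(mu > stats::quantile(mu, 0.15))
  diff_idx <- sort(sample(plantable, cfg$n_differential))
  lfc <- sample(cfg$effect_sizes, cfg$n_differential, replace = TRUE) *
    sample(c(-1, 1), cfg$n_differential, replace = TRUE)
  delta <- numeric(n_feat)
  delta[diff_idx] <- lfc

  # planted edges live on differential features (the network is built on the
  # differential set downstream)
  n_post <- cfg$n_planted_edges
  n_pre <- cfg$n_planted_edges_pre
  edge_feat <- sample(diff_idx, n_post + n_pre)
  pk_pool <- c("auc0t", "cmax", "kel", "t_half")
  trait_pool <- names(cfg$trait_centers)
  edges <- NULL
  if (n_post + n_pre > 0) {
    post_par <- if (n_post > 0)
      c(pk_pool, trait_pool)[1 + (seq_len(n_post) - 1) %%
                               (length(pk_pool) + length(trait_pool))]
    else character(0)
    pre_par <- if (n_pre > 0)
      trait_pool[1 + (seq_len(n_pre) - 1) %% length(trait_pool)]
    else character(0)
    edges <- data.frame(
      metabolite_id = feat_ids[edge_feat],
      parameter = c(post_par, pre_par),
      parameter_class = c(ifelse(post_par %in% pk_pool, "PK", "trait"),
                          rep("trait", n_pre)),
      sign = sample(c("+", "-"), n_post + n_pre, replace = TRUE),
      form = sample(cfg$edge_forms, n_post + n_pre, replace = TRUE),
      timepoint = c(rep("post", n_post), rep("pre", n_pre)),
      stringsAsFactors = FALSE)
  }

  param_tab <- merge(true_pk[, c("subject_id", pk_pool)],
                     traits[, c("subject_id", trait_pool)], by = "subject_id")
  param_tab <- param_tab[match(ids, param_tab$subject_id), ]

  # subject x feature log-intensities per timepoint
  b <- matrix(stats::rnorm(n_sub * n_feat, 0, rep(sb, each = n_sub)),
              n_sub, n_feat)
  log_pre <- sweep(b, 2, mu, "+")
  log_post <- sweep(b, 2, mu + delta, "+")
  if (!is.null(edges)) {
    for (k in seq_len(nrow(edges))) {
      fi <- edge_feat[k]
      z <- unit_scale(param_tab[[edges$parameter[k]]])
      if (edges$sign[k] == "-") z <- 1 - z
      h <- if (edges$form[k] == "linear") log1p(cfg$edge_strength * z)
           else 1.5 * cfg$edge_strength * z
      h <- h - mean(h)   # keep the pre/post effect of edge features at delta
      # association replaces the random subject effect so the noiseless
      # association is exact
      if (edges$timepoint[k] == "post") {
        log_post[, fi] <- mu[fi] + delta[fi] + h
        log_pre[, fi] <- mu[fi] + b[, fi]
      } else {
        log_pre[, fi] <- mu[fi] + h
        log_post[, fi] <- mu[fi] + delta[fi] + h
      }
    }
  }

  # injection sequence: randomized study samples, QC every qc_interval
  samp <- data.frame(subject_id = rep(ids, 2),
                     timepoint = rep(c("pre", "post"), each = n_sub),
                     stringsAsFactors = FALSE)
  samp <- samp[sample.int(nrow(samp)), ]
  n_study <- nrow(samp)
  seq_rows <- list()
  qc_count <- 0L
  add_qc <- function() {
    qc_count <<- qc_count + 1L
    data.frame(subject_id = NA_character_, timepoint = "QC",
               stringsAsFactors = FALSE)
  }
  seq_rows[[1]] <- add_qc()
  i <- 1L
  while (i <= n_study) {
    j <- min(i + cfg$qc_interval - 1L, n_study)
    seq_rows[[length(seq_rows) + 1L]] <- samp[i:j, ]
    seq_rows[[length(seq_rows) + 1L]] <- add_qc()
    i <- j + 1L
  }
  meta <- do.call(rbind, seq_rows)
  meta$injection_order <- seq_len(nrow(meta))
  meta$injection_id <- sprintf("inj%03d", meta$injection_order)
  meta$period <- ifelse(is.na(meta$subject_id), NA_character_,
                        traits$period[match(meta$subject_id, traits$subject_id)])
  rownames(meta) <- NULL
  n_inj <- nrow(meta)

  # pre-drift, pre-noise intensities (features x injections); QC = per-feature
  # mean of all study samples before drift/noise
  study_int <- matrix(NA_real_, n_feat, n_study)
  for (s in seq_len(n_study)) {
    si <- match(samp$subject_id[s], ids)
    study_int[, s] <- if (samp$timepoint[s] == "pre") exp(log_pre[si, ])
                      else exp(log_post[si, ])
  }
  qc_truth <- rowMeans(study_int)
  intens <- matrix(NA_real_, n_feat, n_inj,
                   dimnames = list(feat_ids, meta$injection_id))
  is_qc <- meta$timepoint == "QC"
  intens[, is_qc] <- qc_truth
  intens[, !is_qc] <- study_int[, match(
    paste(meta$subject_id[!is_qc], meta$timepoint[!is_qc]),
    paste(samp$subject_id, samp$timepoint))]

  # multiplicative drift: feature-specific monotone trend + low-frequency
  # smooth component over the injection sequence
  if (cfg$drift_magnitude > 0) {
    s01 <- (meta$injection_order - 1) / (n_inj - 1)
    a <- stats::runif(n_feat, 0.5, 1.5) * sample(c(-1, 1), n_feat, replace = TRUE)
    cc <- stats::runif(n_feat, 0.2, 0.6)
    phi <- stats::runif(n_feat, 0, 2 * pi)
    for (f in seq_len(n_feat)) {
      w <- a[f] * (s01 - 0.5) + cc[f] * sin(pi * s01 + phi[f])
      intens[f, ] <- intens[f, ] * exp(cfg$drift_magnitude * w)
    }
  }

  if (cfg$noise_cv > 0) {
    s_n <- sqrt(log1p(cfg$noise_cv^2))
    intens <- intens * exp(matrix(stats::rnorm(length(intens), -s_n^2 / 2, s_n),
                                  n_feat, n_inj))
  }

  truth <- list(differential = data.frame(feature_id = feat_ids[diff_idx],
                                          lfc = lfc, stringsAsFactors = FALSE),
                edges = edges,
                enriched_pathway = NA_character_)
  list(matrix = feature_matrix(intens, meta), truth = truth)
}

#' Simulate a pathway database with one planted enriched set
#'
#' Emits `n_pathways` random metabolite sets with sizes drawn uniformly in
#' `pathway_size_range`, plus one planted pathway whose members are
#' predominantly differential features, so that over-representation analysis
#' has a known positive control.
#'
#' @param cfg A [sim_config()] object.
#' @param feature_ids All feature ids in the study.
#' @param differential_ids Differential feature ids (ground truth).
#' @return A list with `db` (a pathway database as used by [enrich()]: a named
#'   list of lists with `source`, `description`, `members`) and `planted_id`.
#' @export
simulate_pathways <- function(cfg, feature_ids, differential_ids) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg, 4L))
  sources <- c("KEGG", "Reactome", "WikiPathways")
  db <- list()
  hi <- min(cfg$pathway_size_range[2], length(feature_ids))
  if (cfg$pathway_size_range[1] > hi)
    stop("pathway size range exceeds the number of features")
  sz <- sample(seq(cfg$pathway_size_range[1], hi),
               cfg$n_pathways, replace = TRUE)
  for (k in seq_len(cfg$n_pathways)) {
    id <- sprintf("PW%03d", k)
    db[[id]] <- list(source = sources[1 + (k - 1) %% 3],
                     description = sprintf("simulated pathway %d", k),
                     members = sort(sample(feature_ids, sz[k])))
  }
  planted_id <- sprintf("PW%03d", cfg$n_pathways + 1L)
  n_hit <- min(cfg$planted_pathway_hits, length(differential_ids))
  fill <- setdiff(feature_ids, differential_ids)
  db[[planted_id]] <- list(
    source = "KEGG", description = "planted enriched pathway",
    members = sort(c(sample(differential_ids, n_hit),
                     sample(fill, cfg$planted_pathway_size - n_hit))))
  list(db = db, planted_id = planted_id)
}

#' Simulate a complete study
#'
#' Runs every generator stage under the configuration's seed and returns the
#' full bundle: concentration profiles, true PK parameters, traits, feature
#' matrix with injection metadata, pathway database, and ground truth.
#'
#' @param cfg A [sim_config()] object.
#' @return A list with elements `config`, `profiles`, `true_pk`, `traits`,
#'   `features` (a [feature_matrix()]), `pathways` (db) and `truth`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  pk <- simulate_pk_profiles(cfg)
  traits <- simulate_traits(cfg)
  fm <- simulate_feature_matrix(cfg, pk$true_pk, traits)
  pw <- simulate_pathways(cfg, rownames(fm$matrix$intensities),
                          fm$truth$differential$feature_id)
  truth <- fm$truth
  truth$enriched_pathway <- pw$planted_id
  list(config = cfg, profiles = pk$profiles, true_pk = pk$true_pk,
       traits = traits, features = fm$matrix, pathways = pw$db, truth = truth)
}

#' Write a simulated study to plain-text files
#'
#' Writes `concentrations.csv`, `features.csv`, `injections.csv`,
#' `traits.csv`, `pk_true.csv`, `pathways.gmt` and `truth.json` into `dir`.
#' Output is byte-identical across runs for identical configurations.
#'
#' @param study Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(study$profiles, file.path(dir, "concentrations.csv"),
                   row.names = FALSE)
  fm <- study$features
  feat <- data.frame(feature_id = rownames(fm$intensities),
                     fm$intensities, check.names = FALSE,
                     stringsAsFactors = FALSE)
  utils::write.csv(feat, file.path(dir, "features.csv"), row.names = FALSE)
  utils::write.csv(fm$meta[, c("injection_id", "subject_id", "timepoint",
                               "injection_order", "period")],
                   file.path(dir, "injections.csv"), row.names = FALSE)
  utils::write.csv(study$traits, file.path(dir, "traits.csv"), row.names = FALSE)
  utils::write.csv(study$true_pk, file.path(dir, "pk_true.csv"), row.names = FALSE)
  write_gmt(study$pathways, file.path(dir, "pathways.gmt"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}
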