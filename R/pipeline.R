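#' Run the full analysis on a simulated (or assembled) study
#'
#' Executes the complete pipeline: non-compartmental PK on the concentration
#' profiles, preprocessing of the feature matrix, paired differential
#' abundance, pathway over-representation of the selected features, the
#' pre-dose and post-dose signed distance-correlation tripartite networks
#' with Leiden communities, and the integrated module/pathway report (on the
#' post-dose network).
#'
#' @param study A list shaped like [simulate_study()] output: `profiles`,
#'   `traits`, `features`, `pathways`.
#' @param alpha FDR threshold used throughout.
#' @param d_min Distance-correlation threshold for edges.
#' @param B Permutations per association test.
#' @param seed Seed for the permutation draws and Leiden refinement.
#' @param drift_method Drift-correction method (see [drift_correct()]).
#' @return List with `pk` (per-subject table), `pk_summary`, `preprocessed`
#'   (matrix + report), `diffabund`, `selected`, `enrichment`, `network_pre`,
#'   `network_post`, `integrated`.
#' @export
run_study_analysis <- function(study, alpha = 0.05, d_min = 0.5, B = 4999,
                               seed = 1, drift_method = "loess") {
  pk <- compute_pk_table(study$profiles)
  prep <- preprocess(study$features, drift_method = drift_method)
  da <- diff_abundance(prep$matrix, study$traits, alpha = alpha)
  selected <- select_features(da, alpha)
  db_universe <- unique(unlist(lapply(study$pathways, `[[`, "members")))
  background <- intersect(rownames(prep$matrix$intensities), db_universe)
  enr <- enrich(selected, study$pathways, background = background,
                alpha = alpha)
  net_pre <- net_post <- NULL
  if (length(selected) > 0) {
    net_pre <- association_network(prep$matrix, selected, pk, study$traits,
                                   timepoint = "pre", d_min = d_min,
                                   alpha = alpha, B = B, seed = seed)
    net_post <- association_network(prep$matrix, selected, pk, study$traits,
                                    timepoint = "post", d_min = d_min,
                                    alpha = alpha, B = B, seed = seed + 1)
  }
  integrated <- if (!is.null(net_post))
    integrate_results(net_post$edges, net_post$partition, enr)
  else NULL
  list(pk = pk, pk_summary = summarize_pk(pk), preprocessed = prep,
       diffabund = da, selected = selected, enrichment = enr,
       network_pre = net_pre, network_post = net_post,
       integrated = integrated)
}
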