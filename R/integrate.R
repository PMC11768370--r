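#' Join network communities with enrichment results
#'
#' Left join on the retained association edges: each edge contributes one
#' record carrying its metabolite's community module and the enriched
#' pathways that contain the metabolite. Metabolites in no enriched pathway
#' are kept and flagged (`pathway_less`), matching the shape of an integrated
#' report where some entries carry only a chemical-class description.
#'
#' @param edges Result of [build_edges()]; only retained rows are used.
#' @param partition Result of [leiden_partition()] on the corresponding
#'   graph.
#' @param enrichment Result of [enrich()]. May be empty.
#' @param alpha FDR threshold defining "enriched" pathways within
#'   `enrichment` (default: use its `significant` flag).
#' @return Data.frame with `module`, `metabolite_id`, `parameter`,
#'   `parameter_class`, `d`, `sign`, `q`, `pathways`
#'   (semicolon-separated enriched pathway ids), `pathway_less`; one record
#'   per retained edge, sorted by module then metabolite.
#' @export
integrate_results <- function(edges, partition, enrichment, alpha = NULL) {
  e <- edges[edges$retained, , drop = FALSE]
  if (nrow(e) == 0)
    return(data.frame(module = integer(0), metabolite_id = character(0),
                      parameter = character(0), parameter_class = character(0),
                      d = numeric(0), sign = character(0), q = numeric(0),
                      pathways = character(0), pathway_less = logical(0),
                      stringsAsFactors = FALSE))
  if (nrow(enrichment) > 0) {
    hit_sets <- strsplit(enrichment$hit_ids, ";", fixed = TRUE)
    all_hits <- unique(unlist(hit_sets))
    if (length(intersect(e$metabolite_id, all_hits)) == 0 &&
        length(all_hits) > 0)
      stop("no overlap between edge metabolites and pathway metabolite ids; ",
           "check id-mapping configuration")
    sig <- if (is.null(alpha)) enrichment$significant else enrichment$q <= alpha
  }
  pathways_of <- function(met) {
    if (nrow(enrichment) == 0) return(character(0))
    idx <- which(sig & vapply(hit_sets, function(h) met %in% h, logical(1)))
    enrichment$pathway_id[idx]
  }
  pw <- vapply(e$metabolite_id, function(m)
    paste(sort(pathways_of(m)), collapse = ";"), character(1))
  out <- data.frame(module = unname(partition$membership[e$metabolite_id]),
                    metabolite_id = e$metabolite_id,
                    parameter = e$parameter,
                    parameter_class = e$parameter_class,
                    d = e$d, sign = e$sign, q = e$q,
                    pathways = unname(pw), pathway_less = !nzchar(pw),
                    stringsAsFactors = FALSE)
  out <- out[order(out$module, out$metabolite_id, out$parameter), ]
  rownames(out) <- NULL
  out
}

#' Write the integrated report as markdown and CSV
#'
#' @param records Result of [integrate_results()].
#' @param md_path Markdown output path.
#' @param csv_path Optional CSV output path.
#' @return `md_path`, invisibly.
#' @export
write_integration_report <- function(records, md_path, csv_path = NULL) {
  lines <- c("# Integrated network and pathway report", "",
             sprintf("%d association edges across %d modules.",
                     nrow(records), length(unique(records$module))), "",
             "| Module | Metabolite | Parameter | Class | d | Sign | q | Enriched pathways |",
             "|---|---|---|---|---|---|---|---|")
  if (nrow(records) > 0)
    lines <- c(lines, sprintf("| %d | %s | %s | %s | %.3f | %s | %.3g | %s |",
                              records$module, records$metabolite_id,
                              records$parameter, records$parameter_class,
                              records$d, records$sign, records$q,
                              ifelse(records$pathway_less, "(none)",
                                     records$pathways)))
  writeLines(lines, md_path)
  if (!is.null(csv_path)) utils::write.csv(records, csv_path, row.names = FALSE)
  invisible(md_path)
}
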