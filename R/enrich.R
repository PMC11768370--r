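#' Read a pathway database from a GMT file
#'
#' Standard tab-separated GMT: pathway id, description, then member ids. The
#' description field holds the source label (e.g. KEGG / Reactome /
#' WikiPathways), as written by [write_gmt()].
#'
#' @param path GMT file path.
#' @return Named list; each element has `source`, `description`, `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  db <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(ln, 1, 40))
    db[[parts[1]]] <- list(source = parts[2], description = parts[2],
                           members = unique(parts[-(1:2)]))
  }
  if (length(db) == 0) stop("empty pathway database")
  db
}

#' Write a pathway database to a GMT file
#'
#' @param db Pathway database (named list with `source`, `members`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(names(db), function(id) {
    paste(c(id, db[[id]]$source, db[[id]]$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Filter pathways to the testable set
#'
#' A pathway is testable when its size (members restricted to the background
#' universe) falls within `[min_size, max_size]` and it has at least
#' `min_hits` members in the selected set.
#'
#' @param db Pathway database (see [read_gmt()]).
#' @param selected Character vector of selected metabolite ids.
#' @param background Background universe; default is the union of all pathway
#'   members.
#' @param min_size,max_size Inclusive pathway-size window (default 5-150).
#' @param min_hits Minimum selected-set hits (default 1).
#' @return Character vector of testable pathway ids.
#' @export
filter_pathways <- function(db, selected, background = NULL,
                            min_size = 5, max_size = 150, min_hits = 1) {
  if (length(db) == 0) stop("empty pathway database")
  if (is.null(background))
    background <- unique(unlist(lapply(db, `[[`, "members")))
  selected <- intersect(selected, background)
  ok <- vapply(names(db), function(id) {
    mem <- intersect(db[[id]]$members, background)
    length(mem) >= min_size && length(mem) <= max_size &&
      length(intersect(mem, selected)) >= min_hits
  }, logical(1))
  names(db)[ok]
}

#' One-sided hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= n_hits)` for the number of selected
#' metabolites falling in a pathway, under sampling without replacement from
#' the background.
#'
#' @param n_hits Selected metabolites inside the pathway.
#' @param pathway_size Pathway members in the background.
#' @param selected_size Size of the selected set (within the background).
#' @param background_size Background universe size.
#' @return p-value.
#' @export
hypergeom_test <- function(n_hits, pathway_size, selected_size,
                           background_size) {
  if (n_hits > min(pathway_size, selected_size) ||
      max(pathway_size, selected_size) > background_size || n_hits < 0)
    stop("inconsistent counts for hypergeometric test")
  stats::phyper(n_hits - 1, pathway_size, background_size - pathway_size,
                selected_size, lower.tail = FALSE)
}

#' Over-representation analysis of a metabolite set
#'
#' Tests every testable pathway (see [filter_pathways()]) with the one-sided
#' hypergeometric test, applies BH adjustment over the tested pathways only,
#' and returns the table sorted by q, then p, then pathway id.
#'
#' @param selected Selected metabolite ids.
#' @param db Pathway database.
#' @param background Background universe; default `NULL` uses the union of
#'   all pathway members. In a pipeline, pass the preprocessed feature ids
#'   present in the database.
#' @param alpha FDR threshold for the `significant` flag.
#' @param min_size,max_size,min_hits Passed to [filter_pathways()].
#' @return Data.frame with `pathway_id`, `source`, `n_hits`, `pathway_size`,
#'   `selected_size`, `background_size`, `p`, `q`, `significant`, `hit_ids`
#'   (semicolon-separated). Empty selected set gives an empty table.
#' @export
enrich <- function(selected, db, background = NULL, alpha = 0.05,
                   min_size = 5, max_size = 150, min_hits = 1) {
  if (is.null(background))
    background <- unique(unlist(lapply(db, `[[`, "members")))
  selected <- intersect(unique(selected), background)
  empty <- data.frame(pathway_id = character(0), source = character(0),
                      n_hits = integer(0), pathway_size = integer(0),
                      selected_size = integer(0), background_size = integer(0),
                      p = numeric(0), q = numeric(0),
                      significant = logical(0), hit_ids = character(0),
                      stringsAsFactors = FALSE)
  if (length(selected) == 0) return(empty)
  ids <- filter_pathways(db, selected, background, min_size, max_size, min_hits)
  if (length(ids) == 0) return(empty)
  rows <- lapply(ids, function(id) {
    mem <- intersect(db[[id]]$members, background)
    hits <- intersect(mem, selected)
    data.frame(pathway_id = id, source = db[[id]]$source,
               n_hits = length(hits), pathway_size = length(mem),
               selected_size = length(selected),
               background_size = length(background),
               p = hypergeom_test(length(hits), length(mem),
                                  length(selected), length(background)),
               hit_ids = paste(sort(hits), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q <= alpha
  out <- out[order(out$q, out$p, out$pathway_id), ]
  rownames(out) <- NULL
  out[, c("pathway_id", "source", "n_hits", "pathway_size", "selected_size",
          "background_size", "p", "q", "significant", "hit_ids")]
}
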