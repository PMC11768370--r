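# double-centered Euclidean distance matrix and its distance variance
dcor_prep <- function(x) {
  a <- abs(outer(x, x, "-"))
  A <- a - rowMeans(a)
  A <- sweep(A, 2, colMeans(a), "-") + mean(a)
  list(A = A, dvar = mean(A * A))
}

#' Distance correlation
#'
#' Sample distance correlation between two real vectors: pairwise Euclidean
#' distance matrices are double-centered, the squared distance covariance is
#' the mean of their elementwise product, and the correlation is normalized
#' by the distance variances. Lies in `[0, 1]`; 0 is returned when either
#' distance variance vanishes (a constant vector).
#'
#' @param x,y Numeric vectors of equal length (n >= 4), no missing values.
#' @return Distance correlation in `[0, 1]`.
#' @export
distance_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4) stop("distance correlation needs n >= 4")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  px <- dcor_prep(x); py <- dcor_prep(y)
  if (px$dvar == 0 || py$dvar == 0) return(0)
  dcov2 <- mean(px$A * py$A)
  d2 <- dcov2 / sqrt(px$dvar * py$dvar)
  min(max(sqrt(max(d2, 0)), 0), 1)
}

#' Signed distance-correlation association with permutation p-value
#'
#' The dependence strength is the distance correlation; its direction is the
#' sign of the Pearson correlation on the same values (flagged ambiguous when
#' `|r| < 1e-10`, e.g. a symmetric quadratic). Significance comes from a
#' permutation test: `y` is permuted `B` times and
#' `p = (1 + #\{d_perm >= d_obs\}) / (1 + B)`. Uses the current RNG state;
#' seed upstream for reproducibility.
#'
#' @param x,y Numeric vectors of equal length (n >= 4).
#' @param B Number of permutations.
#' @return List with `d`, `sign` (`"+"`/`"-"`), `ambiguous`, `p`.
#' @export
signed_association <- function(x, y, B = 4999) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  px <- dcor_prep(x); py <- dcor_prep(y)
  if (px$dvar == 0 || py$dvar == 0)
    return(list(d = 0, sign = "+", ambiguous = TRUE, p = 1))
  d2obs <- mean(px$A * py$A)
  n <- length(x)
  count <- 0L
  for (b in seq_len(B)) {
    pp <- sample.int(n)
    if (mean(px$A[pp, pp] * py$A) >= d2obs - 1e-15) count <- count + 1L
  }
  r <- stats::cor(x, y)
  amb <- is.na(r) || abs(r) < 1e-10
  list(d = min(max(sqrt(max(d2obs / sqrt(px$dvar * py$dvar), 0)), 0), 1),
       sign = if (!amb && r < 0) "-" else "+",
       ambiguous = amb,
       p = (1 + count) / (1 + B))
}

#' Test all metabolite-parameter pairs and retain significant edges
#'
#' Computes the signed distance correlation for every metabolite x parameter
#' pair, with a shared set of `B` seeded permutations (permuting subjects is
#' equivalent to simultaneously permuting rows and columns of the centered
#' distance matrix, so each permutation reduces to an indexed product).
#' BH adjustment is applied globally across the full pair set; an edge is
#' retained when `d > d_min` and `q < alpha`.
#'
#' @param metab Numeric matrix, subjects x metabolites (column names are
#'   metabolite ids), on the analysis scale.
#' @param params Data.frame or matrix, subjects x parameters (PK parameters
#'   and traits), numeric columns, aligned to the same subjects.
#' @param param_class Named character vector mapping parameter names to
#'   `"PK"` or `"trait"`.
#' @param d_min Distance-correlation threshold (default 0.5).
#' @param alpha FDR threshold (default 0.05).
#' @param B Number of permutations (default 4999; the smallest attainable
#'   p-value is `1/(B+1)`, which must be small enough to survive global BH
#'   adjustment over all pairs).
#' @param seed Optional seed for the permutation draw.
#' @return Data.frame of all tested pairs: `metabolite_id`, `parameter`,
#'   `parameter_class`, `d`, `sign`, `ambiguous`, `p`, `q`, `retained`.
#' @export
build_edges <- function(metab, params, param_class, d_min = 0.5,
                        alpha = 0.05, B = 4999, seed = NULL) {
  params <- as.data.frame(params)
  if (nrow(metab) != nrow(params))
    stop("metab and params must cover the same subjects")
  cc <- stats::complete.cases(params) & stats::complete.cases(metab)
  if (!any(cc)) stop("no complete subjects across inputs")
  metab <- metab[cc, , drop = FALSE]
  params <- params[cc, , drop = FALSE]
  n <- nrow(metab)
  if (n < 4) stop("need at least 4 complete subjects")
  if (!all(names(params) %in% names(param_class)))
    stop("param_class must name every parameter column")
  if (!is.null(seed)) set.seed(seed)

  # index vectors realizing vec(A[p,p]) for each permutation p
  IV <- matrix(0L, n * n, B)
  for (b in seq_len(B)) {
    pp <- sample.int(n)
    IV[, b] <- rep((pp - 1L) * n, each = n) + pp
  }
  pprep <- lapply(params, dcor_prep)

  rows <- vector("list", ncol(metab) * ncol(params))
  k <- 0L
  for (mi in seq_len(ncol(metab))) {
    x <- metab[, mi]
    px <- dcor_prep(x)
    vecA <- as.vector(px$A)
    M <- NULL
    if (px$dvar > 0) {
      M <- vecA[IV]
      dim(M) <- c(n * n, B)
    }
    for (pi in seq_len(ncol(params))) {
      k <- k + 1L
      py <- pprep[[pi]]
      if (px$dvar == 0 || py$dvar == 0) {
        rows[[k]] <- data.frame(metabolite_id = colnames(metab)[mi],
                                parameter = names(params)[pi],
                                d = 0, sign = "+", ambiguous = TRUE, p = 1,
                                stringsAsFactors = FALSE)
        next
      }
      vecB <- as.vector(py$A)
      d2obs <- sum(vecA * vecB) / (n * n)
      d2perm <- as.vector(crossprod(M, vecB)) / (n * n)
      pval <- (1 + sum(d2perm >= d2obs - 1e-15)) / (1 + B)
      r <- stats::cor(x, params[, pi])
      amb <- is.na(r) || abs(r) < 1e-10
      rows[[k]] <- data.frame(
        metabolite_id = colnames(metab)[mi],
        parameter = names(params)[pi],
        d = min(max(sqrt(max(d2obs / sqrt(px$dvar * py$dvar), 0)), 0), 1),
        sign = if (!amb && r < 0) "-" else "+",
        ambiguous = amb, p = pval, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$parameter_class <- unname(param_class[out$parameter])
  out$q <- bh_adjust(out$p)
  out$retained <- out$d > d_min & out$q < alpha
  out[, c("metabolite_id", "parameter", "parameter_class", "d", "sign",
          "ambiguous", "p", "q", "retained")]
}

#' Assemble the tripartite association graph
#'
#' Builds a weighted undirected graph from the retained edges. Metabolites
#' are the only connector class: every edge joins a metabolite to a PK
#' parameter or a trait. Edge weight is the (unsigned) distance correlation;
#' the sign is kept as an edge attribute.
#'
#' @param edges Result of [build_edges()] (only rows with
#'   `retained == TRUE` are used).
#' @return An igraph object with vertex attribute `class` (`metabolite`,
#'   `PK`, `trait`) and edge attributes `weight`, `sign`, `q`.
#' @export
build_network <- function(edges) {
  e <- edges[edges$retained, , drop = FALSE]
  if (nrow(e) == 0)
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  verts <- rbind(
    data.frame(name = unique(e$metabolite_id), class = "metabolite",
               stringsAsFactors = FALSE),
    unique(data.frame(name = e$parameter, class = e$parameter_class,
                      stringsAsFactors = FALSE)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$metabolite_id, to = e$parameter,
               weight = e$d, sign = e$sign, q = e$q,
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
  assert_tripartite(g)
  g
}

#' Assert the tripartite constraint
#'
#' Every edge must join a metabolite to a PK parameter or trait; no
#' metabolite-metabolite, PK-PK, trait-trait or PK-trait edges are allowed.
#'
#' @param g An igraph graph with a `class` vertex attribute.
#' @return `TRUE` invisibly; stops otherwise.
#' @export
assert_tripartite <- function(g) {
  if (igraph::ecount(g) == 0) return(invisible(TRUE))
  cls <- igraph::V(g)$class
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  c1 <- cls[ends[, 1]]; c2 <- cls[ends[, 2]]
  ok <- (c1 == "metabolite") != (c2 == "metabolite")
  if (!all(ok))
    stop("tripartite constraint violated: metabolites must be the only connectors")
  invisible(TRUE)
}

#' Leiden community detection
#'
#' Partitions the weighted graph by the Leiden algorithm (modularity
#' objective), deterministic under the given seed. Module ids are renumbered
#' by decreasing module size.
#'
#' @param g An igraph graph with edge `weight`s.
#' @param resolution Resolution parameter (default 1).
#' @param seed RNG seed for the Leiden refinement (default 1).
#' @param n_iterations Leiden iterations per restart (default 10).
#' @param n_restarts Independent restarts; the partition with the best
#'   modularity is kept (default 5). Restart seeds derive from `seed`, so the
#'   result is deterministic.
#' @return List with `membership` (named integer vector), `modularity`
#'   (weighted), and `n_modules`. An empty graph gives an empty partition.
#' @export
leiden_partition <- function(g, resolution = 1, seed = 1, n_iterations = 10,
                             n_restarts = 5) {
  if (igraph::ecount(g) == 0)
    return(list(membership = integer(0), modularity = NA_real_,
                n_modules = 0L))
  w <- igraph::E(g)$weight
  mem <- NULL; best_q <- -Inf
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 weights = w,
                                 resolution = resolution,
                                 n_iterations = n_iterations)
    m <- igraph::membership(cl)
    q <- igraph::modularity(g, m, weights = w)
    if (q > best_q + 1e-15) { best_q <- q; mem <- m }
  }
  sizes <- sort(table(mem), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  mem2 <- as.integer(relabel[as.character(mem)])
  names(mem2) <- igraph::V(g)$name
  list(membership = mem2,
       modularity = igraph::modularity(g, mem2,
                                       weights = igraph::E(g)$weight),
       n_modules = length(sizes))
}

#' Summarize the community structure
#'
#' @param g Graph from [build_network()].
#' @param partition Result of [leiden_partition()].
#' @return List with `members` (data.frame: `module`, `node`, `class`),
#'   `modules` (per-module node/edge counts by class) and `summary`
#'   (`n_modules`, `n_edges`, `n_within_edges`, `n_cross_edges`, node counts
#'   per class).
#' @export
community_report <- function(g, partition) {
  if (igraph::ecount(g) == 0) {
    return(list(members = data.frame(module = integer(0), node = character(0),
                                     class = character(0)),
                modules = data.frame(),
                summary = list(n_modules = 0L, n_edges = 0L,
                               n_within_edges = 0L, n_cross_edges = 0L,
                               n_metabolites = 0L, n_pk = 0L, n_traits = 0L)))
  }
  mem <- partition$membership
  cls <- stats::setNames(igraph::V(g)$class, igraph::V(g)$name)
  members <- data.frame(module = unname(mem[names(mem)]), node = names(mem),
                        class = unname(cls[names(mem)]),
                        stringsAsFactors = FALSE)
  members <- members[order(members$module, members$class, members$node), ]
  rownames(members) <- NULL
  ends <- igraph::ends(g, igraph::E(g))
  within <- mem[ends[, 1]] == mem[ends[, 2]]
  modules <- do.call(rbind, lapply(sort(unique(members$module)), function(m) {
    sub <- members[members$module == m, ]
    data.frame(module = m, n_nodes = nrow(sub),
               n_metabolites = sum(sub$class == "metabolite"),
               n_pk = sum(sub$class == "PK"),
               n_traits = sum(sub$class == "trait"),
               n_within_edges = sum(within & mem[ends[, 1]] == m))
  }))
  list(members = members, modules = modules,
       summary = list(n_modules = partition$n_modules,
                      n_edges = igraph::ecount(g),
                      n_within_edges = sum(within),
                      n_cross_edges = sum(!within),
                      n_metabolites = sum(members$class == "metabolite"),
                      n_pk = sum(members$class == "PK"),
                      n_traits = sum(members$class == "trait")))
}

#' Timepoint association network from an analysis-scale matrix
#'
#' Extracts the selected metabolites' abundances at one timepoint (subjects
#' as rows), joins the per-subject PK parameters and traits, tests all pairs
#' with [build_edges()], assembles the tripartite graph and partitions it.
#' Subjects with a missing parameter (e.g. undefined elimination constant)
#' are excluded listwise.
#'
#' @param fm Analysis-scale [feature_matrix()].
#' @param selected Metabolite ids to include (the differential set).
#' @param pk_table Per-subject PK table ([compute_pk_table()]).
#' @param traits Subject trait table.
#' @param timepoint `"pre"` or `"post"`.
#' @param trait_vars Trait columns to use as network parameters; default all
#'   numeric trait columns except the covariates.
#' @param ... Passed to [build_edges()] (`d_min`, `alpha`, `B`, `seed`).
#' @return List with `edges` (all tested pairs), `graph`, `partition` and
#'   `report`.
#' @export
association_network <- function(fm, selected, pk_table, traits,
                                timepoint = c("post", "pre"),
                                trait_vars = NULL, ...) {
  timepoint <- match.arg(timepoint)
  meta <- fm$meta
  cols <- which(meta$timepoint == timepoint)
  subs <- meta$subject_id[cols]
  selected <- intersect(selected, rownames(fm$intensities))
  if (length(selected) == 0) stop("no selected metabolites present in matrix")
  metab <- t(fm$intensities[selected, cols, drop = FALSE])
  rownames(metab) <- subs

  pk_vars <- c("auc0t", "cmax", "tmax", "kel", "t_half")
  if (is.null(trait_vars)) {
    num <- vapply(traits, is.numeric, logical(1))
    trait_vars <- setdiff(names(traits)[num], c("age", "bmi"))
  }
  ptab <- merge(pk_table[, c("subject_id", pk_vars)],
                traits[, c("subject_id", trait_vars)], by = "subject_id")
  ptab <- ptab[match(subs, ptab$subject_id), ]
  params <- ptab[, c(pk_vars, trait_vars), drop = FALSE]
  param_class <- stats::setNames(
    c(rep("PK", length(pk_vars)), rep("trait", length(trait_vars))),
    c(pk_vars, trait_vars))

  edges <- build_edges(metab, params, param_class, ...)
  g <- build_network(edges)
  part <- leiden_partition(g)
  list(edges = edges, graph = g, partition = part,
       report = community_report(g, part))
}

#' Write a network, partition and edge list to JSON/CSV
#'
#' @param g Graph from [build_network()].
#' @param partition Result of [leiden_partition()].
#' @param json_path Output JSON path (nodes with class and module, edges with
#'   weight/sign/q).
#' @param csv_path Optional edge-list CSV path.
#' @return `json_path`, invisibly.
#' @export
write_network <- function(g, partition, json_path, csv_path = NULL) {
  if (igraph::ecount(g) > 0) {
    ends <- igraph::ends(g, igraph::E(g))
    edges <- data.frame(from = ends[, 1], to = ends[, 2],
                        d = igraph::E(g)$weight, sign = igraph::E(g)$sign,
                        q = igraph::E(g)$q, stringsAsFactors = FALSE)
    nodes <- data.frame(name = igraph::V(g)$name, class = igraph::V(g)$class,
                        module = unname(partition$membership[igraph::V(g)$name]),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(); nodes <- data.frame()
  }
  jsonlite::write_json(list(nodes = nodes, edges = edges,
                            modularity = partition$modularity,
                            n_modules = partition$n_modules),
                       json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(csv_path)) utils::write.csv(edges, csv_path, row.names = FALSE)
  invisible(json_path)
}
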