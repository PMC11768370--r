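# Small factories and independent brute-force oracles used across tests.

# quick feature_matrix: mat has features in rows; timepoints is one label per
# column ("pre"/"post"/"QC"); subjects are auto-assigned pairing pre/post
# columns in order unless given.
make_fm <- function(mat, timepoints, subjects = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("F%03d", seq_len(nrow(mat)))
  ids <- sprintf("inj%03d", seq_len(ncol(mat)))
  colnames(mat) <- ids
  if (is.null(subjects)) {
    subjects <- rep(NA_character_, length(timepoints))
    for (tp in c("pre", "post")) {
      k <- which(timepoints == tp)
      subjects[k] <- sprintf("S%02d", seq_along(k))
    }
  }
  meta <- data.frame(injection_id = ids, subject_id = subjects,
                     timepoint = timepoints,
                     injection_order = seq_along(ids),
                     period = "P1", stringsAsFactors = FALSE)
  feature_matrix(mat, meta)
}

# paired-difference fm on the analysis scale: D is features x subjects
# (post - pre); pre columns are set to 0 and post to D.
make_diff_fm <- function(D) {
  n <- ncol(D)
  mat <- cbind(matrix(0, nrow(D), n), D)
  make_fm(mat, rep(c("pre", "post"), each = n),
          subjects = rep(sprintf("S%02d", seq_len(n)), 2))
}

basic_traits <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(subject_id = sprintf("S%02d", seq_len(n)),
             sex = sample(c("F", "M"), n, replace = TRUE),
             age = sample(18:41, n, replace = TRUE),
             bmi = round(runif(n, 19, 29), 1),
             period = sample(c("P1", "P2"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# textbook double-loop distance correlation
bf_dcor <- function(x, y) {
  n <- length(x)
  a <- abs(outer(x, x, "-")); b <- abs(outer(y, y, "-"))
  A <- B <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    A[i, j] <- a[i, j] - mean(a[i, ]) - mean(a[, j]) + mean(a)
    B[i, j] <- b[i, j] - mean(b[i, ]) - mean(b[, j]) + mean(b)
  }
  dcov2 <- 0; dvx <- 0; dvy <- 0
  for (i in 1:n) for (j in 1:n) {
    dcov2 <- dcov2 + A[i, j] * B[i, j]
    dvx <- dvx + A[i, j]^2
    dvy <- dvy + B[i, j]^2
  }
  dcov2 <- dcov2 / n^2; dvx <- dvx / n^2; dvy <- dvy / n^2
  if (dvx == 0 || dvy == 0) return(0)
  sqrt(max(dcov2, 0) / sqrt(dvx * dvy))
}

# exact upper-tail hypergeometric by direct summation of the pmf
bf_hyper_tail <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

# all set partitions of n elements as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(lab, mx) {
    if (length(lab) == n) { out[[length(out) + 1L]] <<- lab; return() }
    for (v in seq_len(mx + 1L)) rec(c(lab, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# single-pass greedy local-move modularity baseline (no refinement, no
# aggregation): each node moves to the neighboring community with the best
# modularity gain until no move improves.
greedy_modularity <- function(g) {
  n <- igraph::vcount(g)
  mem <- seq_len(n)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(g))
  q <- function(m) igraph::modularity(g, m, weights = w)
  repeat {
    moved <- FALSE
    for (v in seq_len(n)) {
      nb <- as.integer(igraph::neighbors(g, v))
      cands <- unique(mem[nb])
      best <- q(mem); best_c <- mem[v]
      for (cm in cands) {
        trial <- mem; trial[v] <- cm
        qq <- q(trial)
        if (qq > best + 1e-12) { best <- qq; best_c <- cm }
      }
      if (best_c != mem[v]) { mem[v] <- best_c; moved <- TRUE }
    }
    if (!moved) break
  }
  q(mem)
}
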