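## Sample clustering on the most variable cassette events: gap-statistic
## choice of k (PCA-aligned uniform reference, Tibshirani's one-SE rule,
## via cluster::clusGap/maxSE) and a best-of-restarts Lloyd K-means whose
## per-iteration objective trace is retained.

#' PSI matrix of the most variable cassette events
#'
#' Compiles all cassette (SE) events with complete PSI across every
#' replicate and keeps the `n` with the largest across-sample variance
#' (ties broken by event id, lexicographically, for determinism).
#'
#' @param table an [event_table()].
#' @param n number of events to keep (default 800). If fewer complete
#'   events are available, all are kept with a warning.
#' @return Numeric matrix (samples x events) with a `genotype` attribute
#'   labelling each row.
#' @export
top_variable_events <- function(table, n = 800) {
  se <- table$events$event_type == "SE"
  psi <- t(table$psi[se, , drop = FALSE])
  complete <- !apply(psi, 2L, anyNA)
  psi <- psi[, complete, drop = FALSE]
  if (ncol(psi) < n) {
    warning("only ", ncol(psi), " complete cassette events available (",
            n, " requested); keeping all")
    n <- ncol(psi)
  }
  v <- apply(psi, 2L, var)
  ord <- order(-v, colnames(psi))
  out <- psi[, ord[seq_len(n)], drop = FALSE]
  rep_geno <- rep(names(table$sample_labels), lengths(table$sample_labels))
  names(rep_geno) <- unlist(table$sample_labels, use.names = FALSE)
  attr(out, "genotype") <- unname(rep_geno[rownames(out)])
  out
}

# one Lloyd run from given initial centers; returns the objective trace
.lloyd <- function(x, centers, max_iter = 100L, tol = 1e-10) {
  k <- nrow(centers)
  trace <- numeric()
  assign <- integer(nrow(x))
  for (it in seq_len(max_iter)) {
    d2 <- vapply(seq_len(k), function(j)
      rowSums(sweep(x, 2L, centers[j, ], "-")^2), numeric(nrow(x)))
    assign <- max.col(-d2, ties.method = "first")
    # empty cluster: seed it with the point farthest from its center
    for (j in which(tabulate(assign, k) == 0L)) {
      far <- which.max(d2[cbind(seq_len(nrow(x)), assign)])
      assign[far] <- j
    }
    obj <- sum(d2[cbind(seq_len(nrow(x)), assign)])
    for (j in seq_len(k))
      centers[j, ] <- colMeans(x[assign == j, , drop = FALSE])
    trace <- c(trace, obj)
    if (it > 1L && trace[it - 1L] - obj < tol) break
  }
  # final objective at the updated centers
  d2 <- vapply(seq_len(k), function(j)
    rowSums(sweep(x, 2L, centers[j, ], "-")^2), numeric(nrow(x)))
  assign <- max.col(-d2, ties.method = "first")
  obj <- sum(d2[cbind(seq_len(nrow(x)), assign)])
  list(assign = assign, centers = centers, objective = obj,
       trace = c(trace, obj))
}

#' K-means partition (best-of-restarts Lloyd's algorithm)
#'
#' Euclidean Lloyd iterations from `n_init` random initialisations; the
#' restart with the lowest within-cluster sum of squares wins (ties by
#' restart order). The winning run's per-iteration objective trace is
#' returned; it is non-increasing by construction of the algorithm.
#'
#' @param matrix numeric samples x features matrix.
#' @param k number of clusters (default 2); must not exceed the sample
#'   count.
#' @param seed RNG seed; `NULL` uses (and advances) the caller's RNG
#'   stream.
#' @param n_init number of random restarts (default 25).
#' @return list (`cluster_result`) with `k`, `assignments` (named by
#'   sample), `centers`, `objective`, `objective_trace`.
#' @export
kmeans_partition <- function(matrix, k = 2, seed = NULL, n_init = 25) {
  x <- as.matrix(matrix)
  if (k > nrow(x)) stop("k exceeds the number of samples")
  run <- function() {
    best <- NULL
    for (r in seq_len(n_init)) {
      init <- x[sample.int(nrow(x), k), , drop = FALSE]
      # nudge duplicate initial centers apart deterministically
      if (k > 1L && anyDuplicated(init))
        init <- init + (seq_len(k) - 1) * 1e-9
      res <- .lloyd(x, init)
      if (is.null(best) || res$objective < best$objective) best <- res
    }
    best
  }
  best <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(list(k = k,
                 assignments = setNames(best$assign, rownames(x)),
                 centers = best$centers,
                 objective = best$objective,
                 objective_trace = best$trace),
            class = "cluster_result")
}

#' Gap statistic for choosing the cluster count
#'
#' For each k up to `k_max`, Gap(k) is the mean over `n_ref` uniform
#' reference datasets (drawn over the principal-component-aligned bounding
#' box of the data) of log(W_ref) minus log(W_data), W being the pooled
#' within-cluster dispersion; the selected k is the smallest k with
#' Gap(k) >= Gap(k+1) - SE(k+1). Clustering inside the reference loop is
#' the package's own [kmeans_partition()].
#'
#' @param matrix numeric samples x features matrix (>= 2 samples).
#' @param k_max largest k tested (default 6); must be below the sample
#'   count.
#' @param n_ref number of reference datasets (default 50).
#' @param seed RNG seed for the reference draws and restarts.
#' @param n_init K-means restarts per clustering.
#' @return list with `k_selected` and `gap_curve` (data.frame `k`, `gap`,
#'   `se`). Degenerate data with zero total dispersion selects k = 1.
#' @export
gap_statistic <- function(matrix, k_max = 6, n_ref = 50, seed = 1L,
                          n_init = 10) {
  x <- as.matrix(matrix)
  if (nrow(x) < 2L) stop("at least 2 samples required")
  if (k_max >= nrow(x)) stop("k_max must be below the sample count")
  if (sum(scale(x, scale = FALSE)^2) == 0)
    return(list(k_selected = 1L,
                gap_curve = data.frame(k = 1L, gap = 0, se = 0)))
  fun <- function(x, k) list(cluster = kmeans_partition(x, k, seed = NULL,
                                                        n_init = n_init)$assignments)
  cg <- with_seed(seed,
    cluster::clusGap(x, FUNcluster = fun, K.max = k_max, B = n_ref,
                     spaceH0 = "scaledPCA", verbose = FALSE))
  tab <- cg$Tab
  k_sel <- cluster::maxSE(tab[, "gap"], tab[, "SE.sim"],
                          method = "Tibs2001SEmax")
  list(k_selected = as.integer(k_sel),
       gap_curve = data.frame(k = seq_len(k_max), gap = tab[, "gap"],
                              se = tab[, "SE.sim"]))
}
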