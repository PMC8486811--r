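#' Pearson correlation matrix of per-run TU activities
#'
#' The sampling unit is one replicate simulation: each run contributes one
#' mean activity per TU, and correlations are computed across runs.  (The
#' published edge thresholds -- |r| > 0.15 at p < 1e-6 for about a thousand
#' runs, and r > 0.12 at p = 7e-4 for 800 runs -- are numerically consistent
#' with the Student t-test at n = number of runs, which motivates this
#' choice of unit.)  P-values come from the two-sided t-test
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}}.  Constant columns yield missing (NA)
#' correlations, never zeros.
#'
#' @param per_run_activities Numeric run x TU matrix
#'   (see [per_run_activity()]).
#' @return A list of class `correlation_matrix`: `r`, `p`, `n_samples`,
#'   `tu_indices`.
#' @export
correlation_matrix <- function(per_run_activities) {
  m <- as.matrix(per_run_activities)
  n <- nrow(m)
  if (n < 3) stop("need at least 3 runs to correlate activities")
  sds <- apply(m, 2, stats::sd)
  r <- suppressWarnings(stats::cor(m))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  p <- corr_pvalue(r, n)
  tu <- if (!is.null(colnames(m))) as.integer(colnames(m)) else seq_len(ncol(m))
  structure(list(r = r, p = p, n_samples = n, tu_indices = tu),
            class = "correlation_matrix")
}

#' Two-sided p-value of a Pearson correlation under the Student t-test
#' @param r Correlation value(s).
#' @param n Number of samples.
#' @export
corr_pvalue <- function(r, n) {
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  if (is.matrix(r)) diag(p) <- NA_real_
  p
}

#' Threshold a correlation matrix into a signed regulatory network
#'
#' Edges join TU pairs with `|r| > r_min` and `p < p_max` (strict
#' inequalities); missing correlations never produce edges.  The toy-model
#' rule is (0.15, 1e-6, both signs); whole-chromosome comparisons use
#' (0.12, positive-only).
#'
#' @param corr A [correlation_matrix()].
#' @param r_min Absolute correlation threshold.
#' @param p_max Significance threshold.
#' @param sign_filter `"both"` or `"positive"`.
#' @return A list of class `regulatory_network`: `graph` (igraph), `edges`
#'   data.frame (i, j, r, p, sign), `nodes`, and the thresholds used.
#' @export
build_network <- function(corr, r_min = 0.15, p_max = 1e-6,
                          sign_filter = c("both", "positive")) {
  sign_filter <- match.arg(sign_filter)
  r <- corr$r; p <- corr$p
  nn <- length(corr$tu_indices)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  keep <- !is.na(r[ut]) & abs(r[ut]) > r_min & p[ut] < p_max
  if (sign_filter == "positive") keep <- keep & r[ut] > 0
  e <- data.frame(i = corr$tu_indices[ut[keep, 1]],
                  j = corr$tu_indices[ut[keep, 2]],
                  r = r[ut][keep], p = p[ut][keep])
  e$sign <- ifelse(e$r > 0, "positive", "negative")
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e$i), to = as.character(e$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(corr$tu_indices)))
  igraph::E(g)$r <- e$r
  igraph::E(g)$sign <- e$sign
  structure(list(graph = g, edges = e, nodes = corr$tu_indices,
                 r_min = r_min, p_max = p_max, sign_filter = sign_filter),
            class = "regulatory_network")
}

#' Fraction of nodes in the largest connected component
#'
#' A value near 1 means the network percolates: (almost) any TU is reachable
#' from any other.
#' @param network A [build_network()] result.
#' @return Fraction in [1/N, 1].
#' @export
largest_component_fraction <- function(network) {
  comp <- igraph::components(network$graph)
  max(comp$csize) / igraph::vcount(network$graph)
}

#' Small-world, degree and modularity statistics
#'
#' Computes the global clustering coefficient C and mean shortest path L on
#' the largest connected component, and compares them with
#' degree-preserving edge rewirings to form the small-world coefficient
#' \eqn{s = (C/C_{rand}) / (L/L_{rand})}.  Also fits an exponential decay
#' rate to the degree survival function by maximum likelihood on degrees
#' >= 1, reports the Spearman correlation between node degree and TU
#' activity, and the modularity of the fast-greedy community partition.
#'
#' @param network A [build_network()] result with at least one edge.
#' @param activities Optional named per-TU activity vector (names = TU
#'   indices) for the degree-activity correlation.
#' @param n_null Number of degree-preserving randomisations.
#' @param seed Seed for the randomisations.
#' @return A list of metrics; degenerate networks yield NA entries.
#' @export
small_world_and_degree_stats <- function(network, activities = NULL,
                                         n_null = 20, seed = 1L) {
  g <- network$graph
  if (igraph::ecount(g) == 0) stop("network has no edges")
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  C <- igraph::transitivity(giant, type = "global")
  L <- igraph::mean_distance(giant)
  nulls <- withr::with_seed(seed, {
    lapply(seq_len(n_null), function(k) {
      gr <- igraph::rewire(giant, igraph::keeping_degseq(
        niter = max(100, igraph::ecount(giant) * 10)))
      compr <- igraph::components(gr)
      grg <- igraph::induced_subgraph(
        gr, which(compr$membership == which.max(compr$csize)))
      c(C = igraph::transitivity(gr, type = "global"),
        L = igraph::mean_distance(grg))
    })
  })
  Cr <- mean(vapply(nulls, `[[`, numeric(1), "C"), na.rm = TRUE)
  Lr <- mean(vapply(nulls, `[[`, numeric(1), "L"), na.rm = TRUE)
  s <- if (isTRUE(Cr > 0) && isTRUE(L > 0)) (C / Cr) / (L / Lr) else NA_real_
  deg <- igraph::degree(g)
  dtail <- deg[deg >= 1]
  decay_rate <- NA_real_; decay_gof <- NA_real_
  if (length(dtail) >= 3 && mean(dtail - 1) > 0) {
    decay_rate <- 1 / mean(dtail - 1)      # MLE exponential on excess degree
    decay_gof <- suppressWarnings(
      stats::ks.test(dtail - 1, "pexp", decay_rate)$statistic)
  }
  rho <- NA_real_; rho_p <- NA_real_
  if (!is.null(activities)) {
    a <- activities[igraph::V(g)$name]
    if (sum(!is.na(a)) >= 3 && stats::sd(a, na.rm = TRUE) > 0 &&
        stats::sd(deg) > 0) {
      ct <- suppressWarnings(stats::cor.test(deg, as.numeric(a),
                                             method = "spearman"))
      rho <- unname(ct$estimate); rho_p <- ct$p.value
    }
  }
  mod <- tryCatch(
    igraph::modularity(igraph::cluster_fast_greedy(
      igraph::simplify(giant))),
    error = function(e) NA_real_)
  list(clustering = C, path_length = L, clustering_rand = Cr,
       path_length_rand = Lr, small_world = s,
       degree_decay_rate = decay_rate, degree_decay_ks = unname(decay_gof),
       degree_activity_spearman = rho, degree_activity_p = rho_p,
       modularity = mod)
}

#' Elementwise change in Pearson correlation between two conditions
#'
#' Returns `corr_b$r - corr_a$r` with missing values propagated.  Both
#' matrices must cover the same TU set (a knocked-out TU is retained with
#' missing correlations).
#'
#' @param corr_a,corr_b Two [correlation_matrix()] objects.
#' @return A TU x TU numeric matrix of correlation changes.
#' @export
network_difference <- function(corr_a, corr_b) {
  if (!identical(corr_a$tu_indices, corr_b$tu_indices))
    stop("correlation matrices cover different TU sets")
  d <- corr_b$r - corr_a$r
  dimnames(d) <- list(corr_a$tu_indices, corr_a$tu_indices)
  d
}
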