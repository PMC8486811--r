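#' Activity record: binary transcription time series
#'
#' @param samples Binary matrix, one row per sample time, one column per
#'   recorded bead (TUs by default).
#' @param tu_indices Bead indices of the recorded columns.
#' @param sample_interval Time between samples (tau_B).
#' @param run_id,seed Provenance of the run.
#' @return A list of class `activity_record`.
#' @export
activity_record <- function(samples, tu_indices, sample_interval = 100,
                            run_id = "run1", seed = NA_integer_) {
  samples <- as.matrix(samples)
  stopifnot(all(samples %in% c(0L, 1L)), ncol(samples) == length(tu_indices))
  structure(list(samples = samples, tu_indices = as.integer(tu_indices),
                 sample_interval = sample_interval, run_id = run_id,
                 seed = seed),
            class = "activity_record")
}

#' Transcription read-out for one configuration
#'
#' A recorded bead is scored as transcribed iff at least one ACTIVE TF centre
#' lies within `rc_transcribe` of the bead centre; inactive TFs never count.
#'
#' @param state A [system_state()].
#' @param fibre A `ChromatinFibre`.
#' @param rc_transcribe Read-out range (default 1.8 sigma).
#' @param beads Bead indices to score (default the fibre's TUs).
#' @return Named binary integer vector over `beads`.
#' @export
detect_transcription <- function(state, fibre, rc_transcribe = 1.8,
                                 beads = tu_indices(fibre)) {
  M <- fibre$n_beads
  act <- which(state$tf_active)
  out <- integer(length(beads))
  if (length(act) > 0 && length(beads) > 0) {
    tfpos <- state$positions[M + act, , drop = FALSE]
    for (k in seq_along(beads)) {
      d2 <- colSums((t(tfpos) - state$positions[beads[k], ])^2)
      out[k] <- as.integer(any(d2 <= rc_transcribe^2))
    }
  }
  names(out) <- beads
  out
}

#' Per-run mean activities
#'
#' One row per run, one column per TU: the fraction of samples in which the
#' TU was transcribed.  This run x TU matrix is the sampling unit for
#' network inference.
#'
#' @param records A list of `activity_record`s or a `sim_ensemble`.
#' @return Numeric matrix (runs x TUs) with TU indices as column names.
#' @export
per_run_activity <- function(records) {
  if (inherits(records, "sim_ensemble")) records <- records$records
  if (inherits(records, "activity_record")) records <- list(records)
  stopifnot(length(records) >= 1)
  tu <- records[[1]]$tu_indices
  for (r in records)
    if (!identical(r$tu_indices, tu)) stop("records have mismatched TU sets")
  m <- do.call(rbind, lapply(records, function(r) colMeans(r$samples)))
  colnames(m) <- tu
  rownames(m) <- vapply(records, function(r) r$run_id, character(1))
  m
}

#' Mean activity per TU with high/medium/low class labels
#'
#' Activity is the mean over all samples and runs; labels follow the
#' conventional thresholds: high > 0.7, medium 0.2--0.7, low < 0.2.
#'
#' @param records A list of `activity_record`s or a `sim_ensemble`.
#' @return A data.frame (tu_index, activity, class) with the run x TU matrix
#'   attached as attribute `"per_run"`.
#' @export
activity_profile <- function(records) {
  m <- per_run_activity(records)
  act <- colMeans(m)
  cls <- cut(act, breaks = c(-Inf, 0.2, 0.7, Inf),
             labels = c("low", "medium", "high"), right = FALSE)
  out <- data.frame(tu_index = as.integer(colnames(m)), activity = act,
                    class = as.character(cls), row.names = NULL)
  attr(out, "per_run") <- m
  out
}

#' Burst statistics and kymograph of a single run
#'
#' A burst is a maximal run of consecutive transcribed samples; a gap is a
#' maximal silent run.  Durations are in tau_B (multiples of the sample
#' interval).  The kymograph is the sample x TU matrix with columns ordered
#' by TU position along the chain.
#'
#' @param record An `activity_record`.
#' @return A list of class `burst_stats`: per-TU lists `bursts` and `gaps`
#'   (durations), a summary data.frame, and the `kymograph` matrix.
#' @export
burst_statistics <- function(record) {
  s <- record$samples
  ord <- order(record$tu_indices)
  kym <- s[, ord, drop = FALSE]
  colnames(kym) <- record$tu_indices[ord]
  dt <- record$sample_interval
  bursts <- gaps <- vector("list", ncol(s))
  names(bursts) <- names(gaps) <- record$tu_indices
  for (k in seq_len(ncol(s))) {
    r <- rle(s[, k])
    bursts[[k]] <- r$lengths[r$values == 1] * dt
    gaps[[k]] <- r$lengths[r$values == 0] * dt
  }
  summary <- data.frame(
    tu_index = record$tu_indices,
    n_bursts = vapply(bursts, length, integer(1)),
    mean_burst = vapply(bursts, function(b) if (length(b)) mean(b) else NA_real_,
                        numeric(1)),
    mean_gap = vapply(gaps, function(g) if (length(g)) mean(g) else NA_real_,
                      numeric(1)),
    row.names = NULL)
  structure(list(bursts = bursts, gaps = gaps, summary = summary,
                 kymograph = kym, sample_interval = dt),
            class = "burst_stats")
}

#' Cluster sizes of active TFs
#'
#' Single-linkage connected components among active TFs with pairwise centre
#' distance at most `cluster_cutoff` (descriptive statistic only; the cutoff
#' plays no role in the dynamics).
#'
#' @param state A [system_state()].
#' @param fibre A `ChromatinFibre` (to locate the TF block of positions).
#' @param cluster_cutoff Linkage distance (default 2 sigma).
#' @return Integer vector of component sizes (one entry per cluster);
#'   empty if no TF is active.
#' @export
tf_cluster_sizes <- function(state, fibre, cluster_cutoff = 2) {
  act <- which(state$tf_active)
  n <- length(act)
  if (n == 0) return(integer(0))
  if (n == 1) return(1L)
  pos <- state$positions[fibre$n_beads + act, , drop = FALSE]
  adj <- as.matrix(stats::dist(pos)) <= cluster_cutoff
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  as.integer(igraph::components(g)$csize)
}
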