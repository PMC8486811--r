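#' Differential activity between two conditions
#'
#' Per-TU two-sample two-sided Student t-test (equal variances) on per-run
#' mean activities.  No multiplicity correction is applied; significance
#' thresholds are report-time parameters.
#'
#' @param runs_a,runs_b Run x TU activity matrices (matched TU sets), e.g.
#'   from [per_run_activity()]; condition A is the reference (wild type).
#' @return A list of class `perturbation_result`: `table` (per-TU data.frame
#'   with means, effect = B - A, t, p) and the `transcriptional_difference`
#'   scalar over all TUs.
#' @export
differential_activity <- function(runs_a, runs_b) {
  runs_a <- as.matrix(runs_a); runs_b <- as.matrix(runs_b)
  if (!identical(colnames(runs_a), colnames(runs_b)) ||
      ncol(runs_a) != ncol(runs_b))
    stop("conditions cover different TU sets")
  if (nrow(runs_a) < 3 || nrow(runs_b) < 3)
    stop("need at least 3 runs per condition")
  na <- nrow(runs_a); nb <- nrow(runs_b)
  ma <- colMeans(runs_a); mb <- colMeans(runs_b)
  va <- apply(runs_a, 2, stats::var); vb <- apply(runs_b, 2, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- ifelse(se > 0, (mb - ma) / se, NA_real_)
  p <- 2 * stats::pt(-abs(t), df = na + nb - 2)
  tu <- if (!is.null(colnames(runs_a))) as.integer(colnames(runs_a))
        else seq_len(ncol(runs_a))
  tab <- data.frame(tu_index = tu, activity_a = ma, activity_b = mb,
                    effect = mb - ma, t = t, p = p, row.names = NULL)
  structure(list(table = tab,
                 transcriptional_difference =
                   transcriptional_difference(ma, mb),
                 n_a = na, n_b = nb),
            class = "perturbation_result")
}

#' Transcriptional difference between two activity profiles
#'
#' Euclidean distance between mean-activity vectors over TUs.  When
#' `exclude_index` names the mutated TU it is excluded, isolating
#' trans-effects of the perturbation.
#'
#' @param mean_a,mean_b Equal-length per-TU mean activity vectors.
#' @param exclude_index Optional TU index (matched against names, else
#'   position) to drop before computing the distance.
#' @return Non-negative scalar.
#' @export
transcriptional_difference <- function(mean_a, mean_b, exclude_index = NULL) {
  if (length(mean_a) != length(mean_b))
    stop("activity vectors have different lengths")
  if (!is.null(exclude_index)) {
    k <- if (!is.null(names(mean_a)))
      which(names(mean_a) == as.character(exclude_index))
    else as.integer(exclude_index)
    if (length(k)) { mean_a <- mean_a[-k]; mean_b <- mean_b[-k] }
  }
  sqrt(sum((mean_b - mean_a)^2))
}

#' Systematic knockout sweep over every TU
#'
#' Knocks each TU out in turn, simulates the mutant with the same seeds as
#' the wild-type ensemble (variance reduction), and tabulates the
#' transcriptional difference and the number of significantly changed TUs.
#'
#' @param fibre Wild-type `ChromatinFibre`.
#' @param config A [sim_config()].
#' @param wt_runs Wild-type run x TU activity matrix; simulated if NULL.
#' @param n_runs,base_seed Ensemble settings (must match `wt_runs` if given).
#' @param p_threshold Report-time significance threshold.
#' @param tus TUs to sweep (default all).
#' @return A data.frame (tu_index, wt_activity, transcriptional_difference,
#'   n_significant) with one row per swept TU.
#' @export
knockout_sweep <- function(fibre, config, wt_runs = NULL, n_runs = 10,
                           base_seed = 1L, p_threshold = 0.05,
                           tus = tu_indices(fibre)) {
  if (is.null(wt_runs))
    wt_runs <- per_run_activity(simulate_ensemble(fibre, config, n_runs,
                                                  base_seed))
  out <- lapply(tus, function(tu) {
    mut <- knockout_tu(fibre, tu)
    mut_runs <- per_run_activity(simulate_ensemble(mut, config,
                                                   nrow(wt_runs), base_seed))
    da <- differential_activity(wt_runs, mut_runs)
    data.frame(
      tu_index = tu,
      wt_activity = mean(wt_runs[, as.character(tu)]),
      transcriptional_difference = transcriptional_difference(
        colMeans(wt_runs), colMeans(mut_runs), exclude_index = tu),
      n_significant = sum(da$table$p < p_threshold & da$table$tu_index != tu,
                          na.rm = TRUE))
  })
  do.call(rbind, out)
}

#' Manhattan and QQ series for a perturbation scan
#'
#' Manhattan: genomic position (Mbp) versus -log10(p) per TU.  QQ: sorted
#' observed -log10(p) versus expected -log10 of uniform order-statistic
#' quantiles, the null in which activity changes are pure random variation.
#'
#' @param result A [differential_activity()] result.
#' @param positions Data.frame with columns `tu_index` and `pos` (bp), or a
#'   fibre with a genomic map (bin midpoints are used).
#' @return A list with data.frames `manhattan` (tu_index, pos_mbp, neglog10p)
#'   and `qq` (expected, observed).
#' @export
manhattan_qq <- function(result, positions) {
  tab <- result$table
  if (inherits(positions, "ChromatinFibre")) {
    gm <- positions$genomic_map
    if (is.null(gm)) stop("fibre has no genomic map")
    positions <- data.frame(tu_index = seq_len(positions$n_beads),
                            pos = (gm$start + gm$end) / 2)
  }
  m <- match(tab$tu_index, positions$tu_index)
  if (anyNA(m)) stop("missing genomic positions for some TUs")
  ok <- !is.na(tab$p)
  manhattan <- data.frame(tu_index = tab$tu_index,
                          pos_mbp = positions$pos[m] / 1e6,
                          neglog10p = -log10(tab$p))
  pobs <- sort(tab$p[ok])
  k <- length(pobs)
  qq <- data.frame(expected = -log10((seq_len(k) - 0.5) / k),
                   observed = -log10(pobs))
  qq <- qq[order(qq$expected), ]
  list(manhattan = manhattan, qq = qq)
}
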