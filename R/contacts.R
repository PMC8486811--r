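#' Hi-C-like contact map from simulation trajectories
#'
#' Two chromatin beads are in contact when their centres are within
#' `contact_cutoff` (default 3.5 sigma); contacts are accumulated over all
#' frames and runs into square genomic bins of `bin_width` bp (default
#' 30 kbp, i.e. 10 beads).  Optionally the map is restricted to anchor bins
#' containing at least one TU, mimicking promoter-capture Hi-C.
#'
#' @param trajectories A single beads x 3 x frames array, or a list of such
#'   arrays (one per run), as returned in `sim_result$trajectory`.  Only the
#'   first `n_beads` rows are used (TF coordinates are ignored).
#' @param fibre The simulated `ChromatinFibre`.
#' @param contact_cutoff Contact distance (sigma).
#' @param bin_width Genomic bin width in bp.
#' @param bead_bp Genomic span of one bead in bp (default 3000).
#' @param tu_filter Restrict to bins containing a TU bead.
#' @return A list of class `contact_map`: `counts` (symmetric matrix),
#'   `bin_width`, `bead_bp`, `tu_bins` (logical mask), `n_frames`.
#' @export
contact_map_from_trajectories <- function(trajectories, fibre,
                                          contact_cutoff = 3.5,
                                          bin_width = 30000, bead_bp = 3000,
                                          tu_filter = FALSE) {
  if (!is.list(trajectories)) trajectories <- list(trajectories)
  trajectories <- Filter(Negate(is.null), trajectories)
  if (length(trajectories) == 0) stop("no trajectory frames supplied")
  beads_per_bin <- as.integer(round(bin_width / bead_bp))
  M <- fibre$n_beads
  n_bins <- as.integer(ceiling(M / beads_per_bin))
  counts <- matrix(0, n_bins, n_bins)
  n_frames <- 0L
  for (tr in trajectories) {
    stopifnot(length(dim(tr)) == 3, dim(tr)[2] == 3)
    for (f in seq_len(dim(tr)[3])) {
      .contact_map_frame_cpp(tr[, , f], M, contact_cutoff, beads_per_bin,
                             counts)
      n_frames <- n_frames + 1L
    }
  }
  tu_bins <- rep(FALSE, n_bins)
  tu_bins[unique((tu_indices(fibre, include_knockouts = FALSE) - 1L) %/%
                   beads_per_bin + 1L)] <- TRUE
  if (tu_filter) {
    counts[!tu_bins, ] <- NA_real_
    counts[, !tu_bins] <- NA_real_
  }
  structure(list(counts = counts, bin_width = bin_width, bead_bp = bead_bp,
                 tu_bins = tu_bins, n_frames = n_frames),
            class = "contact_map")
}

#' Construct a contact map directly from a counts matrix
#' @param counts Symmetric non-negative matrix.
#' @param bin_width Genomic bin width in bp.
#' @return A `contact_map`.
#' @export
contact_map <- function(counts, bin_width = 30000) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0, na.rm = TRUE))
  structure(list(counts = counts, bin_width = bin_width, bead_bp = NA,
                 tu_bins = rep(TRUE, nrow(counts)), n_frames = NA),
            class = "contact_map")
}

#' Contact-probability decay P(s) and its power-law exponent
#'
#' Averages map counts at fixed bin separation s to form P(s), then fits a
#' least-squares slope of log P(s) versus log s over genomic separations in
#' `[s_min, s_max]` (default 30 kbp to 1.5 Mbp).  A fractal globule gives an
#' exponent near -1.
#'
#' @param map A `contact_map`.
#' @param s_min,s_max Fit range in bp.
#' @return A list: `exponent`, and the `decay` data.frame (s_bp, p).
#' @export
contact_decay_exponent <- function(map, s_min = 30000, s_max = 1.5e6) {
  counts <- map$counts
  n <- nrow(counts)
  seps <- seq_len(n - 1)
  p <- vapply(seps, function(s) {
    v <- counts[cbind(seq_len(n - s), seq_len(n - s) + s)]
    mean(v, na.rm = TRUE)
  }, numeric(1))
  decay <- data.frame(s_bp = seps * map$bin_width, p = p)
  fitrows <- decay$s_bp >= s_min & decay$s_bp <= s_max & decay$p > 0 &
    is.finite(decay$p)
  if (sum(fitrows) < 3) stop("insufficient separation range for the fit")
  fit <- stats::lm(log(p) ~ log(s_bp), data = decay[fitrows, ])
  list(exponent = unname(stats::coef(fit)[2]), decay = decay)
}
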