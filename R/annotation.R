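#' Tile a chromosome into 3-kbp bead bins
#'
#' Bins are 0-based half-open internally (BED convention); returned as a
#' GRanges (1-based closed, as usual for GenomicRanges) tiling the chromosome
#' contiguously, the last bin possibly short.
#'
#' @param chrom Chromosome name.
#' @param length Chromosome length in bp.
#' @param bin_width Bin width in bp (default 3000, one bead).
#' @return A GRanges with one range per bead, metadata column `bead_index`.
#' @export
bead_bins <- function(chrom, length, bin_width = 3000) {
  starts <- seq(0, length - 1, by = bin_width)
  ends <- pmin(starts + bin_width, length)
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = starts + 1, end = ends))
  gr$bead_index <- seq_along(gr)
  gr
}

#' Number of beads for a chromosome length
#' @inheritParams bead_bins
#' @export
n_beads_for_chromosome <- function(length, bin_width = 3000) {
  as.integer(ceiling(length / bin_width))
}

#' Classify beads from DHS and H3K27ac tracks (the "DHS model")
#'
#' A bead whose 3-kbp bin overlaps a DNase-hypersensitive site (any overlap
#' of at least 1 bp) is a TU; otherwise, if it overlaps an H3K27ac peak it is
#' euchromatin; all remaining beads are non-binding heterochromatin.
#'
#' @param dhs_track,h3k27ac_track GRanges of peak intervals (or data.frames
#'   with chrom/start/end in BED convention).
#' @param chrom Chromosome name.
#' @param length Chromosome length in bp.
#' @param bin_width Bin width (default 3000).
#' @return Character vector of per-bead classes.
#' @export
classify_beads_dhs <- function(dhs_track, h3k27ac_track, chrom, length,
                               bin_width = 3000) {
  bins <- bead_bins(chrom, length, bin_width)
  dhs <- as_granges_track(dhs_track)
  ac <- as_granges_track(h3k27ac_track)
  cls <- rep("heterochromatin", length(bins))
  if (length(ac) > 0)
    cls[unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(bins, ac)))] <- "euchromatin"
  if (length(dhs) > 0)
    cls[unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(bins, dhs)))] <- "TU"
  cls
}

#' Classify beads from a chromatin-state (chromHMM-like) segmentation
#'
#' Each bin takes the state with the largest overlap (ties broken in favour
#' of the interval with the lower start coordinate), then the state label is
#' mapped to a bead class through the user-supplied `state_map`.
#'
#' @param chromhmm_track GRanges with a `state` metadata column (or a
#'   data.frame/BED4 with the state in the 4th column).
#' @param state_map Named character vector mapping state labels to
#'   `"TU"`, `"euchromatin"` or `"heterochromatin"`.
#' @param chrom,length,bin_width As in [classify_beads_dhs()].
#' @param default Class for bins with no overlapping state.
#' @return Character vector of per-bead classes.
#' @export
classify_beads_hmm <- function(chromhmm_track, state_map, chrom, length,
                               bin_width = 3000,
                               default = "heterochromatin") {
  gr <- as_granges_track(chromhmm_track, keep_col = "state")
  if (is.null(gr$state)) stop("chromHMM track must carry a 'state' column")
  stopifnot(all(state_map %in% c("TU", "euchromatin", "heterochromatin")))
  unmapped <- setdiff(unique(gr$state), names(state_map))
  if (length(unmapped) > 0)
    stop("no class mapping for state(s): ", paste(unmapped, collapse = ", "))
  bins <- bead_bins(chrom, length, bin_width)
  hits <- GenomicRanges::findOverlaps(bins, gr)
  cls <- rep(default, length(bins))
  if (length(hits) > 0) {
    ov <- GenomicRanges::pintersect(bins[S4Vectors::queryHits(hits)],
                                    gr[S4Vectors::subjectHits(hits)])
    d <- data.frame(bin = S4Vectors::queryHits(hits),
                    width = BiocGenerics::width(ov),
                    start = BiocGenerics::start(gr)[S4Vectors::subjectHits(hits)],
                    state = gr$state[S4Vectors::subjectHits(hits)])
    # majority overlap; tie -> lower start coordinate
    d <- d[order(d$bin, -d$width, d$start), ]
    d <- d[!duplicated(d$bin), ]
    cls[d$bin] <- unname(state_map[d$state])
  }
  cls
}

as_granges_track <- function(x, keep_col = NULL) {
  if (methods::is(x, "GRanges")) return(x)
  x <- as.data.frame(x)
  names(x)[1:3] <- c("chrom", "start", "end")
  gr <- GenomicRanges::GRanges(x$chrom,
                               IRanges::IRanges(start = x$start + 1, end = x$end))
  if (!is.null(keep_col) && ncol(x) >= 4) gr$state <- x[[4]]
  gr
}

#' Build a fibre from per-bead classes and a genomic map
#'
#' @param classes Character vector of bead classes.
#' @param chrom Chromosome name.
#' @param bin_width Bin width in bp.
#' @return A `ChromatinFibre` with genomic map attached.
#' @export
fibre_from_classes <- function(classes, chrom, bin_width = 3000) {
  M <- length(classes)
  gm <- data.frame(chrom = chrom, start = (seq_len(M) - 1) * bin_width,
                   end = seq_len(M) * bin_width)
  chromatin_fibre(classes, genomic_map = gm)
}

#' Semi-axes of a chromosome-territory ellipsoid
#'
#' Sizes the confining ellipsoid so that the bead volume fraction equals
#' `volume_fraction` (~14% in vivo): \eqn{(4/3)\pi abc = M (\pi\sigma^3/6) /
#' \phi}, with the given axis ratios (default prolate 2:1:1).
#'
#' @param n_beads Number of chromatin beads.
#' @param volume_fraction Target bead volume fraction (0, 0.5).
#' @param axis_ratios Length-3 ratios a:b:c.
#' @return Numeric length-3 semi-axes (sigma units), decreasing.
#' @export
ellipsoid_for_territory <- function(n_beads, volume_fraction = 0.14,
                                    axis_ratios = c(2, 1, 1)) {
  stopifnot(volume_fraction > 0, volume_fraction < 0.5,
            length(axis_ratios) == 3, all(axis_ratios > 0))
  v_beads <- n_beads * pi / 6          # sigma = 1
  v_ell <- v_beads / volume_fraction
  u <- (3 * v_ell / (4 * pi * prod(axis_ratios)))^(1 / 3)
  sort(axis_ratios * u, decreasing = TRUE)
}

#' Rank/quintile comparison of simulated activity with an experimental signal
#'
#' Both vectors are ranked (mid-ranks for ties), binned into quintiles, and
#' cross-tabulated into a 5 x 5 heat-map count matrix; the Spearman
#' correlation is computed on the unbinned ranks.  In `"tu_only"` mode only
#' TU beads enter; in `"patch"` mode both vectors are first averaged within
#' contiguous patches of beads that are all TUs or all euchromatin.
#'
#' @param sim_activity,expt_signal Aligned per-bead numeric vectors.
#' @param mode `"all"`, `"tu_only"` or `"patch"`.
#' @param bead_classes Per-bead classes (required for tu_only/patch).
#' @return A list: `quintile_counts` (5 x 5), `spearman`, `p`, `n`.
#' @export
rank_quintile_compare <- function(sim_activity, expt_signal,
                                  mode = c("all", "tu_only", "patch"),
                                  bead_classes = NULL) {
  mode <- match.arg(mode)
  if (length(sim_activity) != length(expt_signal))
    stop("vectors have different lengths")
  a <- sim_activity; b <- expt_signal
  if (mode == "tu_only") {
    stopifnot(!is.null(bead_classes))
    keep <- bead_classes == "TU"
    a <- a[keep]; b <- b[keep]
  } else if (mode == "patch") {
    stopifnot(!is.null(bead_classes))
    r <- rle(bead_classes)
    patch_id <- rep(seq_along(r$lengths), r$lengths)
    keep <- bead_classes %in% c("TU", "euchromatin")
    a <- tapply(a[keep], patch_id[keep], mean)
    b <- tapply(b[keep], patch_id[keep], mean)
  }
  n <- length(a)
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  qa <- pmin(5L, pmax(1L, ceiling(5 * ra / n)))
  qb <- pmin(5L, pmax(1L, ceiling(5 * rb / n)))
  counts <- table(factor(qa, levels = 1:5), factor(qb, levels = 1:5))
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
  list(quintile_counts = unclass(counts), spearman = unname(ct$estimate),
       p = ct$p.value, n = n)
}

#' Spearman correlation of activity with distance to the nearest TU
#'
#' For each TU, the 1D distance (in beads) to the nearest other TU is
#' correlated with its activity; in this model the correlation is strongly
#' negative because closely spaced TUs share TF clusters.
#'
#' @param activity Per-TU activity vector (same order as `tu_positions`).
#' @param tu_positions TU bead indices along the chain.
#' @return A list: `spearman`, `p`, `distances`; degenerate inputs
#'   (constant distance or activity) yield NA with a flag.
#' @export
nearest_tu_distance_correlation <- function(activity, tu_positions) {
  if (length(tu_positions) < 3) stop("need at least 3 TUs")
  if (length(activity) != length(tu_positions))
    stop("activity and positions have different lengths")
  d <- vapply(seq_along(tu_positions), function(k)
    min(abs(tu_positions[-k] - tu_positions[k])), numeric(1))
  if (stats::sd(d) == 0 || stats::sd(activity) == 0)
    return(list(spearman = NA_real_, p = NA_real_, distances = d,
                degenerate = TRUE))
  ct <- suppressWarnings(stats::cor.test(activity, d, method = "spearman"))
  list(spearman = unname(ct$estimate), p = ct$p.value, distances = d,
       degenerate = FALSE)
}
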