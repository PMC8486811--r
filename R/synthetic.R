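#' Synthetic annotation fixture for whole-chromosome mode
#'
#' Generates the input tracks the whole-chromosome workflow consumes --
#' clustered DHS and H3K27ac interval tracks, a positive signal track
#' (GRO-seq-like), and a super-enhancer track -- for a fictitious chromosome,
#' so every analytic stage can be exercised without external data.  Open
#' (binding) regions are laid down as a two-state Markov chain with mean
#' patch length `patchiness` bins; inside open patches bins become TUs at
#' the rate needed to meet `tu_density` overall.  DHS intervals are placed
#' inside TU bins only and H3K27ac intervals inside euchromatin (and some TU)
#' bins, so classifying the generated tracks recovers the generating classes
#' exactly.  When an `activity` vector is supplied the signal track is drawn
#' from a Gaussian copula calibrated so its Spearman correlation with
#' activity equals `target_rank_corr`.
#'
#' @param chrom_length Chromosome length in bp.
#' @param tu_density Overall fraction of TU bins (default 0.039, the toy
#'   chain's 39/1000).
#' @param patchiness Mean open-patch length in bins.
#' @param open_fraction Fraction of the chromosome in open patches.
#' @param target_rank_corr Spearman correlation between signal and
#'   `activity`.
#' @param activity Optional per-bead activity vector to correlate against.
#' @param chrom Chromosome name used in all tracks.
#' @param bin_width Bin width in bp.
#' @param seed Integer seed.
#' @return A list: `classes`, `dhs`, `h3k27ac` (data.frames, BED convention),
#'   `signal` (bedGraph data.frame), `super_enhancers`, `chrom`, `length`.
#' @export
synthetic_annotation_fixture <- function(chrom_length = 3e6,
                                         tu_density = 0.039,
                                         patchiness = 10,
                                         open_fraction = 0.4,
                                         target_rank_corr = 0.4,
                                         activity = NULL,
                                         chrom = "chrS",
                                         bin_width = 3000,
                                         seed = 1L) {
  stopifnot(tu_density > 0, tu_density < 1, patchiness >= 1,
            open_fraction > tu_density, open_fraction < 1,
            abs(target_rank_corr) <= 1)
  n <- as.integer(ceiling(chrom_length / bin_width))
  withr::with_seed(seed, {
    # two-state Markov chain over bins: closed <-> open
    p_oc <- 1 / patchiness                          # leave an open patch
    p_co <- p_oc * open_fraction / (1 - open_fraction)
    open <- logical(n)
    open[1] <- stats::runif(1) < open_fraction
    u <- stats::runif(n)
    for (i in 2:n)
      open[i] <- if (open[i - 1]) u[i] >= p_oc else u[i] < p_co
    p_tu <- min(1, tu_density / max(mean(open), 1e-9))
    classes <- rep("heterochromatin", n)
    classes[open] <- ifelse(stats::runif(sum(open)) < p_tu, "TU",
                            "euchromatin")
    bin_start <- (seq_len(n) - 1) * bin_width
    bin_end <- pmin(seq_len(n) * bin_width, chrom_length)
    # DHS: one sub-bin interval per TU bin
    tu <- which(classes == "TU")
    dhs <- data.frame(chrom = chrom,
                      start = bin_start[tu] + 1000,
                      end = pmin(bin_start[tu] + 1600, bin_end[tu]))
    # H3K27ac: euchromatin bins, plus a third of TU bins (DHS has precedence)
    eu <- which(classes == "euchromatin")
    acc <- sort(c(eu, sample(tu, size = floor(length(tu) / 3))))
    ac <- data.frame(chrom = chrom,
                     start = bin_start[acc] + 200,
                     end = pmin(bin_start[acc] + 2500, bin_end[acc]))
    # signal track correlated with activity (or with openness by default)
    base <- if (is.null(activity)) as.numeric(open) + stats::runif(n, 0, 0.1)
            else activity
    stopifnot(length(base) == n)
    rho_n <- 2 * sin(pi * target_rank_corr / 6)     # copula calibration
    z_base <- stats::qnorm((rank(base, ties.method = "average") - 0.5) / n)
    z <- rho_n * z_base + sqrt(1 - rho_n^2) * stats::rnorm(n)
    signal <- data.frame(chrom = chrom, start = bin_start, end = bin_end,
                         score = round(exp(z), 6))
    # super-enhancers: merged runs of top-decile signal within open patches
    hot <- open & signal$score >= stats::quantile(signal$score, 0.9)
    r <- rle(hot)
    se_runs <- which(r$values & r$lengths >= 2)
    ends_idx <- cumsum(r$lengths)
    se <- if (length(se_runs) > 0) {
      data.frame(chrom = chrom,
                 start = bin_start[ends_idx[se_runs] - r$lengths[se_runs] + 1],
                 end = bin_end[ends_idx[se_runs]])
    } else data.frame(chrom = character(), start = numeric(), end = numeric())
    list(classes = classes, dhs = dhs, h3k27ac = ac, signal = signal,
         super_enhancers = se, chrom = chrom, length = chrom_length,
         bin_width = bin_width)
  })
}

#' Write fixture tracks as BED/bedGraph files
#'
#' @param fixture A [synthetic_annotation_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths (dhs, h3k27ac, signal,
#'   super_enhancers).
#' @export
write_fixture_tracks <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(dhs = file.path(dir, "dhs.bed"),
             h3k27ac = file.path(dir, "h3k27ac.bed"),
             signal = file.path(dir, "signal.bedGraph"),
             super_enhancers = file.path(dir, "super_enhancers.bed"))
  write_bed3 <- function(df, path) {
    df <- data.frame(chrom = df$chrom, start = as.integer(df$start),
                     end = as.integer(df$end))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  write_bed3(fixture$dhs, paths["dhs"])
  write_bed3(fixture$h3k27ac, paths["h3k27ac"])
  sig <- fixture$signal
  sig$start <- as.integer(sig$start); sig$end <- as.integer(sig$end)
  utils::write.table(sig, paths["signal"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_bed3(fixture$super_enhancers, paths["super_enhancers"])
  paths
}

#' Read a BED3/BED4 track into BED-convention data.frame
#' @param path File path.
#' @return data.frame with chrom, start, end (0-based half-open) and
#'   optionally `state`.
#' @export
read_bed_track <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = BiocGenerics::start(gr) - 1,
                    end = BiocGenerics::end(gr))
  if (!is.null(gr$name)) out$state <- gr$name
  out
}

#' Read a bedGraph signal track
#' @param path File path.
#' @return data.frame with chrom, start, end, score.
#' @export
read_bedgraph_track <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1,
             end = BiocGenerics::end(gr), score = gr$score)
}

#' Average a signal track over bead bins
#' @param signal data.frame (chrom, start, end, score), BED convention.
#' @param chrom,length,bin_width Bead-bin layout.
#' @return Per-bead mean signal (0 where no coverage).
#' @export
signal_per_bead <- function(signal, chrom, length, bin_width = 3000) {
  bins <- bead_bins(chrom, length, bin_width)
  gr <- GenomicRanges::GRanges(signal$chrom,
                               IRanges::IRanges(signal$start + 1, signal$end),
                               score = signal$score)
  hits <- GenomicRanges::findOverlaps(bins, gr)
  out <- numeric(length(bins))
  if (length(hits) > 0) {
    ov <- GenomicRanges::pintersect(bins[S4Vectors::queryHits(hits)],
                                    gr[S4Vectors::subjectHits(hits)])
    w <- BiocGenerics::width(ov)
    sc <- gr$score[S4Vectors::subjectHits(hits)]
    num <- tapply(w * sc, S4Vectors::queryHits(hits), sum)
    den <- tapply(w, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(num))] <- num / den
  }
  out
}
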