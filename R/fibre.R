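#' Construct a chromatin fibre
#'
#' A `ChromatinFibre` is the 1D description of the simulated chain: per-bead
#' class (`"TU"`, `"euchromatin"`, `"heterochromatin"`), bond list (backbone
#' plus optional permanent loops), consecutive-triplet bending angles, and an
#' optional genomic map (one 3-kbp bin per bead).  Bead indices are 1-based.
#'
#' @param bead_class Character vector of per-bead classes.
#' @param loops Optional two-column matrix/data.frame of loop anchor pairs.
#' @param genomic_map Optional data.frame with columns chrom, start, end
#'   (0-based half-open bins, one row per bead, contiguous and sorted).
#' @param backbone Bond kind for backbone bonds: `"fene"` (default) or
#'   `"harmonic_backbone"` (used when permanent loops are present).
#' @return A `ChromatinFibre` object.
#' @export
chromatin_fibre <- function(bead_class, loops = NULL, genomic_map = NULL,
                            backbone = c("fene", "harmonic_backbone")) {
  backbone <- match.arg(backbone)
  M <- length(bead_class)
  stopifnot(M >= 2, all(bead_class %in% c("TU", "euchromatin", "heterochromatin")))
  bonds <- data.frame(i = seq_len(M - 1), j = seq_len(M - 1) + 1L,
                      kind = backbone, stringsAsFactors = FALSE)
  fibre <- structure(list(n_beads = M, bead_class = bead_class,
                          bonds = bonds,
                          angles = if (M >= 3)
                            data.frame(i = seq_len(M - 2),
                                       j = seq_len(M - 2) + 1L,
                                       k = seq_len(M - 2) + 2L)
                          else data.frame(i = integer(), j = integer(), k = integer()),
                          loops = data.frame(i = integer(), j = integer()),
                          genomic_map = genomic_map,
                          knocked_out = integer(0)),
                     class = "ChromatinFibre")
  if (!is.null(loops) && nrow(as.data.frame(loops)) > 0)
    fibre <- add_loops(fibre, loops)
  validate_fibre(fibre)
}

#' @export
print.ChromatinFibre <- function(x, ...) {
  cat("ChromatinFibre:", x$n_beads, "beads |",
      sum(x$bead_class == "TU"), "TU,",
      sum(x$bead_class == "euchromatin"), "euchromatin,",
      sum(x$bead_class == "heterochromatin"), "heterochromatin |",
      nrow(x$loops), "loops\n")
  if (!is.null(x$genomic_map))
    cat("  mapped to", x$genomic_map$chrom[1], "in",
        x$genomic_map$end[1] - x$genomic_map$start[1], "bp bins\n")
  invisible(x)
}

#' Validate a fibre's internal consistency
#'
#' Checks backbone connectivity (consecutive beads bonded exactly once),
#' index ranges, class labels, loop sanity, and genomic-map contiguity.
#' @param fibre A `ChromatinFibre`.
#' @return The fibre, invisibly usable in pipelines; errors on violation.
#' @export
validate_fibre <- function(fibre) {
  M <- fibre$n_beads
  stopifnot(length(fibre$bead_class) == M,
            all(fibre$bead_class %in% c("TU", "euchromatin", "heterochromatin")))
  bb <- fibre$bonds[fibre$bonds$kind %in% c("fene", "harmonic_backbone"), ]
  if (nrow(bb) != M - 1 || !all(bb$i == seq_len(M - 1)) || !all(bb$j == bb$i + 1L))
    stop("backbone bonds must connect exactly consecutive beads")
  if (length(unique(bb$kind)) > 1)
    stop("backbone bonds must share a single kind")
  lp <- fibre$bonds[fibre$bonds$kind == "harmonic_loop", ]
  if (nrow(lp) > 0) {
    if (any(lp$i >= lp$j)) stop("loop anchors must satisfy i < j")
    if (any(lp$j - lp$i == 1)) stop("loop bonds must not duplicate backbone bonds")
    if (any(lp$i < 1 | lp$j > M)) stop("loop anchor out of range")
  }
  if (!identical(fibre$loops$i, lp$i) && nrow(lp) != nrow(fibre$loops))
    stop("loop table out of sync with bonds")
  gm <- fibre$genomic_map
  if (!is.null(gm)) {
    stopifnot(nrow(gm) == M, all(c("chrom", "start", "end") %in% names(gm)))
    if (any(gm$start >= gm$end)) stop("genomic bins must be non-empty")
    byc <- split(seq_len(M), gm$chrom)
    for (idx in byc) {
      if (any(diff(gm$start[idx]) <= 0)) stop("genomic map must be sorted")
    }
  }
  fibre
}

#' TU bead indices of a fibre
#'
#' The bead class is the single source of truth for binding; the TU list is a
#' derived view.  Knocked-out TUs (non-binding but still reported) are
#' appended when `include_knockouts = TRUE`.
#' @param fibre A `ChromatinFibre`.
#' @param include_knockouts Include knocked-out (non-binding) TU identities.
#' @return Sorted integer vector of bead indices.
#' @export
tu_indices <- function(fibre, include_knockouts = TRUE) {
  idx <- which(fibre$bead_class == "TU")
  if (include_knockouts) idx <- union(idx, fibre$knocked_out)
  sort(idx)
}

#' Build the toy chain: M beads with randomly placed TUs
#'
#' Draws `n_tu` distinct TU positions uniformly without replacement from a
#' seeded stream; all other beads are weak-binding euchromatin.  The backbone
#' is FENE-bonded with bending on every consecutive triplet.
#'
#' @param M Chain length in beads (default 1000, i.e. 3 Mbp).
#' @param n_tu Number of TU beads (default 39, matching the TU density of
#'   human chromosome 22).
#' @param seed Integer seed for TU placement.
#' @return A `ChromatinFibre`.
#' @export
build_toy_fibre <- function(M = 1000, n_tu = 39, seed = 1L) {
  if (n_tu >= M) stop("n_tu must be smaller than the chain length")
  cls <- rep("euchromatin", M)
  if (n_tu > 0) {
    tus <- withr::with_seed(seed, sample.int(M, n_tu))
    cls[tus] <- "TU"
  }
  chromatin_fibre(cls)
}

#' The frozen reference toy fibre
#'
#' A fixed 1000-bead chain with 39 TUs used throughout the package's worked
#' examples and tests.  Eight anchor TUs sit at named positions (33, 396,
#' 404, 886, 905, 907, 930, 931) so that the documented perturbation
#' experiments (knockout of bead 930, the heterochromatin island spanning
#' beads 901-940, loops d and h) address real TUs; the remaining 31 TUs are
#' drawn from a fixed seed, excluding the island region so that it contains
#' exactly its four embedded TUs.  Any random placement gives the same
#' qualitative behaviour; this one is frozen for reproducibility.
#'
#' @return A `ChromatinFibre`.
#' @export
toy_reference_fibre <- function() {
  M <- 1000L
  anchors <- c(33L, 396L, 404L, 886L, 905L, 907L, 930L, 931L)
  pool <- setdiff(seq_len(M), c(anchors, 901:940))
  extra <- withr::with_seed(20211001L, sample(pool, 31L))
  cls <- rep("euchromatin", M)
  cls[c(anchors, extra)] <- "TU"
  chromatin_fibre(cls)
}

#' Loop preset for the reference fibre: eight non-overlapping loops
#'
#' Loop d spans TUs 396 and 404 and loop h spans TUs 905, 907 and 930;
#' the others tile TU-containing stretches of the chain.
#' @return A two-column matrix of anchor pairs (columns i, j).
#' @export
toy_reference_loops <- function() {
  cbind(i = c(15L, 120L, 250L, 390L, 450L, 600L, 750L, 898L),
        j = c(70L, 200L, 330L, 410L, 540L, 690L, 830L, 935L))
}

#' Add permanent loops to a fibre
#'
#' Adds one harmonic loop bond (rest length 1.8 sigma) per anchor pair and,
#' whenever at least one loop is added, converts all backbone bonds from FENE
#' to harmonic springs (rest length 1.1 sigma) for numerical stability, as is
#' done for looped chains.
#'
#' @param fibre A `ChromatinFibre`.
#' @param loop_anchor_pairs Two-column matrix/data.frame of (i, j) anchors.
#' @return The modified fibre.
#' @export
add_loops <- function(fibre, loop_anchor_pairs) {
  lp <- as.data.frame(loop_anchor_pairs)
  if (nrow(lp) == 0) return(fibre)
  names(lp)[1:2] <- c("i", "j")
  lp$i <- as.integer(lp$i); lp$j <- as.integer(lp$j)
  swap <- lp$i > lp$j
  tmp <- lp$i[swap]; lp$i[swap] <- lp$j[swap]; lp$j[swap] <- tmp
  if (any(lp$i < 1 | lp$j > fibre$n_beads)) stop("loop anchor out of range")
  if (any(lp$i == lp$j)) stop("loop anchors must differ")
  bb <- fibre$bonds$kind %in% c("fene", "harmonic_backbone")
  fibre$bonds$kind[bb] <- "harmonic_backbone"
  fibre$bonds <- rbind(fibre$bonds,
                       data.frame(i = lp$i, j = lp$j, kind = "harmonic_loop"))
  fibre$loops <- rbind(fibre$loops, lp[, c("i", "j")])
  validate_fibre(fibre)
}

#' The "all-loops" preset: consecutive non-overlapping loops tiling the chain
#'
#' Used for the experiment packing every bead into closely spaced loops
#' (which raises total activity modestly, by around 10% at full scale).
#' @param fibre A `ChromatinFibre`.
#' @param loop_size Beads per loop.
#' @return The looped fibre.
#' @export
add_all_loops <- function(fibre, loop_size = 50L) {
  starts <- seq(1L, fibre$n_beads - loop_size, by = loop_size)
  add_loops(fibre, cbind(starts, starts + loop_size - 1L))
}

#' Relabel a contiguous bead region
#'
#' Beads `from..to` (1-based, inclusive) get the given class; used to carve
#' heterochromatin islands or euchromatin embedments.  Relabelling a TU bead
#' removes it from the derived TU list.
#'
#' @param fibre A `ChromatinFibre`.
#' @param from,to 1-based inclusive bead range.
#' @param class New class for the region.
#' @return The modified fibre.
#' @export
set_region_class <- function(fibre, from, to,
                             class = c("heterochromatin", "euchromatin", "TU")) {
  class <- match.arg(class)
  if (from < 1 || to > fibre$n_beads || from > to) stop("invalid bead range")
  fibre$bead_class[from:to] <- class
  validate_fibre(fibre)
}

#' Heterochromatin-island preset on the reference fibre
#'
#' Beads 901-940 become non-binding except the four embedded TUs
#' (905, 907, 930, 931), which stay TUs.
#' @param fibre A fibre with TUs at the island positions
#'   (default [toy_reference_fibre()]).
#' @return The modified fibre.
#' @export
toy_het_island_fibre <- function(fibre = toy_reference_fibre()) {
  island <- 901:940
  tus <- intersect(which(fibre$bead_class == "TU"), island)
  fibre$bead_class[island] <- "heterochromatin"
  fibre$bead_class[tus] <- "TU"
  validate_fibre(fibre)
}

#' Knock out a TU (abrogate TF binding)
#'
#' The bead is reclassified as non-binding (heterochromatin-like repulsion)
#' but its TU identity is retained for reporting, so its activity is still
#' recorded (and is approximately zero).  Idempotent.
#'
#' @param fibre A `ChromatinFibre`.
#' @param tu_index Bead index of the TU to knock out.
#' @return The mutant fibre.
#' @export
knockout_tu <- function(fibre, tu_index) {
  if (tu_index %in% fibre$knocked_out) return(fibre)
  if (fibre$bead_class[tu_index] != "TU")
    stop("bead ", tu_index, " is not a TU")
  fibre$bead_class[tu_index] <- "heterochromatin"
  fibre$knocked_out <- sort(c(fibre$knocked_out, as.integer(tu_index)))
  validate_fibre(fibre)
}

#' Delete a contiguous bead region and re-join the chain
#'
#' Removes beads `from..to` (1-based, inclusive), re-joins the chain with a
#' backbone bond of the same kind across the junction, re-indexes bonds,
#' angles and loops, and keeps the genomic map of surviving beads (so the
#' deletion is visible as a gap in genomic coordinates).  Loops with a
#' deleted anchor are dropped.
#'
#' @param fibre A `ChromatinFibre`.
#' @param from,to 1-based inclusive bead range; empty range (`to < from`) is
#'   the identity.
#' @return The deleted fibre.
#' @export
delete_region <- function(fibre, from, to) {
  if (to < from) return(fibre)
  if (from < 1 || to > fibre$n_beads) stop("invalid bead range")
  if (from == 1 && to == fibre$n_beads) stop("cannot delete the whole chain")
  keep <- setdiff(seq_len(fibre$n_beads), from:to)
  newidx <- integer(fibre$n_beads)
  newidx[keep] <- seq_along(keep)
  lp <- fibre$loops
  if (nrow(lp) > 0) {
    ok <- lp$i %in% keep & lp$j %in% keep
    lp <- data.frame(i = newidx[lp$i[ok]], j = newidx[lp$j[ok]])
  }
  backbone <- fibre$bonds$kind[1]
  gm <- if (!is.null(fibre$genomic_map)) fibre$genomic_map[keep, , drop = FALSE] else NULL
  if (!is.null(gm)) rownames(gm) <- NULL
  out <- chromatin_fibre(fibre$bead_class[keep], genomic_map = gm,
                         backbone = if (backbone == "fene") "fene" else "harmonic_backbone")
  if (nrow(lp) > 0) out <- add_loops(out, lp)
  ko <- fibre$knocked_out[fibre$knocked_out %in% keep]
  out$knocked_out <- as.integer(newidx[ko])
  validate_fibre(out)
}
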