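#' Write an activity record as TSV
#'
#' One row per sample: `sample_time` followed by one 0/1 column per TU
#' (`tu_<index>`).  A header comment records run id, seed and sample
#' interval.
#' @param record An `activity_record`.
#' @param path Output path.
#' @export
write_activity_tsv <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# run_id=%s seed=%s sample_interval=%g",
                     record$run_id, record$seed, record$sample_interval), con)
  df <- data.frame(sample_time = seq_len(nrow(record$samples)) *
                     record$sample_interval, record$samples)
  names(df) <- c("sample_time", paste0("tu_", record$tu_indices))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an activity record written by [write_activity_tsv()]
#' @param path File path.
#' @return An `activity_record`.
#' @export
read_activity_tsv <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  kv <- do.call(rbind, strsplit(meta, "="))
  vals <- stats::setNames(kv[, 2], kv[, 1])
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  tu <- as.integer(sub("tu_", "", names(df)[-1]))
  activity_record(as.matrix(df[, -1, drop = FALSE]), tu,
                  sample_interval = as.numeric(vals["sample_interval"]),
                  run_id = vals[["run_id"]],
                  seed = suppressWarnings(as.integer(vals["seed"])))
}

#' Write a per-run activity matrix as TSV (runs x TUs)
#' @param runs Matrix from [per_run_activity()].
#' @param path Output path.
#' @export
write_activity_matrix_tsv <- function(runs, path) {
  df <- data.frame(run = rownames(runs), runs, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-run activity matrix written by [write_activity_matrix_tsv()]
#' @param path File path.
#' @return Runs x TU numeric matrix.
#' @export
read_activity_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Serialise a fibre as sectioned TSV
#'
#' Two sections: `#%beads` (bead_index, class, chrom, start, end) and
#' `#%bonds` (i, j, kind) covering backbone, loop bonds and knockout marks.
#' @param fibre A `ChromatinFibre`.
#' @param path Output path.
#' @export
write_fibre_tsv <- function(fibre, path) {
  con <- file(path, "w")
  on.exit(close(con))
  gm <- fibre$genomic_map
  beads <- data.frame(bead_index = seq_len(fibre$n_beads),
                      class = fibre$bead_class,
                      chrom = if (is.null(gm)) "." else gm$chrom,
                      start = if (is.null(gm)) -1 else gm$start,
                      end = if (is.null(gm)) -1 else gm$end,
                      knocked_out = as.integer(
                        seq_len(fibre$n_beads) %in% fibre$knocked_out))
  writeLines("#%beads", con)
  utils::write.table(beads, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("#%bonds", con)
  utils::write.table(fibre$bonds, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a fibre written by [write_fibre_tsv()]
#' @param path File path.
#' @return A `ChromatinFibre`.
#' @export
read_fibre_tsv <- function(path) {
  lines <- readLines(path)
  b0 <- which(lines == "#%beads")
  b1 <- which(lines == "#%bonds")
  beads <- utils::read.table(text = lines[(b0 + 1):(b1 - 1)], header = TRUE,
                             sep = "\t")
  bonds <- utils::read.table(text = lines[(b1 + 1):length(lines)],
                             header = TRUE, sep = "\t")
  gm <- if (all(beads$chrom == ".")) NULL
        else beads[, c("chrom", "start", "end")]
  backbone <- bonds$kind[1]
  fibre <- chromatin_fibre(beads$class, genomic_map = gm,
                           backbone = if (backbone == "fene") "fene"
                                      else "harmonic_backbone")
  lp <- bonds[bonds$kind == "harmonic_loop", c("i", "j")]
  if (nrow(lp) > 0) fibre <- add_loops(fibre, lp)
  fibre$knocked_out <- as.integer(beads$bead_index[beads$knocked_out == 1])
  validate_fibre(fibre)
}

#' Write a regulatory network as edge-list TSV and GraphML
#' @param network A [build_network()] result.
#' @param path_tsv Edge-list path (i, j, r, p, sign).
#' @param path_graphml Optional GraphML path.
#' @export
write_network <- function(network, path_tsv, path_graphml = NULL) {
  utils::write.table(network$edges, path_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(path_graphml))
    igraph::write_graph(network$graph, path_graphml, format = "graphml")
  invisible(path_tsv)
}

#' Write a contact map as sparse triplet text
#' @param map A `contact_map`.
#' @param path Output path (bin_i, bin_j, count; upper triangle incl. diag).
#' @export
write_contact_map <- function(map, path) {
  idx <- which(upper.tri(map$counts, diag = TRUE) & map$counts > 0 &
                 !is.na(map$counts), arr.ind = TRUE)
  df <- data.frame(bin_i = idx[, 1], bin_j = idx[, 2],
                   count = map$counts[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a trajectory as extended-XYZ text
#'
#' One block per frame: particle count, a comment line with the time, then
#' one `type x y z` row per particle (bead class code or TF).
#' @param trajectory beads x 3 x frames array.
#' @param fibre The simulated fibre (for particle types).
#' @param path Output path.
#' @param times Optional frame times (tau_B).
#' @export
write_xyz <- function(trajectory, fibre, path, times = NULL) {
  stopifnot(length(dim(trajectory)) == 3)
  N <- dim(trajectory)[1]
  types <- c(substr(fibre$bead_class, 1, 2),
             rep("TF", N - fibre$n_beads))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(dim(trajectory)[3])) {
    writeLines(as.character(N), con)
    writeLines(sprintf("frame=%d time=%g", f,
                       if (is.null(times)) f else times[f]), con)
    writeLines(sprintf("%s %.5f %.5f %.5f", types,
                       trajectory[, 1, f], trajectory[, 2, f],
                       trajectory[, 3, f]), con)
  }
  invisible(path)
}

#' Read a flat key=value run-configuration file
#'
#' Lines are `key = value`; blank lines and `#` comments are ignored.
#' Values are converted to numeric where possible.
#' @param path File path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  vals <- lapply(kv, function(x) {
    v <- x[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, vapply(kv, `[[`, character(1), 1))
}

#' Hash of a configuration (for output provenance)
#' @param config Named list.
#' @return Character md5 string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(config[order(names(config))], file = tmp)
  unname(tools::md5sum(tmp))
}
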