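#' Construct a per-base-pair coverage track
#'
#' A coverage track holds one nonnegative numeric vector per chromosome at
#' single-base resolution, together with the total number of mapped reads of
#' the originating library (needed for CPM scaling) and a flag recording
#' whether CPM normalization has already been applied.  All coordinates are
#' 0-based, half-open, the native bedGraph/BED convention.
#'
#' @param signal named list of nonnegative numeric vectors, one per chromosome.
#' @param total_mapped_reads total mapped reads of the library (scalar, > 0),
#'   or `NA` if unknown.  Taken from sequencing metadata, not inferred from
#'   the coverage integral.
#' @param normalized logical; `TRUE` if values are already counts per million.
#' @return an object of class `coverage_track`.
#' @export
coverage_track <- function(signal, total_mapped_reads = NA_real_, normalized = FALSE) {
  stopifnot(is.list(signal), length(signal) > 0, !is.null(names(signal)))
  for (chrom in names(signal)) {
    v <- signal[[chrom]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0))
      stop("signal for ", chrom, " must be nonnegative and NA-free")
  }
  structure(list(
    signal = signal,
    genome_lengths = vapply(signal, length, integer(1)),
    total_mapped_reads = as.numeric(total_mapped_reads),
    normalized = isTRUE(normalized)
  ), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$signal), "chromosome(s),",
      sum(x$genome_lengths), "bp total;",
      if (x$normalized) "CPM-normalized" else "raw", "\n")
  cat("  total_mapped_reads:", x$total_mapped_reads, "\n")
  invisible(x)
}

#' Read a 4-column bedGraph file into a coverage track
#'
#' Gaps between intervals are filled with zero.  Overlapping intervals and
#' intervals extending beyond the declared chromosome length are rejected
#' with the offending line number, since either indicates a malformed track.
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open).
#' @param genome_lengths named integer vector of chromosome lengths (bp).
#' @param total_mapped_reads optional library size to attach to the track.
#' @param normalized whether the values in the file are already CPM.
#' @return a [coverage_track()].
#' @export
read_bedgraph <- function(path, genome_lengths, total_mapped_reads = NA_real_,
                          normalized = FALSE) {
  stopifnot(is.numeric(genome_lengths), !is.null(names(genome_lengths)))
  signal <- lapply(genome_lengths, function(L) numeric(L))
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "", comment.char = "#",
                      col.names = c("chrom", "start", "end", "value"),
                      colClasses = c("character", "numeric", "numeric", "numeric")),
    error = function(e) NULL)
  if (!is.null(tab) && nrow(tab) > 0) {
    tab$line <- seq_len(nrow(tab))
    bad_chrom <- !(tab$chrom %in% names(genome_lengths))
    if (any(bad_chrom))
      stop("bedGraph line ", tab$line[bad_chrom][1], ": unknown chromosome '",
           tab$chrom[bad_chrom][1], "'")
    oob <- tab$start < 0 | tab$end > genome_lengths[tab$chrom] | tab$start >= tab$end
    if (any(oob))
      stop("bedGraph line ", tab$line[oob][1], ": interval [", tab$start[oob][1],
           ", ", tab$end[oob][1], ") outside chromosome '", tab$chrom[oob][1], "'")
    for (chrom in unique(tab$chrom)) {
      sub <- tab[tab$chrom == chrom, , drop = FALSE]
      o <- order(sub$start)
      sub <- sub[o, , drop = FALSE]
      if (nrow(sub) > 1) {
        ovl <- which(sub$start[-1] < sub$end[-nrow(sub)])
        if (length(ovl))
          stop("bedGraph line ", sub$line[ovl[1] + 1],
               ": interval overlaps the previous interval on '", chrom, "'")
      }
      v <- signal[[chrom]]
      for (i in seq_len(nrow(sub)))
        v[(sub$start[i] + 1):sub$end[i]] <- sub$value[i]
      signal[[chrom]] <- v
    }
  }
  coverage_track(signal, total_mapped_reads = total_mapped_reads,
                 normalized = normalized)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal nonzero value are collapsed into single intervals; zero runs
#' are omitted (readers fill gaps with zero), so write/read round-trips are
#' exact.
#'
#' @param track a [coverage_track()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$signal)) {
    r <- rle(track$signal[[chrom]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%.10g", chrom, starts[keep], ends[keep],
                         r$values[keep]), con)
    }
  }
  invisible(path)
}

#' CPM-normalize a coverage track
#'
#' Multiplies every per-bp value by the scaling factor
#' 1e6 / total_mapped_reads, yielding coverage in counts per million mapped
#' reads so that tracks from libraries of different depth are comparable.
#' Normalizing twice is an error; the operation is exactly inverted by
#' multiplying by total_mapped_reads / 1e6.
#'
#' @param track a raw [coverage_track()] with `total_mapped_reads` set.
#' @return the normalized track.
#' @export
cpm_normalize <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$normalized) stop("track is already CPM-normalized")
  if (!is.finite(track$total_mapped_reads) || track$total_mapped_reads <= 0)
    stop("total_mapped_reads must be a positive number for CPM normalization")
  f <- 1e6 / track$total_mapped_reads
  track$signal <- lapply(track$signal, function(v) v * f)
  track$normalized <- TRUE
  track
}

#' Smooth a coverage track with a sliding window and bin it
#'
#' Each output bin `i` holds the mean per-bp signal over the window
#' `[i*step, i*step + window)` on the chromosome: a 100-bp averaging window
#' slid in 10-bp increments by default, which smooths the track and reduces
#' it to 10-bp resolution in one pass.  Windows are left-anchored at the bin
#' origin; trailing windows that would run past the chromosome end are
#' truncated and averaged over the covered bases only, so subtelomeric signal
#' is not diluted by zero padding.
#'
#' @param track a CPM-normalized [coverage_track()].
#' @param window averaging window length, bp.
#' @param step bin step, bp; must not exceed `window`.
#' @return an object of class `binned_track` with fields `bin_size` (the
#'   window), `step`, and per-chromosome bin-value vectors.
#' @export
smooth_and_bin <- function(track, window = 100L, step = 10L) {
  stopifnot(inherits(track, "coverage_track"))
  window <- as.integer(window); step <- as.integer(step)
  if (step < 1L || window < step) stop("require window >= step >= 1")
  if (!track$normalized)
    warning("smoothing a non-normalized track; bins will be raw coverage")
  bins <- lapply(track$signal, function(v) {
    L <- length(v)
    cs <- c(0, cumsum(v))
    starts <- seq.int(0L, L - 1L, by = step)
    ends <- pmin(starts + window, L)
    (cs[ends + 1L] - cs[starts + 1L]) / (ends - starts)
  })
  structure(list(
    bin_size = window, step = step, bins = bins,
    genome_lengths = track$genome_lengths,
    total_mapped_reads = track$total_mapped_reads,
    normalized = track$normalized
  ), class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat("binned_track: window", x$bin_size, "bp, step", x$step, "bp,",
      length(x$bins), "chromosome(s)\n")
  invisible(x)
}

#' Write a binned track in sgr format
#'
#' Three tab-separated columns: chromosome, bin start position, value.
#'
#' @param binned a `binned_track`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sgr <- function(binned, path) {
  stopifnot(inherits(binned, "binned_track"))
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(binned$bins)) {
    v <- binned$bins[[chrom]]
    pos <- seq.int(0L, by = binned$step, length.out = length(v))
    writeLines(sprintf("%s\t%d\t%.10g", chrom, pos, v), con)
  }
  invisible(path)
}

# Per-bp view of a track: returns the signal vector for one chromosome,
# expanding a binned track by nearest-bin lookup when needed.
per_bp_signal <- function(x, chrom) {
  if (inherits(x, "coverage_track")) return(x$signal[[chrom]])
  if (inherits(x, "binned_track")) {
    v <- x$bins[[chrom]]
    L <- x$genome_lengths[[chrom]]
    idx <- pmin((seq_len(L) - 1L) %/% x$step + 1L, length(v))
    return(v[idx])
  }
  stop("expected a coverage_track or binned_track")
}
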