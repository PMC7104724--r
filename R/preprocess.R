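#' Read a per-base depth table
#'
#' Reads the 3-column `samtools depth` dialect (reference, 1-based position,
#' depth) or an equivalent 2-column position/depth table, and densifies it:
#' positions absent from the file get depth 0.
#'
#' @param path TSV file path.
#' @param reference reference name to extract (3-column input); defaults to
#'   the single reference present.
#' @param length declared replicon length; defaults to the largest position
#'   seen.
#' @return an object of class `"raw_depth"`: list with `reference`, `length`
#'   and the dense `depth` vector.
#' @export
read_depth <- function(path, reference = NULL, length = NULL) {
  dat <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "\t",
                      colClasses = NA, stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(dat) || nrow(dat) == 0L) {
    warning("empty depth file: returning an all-zero track")
    if (is.null(length)) stop("empty file needs an explicit 'length'")
    return(structure(list(reference = reference %||% "unknown",
                          length = length, depth = numeric(length)),
                     class = "raw_depth"))
  }
  if (ncol(dat) == 3L) {
    refs <- unique(dat[[1L]])
    if (is.null(reference)) {
      if (length(refs) > 1L)
        stop("multiple references in file; pass 'reference'")
      reference <- refs[1L]
    }
    dat <- dat[dat[[1L]] == reference, 2:3]
  } else if (ncol(dat) == 2L) {
    reference <- reference %||% "unknown"
  } else {
    stop("depth file must have 2 or 3 tab-separated columns")
  }
  pos <- dat[[1L]]; dp <- dat[[2L]]
  if (!is.numeric(pos) || !is.numeric(dp) || any(dp != round(dp)))
    stop("malformed depth file: positions and integer depths expected")
  if (any(pos < 1)) stop("positions must be 1-based")
  if (is.null(length)) length <- max(pos)
  if (any(pos > length))
    stop("position exceeds declared sequence length")
  depth <- numeric(length)
  depth[pos] <- dp
  structure(list(reference = as.character(reference), length = length,
                 depth = depth), class = "raw_depth")
}

#' Moving median filter
#'
#' Replaces each window of depths with its median; with stride equal to the
#' window size (the default, 100 nt window / 100 nt stride) this both
#' denoises and compresses the track by the window factor. A tail window
#' shorter than `window` uses the positions available. An even number of
#' values yields the mean of the middle pair.
#'
#' @param depths numeric vector of per-position depths.
#' @param window window size in positions (default 100).
#' @param stride stride in positions (default 100).
#' @return the binned depth vector, length `ceiling(length(depths)/stride)`.
#' @export
moving_median <- function(depths, window = 100L, stride = 100L) {
  n <- length(depths)
  if (window < 1L || stride < 1L) stop("window and stride must be >= 1")
  if (window > n) stop("window larger than the sequence")
  starts <- seq.int(1L, n, by = stride)
  vapply(starts, function(s)
    stats::median(depths[s:min(s + window - 1L, n)]), 1.0)
}

#' Remove the top percent of bins as outliers
#'
#' Sets the highest `ceiling(percent/100 * nbins)` bins to blank (`NA`);
#' ties at the cutoff are broken by position. Blanks are subsequently filled
#' with 0 by [fill_blanks_zero()] (conserved-region read pileups become
#' zero-information bins rather than spurious peaks).
#'
#' @param binned binned depth vector.
#' @param percent percentage of bins to blank, in `[0, 100)`; default 1.
#' @return depth vector with blanks as `NA` and attribute `n_removed`.
#' @export
remove_top_percent <- function(binned, percent = 1) {
  if (percent < 0 || percent >= 100) stop("'percent' must be in [0, 100)")
  k <- ceiling(percent / 100 * length(binned))
  if (k > 0) {
    idx <- order(binned, decreasing = TRUE)[seq_len(k)]
    binned[idx] <- NA_real_
  }
  attr(binned, "n_removed") <- as.integer(k)
  binned
}

#' @rdname remove_top_percent
#' @param x depth vector possibly containing blanks (`NA`).
#' @export
fill_blanks_zero <- function(x) {
  x[is.na(x)] <- 0
  x
}

#' Build a clean coverage track from raw depth
#'
#' The preprocessing pipeline: moving median filter (window/stride 100 nt),
#' optional top-percent outlier blanking (default 1% for metagenomic data;
#' use 0 for clean culture data), blank filling with 0, and conversion of bin
#' indices to angles. Every step is recorded in the track metadata.
#'
#' @param x a `"raw_depth"` object from [read_depth()], or a numeric
#'   per-position depth vector.
#' @param sample_id sample label.
#' @param window,stride moving median filter geometry (default 100/100).
#' @param top_percent percentage of highest bins blanked after binning.
#' @return a [coverage_track()].
#' @export
make_track <- function(x, sample_id = "sample", window = 100L, stride = 100L,
                       top_percent = 1) {
  depth <- if (inherits(x, "raw_depth")) x$depth else as.numeric(x)
  binned <- moving_median(depth, window, stride)
  binned <- remove_top_percent(binned, top_percent)
  n_removed <- attr(binned, "n_removed")
  binned <- fill_blanks_zero(binned)
  coverage_track(binned, sample_id = sample_id,
                 meta = list(window = window, stride = stride,
                             top_percent = top_percent,
                             n_outliers_removed = n_removed,
                             raw_length = length(depth),
                             reference = if (inherits(x, "raw_depth"))
                               x$reference else NA_character_))
}

#' Write a binned track as a two-column TSV
#'
#' Writes `bin_start_1based` / `depth` pairs; the dialect [read_depth()]
#' accepts back (positions are the first base of each bin).
#'
#' @param track a [coverage_track()].
#' @param path output file.
#' @param stride bin width used to compute 1-based bin starts.
#' @export
write_track <- function(track, path, stride = track$meta$stride %||% 1L) {
  utils::write.table(
    data.frame(pos = (seq_len(track$I) - 1L) * stride + 1L,
               depth = track$depths),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
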