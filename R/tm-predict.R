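# Built-in transmembrane-segment predictor: Kyte-Doolittle hydropathy in a
# sliding window, thresholded into segments.  Serves as the stand-in for an
# external topology predictor when no TMHMM-style file is supplied; the
# external-file pathway (read_tm_short) is always available.

# Kyte & Doolittle hydropathy indices; ambiguous residues (X/B/Z/U) score 0.
KD_SCALE <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
              Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
              L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
              S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2,
              X = 0, B = 0, Z = 0, U = 0)

#' Transmembrane topology
#'
#' @param segments Two-column integer matrix of 1-based inclusive
#'   \code{(start, end)} residue intervals, sorted and non-overlapping.
#' @return Object of class \code{tm_topology} with fields
#'   \code{tm_count} (number of segments) and \code{segments}.
#' @export
tm_topology <- function(segments = matrix(integer(), ncol = 2)) {
  segments <- matrix(as.integer(segments), ncol = 2,
                     dimnames = list(NULL, c("start", "end")))
  if (nrow(segments) > 0) {
    if (any(segments[, 2] < segments[, 1]))
      stop("segment end before start")
    if (is.unsorted(segments[, 1], strictly = TRUE) && nrow(segments) > 1)
      segments <- segments[order(segments[, 1]), , drop = FALSE]
    if (nrow(segments) > 1 &&
        any(segments[-1, 1] <= segments[-nrow(segments), 2]))
      stop("overlapping transmembrane segments")
  }
  structure(list(tm_count = nrow(segments), segments = segments),
            class = "tm_topology")
}

#' @export
print.tm_topology <- function(x, ...) {
  cat(sprintf("tm_topology: %d segment(s)\n", x$tm_count))
  if (x$tm_count > 0)
    cat(paste(sprintf("  %d-%d", x$segments[, 1], x$segments[, 2]),
              collapse = "\n"), "\n")
  invisible(x)
}

#' Hydropathy caller parameters
#'
#' Defaults follow the classic Kyte-Doolittle convention for membrane
#' proteins: a 19-residue window, a mean-hydropathy threshold of 1.6, a
#' minimum called-segment length of 15 residues, and merging of
#' supra-threshold runs separated by at most 3 sub-threshold positions.
#'
#' @param window Odd sliding-window width, >= 5 (residues).
#' @param threshold Mean-hydropathy cutoff for membrane-spanning calls.
#' @param min_len Minimum retained segment length (residues);
#'   must not exceed twice the window.
#' @param merge_gap Maximum sub-threshold gap merged into a segment.
#' @return Object of class \code{hydropathy_params}.
#' @export
hydropathy_params <- function(window = 19L, threshold = 1.6,
                              min_len = 15L, merge_gap = 3L) {
  window <- as.integer(window)
  if (window < 5L || window %% 2L == 0L)
    stop("window must be an odd integer >= 5")
  min_len <- as.integer(min_len)
  if (min_len < 1L || min_len > 2L * window)
    stop("min_len must be positive and <= 2 * window")
  if (merge_gap < 0L) stop("merge_gap must be non-negative")
  structure(list(window = window, threshold = threshold,
                 min_len = min_len, merge_gap = as.integer(merge_gap)),
            class = "hydropathy_params")
}

#' Per-residue windowed hydropathy profile
#'
#' Score at position i is the mean Kyte-Doolittle index over the window
#' centred at i; positions within \code{window \%/\% 2} of either end use
#' the mean over the truncated window.  Ambiguous residues (X/B/Z/U)
#' contribute 0.
#'
#' @param sequence Amino-acid string.
#' @param window Odd window width.
#' @return Numeric vector, one score per residue.
#' @export
hydropathy_profile <- function(sequence, window = 19L) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  if (n == 0L) transannot_error("empty sequence", "transannot_parse_error")
  s <- unname(KD_SCALE[chars])
  s[is.na(s)] <- 0
  h <- window %/% 2L
  cs <- cumsum(c(0, s))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Call transmembrane segments from a hydropathy profile
#'
#' Maximal runs of positions with score >= threshold; runs separated by at
#' most \code{merge_gap} sub-threshold positions are merged; merged runs
#' shorter than \code{min_len} are discarded.
#'
#' @param profile Numeric per-residue score vector.
#' @param params A [hydropathy_params()] object.
#' @return A [tm_topology()] object (possibly empty).
#' @export
call_tm_segments <- function(profile, params = hydropathy_params()) {
  stopifnot(length(profile) > 0)
  above <- profile >= params$threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (nrow(runs) == 0L) return(tm_topology())
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- runs[i, 1] - merged[nrow(merged), 2] - 1L
      if (gap <= params$merge_gap) {
        merged[nrow(merged), 2] <- runs[i, 2]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  keep <- (merged[, 2] - merged[, 1] + 1L) >= params$min_len
  tm_topology(merged[keep, , drop = FALSE])
}

#' Predict transmembrane topology for one protein
#'
#' Composition of [hydropathy_profile()] and [call_tm_segments()].
#'
#' @param protein A single-row proteome data frame row, a list with a
#'   \code{sequence} field, or a plain amino-acid string.
#' @param params A [hydropathy_params()] object.
#' @return A [tm_topology()] object.
#' @export
predict_topology <- function(protein, params = hydropathy_params()) {
  seq <- if (is.character(protein)) protein else protein$sequence
  call_tm_segments(hydropathy_profile(seq, params$window), params)
}

#' Predict topologies for a whole proteome
#'
#' @param proteome Proteome data frame (see [read_fasta()]).
#' @param params A [hydropathy_params()] object.
#' @return Named list of [tm_topology()] objects keyed by protein id.
#' @export
predict_topologies <- function(proteome, params = hydropathy_params()) {
  setNames(lapply(proteome$sequence, predict_topology, params = params),
           proteome$protein_id)
}
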