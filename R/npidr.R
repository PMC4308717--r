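# Non-parametric irreproducible discovery rate (npIDR) for replicated
# quantifications. The estimator bins elements detected in at least one
# replicate by signal strength (log-spaced bins of the max replicate value)
# and scores each bin by the fraction of its elements seen in exactly one
# replicate; reproducibility is then forced to be monotone non-decreasing in
# signal by a cumulative minimum taken from the low-signal end upward.

#' npIDR scores for a replicate pair
#'
#' @param signal_rep1,signal_rep2 non-negative signal (RPKM or counts) per
#'   element, equal length; optionally named (names must agree). Absence is
#'   encoded as 0.
#' @param n_bins number of log-spaced signal bins (default 20).
#' @param min_bin minimum elements per bin; sparser bins are merged upward
#'   (default 25).
#' @param bin_by bin elements by the `"max"` (default) or `"mean"` of the two
#'   replicate signals.
#' @return object of class `npidr_result`: list with
#'   \describe{
#'     \item{npidr}{per-element score in `[0,1]`; 1 for elements zero in both
#'       replicates, monotone non-increasing in signal otherwise.}
#'     \item{bins}{data.frame of bin edges (log10 signal), element counts,
#'       raw discordance and monotonicity-adjusted npIDR per bin.}
#'     \item{bin_index}{bin assignment per detected element.}
#'   }
#' @export
npidr_scores <- function(signal_rep1, signal_rep2, n_bins = 20L, min_bin = 25L,
                         bin_by = c("max", "mean")) {
  bin_by <- match.arg(bin_by)
  if (length(signal_rep1) != length(signal_rep2)) stop("replicate vectors differ in length")
  if (!is.null(names(signal_rep1)) && !is.null(names(signal_rep2)) &&
      !identical(names(signal_rep1), names(signal_rep2))) {
    stop("replicate element ids disagree")
  }
  if (any(signal_rep1 < 0, na.rm = TRUE) || any(signal_rep2 < 0, na.rm = TRUE)) {
    stop("negative signal")
  }
  if (n_bins < 1L) stop("n_bins must be >= 1")
  s1 <- as.numeric(signal_rep1)
  s2 <- as.numeric(signal_rep2)
  detected <- (s1 > 0) | (s2 > 0)
  if (!any(detected)) stop("nothing detected: all elements zero in both replicates")

  x <- switch(bin_by, max = pmax(s1, s2), mean = (s1 + s2) / 2)
  lx <- log10(x[detected])
  lo <- min(lx); hi <- max(lx)
  if (hi - lo < .Machine$double.eps^0.5) {
    edges <- c(lo - 0.5, hi + 0.5)
  } else {
    edges <- seq(lo, hi, length.out = n_bins + 1L)
  }
  # ties at an edge fall in the lower bin: intervals are (e[i], e[i+1]]
  bin <- findInterval(lx, edges, left.open = TRUE, rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L

  k <- length(edges) - 1L
  counts <- tabulate(bin, nbins = k)
  # merge sparse bins upward (into the next higher-signal bin); a sparse top
  # bin merges downward
  remap <- seq_len(k)
  i <- 1L
  while (i <= k) {
    members <- which(remap == remap[i])
    if (sum(counts[members]) < min_bin) {
      nxt <- if (max(members) < k) max(members) + 1L else min(members) - 1L
      if (nxt >= 1L) remap[members] <- remap[nxt] else break
      i <- 1L
    } else i <- max(members) + 1L
  }
  bin <- remap[bin]
  groups <- sort(unique(bin))

  disc <- xor(s1[detected] == 0, s2[detected] == 0)
  raw <- vapply(groups, function(g) mean(disc[bin == g]), numeric(1))
  n_g <- vapply(groups, function(g) sum(bin == g), numeric(1))
  # monotone non-increase with signal: running minimum from low to high bins
  adj <- cummin(raw)

  npidr <- rep(1, length(s1))
  npidr[detected] <- adj[match(bin, groups)]
  if (!is.null(names(signal_rep1))) names(npidr) <- names(signal_rep1)

  bins_df <- data.frame(
    bin = groups,
    log10_lo = edges[vapply(groups, function(g) min(which(remap == g)), integer(1))],
    log10_hi = edges[vapply(groups, function(g) max(which(remap == g)) + 1L, integer(1))],
    n = n_g, discordance = raw, npidr = adj)
  structure(list(npidr = npidr, bins = bins_df, bin_index = bin,
                 detected = detected, bin_by = bin_by),
            class = "npidr_result")
}

#' @export
print.npidr_result <- function(x, ...) {
  cat(sprintf("npIDR over %d elements (%d detected), %d signal bins\n",
              length(x$npidr), sum(x$detected), nrow(x$bins)))
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' Collapse replicate pairs to reproducibility-filtered biosample values
#'
#' Per biosample, the value is the mean of the two replicates when the
#' element's npIDR is at or below `threshold`, and 0 otherwise
#' (non-reproducible values are set to zero, i.e. treated as undetected).
#'
#' @param m `expr_matrix` whose `replicate_of` attribute (or the
#'   `replicate_of` argument) maps each sample to its biosample; every
#'   biosample must have exactly two replicate samples.
#' @param threshold npIDR cutoff, default 0.1; `threshold = 1` disables the
#'   filter and returns plain replicate means.
#' @param replicate_of optional named map sample -> biosample overriding the
#'   matrix attribute.
#' @param ... passed to [npidr_scores()].
#' @return `expr_matrix` with one column per biosample.
#' @export
filter_reproducible <- function(m, threshold = 0.1, replicate_of = NULL, ...) {
  if (is.null(replicate_of)) replicate_of <- attr(m, "replicate_of")
  if (is.null(replicate_of)) stop("no replicate pairing defined")
  if (!all(colnames(m) %in% names(replicate_of))) {
    bad <- setdiff(colnames(m), names(replicate_of))
    stop("unpaired sample(s): ", paste(bad, collapse = ", "))
  }
  replicate_of <- replicate_of[colnames(m)]
  groups <- split(colnames(m), replicate_of)
  if (any(lengths(groups) != 2L)) {
    bad <- names(groups)[lengths(groups) != 2L]
    stop("biosample(s) without exactly two replicates: ", paste(bad, collapse = ", "))
  }
  out <- matrix(0, nrow = nrow(m), ncol = length(groups),
                dimnames = list(rownames(m), names(groups)))
  for (b in names(groups)) {
    r1 <- m[, groups[[b]][1L]]
    r2 <- m[, groups[[b]][2L]]
    sc <- npidr_scores(r1, r2, ...)
    v <- (r1 + r2) / 2
    v[sc$npidr > threshold] <- 0
    out[, b] <- v
  }
  expression_matrix(out, species = attr(m, "species"))
}
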