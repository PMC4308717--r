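# Binned read-density conservation and metagene chromatin profiles.
# "Read density" is mean per-nucleotide coverage (length-free and
# bedGraph-native); cross-species comparisons run over externally supplied
# orthologous 100-nt bin pairs.

#' Mean per-nucleotide coverage in fixed bins
#'
#' @param coverage `GRanges` with a `score` column (non-overlapping
#'   intervals, e.g. from [read_bedgraph()]).
#' @param bins data.frame `chrom, start, end` (0-based half-open) or
#'   `GRanges`. Bins extending past the chromosome end (when `chrom_sizes`
#'   is given) are dropped with a warning.
#' @param chrom_sizes optional named chromosome lengths.
#' @return numeric vector of coverage-weighted mean densities, one per bin
#'   (dropped bins get `NA`).
#' @export
bin_densities <- function(coverage, bins, chrom_sizes = NULL) {
  if (is.data.frame(bins)) {
    bgr <- GenomicRanges::GRanges(bins$chrom,
                                  IRanges::IRanges(bins$start + 1L, bins$end))
  } else bgr <- bins
  out <- rep(NA_real_, length(bgr))
  keep <- rep(TRUE, length(bgr))
  if (!is.null(chrom_sizes)) {
    ends <- chrom_sizes[as.character(GenomicRanges::seqnames(bgr))]
    keep <- !is.na(ends) & GenomicRanges::end(bgr) <= ends
    if (any(!keep)) warning(sum(!keep), " bin(s) beyond chromosome end; dropped")
  }
  cov_rle <- GenomicRanges::coverage(coverage, weight = "score")
  chroms <- as.character(GenomicRanges::seqnames(bgr))
  for (ch in unique(chroms[keep])) {
    idx <- which(keep & chroms == ch)
    rle <- if (ch %in% names(cov_rle)) cov_rle[[ch]] else S4Vectors::Rle(0, 0)
    st <- GenomicRanges::start(bgr)[idx]
    en <- GenomicRanges::end(bgr)[idx]
    # extend the per-chromosome coverage with zeros so every bin is in range
    need <- max(en)
    if (length(rle) < need) {
      rle <- c(rle, S4Vectors::Rle(0, need - length(rle)))
    }
    v <- IRanges::viewMeans(IRanges::Views(rle, start = st, end = en))
    out[idx] <- as.numeric(v)
  }
  out
}

#' Tile chromosomes into fixed-width bins
#'
#' @param chrom_sizes named chromosome lengths.
#' @param width bin width in nt (default 100); the trailing partial bin is
#'   dropped.
#' @return data.frame `chrom, start, end` (0-based half-open).
#' @export
tile_bins <- function(chrom_sizes, width = 100L) {
  do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    n <- chrom_sizes[[ch]] %/% width
    if (n == 0L) return(NULL)
    st <- (seq_len(n) - 1L) * width
    data.frame(chrom = ch, start = st, end = st + width, stringsAsFactors = FALSE)
  }))
}

#' Cross-species correlation of orthologous bin densities
#'
#' Pearson correlation of `log10(density + pseudo)` over orthologous bin
#' pairs, overall and stratified by region class, by distance-to-gene decile
#' and (when present) by conservation-score bin.
#'
#' @param table data.frame with columns `density1, density2` and optionally
#'   `region_class`, `distance_to_gene`, `conservation_score`.
#' @param pseudo pseudo-count added before log10 (default `1e-2`).
#' @param n_dist_bins number of distance strata (default 10).
#' @param n_cons_bins number of conservation-score strata (default 5).
#' @return list of class `binpair_cor`: `cc`, `n`, and data.frames
#'   `by_class`, `by_distance`, `by_conservation` (stratum, n, cc; `NA` for
#'   strata with fewer than 3 pairs).
#' @export
binpair_correlation <- function(table, pseudo = 1e-2, n_dist_bins = 10L,
                                n_cons_bins = 5L) {
  if (pseudo <= 0) stop("pseudo must be > 0")
  l1 <- log10(table$density1 + pseudo)
  l2 <- log10(table$density2 + pseudo)
  cc_of <- function(idx) {
    if (sum(idx) < 3L) return(NA_real_)
    if (sd(l1[idx]) == 0 || sd(l2[idx]) == 0) return(NA_real_)
    cor(l1[idx], l2[idx])
  }
  strat <- function(f) {
    lv <- levels(factor(f))
    data.frame(stratum = lv,
               n = vapply(lv, function(s) sum(f == s, na.rm = TRUE), numeric(1)),
               cc = vapply(lv, function(s) cc_of(!is.na(f) & f == s), numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- list(cc = cc_of(rep(TRUE, nrow(table))), n = nrow(table))
  out$by_class <- if (!is.null(table$region_class)) strat(table$region_class)
  out$by_distance <- if (!is.null(table$distance_to_gene)) {
    d <- table$distance_to_gene
    br <- unique(quantile(d, probs = seq(0, 1, length.out = n_dist_bins + 1L),
                          na.rm = TRUE))
    if (length(br) >= 3L) {
      f <- cut(d, breaks = br, include.lowest = TRUE)
      s <- strat(as.character(f))
      s[order(match(s$stratum, levels(f))), , drop = FALSE]
    }
  }
  out$by_conservation <- if (!is.null(table$conservation_score)) {
    sc <- table$conservation_score
    br <- unique(quantile(sc, probs = seq(0, 1, length.out = n_cons_bins + 1L),
                          na.rm = TRUE))
    if (length(br) >= 3L) {
      f <- cut(sc, breaks = br, include.lowest = TRUE)
      s <- strat(as.character(f))
      s[order(match(s$stratum, levels(f))), , drop = FALSE]
    }
  }
  class(out) <- "binpair_cor"
  out
}

#' @export
print.binpair_cor <- function(x, ...) {
  cat(sprintf("orthologous bin-density correlation: cc = %.4f over %d pairs\n",
              x$cc, x$n))
  if (!is.null(x$by_class)) {
    cat("by region class:\n"); print(x$by_class, row.names = FALSE)
  }
  invisible(x)
}

# Per-gene signal vectors in the +/-500 nt window around an anchor,
# strand-oriented (offset increases 5'->3' along the gene).
gene_window_signal <- function(cov_rle, gm, anchor = c("TSS", "TTS"), flank = 500L) {
  anchor <- match.arg(anchor)
  g <- gm$genes
  sig <- matrix(NA_real_, nrow = nrow(g), ncol = 2L * flank,
                dimnames = list(g$gene_id, NULL))
  skipped <- 0L
  for (i in seq_len(nrow(g))) {
    plus <- g$strand[i] != "-"
    a <- if (anchor == "TSS") {
      if (plus) g$start[i] else g$end[i] - 1L
    } else {
      if (plus) g$end[i] - 1L else g$start[i]
    }
    # transcript-oriented offsets -flank .. flank-1 around the anchor: on the
    # minus strand offset o sits at genomic position a - o, so the genomic
    # window is mirrored before reversal
    if (plus) {
      st <- a - flank; en <- a + flank - 1L     # 0-based positions
    } else {
      st <- a - flank + 1L; en <- a + flank
    }
    ch <- g$chrom[i]
    rle <- if (ch %in% names(cov_rle)) cov_rle[[ch]] else NULL
    if (st < 0L || is.null(rle) || en + 1L > length(rle)) {
      skipped <- skipped + 1L
      next
    }
    v <- as.numeric(S4Vectors::window(rle, start = st + 1L, end = en + 1L))
    if (!plus) v <- rev(v)
    sig[i, ] <- v
  }
  if (skipped > 0L) {
    warning(skipped, " gene(s) with the anchor window beyond chromosome bounds; skipped")
  }
  sig[!is.na(sig[, 1L]), , drop = FALSE]
}

#' Normalized metagene profile around TSS or TTS
#'
#' Per sample, per-nucleotide read density is extracted in the 1-kb window
#' around the anchor of every gene (orientation-flipped for minus-strand
#' genes), averaged within each gene group, normalized to the maximum signal
#' across all genes for the mark, and finally averaged across samples.
#'
#' @param coverages list (one element per sample) of `GRanges` coverage
#'   tracks, or of `RleList` objects.
#' @param gm `gene_models`.
#' @param groups named list of gene-id vectors (e.g. constrained /
#'   unconstrained).
#' @param anchor `"TSS"` (default) or `"TTS"`.
#' @param flank half-window in nt (default 500).
#' @param mark label stored with the profile.
#' @return object of class `metagene_profile`: data.frame with `offset`
#'   (-flank .. flank-1) and one normalized-signal column per group.
#' @export
metagene_profile <- function(coverages, gm, groups, anchor = c("TSS", "TTS"),
                             flank = 500L, mark = "mark") {
  anchor <- match.arg(anchor)
  if (!is.list(coverages)) coverages <- list(coverages)
  acc <- NULL
  for (cov in coverages) {
    cov_rle <- if (methods::is(cov, "GRanges")) {
      GenomicRanges::coverage(cov, weight = "score")
    } else cov
    sig <- gene_window_signal(cov_rle, gm, anchor = anchor, flank = flank)
    norm <- max(sig)
    prof <- vapply(groups, function(ids) {
      rows <- intersect(ids, rownames(sig))
      if (length(rows) == 0L) return(rep(NA_real_, ncol(sig)))
      colMeans(sig[rows, , drop = FALSE]) / if (norm > 0) norm else 1
    }, numeric(ncol(sig)))
    acc <- if (is.null(acc)) prof else acc + prof
  }
  prof <- acc / length(coverages)
  out <- data.frame(offset = seq(-flank, flank - 1L), prof, check.names = FALSE)
  structure(out, mark = mark, anchor = anchor,
            class = c("metagene_profile", "data.frame"))
}

#' Mean window signal per gene
#'
#' The per-gene mean read density in the anchor window, averaged across
#' samples — the per-gene summary compared across species by
#' [mark_divergence()].
#'
#' @inheritParams metagene_profile
#' @return named numeric vector per gene.
#' @export
gene_window_means <- function(coverages, gm, anchor = c("TSS", "TTS"),
                              flank = 500L) {
  anchor <- match.arg(anchor)
  if (!is.list(coverages)) coverages <- list(coverages)
  per_sample <- lapply(coverages, function(cov) {
    cov_rle <- if (methods::is(cov, "GRanges")) {
      GenomicRanges::coverage(cov, weight = "score")
    } else cov
    sig <- gene_window_signal(cov_rle, gm, anchor = anchor, flank = flank)
    rowMeans(sig)
  })
  ids <- Reduce(intersect, lapply(per_sample, names))
  rowMeans(do.call(cbind, lapply(per_sample, `[`, ids)))
}

#' Cross-species divergence of a chromatin mark
#'
#' Per orthologue pair, the absolute difference of log10 mean window signal,
#' `|log10(s1 + pseudo) - log10(s2 + pseudo)|`; optionally compared between
#' gene classes with a Wilcoxon rank-sum test.
#'
#' @param signal1,signal2 named per-gene mean window signals (see
#'   [gene_window_means()]) for the two species.
#' @param orth orthology map (`id1` in species 1, `id2` in species 2).
#' @param pseudo pseudo-count (default 1, suited to window-mean coverage).
#' @param classes optional named class labels (by `id1`) to compare.
#' @return list: `per_gene` data.frame (`id1, id2, divergence`, and `class`
#'   when given), `class_medians`, `wilcox_p`.
#' @export
mark_divergence <- function(signal1, signal2, orth, pseudo = 1, classes = NULL) {
  i1 <- match(orth$id1, names(signal1))
  i2 <- match(orth$id2, names(signal2))
  keep <- !is.na(i1) & !is.na(i2)
  d <- abs(log10(signal1[i1[keep]] + pseudo) - log10(signal2[i2[keep]] + pseudo))
  out <- data.frame(id1 = orth$id1[keep], id2 = orth$id2[keep],
                    divergence = unname(d), stringsAsFactors = FALSE)
  res <- list(per_gene = out, class_medians = NULL, wilcox_p = NA_real_)
  if (!is.null(classes)) {
    out$class <- as.character(classes[out$id1])
    res$per_gene <- out
    lv <- unique(out$class[!is.na(out$class)])
    res$class_medians <- vapply(lv, function(cl) {
      median(out$divergence[out$class == cl], na.rm = TRUE)
    }, numeric(1))
    if (length(lv) == 2L) {
      res$wilcox_p <- suppressWarnings(wilcox.test(
        out$divergence[out$class == lv[1L]],
        out$divergence[out$class == lv[2L]])$p.value)
    }
  }
  res
}
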