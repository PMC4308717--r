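# Vls/Vt: the fraction of per-gene transcript-abundance variance explained
# by overall gene expression. Samples are points in transcript space; a
# "constant splicing" model is a ray from the origin along the common
# direction of fixed isoform proportions. Vls is the variance of the sample
# projections onto that ray, Vt the total variance; their ratio is ~1 when
# isoform proportions are stable (variation is expression-driven) and ~0
# when splicing drives the variation. Abundances are square-root rescaled
# first, which tempers the dominance of extreme major isoforms.

#' Expression-explained fraction of transcript-abundance variance
#'
#' @param m numeric matrix, samples x transcripts, non-negative abundances
#'   (RPKM) of one gene's isoforms; at least 3 samples with signal.
#' @return Vls/Vt in `[0,1]` (1 by convention for single-transcript genes;
#'   `NA` with a warning for an all-zero matrix).
#' @export
vls_ratio <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0, na.rm = TRUE)) stop("negative abundances")
  if (all(m == 0, na.rm = TRUE)) {
    warning("all-zero isoform matrix; ratio undefined")
    return(NA_real_)
  }
  nonzero <- rowSums(m) > 0
  if (sum(nonzero) < 3L) stop("need at least 3 samples with signal")
  if (ncol(m) == 1L) return(1)

  y <- sqrt(m)
  norms <- sqrt(rowSums(y^2))
  dirs <- y[nonzero, , drop = FALSE] / norms[nonzero]
  u <- colMeans(dirs)
  u <- u / sqrt(sum(u^2))
  p <- drop(y %*% u)
  v_ls <- var(p)                       # variance of projections along the ray
  v_t <- sum(apply(y, 2L, var))        # total variance about the centroid
  if (v_t == 0) return(1)
  min(max(v_ls / v_t, 0), 1)
}

#' Bootstrap-stabilised Vls/Vt
#'
#' Resamples the gene's samples with replacement `B` times and reports the
#' median resample ratio, which damps the influence of outlier samples;
#' resamples with fewer than 3 distinct samples or no total variance are
#' redrawn (up to `10 * B` attempts).
#'
#' @param m samples x transcripts abundance matrix.
#' @param B number of bootstrap resamples (default 100).
#' @param seed RNG seed.
#' @return object of class `vls_result`: list `ratio` (plain estimate),
#'   `bootstrap_median`, `bootstrap_iqr`, `B`, `seed`.
#' @export
vls_bootstrap <- function(m, B = 100L, seed = 1L) {
  m <- as.matrix(m)
  plain <- vls_ratio(m)
  if (is.na(plain) || ncol(m) == 1L) {
    return(structure(list(ratio = plain, bootstrap_median = plain,
                          bootstrap_iqr = 0, B = 0L, seed = seed),
                     class = "vls_result"))
  }
  S <- nrow(m)
  ratios <- numeric(0)
  local_seed(seed, {
    attempts <- 0L
    while (length(ratios) < B && attempts < 10L * B) {
      attempts <- attempts + 1L
      idx <- sample.int(S, S, replace = TRUE)
      if (length(unique(idx)) < 3L) next
      mb <- m[idx, , drop = FALSE]
      if (sum(rowSums(mb) > 0) < 3L) next
      yb <- sqrt(mb)
      if (sum(apply(yb, 2L, var)) == 0) next
      ratios[length(ratios) + 1L] <- vls_ratio(mb)
    }
  })
  if (length(ratios) == 0L) {
    warning("could not form valid bootstrap resamples; falling back to the plain ratio")
    return(structure(list(ratio = plain, bootstrap_median = plain,
                          bootstrap_iqr = 0, B = 0L, seed = seed),
                     class = "vls_result"))
  }
  structure(list(ratio = plain, bootstrap_median = median(ratios),
                 bootstrap_iqr = IQR(ratios), B = length(ratios), seed = seed),
            class = "vls_result")
}

#' @export
print.vls_result <- function(x, ...) {
  cat(sprintf("Vls/Vt = %.4f (bootstrap median %.4f, IQR %.4f, B = %d)\n",
              x$ratio, x$bootstrap_median, x$bootstrap_iqr, x$B))
  invisible(x)
}

#' Cohort summary of Vls/Vt by constraint class
#'
#' @param matrices named list of per-gene samples x transcripts matrices.
#' @param calls named character (or factor) vector of gene classes
#'   (`constrained`/`unconstrained`), named by gene id.
#' @param B,seed passed to [vls_bootstrap()] (each gene gets a sub-seed).
#' @return list with `per_gene` data.frame (gene, class, ratio,
#'   bootstrap_median, n_transcripts), `class_means` (mean bootstrap median
#'   per class), and `wilcox_p` (rank-sum test between the classes, `NA` if a
#'   class is empty).
#' @export
vls_cohort <- function(matrices, calls, B = 100L, seed = 1L) {
  genes <- intersect(names(matrices), names(calls))
  if (length(genes) == 0L) stop("no genes shared between matrices and calls")
  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    r <- vls_bootstrap(matrices[[g]], B = B, seed = sub_seed(seed, i))
    data.frame(gene = g, class = as.character(calls[[g]]), ratio = r$ratio,
               bootstrap_median = r$bootstrap_median,
               n_transcripts = ncol(as.matrix(matrices[[g]])),
               stringsAsFactors = FALSE)
  })
  per_gene <- do.call(rbind, rows)
  cls <- c("constrained", "unconstrained")
  means <- vapply(cls, function(cl) {
    v <- per_gene$bootstrap_median[per_gene$class == cl]
    if (length(v)) mean(v, na.rm = TRUE) else NA_real_
  }, numeric(1))
  wp <- if (all(table(factor(per_gene$class, levels = cls)) > 0)) {
    suppressWarnings(wilcox.test(
      per_gene$bootstrap_median[per_gene$class == cls[1L]],
      per_gene$bootstrap_median[per_gene$class == cls[2L]])$p.value)
  } else NA_real_
  list(per_gene = per_gene, class_means = means, wilcox_p = wp)
}

#' Read per-gene isoform abundance matrices
#'
#' @param path TSV with columns `transcript_id`, `gene_id`, then one column
#'   per sample.
#' @return named list of samples x transcripts matrices, one per gene.
#' @export
read_isoform_matrices <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "gene_id") %in% colnames(df))) {
    stop("isoform table needs transcript_id and gene_id columns")
  }
  samples <- setdiff(colnames(df), c("transcript_id", "gene_id"))
  lapply(split(df, df$gene_id), function(d) {
    m <- t(as.matrix(d[, samples, drop = FALSE]))
    colnames(m) <- d$transcript_id
    m
  })
}
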