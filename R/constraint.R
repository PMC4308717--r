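# The dynamic-range (DNR) statistic and the constrained-gene analyses built
# on it. DNR pools the non-zero, reproducibility-filtered RPKM of an
# orthologous gene pair across every sample of both species and takes the
# log10 ratio of the maximum to the minimum; it is only defined for genes
# expressed in at least two samples of each species.

#' Dynamic range of orthologous gene expression
#'
#' @param m1,m2 expression matrices (genes x samples) for the two species,
#'   already reproducibility-filtered (zeros mean reproducibly undetected).
#' @param orth one-to-one orthology map (`id1` in `m1`, `id2` in `m2`).
#' @param min_expressed minimum number of non-zero samples required per
#'   species for the DNR to be defined (default 2).
#' @return data.frame of class `dnr_table` with one row per orthologue pair:
#'   `id1, id2, n_expressed1, n_expressed2, max_rpkm, min_rpkm, dnr`
#'   (`dnr = log10(max/min)` in log10 units, `NA` when undefined).
#' @export
compute_dnr <- function(m1, m2, orth, min_expressed = 2L) {
  miss1 <- !(orth$id1 %in% rownames(m1))
  miss2 <- !(orth$id2 %in% rownames(m2))
  if (any(miss1 | miss2)) {
    warning(sum(miss1 | miss2),
            " orthologue pair(s) missing from a matrix; DNR undefined for them")
  }
  n <- nrow(orth)
  n1 <- n2 <- integer(n)
  mx <- mn <- dnr <- rep(NA_real_, n)
  i1 <- match(orth$id1, rownames(m1))
  i2 <- match(orth$id2, rownames(m2))
  for (i in seq_len(n)) {
    if (is.na(i1[i]) || is.na(i2[i])) next
    v1 <- m1[i1[i], ]; v1 <- v1[!is.na(v1) & v1 > 0]
    v2 <- m2[i2[i], ]; v2 <- v2[!is.na(v2) & v2 > 0]
    n1[i] <- length(v1); n2[i] <- length(v2)
    if (length(v1) >= min_expressed && length(v2) >= min_expressed) {
      pooled <- c(v1, v2)
      mx[i] <- max(pooled); mn[i] <- min(pooled)
      dnr[i] <- log10(mx[i]) - log10(mn[i])
    }
  }
  structure(data.frame(id1 = orth$id1, id2 = orth$id2,
                       n_expressed1 = n1, n_expressed2 = n2,
                       max_rpkm = mx, min_rpkm = mn, dnr = dnr,
                       stringsAsFactors = FALSE),
            class = c("dnr_table", "data.frame"))
}

#' Classify orthologues as constrained or unconstrained
#'
#' Constrained genes have a defined DNR at or below the threshold (expression
#' varying less than `threshold` orders of magnitude across every sample of
#' both species); genes with a defined DNR above it are unconstrained; genes
#' without a defined DNR are `undefined` and excluded from both sets.
#'
#' @param dnr `dnr_table` from [compute_dnr()].
#' @param threshold DNR cutoff in log10 units (the fitted mixture
#'   intersection, or 2 for the canonical two-orders-of-magnitude rule).
#' @return the table with a `call` factor column
#'   (`constrained`/`unconstrained`/`undefined`); class counts in the
#'   `counts` attribute.
#' @export
classify_constraint <- function(dnr, threshold) {
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be > 0")
  call <- ifelse(is.na(dnr$dnr), "undefined",
                 ifelse(dnr$dnr <= threshold, "constrained", "unconstrained"))
  dnr$call <- factor(call, levels = c("constrained", "unconstrained", "undefined"))
  attr(dnr, "counts") <- table(dnr$call)
  attr(dnr, "threshold") <- threshold
  dnr
}

#' Expression-matched constrained and unconstrained subsets
#'
#' Removes expression level as a confounder: genes are placed on a
#' `bins` x `bins` grid of per-species average-expression quantile cells, and
#' from every cell an equal number of constrained and unconstrained genes is
#' sampled without replacement, giving two subsets of identical size with a
#' cell-identical joint expression distribution.
#'
#' @param calls classified `dnr_table` (from [classify_constraint()]).
#' @param avg_expr_sp1,avg_expr_sp2 per-gene log10 average RPKM, named by
#'   `id1`.
#' @param bins quantile bins per species axis (default 10, i.e. deciles).
#' @param seed RNG seed for the within-cell sampling.
#' @return list with character vectors `constrained` and `unconstrained`
#'   (gene ids in species 1), of identical length.
#' @export
match_by_expression <- function(calls, avg_expr_sp1, avg_expr_sp2,
                                bins = 10L, seed = 1L) {
  if (bins < 2L) stop("bins must be >= 2")
  keep <- calls$call %in% c("constrained", "unconstrained") &
    calls$id1 %in% names(avg_expr_sp1) & calls$id1 %in% names(avg_expr_sp2)
  ids <- calls$id1[keep]
  cls <- as.character(calls$call[keep])
  e1 <- avg_expr_sp1[ids]; e2 <- avg_expr_sp2[ids]
  ok <- is.finite(e1) & is.finite(e2)
  ids <- ids[ok]; cls <- cls[ok]; e1 <- e1[ok]; e2 <- e2[ok]
  if (length(ids) == 0L || !all(c("constrained", "unconstrained") %in% cls)) {
    warning("no overlap between classes; matched subsets are empty")
    return(list(constrained = character(), unconstrained = character()))
  }
  qcut <- function(v) {
    br <- unique(quantile(v, probs = seq(0, 1, length.out = bins + 1L)))
    if (length(br) < 2L) br <- c(br, br + 1)
    cut(v, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  cell <- paste(qcut(e1), qcut(e2), sep = ":")
  cons_out <- uncons_out <- character()
  local_seed(seed, {
    for (cl in unique(cell)) {
      in_cell <- cell == cl
      cset <- ids[in_cell & cls == "constrained"]
      uset <- ids[in_cell & cls == "unconstrained"]
      k <- min(length(cset), length(uset))
      if (k == 0L) next
      cons_out <- c(cons_out, if (length(cset) == k) cset else sample(cset, k))
      uncons_out <- c(uncons_out, if (length(uset) == k) uset else sample(uset, k))
    }
  })
  if (length(cons_out) == 0L) warning("matched subsets are empty")
  list(constrained = cons_out, unconstrained = uncons_out)
}

#' Fraction of transcriptional output from a gene set
#'
#' Per sample, the proportion of transcribed nucleotides (RPKM weighted by
#' exonic length) that originates from the given gene set, among all
#' expressed genes.
#'
#' @param m expression matrix (genes x samples).
#' @param lengths named exonic length (nt) per gene; required for every
#'   expressed gene.
#' @param gene_set character vector of gene ids (e.g. constrained genes).
#' @return named numeric vector, one fraction in `[0,1]` per sample (`NA`
#'   where nothing is expressed).
#' @export
output_fraction <- function(m, lengths, gene_set) {
  expressed_any <- rownames(m)[rowSums(m > 0, na.rm = TRUE) > 0]
  missing_len <- setdiff(expressed_any, names(lengths))
  if (length(missing_len)) {
    stop("exonic length missing for expressed gene(s): ",
         paste(head(missing_len, 3L), collapse = ", "))
  }
  L <- lengths[rownames(m)]
  L[is.na(L)] <- 0
  w <- m * L
  tot <- colSums(w, na.rm = TRUE)
  sel <- rownames(m) %in% gene_set
  num <- colSums(w[sel, , drop = FALSE], na.rm = TRUE)
  out <- ifelse(tot > 0, num / tot, NA_real_)
  setNames(out, colnames(m))
}

#' Two-factor variance decomposition of log expression
#'
#' Additive two-way (gene + sample, no interaction) decomposition of the
#' total sum of squares of a complete log-expression matrix: the fractions of
#' variance attributable to gene, to sample (condition), and to the residual.
#' Zeros must already be replaced by a small effective value (see
#' [replace_zeros()]) before taking logs.
#'
#' @param log_m numeric matrix of log expression, genes x samples, no missing
#'   values, at least 2 genes and 2 samples.
#' @return named numeric vector `gene, sample, residual`; the fractions sum
#'   to 1.
#' @export
anova_decomposition <- function(log_m) {
  if (nrow(log_m) < 2L || ncol(log_m) < 2L) {
    stop("need at least 2 genes and 2 samples")
  }
  if (anyNA(log_m)) stop("log expression matrix contains missing values")
  grand <- mean(log_m)
  ss_gene <- ncol(log_m) * sum((rowMeans(log_m) - grand)^2)
  ss_sample <- nrow(log_m) * sum((colMeans(log_m) - grand)^2)
  ss_total <- sum((log_m - grand)^2)
  ss_res <- ss_total - ss_gene - ss_sample
  c(gene = ss_gene, sample = ss_sample, residual = ss_res) / ss_total
}

#' Replace zero RPKM values by a small effective value
#'
#' @param m numeric matrix.
#' @param effective value substituted for zeros (default `1e-3`).
#' @export
replace_zeros <- function(m, effective = 1e-3) {
  m[m == 0] <- effective
  m
}

#' Expression breadth
#'
#' Number of samples in which each gene is detected (non-zero value).
#'
#' @param m expression matrix.
#' @return named integer vector per gene.
#' @export
expression_breadth <- function(m) {
  setNames(as.integer(rowSums(m > 0, na.rm = TRUE)), rownames(m))
}

#' Cross-species correlation of average expression
#'
#' Pearson correlation of per-gene log10 average RPKM between the two
#' species, restricted to a gene subset (averaging is done before the log;
#' zero averages are replaced by `1e-3`).
#'
#' @param avg1,avg2 per-gene log10 average expression, named by a shared id.
#' @param subset gene ids to restrict to (default: all shared genes).
#' @return Pearson correlation coefficient (`NA` with a warning when either
#'   vector is constant).
#' @export
cross_species_corr <- function(avg1, avg2, subset = NULL) {
  ids <- intersect(names(avg1), names(avg2))
  if (!is.null(subset)) ids <- intersect(ids, subset)
  x <- avg1[ids]; y <- avg2[ids]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 genes with defined averages")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  cor(x, y)
}

#' Per-gene log10 average expression
#'
#' Average RPKM across samples first, then log10, with zero averages replaced
#' by the effective value.
#'
#' @param m expression matrix.
#' @param effective replacement for zero averages (default `1e-3`).
#' @export
log_avg_expression <- function(m, effective = 1e-3) {
  avg <- rowMeans(m, na.rm = TRUE)
  avg[avg == 0] <- effective
  setNames(log10(avg), rownames(m))
}

#' Antisense-to-total expression ratio
#'
#' Per gene and sample, antisense reads as a fraction of reads on both
#' strands, `a / (a + s)`; summarised per gene by the mean and s.d. over
#' samples with any signal.
#'
#' @param sense,antisense non-negative count matrices, genes x samples, same
#'   dimnames.
#' @return data.frame `gene, mean_ratio, sd_ratio, n_samples`; genes with no
#'   signal in any sample get `NA`.
#' @export
antisense_ratio <- function(sense, antisense) {
  stopifnot(identical(dim(sense), dim(antisense)),
            identical(dimnames(sense), dimnames(antisense)))
  if (any(sense < 0, na.rm = TRUE) || any(antisense < 0, na.rm = TRUE)) {
    stop("negative counts")
  }
  tot <- sense + antisense
  ratio <- ifelse(tot > 0, antisense / tot, NA_real_)
  data.frame(
    gene = rownames(sense),
    mean_ratio = apply(ratio, 1L, function(r) if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE)),
    sd_ratio = apply(ratio, 1L, function(r) if (sum(!is.na(r)) < 2L) NA_real_ else sd(r, na.rm = TRUE)),
    n_samples = rowSums(!is.na(ratio)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Nuclear-to-cytosolic localization statistics
#'
#' Per gene, the mean and s.d. across matched samples of the log10
#' nuclear-to-cytosolic expression ratio (zeros replaced by `1e-3` before the
#' ratio); genes with negative mean log-ratio are flagged cytosolic.
#'
#' @param nuclear,cytosolic expression matrices with matched sample columns.
#' @param effective zero replacement (default `1e-3`).
#' @return data.frame `gene, mean_log_ratio, sd_log_ratio, cytosolic`.
#' @export
localization_stats <- function(nuclear, cytosolic, effective = 1e-3) {
  common_s <- intersect(colnames(nuclear), colnames(cytosolic))
  if (length(common_s) < 1L) stop("no matched samples")
  genes <- intersect(rownames(nuclear), rownames(cytosolic))
  skipped <- length(union(rownames(nuclear), rownames(cytosolic))) - length(genes)
  if (skipped > 0L) warning(skipped, " gene(s) absent from one matrix; skipped")
  n <- replace_zeros(unclass(nuclear)[genes, common_s, drop = FALSE], effective)
  cy <- replace_zeros(unclass(cytosolic)[genes, common_s, drop = FALSE], effective)
  lr <- log10(n / cy)
  data.frame(
    gene = genes,
    mean_log_ratio = rowMeans(lr),
    sd_log_ratio = apply(lr, 1L, sd),
    cytosolic = rowMeans(lr) < 0,
    row.names = NULL, stringsAsFactors = FALSE)
}
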