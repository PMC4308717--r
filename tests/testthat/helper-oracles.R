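# Independent brute-force oracles used by the tests. These re-derive the
# quantities with naive code paths (explicit loops, dense linear algebra)
# that share nothing with the package implementation.

# DNR by direct max/min scan over the pooled non-zero values of a pair.
oracle_dnr <- function(v1, v2, min_expressed = 2L) {
  v1 <- v1[v1 > 0]; v2 <- v2[v2 > 0]
  if (length(v1) < min_expressed || length(v2) < min_expressed) return(NA_real_)
  pooled <- c(v1, v2)
  log10(max(pooled)) - log10(min(pooled))
}

# npIDR per-bin discordance by naive recount, given the implementation's bin
# assignment; monotone adjustment by an explicit loop.
oracle_npidr_bins <- function(s1, s2, bin_index) {
  det <- s1 > 0 | s2 > 0
  d1 <- s1[det]; d2 <- s2[det]
  groups <- sort(unique(bin_index))
  raw <- sapply(groups, function(g) {
    in_g <- bin_index == g
    n_disc <- 0
    for (i in which(in_g)) {
      if ((d1[i] == 0 && d2[i] > 0) || (d1[i] > 0 && d2[i] == 0)) n_disc <- n_disc + 1
    }
    n_disc / sum(in_g)
  })
  adj <- raw
  for (i in seq_along(adj)[-1]) adj[i] <- min(adj[i], adj[i - 1])
  list(raw = raw, adj = adj, groups = groups)
}

# Vls/Vt via an explicit projection matrix P = u u^T on sqrt-rescaled data.
oracle_vls <- function(m) {
  if (ncol(m) == 1L) return(1)   # single transcript: no splicing dimension
  y <- sqrt(m)
  nz <- rowSums(y^2) > 0
  dirs <- t(apply(y[nz, , drop = FALSE], 1, function(r) r / sqrt(sum(r^2))))
  u <- colMeans(dirs)
  u <- u / sqrt(sum(u^2))
  P <- u %*% t(u)
  proj <- y %*% P
  v_ls <- sum(apply(proj, 2, stats::var))
  v_t <- sum(apply(y, 2, stats::var))
  min(max(v_ls / v_t, 0), 1)
}

# distance to nearest gene by exhaustive all-pairs scan
oracle_distance <- function(bin_start, bin_end, gene_starts, gene_ends) {
  best <- Inf
  for (i in seq_along(gene_starts)) {
    gs <- gene_starts[i]; ge <- gene_ends[i]
    if (bin_start < ge && bin_end > gs) return(0L)
    best <- min(best, if (bin_end <= gs) gs - bin_end else bin_start - ge)
  }
  as.integer(best)
}

# mean bin coverage by a position-by-position tally over a piecewise track
oracle_bin_density <- function(cov_df, bin_start, bin_end) {
  pos_vals <- numeric(bin_end - bin_start)
  for (k in seq_len(nrow(cov_df))) {
    idx <- which(seq(bin_start, bin_end - 1) >= cov_df$start[k] &
                   seq(bin_start, bin_end - 1) < cov_df$end[k])
    pos_vals[idx] <- pos_vals[idx] + cov_df$value[k]
  }
  mean(pos_vals)
}

# balanced two-way sums of squares via R's aov as the independent route
oracle_anova_aov <- function(log_m) {
  df <- data.frame(y = as.vector(log_m),
                   gene = factor(rep(rownames(log_m), ncol(log_m))),
                   sample = factor(rep(colnames(log_m), each = nrow(log_m))))
  ss <- summary(stats::aov(y ~ gene + sample, data = df))[[1]][["Sum Sq"]]
  setNames(ss / sum(ss), c("gene", "sample", "residual"))
}

# small GTF writer for fixtures (1-based closed coordinates)
write_gtf <- function(path, rows) {
  lines <- vapply(rows, function(r) {
    sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
            r$chrom, r$type, r$start, r$end, r$strand, r$gene, r$tx)
  }, character(1))
  writeLines(lines, path)
  path
}
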