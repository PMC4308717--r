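# Seeded generators producing every input the pipeline consumes, with known
# ground truth. They emulate the statistical structure of a two-species
# orthologous RNA-seq panel: shared per-orthologue expression baselines, a
# bimodal per-gene dynamic range (a bounded-range constrained class and a
# wide-range unconstrained class), replicated measurements with
# signal-dependent dropout, binomially sampled junction reads, per-gene
# isoform abundance tables, and paired bin/TSS coverage tracks. Every
# generator is a pure function of (config, seed).

#' Simulation configuration
#'
#' Defaults mirror a scaled-down two-species panel: 2 species x 20 samples x
#' 5,000 orthologues, a 2,000-junction panel with 30 samples per species.
#'
#' @param n_genes number of orthologue pairs.
#' @param n_samples samples per species.
#' @param frac_constrained fraction of genes in the constrained class.
#' @param mu_b,sd_b per-gene log10 baseline distribution (shared across
#'   species).
#' @param r total width (log10 units) of the uniform per-sample deviation of
#'   constrained genes; must be < 2 so their true range stays below two
#'   orders of magnitude.
#' @param sd_t s.d. of per-sample tissue effects of unconstrained genes
#'   (chosen so their range exceeds 2 with high probability).
#' @param noise_sd log10 measurement noise s.d.
#' @param dropout_mid,dropout_scale logistic dropout midpoint/scale on the
#'   log10 expression scale (detection probability rises with signal).
#' @param replicate_noise_sd log10 noise between technical replicates.
#' @param n_junctions junction panel size.
#' @param n_junction_samples junction samples per species.
#' @param junction_depth mean split-read depth per junction and sample
#'   (Poisson).
#' @param junction_class_probs probabilities of the four junction regimes
#'   (`constitutive_high`, `constitutive_low`, `constrained_intermediate`,
#'   `variable`).
#' @param theta_range range of the per-junction true splicing-completeness
#'   level.
#' @param n_isoform_genes,n_isoform_samples,max_transcripts isoform panel.
#' @param isoform_noise_sd log10 noise on isoform abundances.
#' @param n_bins orthologous 100-nt bin pairs.
#' @param bin_rho either a single correlation (flat kernel) or `NULL` for the
#'   default class- and distance-dependent kernel.
#' @param mu_density,sd_density log10 bin-density distribution.
#' @param n_mark_genes genes in the chromatin-mark panel.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000L, n_samples = 20L, frac_constrained = 0.46,
                       mu_b = 0.5, sd_b = 1.0, r = 1.2, sd_t = 1.0,
                       noise_sd = 0.05, dropout_mid = -1.5, dropout_scale = 0.5,
                       replicate_noise_sd = 0.1,
                       n_junctions = 2000L, n_junction_samples = 30L,
                       junction_depth = 50,
                       junction_class_probs = c(constitutive_high = 0.55,
                                                constitutive_low = 0.05,
                                                constrained_intermediate = 0.2,
                                                variable = 0.2),
                       theta_range = c(0.7, 1),
                       n_isoform_genes = 200L, n_isoform_samples = 20L,
                       max_transcripts = 5L, isoform_noise_sd = 0.05,
                       n_bins = 10000L, bin_rho = NULL,
                       mu_density = 1.0, sd_density = 1.0,
                       n_mark_genes = 200L) {
  if (r >= 2) stop("infeasible config: constrained range r must be < 2")
  if (frac_constrained < 0 || frac_constrained > 1) stop("frac_constrained not in [0,1]")
  stopifnot(abs(sum(junction_class_probs) - 1) < 1e-8)
  structure(as.list(environment()), class = "sim_config")
}

# detection probability as a function of log10 expression
detect_prob <- function(log10_expr, mid, scale) {
  plogis((log10_expr - mid) / scale)
}

#' Simulate a two-species orthologous expression panel
#'
#' Constrained genes: shared per-gene baseline plus a per-sample deviation
#' uniform on (-r/2, r/2), so the true range is below two orders of
#' magnitude by construction. Unconstrained genes: baseline plus per-sample
#' tissue effects N(0, sd_t^2). Measured values carry lognormal measurement
#' noise and signal-dependent dropout.
#'
#' @param cfg `sim_config`.
#' @param seed RNG seed (mandatory; the output is a pure function of
#'   `(cfg, seed)`).
#' @return list: `m1`, `m2` (`expr_matrix` per species), `orth` (orthology
#'   map), `truth` (per-gene class, true log10 expression per species, true
#'   DNR over the pooled true values).
#' @export
simulate_expression <- function(cfg, seed) {
  stopifnot(inherits(cfg, "sim_config"))
  local_seed(sub_seed(seed, 101L), {
    G <- cfg$n_genes; S <- cfg$n_samples
    ids1 <- sprintf("g%05d_sp1", seq_len(G))
    ids2 <- sprintf("g%05d_sp2", seq_len(G))
    n_cons <- round(cfg$frac_constrained * G)
    cls <- c(rep("constrained", n_cons), rep("unconstrained", G - n_cons))
    base <- rnorm(G, cfg$mu_b, cfg$sd_b)

    true_log <- function() {
      dev <- matrix(0, G, S)
      if (n_cons > 0) {
        dev[cls == "constrained", ] <- runif(n_cons * S, -cfg$r / 2, cfg$r / 2)
      }
      if (n_cons < G) {
        dev[cls == "unconstrained", ] <- rnorm((G - n_cons) * S, 0, cfg$sd_t)
      }
      base + dev
    }
    t1 <- true_log(); t2 <- true_log()
    measure <- function(tl, ids, species) {
      obs <- tl + rnorm(length(tl), 0, cfg$noise_sd)
      keep <- matrix(runif(length(tl)) <
                       detect_prob(tl, cfg$dropout_mid, cfg$dropout_scale),
                     nrow(tl), ncol(tl))
      m <- ifelse(keep, 10^obs, 0)
      dimnames(m) <- list(ids, sprintf("%s_s%02d", species, seq_len(ncol(tl))))
      expression_matrix(m, species = species)
    }
    m1 <- measure(t1, ids1, "sp1")
    m2 <- measure(t2, ids2, "sp2")
    pooled <- cbind(t1, t2)
    true_dnr <- apply(pooled, 1L, function(v) max(v) - min(v))
    list(m1 = m1, m2 = m2, orth = orthology_map(ids1, ids2),
         truth = list(class = setNames(cls, ids1), log_expr1 = t1,
                      log_expr2 = t2, true_dnr = setNames(true_dnr, ids1),
                      baseline = setNames(base, ids1)))
  })
}

#' Simulate a replicate pair from a truth matrix
#'
#' Each replicate is the truth times lognormal noise, zeroed with a
#' signal-dependent (logistic, decreasing in signal) dropout probability.
#'
#' @param m non-negative truth matrix.
#' @param noise_sd log10 replicate noise s.d.
#' @param dropout_mid,dropout_scale logistic detection parameters on log10
#'   signal; `dropout_mid = -Inf` disables dropout.
#' @param seed RNG seed.
#' @return list `rep1`, `rep2` (matrices) and `replicate_of` mapping the
#'   duplicated sample columns to biosamples.
#' @export
simulate_replicates <- function(m, noise_sd = 0.1, dropout_mid = -1.5,
                                dropout_scale = 0.5, seed = 1L) {
  local_seed(sub_seed(seed, 202L), {
    one <- function() {
      lg <- suppressWarnings(log10(m))
      lg[!is.finite(lg)] <- -Inf
      p <- detect_prob(lg, dropout_mid, dropout_scale)
      p[m == 0] <- 0
      keep <- matrix(runif(length(m)) < p, nrow(m), ncol(m))
      out <- m * 10^rnorm(length(m), 0, noise_sd) * keep
      dimnames(out) <- dimnames(m)
      out
    }
    r1 <- one(); r2 <- one()
    samples <- colnames(m)
    list(rep1 = r1, rep2 = r2,
         replicate_of = setNames(rep(samples, 2L),
                                 c(paste0(samples, "_r1"), paste0(samples, "_r2"))))
  })
}

#' Simulate a two-species orthologous junction panel
#'
#' Each junction has a regime: constant high inclusion (psi* > 0.9), constant
#' low (psi* < 0.1), constrained intermediate (psi* constant in (0.2, 0.8),
#' shared across species), or variable (psi* redrawn per sample from a
#' high-variance Beta). Split reads are Binomial(depth, psi*_s) with
#' Poisson-distributed depth; an alternative junction sharing the donor and
#' another sharing the acceptor carry the remaining depth, so the pooled
#' psi estimate equals n/depth. Boundary reads follow the per-junction true
#' completeness theta*.
#'
#' @param cfg `sim_config`.
#' @param seed RNG seed.
#' @return list: `junctions1`, `junctions2` (junction tables), `boundaries1`,
#'   `boundaries2`, `orth` (junction orthology), `truth` (regime, per-sample
#'   true psi, theta*).
#' @export
simulate_junctions <- function(cfg, seed) {
  stopifnot(inherits(cfg, "sim_config"))
  local_seed(sub_seed(seed, 303L), {
    J <- cfg$n_junctions; S <- cfg$n_junction_samples
    regimes <- sample(names(cfg$junction_class_probs), J, replace = TRUE,
                      prob = cfg$junction_class_probs)
    base_psi <- numeric(J)
    base_psi[regimes == "constitutive_high"] <- runif(sum(regimes == "constitutive_high"), 0.92, 0.99)
    base_psi[regimes == "constitutive_low"] <- runif(sum(regimes == "constitutive_low"), 0.01, 0.08)
    base_psi[regimes == "constrained_intermediate"] <- runif(sum(regimes == "constrained_intermediate"), 0.2, 0.8)
    base_psi[regimes == "variable"] <- runif(sum(regimes == "variable"), 0.3, 0.7)
    theta_star <- runif(J, cfg$theta_range[1L], cfg$theta_range[2L])

    psi_paths <- function() {
      p <- matrix(rep(base_psi, S), J, S)
      idx <- which(regimes == "variable")
      if (length(idx)) {
        # Beta with a + b = 1: variance m(1-m)/2, far above the constrained cut
        m <- base_psi[idx]
        p[idx, ] <- rbeta(length(idx) * S, rep(m, S), rep(1 - m, S))
      }
      p
    }
    one_species <- function(sp, p_true) {
      donors <- 1000L + seq_len(J) * 10000L
      acceptors <- donors + 500L
      samples <- sprintf("%s_j%02d", sp, seq_len(S))
      depth <- matrix(rpois(J * S, cfg$junction_depth), J, S)
      n <- matrix(rbinom(J * S, depth, p_true), J, S)
      rows <- list()
      for (s in seq_len(S)) {
        excl <- depth[, s] - n[, s]
        rows[[s]] <- data.frame(
          chrom = "chrJ",
          donor = c(donors, donors, donors - 200L),
          acceptor = c(acceptors, acceptors + 300L, acceptors),
          strand = "+",
          sample = samples[s],
          n = c(n[, s], excl, excl),
          stringsAsFactors = FALSE)
      }
      tab <- do.call(rbind, rows)
      tab <- tab[tab$n > 0 | (tab$donor %in% donors & tab$acceptor %in% acceptors), ]
      # boundary reads at the main junction's two splice sites
      split_tot <- 2 * depth
      e_tot <- matrix(rpois(J * S, pmin(split_tot * (1 - theta_star) /
                                          pmax(theta_star, 1e-6), 1e6)), J, S)
      bnd <- list()
      for (s in seq_len(S)) {
        eD <- rbinom(J, e_tot[, s], 0.5)
        eA <- e_tot[, s] - eD
        bnd[[s]] <- data.frame(
          chrom = "chrJ", pos = c(donors, acceptors),
          side = rep(c("donor", "acceptor"), each = J),
          sample = samples[s], e = c(eD, eA), stringsAsFactors = FALSE)
      }
      main_ids <- paste("chrJ", donors, acceptors, "+", sep = ":")
      list(tab = junction_table(tab), bnd = do.call(rbind, bnd),
           main_ids = main_ids, p_true = p_true)
    }
    sp1 <- one_species("sp1", psi_paths())
    sp2 <- one_species("sp2", psi_paths())
    list(junctions1 = sp1$tab, junctions2 = sp2$tab,
         boundaries1 = sp1$bnd, boundaries2 = sp2$bnd,
         orth = orthology_map(sp1$main_ids, sp2$main_ids),
         truth = list(regime = setNames(regimes, sp1$main_ids),
                      base_psi = setNames(base_psi, sp1$main_ids),
                      theta_star = setNames(theta_star, sp1$main_ids),
                      psi_true1 = sp1$p_true, psi_true2 = sp2$p_true))
  })
}

#' Simulate per-gene isoform abundance matrices
#'
#' Expression-driven genes keep one Dirichlet-drawn proportion vector across
#' all samples while their total output varies widely (log10 s.d. 0.6);
#' splicing-driven genes redraw the proportions per sample at a stable total
#' (log10 s.d. 0.1) — isoform switching without an output change. Abundances
#' carry lognormal noise.
#'
#' @param cfg `sim_config`.
#' @param seed RNG seed.
#' @return list: `matrices` (named list of samples x transcripts matrices),
#'   `regimes` (named `expression_driven`/`splicing_driven`).
#' @export
simulate_isoforms <- function(cfg, seed) {
  stopifnot(inherits(cfg, "sim_config"))
  local_seed(sub_seed(seed, 404L), {
    G <- cfg$n_isoform_genes; S <- cfg$n_isoform_samples
    rdirichlet1 <- function(k) {
      g <- stats::rgamma(k, shape = 1.5)
      g / sum(g)
    }
    regimes <- sample(c("expression_driven", "splicing_driven"), G, replace = TRUE)
    ids <- sprintf("iso%04d", seq_len(G))
    mats <- vector("list", G)
    names(mats) <- ids
    for (i in seq_len(G)) {
      T_ <- sample.int(cfg$max_transcripts, 1L)
      totals <- 10^rnorm(S, 1, if (regimes[i] == "expression_driven") 0.6 else 0.1)
      props <- if (regimes[i] == "expression_driven" || T_ == 1L) {
        matrix(rep(rdirichlet1(T_), each = S), S, T_)
      } else {
        t(vapply(seq_len(S), function(s) rdirichlet1(T_), numeric(T_)))
      }
      m <- totals * props * 10^matrix(rnorm(S * T_, 0, cfg$isoform_noise_sd), S, T_)
      dimnames(m) <- list(sprintf("s%02d", seq_len(S)), sprintf("%s.t%d", ids[i], seq_len(T_)))
      mats[[i]] <- m
    }
    list(matrices = mats, regimes = setNames(regimes, ids))
  })
}

#' Simulate paired coverage tracks, bin pairs and TSS mark signal
#'
#' Orthologous 100-nt bin densities are drawn log10-bivariate-normal with a
#' correlation given by a flat `bin_rho` or by a class- and
#' distance-dependent kernel (exonic 0.75, intronic 0.6, intergenic 0.45
#' decaying with distance to the nearest gene, e-folding 20 kb). TSS mark
#' coverage is a per-gene amplitude times a Gaussian bump at the TSS;
#' constrained genes share the amplitude across species, unconstrained genes
#' draw it independently.
#'
#' @param cfg `sim_config`.
#' @param seed RNG seed.
#' @return list: `bin_pairs` (BinPairTable data.frame), `coverage1`,
#'   `coverage2` (bedGraph-style data.frames over the bin tiling), `gm1`,
#'   `gm2` (mark-panel gene models), `mark_cov1`, `mark_cov2` (RleList TSS
#'   coverage per species), `orth_marks`, `mark_class`, `truth`.
#' @export
simulate_tracks <- function(cfg, seed) {
  stopifnot(inherits(cfg, "sim_config"))
  local_seed(sub_seed(seed, 505L), {
    B <- cfg$n_bins
    cls <- sample(c("exonic", "intronic", "intergenic"), B, replace = TRUE,
                  prob = c(0.15, 0.25, 0.6))
    dist <- ifelse(cls == "intergenic", round(stats::rexp(B, 1 / 20000)), 0L)
    rho <- if (!is.null(cfg$bin_rho)) {
      rep(cfg$bin_rho, B)
    } else {
      base <- c(exonic = 0.75, intronic = 0.6, intergenic = 0.45)[cls]
      unname(base * exp(-dist / 20000))
    }
    z1 <- rnorm(B)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(B)
    d1 <- 10^(cfg$mu_density + cfg$sd_density * z1)
    d2 <- 10^(cfg$mu_density + cfg$sd_density * z2)
    cons_score <- pmin(pmax(0.5 + 0.3 * z1 / 2 + rnorm(B, 0, 0.15), 0), 1)
    st <- (seq_len(B) - 1L) * 100L
    bin_pairs <- data.frame(
      chrom1 = "chrB1", start1 = st, chrom2 = "chrB2", start2 = st,
      density1 = d1, density2 = d2, region_class = cls,
      distance_to_gene = dist, conservation_score = cons_score,
      stringsAsFactors = FALSE)
    cov_df <- function(d, ch) {
      data.frame(chrom = ch, start = st, end = st + 100L, value = d,
                 stringsAsFactors = FALSE)
    }

    # chromatin-mark panel: genes every 10 kb on a dedicated chromosome
    Gm <- cfg$n_mark_genes
    gene_df <- function(ch) {
      start <- 5000L + (seq_len(Gm) - 1L) * 10000L
      strand <- rep(c("+", "-"), length.out = Gm)
      data.frame(gene_id = sprintf("mk%04d_%s", seq_len(Gm), ch),
                 chrom = ch, start = start, end = start + 2000L,
                 strand = strand, stringsAsFactors = FALSE)
    }
    g1 <- gene_df("chrM1"); g2 <- gene_df("chrM2")
    exon_df <- function(g) g[, c("gene_id", "chrom", "start", "end")]
    gm1 <- gene_models(g1, exon_df(g1))
    gm2 <- gene_models(g2, exon_df(g2))
    mark_class <- setNames(sample(c("constrained", "unconstrained"), Gm, TRUE),
                           g1$gene_id)
    amp1 <- setNames(10^rnorm(Gm, 1, 0.5), g1$gene_id)
    amp2 <- setNames(ifelse(mark_class == "constrained", amp1, 10^rnorm(Gm, 1, 0.5)),
                     g2$gene_id)
    chrom_len <- max(g1$end) + 5000L
    bump <- dnorm(seq(-500, 499), 0, 150)
    bump <- bump / max(bump)
    mark_cov <- function(g, amp) {
      x <- numeric(chrom_len)
      for (i in seq_len(nrow(g))) {
        tss <- if (g$strand[i] == "+") g$start[i] else g$end[i] - 1L
        w <- (tss - 500L):(tss + 499L)
        x[w + 1L] <- x[w + 1L] + amp[i] * bump +
          abs(rnorm(1000L, 0, 0.05 * amp[i]))
      }
      IRanges::RleList(setNames(list(S4Vectors::Rle(x)), g$chrom[1L]), compress = FALSE)
    }
    list(bin_pairs = bin_pairs,
         coverage1 = cov_df(d1, "chrB1"), coverage2 = cov_df(d2, "chrB2"),
         gm1 = gm1, gm2 = gm2,
         mark_cov1 = mark_cov(g1, amp1), mark_cov2 = mark_cov(g2, amp2),
         orth_marks = orthology_map(g1$gene_id, g2$gene_id),
         mark_class = mark_class,
         truth = list(rho = rho, region_class = cls, distance = dist,
                      amp1 = amp1, amp2 = amp2))
  })
}
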