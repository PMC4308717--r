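# toy junction table builder: one sample, plus strand
toy_junctions <- function(rows, sample = "s1") {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = "chr1", donor = r[1], acceptor = r[2], strand = "+",
               sample = sample, n = r[3])
  }))
  junction_table(df)
}

test_that("psi5/psi3/pooled psi follow the intron-centric formulas exactly", {
  # n(D,A)=8, alternative donor partner n(D,A')=2, unique acceptor usage
  jt <- toy_junctions(list(c(100, 500, 8), c(100, 900, 2)))
  pr <- compute_psi(jt, min_count = 5L)
  main <- pr$per_sample[pr$per_sample$junction_id == "chr1:100:500:+", ]
  expect_equal(main$psi5, 8 / 10)
  expect_equal(main$psi3, 1)
  expect_equal(main$psi, 16 / 18)

  # below min_count the estimate is NA, not 0
  jt5 <- toy_junctions(list(c(100, 500, 5)))
  expect_true(is.na(compute_psi(jt5, min_count = 10L)$per_sample$psi))
  expect_equal(compute_psi(jt5, min_count = 5L)$per_sample$psi, 1)
})

test_that("psi estimates a two-way inclusion probability within binomial error", {
  set.seed(13)
  depth <- 1000
  n_incl <- rbinom(1, depth, 0.3)
  jt <- toy_junctions(list(c(100, 500, n_incl),        # inclusion junction
                           c(100, 900, depth - n_incl),  # alt acceptor
                           c(50, 500, depth - n_incl)))  # alt donor
  pr <- compute_psi(jt)
  psi <- pr$per_sample$psi[pr$per_sample$junction_id == "chr1:100:500:+"]
  expect_lt(abs(psi - 0.3), 0.05)
})

test_that("donor-wise psi5 sums to one over each donor's junctions", {
  set.seed(17)
  for (rep in 1:5) {
    rows <- list()
    for (d in 1:6) {
      k <- sample(1:4, 1)
      accs <- sort(sample(seq(2000, 9000, 100), k))
      for (a in accs) rows[[length(rows) + 1]] <- c(d * 10000, d * 10000 + a, sample(10:80, 1))
    }
    pr <- compute_psi(toy_junctions(rows), min_count = 1L)
    ps <- pr$per_sample
    donors <- sub(":(\\d+):\\d+:.*$", ":\\1", ps$junction_id)
    sums <- tapply(ps$psi5, donors, sum)
    expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
    expect_true(all(ps$psi >= 0 & ps$psi <= 1))
    expect_true(all(ps$psi >= pmin(ps$psi5, ps$psi3) - 1e-12 &
                      ps$psi <= pmax(ps$psi5, ps$psi3) + 1e-12))
  }
})

test_that("theta is split reads over split plus boundary reads", {
  jt <- toy_junctions(list(c(100, 500, 90)))
  bnd <- data.frame(chrom = "chr1", pos = c(100, 500), side = c("donor", "acceptor"),
                    sample = "s1", e = c(10, 10))
  pr <- compute_theta(compute_psi(jt), bnd)
  expect_equal(pr$per_sample$theta, 180 / 200)

  bnd0 <- transform(bnd, e = 0)
  pr0 <- compute_theta(compute_psi(jt), bnd0)
  expect_equal(pr0$per_sample$theta, 1)

  # all reads unspliced: theta 0 (or NA below min_count)
  jt0 <- toy_junctions(list(c(100, 500, 0)))
  bnd_big <- transform(bnd, e = 50)
  prz <- compute_theta(compute_psi(jt0), bnd_big)
  expect_equal(prz$per_sample$theta, 0)
  prz_na <- compute_theta(compute_psi(jt0), transform(bnd, e = 2), min_count = 10)
  expect_true(is.na(prz_na$per_sample$theta))

  # missing boundary records are warned about and treated as zero
  expect_warning(compute_theta(compute_psi(jt), bnd[1, ]), "missing")
})

test_that("junction classification follows the all-samples inclusion rules", {
  # alternative partners on both sides so pooled psi of the main junction is
  # exactly n/100
  mk_profile <- function(psis_by_sample) {
    rows <- list()
    for (s in seq_along(psis_by_sample)) {
      p <- psis_by_sample[[s]]
      n <- round(100 * p)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = "chr1", donor = c(100, 100, 50), acceptor = c(500, 900, 500),
        strand = "+", sample = names(psis_by_sample)[s], n = c(n, 100 - n, 100 - n))
    }
    compute_psi(junction_table(do.call(rbind, rows)))
  }
  species <- c(h1 = "h", h2 = "h", m1 = "m", m2 = "m")
  hi <- mk_profile(list(h1 = 0.90, h2 = 0.92, m1 = 0.95, m2 = 0.99))
  cls <- classify_junctions(hi, species)
  expect_equal(as.character(cls$class[cls$junction_id == "chr1:100:500:+"]),
               "constitutive_high")
  lo <- mk_profile(list(h1 = 0.01, h2 = 0.05, m1 = 0.1, m2 = 0.05))
  cls_lo <- classify_junctions(lo, species)
  expect_equal(as.character(cls_lo$class[cls_lo$junction_id == "chr1:100:500:+"]),
               "constitutive_low")
  mix <- mk_profile(list(h1 = 0.9, h2 = 0.5, m1 = 0.95, m2 = 0.9))
  cls_mx <- classify_junctions(mix, species)
  expect_equal(as.character(cls_mx$class[cls_mx$junction_id == "chr1:100:500:+"]),
               "variable")
  # too few usable samples in one species -> unclassified
  one <- mk_profile(list(h1 = 0.9, m1 = 0.9, m2 = 0.9))
  cls_un <- classify_junctions(one, c(h1 = "h", m1 = "m", m2 = "m"))
  expect_true(all(cls_un$class == "unclassified"))
})

test_that("constrained-junction rule applies the Bernoulli variance bound", {
  df <- data.frame(junction_id = c("j1", "j2", "j3"),
                   mean_psi = c(0.5, 0.5, 0.95),
                   var_psi = c(0.04, 0.09, 0.001),
                   n_usable = 10,
                   class = factor(rep("variable", 3),
                                  levels = c("constitutive_high", "constitutive_low",
                                             "variable", "unclassified")))
  fl <- constrained_junctions(df)
  # v = 0.04 <= 0.2 * 0.25; v = 0.09 > 0.05; m = 0.95 outside (0.15, 0.85)
  expect_equal(fl$constrained, c(TRUE, FALSE, FALSE))
  # alternating 0.2/0.8 psi: mean 0.5, variance 0.1 (n-1 denominator), above
  # the 0.05 bound, so not constrained
  p <- rep(c(0.2, 0.8), 5)
  expect_equal(var(p), 0.1)
  expect_gt(var(p), 0.2 * 0.5 * 0.5)
  # constitutive junctions are never flagged
  df$class[1] <- "constitutive_high"
  expect_false(constrained_junctions(df)$constrained[1])
})

test_that("constrained-junction detection has high power and low false-flag rate", {
  set.seed(13)
  n_rep <- 400; S <- 60; depth <- 50   # 30 samples per species, pooled
  # constant psi = 0.5 junctions
  n <- matrix(rbinom(n_rep * S, depth, 0.5), n_rep)
  psi_hat <- n / depth
  m <- rowMeans(psi_hat); v <- apply(psi_hat, 1, var)
  flagged <- m > 0.15 & m < 0.85 & v <= 0.2 * m * (1 - m)
  expect_gte(mean(flagged), 0.9)
  # block psi in {0.2, 0.8}
  p_block <- matrix(rep(c(0.2, 0.8), each = S / 2), n_rep, S, byrow = TRUE)
  nb <- matrix(rbinom(n_rep * S, depth, p_block), n_rep)
  psib <- nb / depth
  mb <- rowMeans(psib); vb <- apply(psib, 1, var)
  flagged_b <- mb > 0.15 & mb < 0.85 & vb <= 0.2 * mb * (1 - mb)
  expect_lte(mean(flagged_b), 0.01)
})

test_that("orthologous junction concordance is exact, null and attenuated correctly", {
  cfg <- sim_config(n_junctions = 300L, n_junction_samples = 15L)
  jx <- simulate_junctions(cfg, seed = 19L)
  p1 <- compute_psi(jx$junctions1)
  cc_self <- ortho_junction_concordance(p1, p1,
                                        orthology_map(jx$orth$id1, jx$orth$id1))
  expect_equal(cc_self$cc_logit_mean, 1, tolerance = 1e-12)
  expect_equal(cc_self$cc_sd, 1, tolerance = 1e-12)

  # independent psi across species -> near-zero correlation
  set.seed(17)
  n_j <- 5000; S <- 10; depth <- 80
  mk_tab <- function() {
    p <- runif(n_j, 0.1, 0.9)
    rows <- list()
    for (s in 1:S) {
      n <- rbinom(n_j, depth, p)
      rows[[s]] <- data.frame(chrom = "chrT", donor = 1:n_j * 1000,
                              acceptor = 1:n_j * 1000 + 500, strand = "+",
                              sample = paste0("s", s),
                              n = n)
      rows[[S + s]] <- data.frame(chrom = "chrT", donor = 1:n_j * 1000,
                                  acceptor = 1:n_j * 1000 + 700, strand = "+",
                                  sample = paste0("s", s), n = depth - n)
    }
    compute_psi(junction_table(do.call(rbind, rows)))
  }
  pa <- mk_tab(); pb <- mk_tab()
  ids <- paste("chrT", 1:n_j * 1000, 1:n_j * 1000 + 500, "+", sep = ":")
  cc_null <- ortho_junction_concordance(pa, pb, orthology_map(ids, ids))
  expect_lt(abs(cc_null$cc_logit_mean), 0.05)

  # shared true psi: correlation attenuated by binomial sampling noise,
  # estimated numerically from a parallel draw of the generator
  both <- simulate_junctions(cfg, seed = 19L)
  c12 <- ortho_junction_concordance(compute_psi(both$junctions1),
                                    compute_psi(both$junctions2), both$orth)
  keep <- both$truth$regime %in% c("constrained_intermediate", "variable")
  # analytic route: correlate logit mean psi of two independent measurement
  # draws around the same truth, via a direct Monte Carlo of the generator
  jx_b <- simulate_junctions(cfg, seed = 907L)
  c12_b <- ortho_junction_concordance(compute_psi(jx_b$junctions1),
                                      compute_psi(jx_b$junctions2), jx_b$orth)
  expect_lt(abs(c12$cc_logit_mean - c12_b$cc_logit_mean), 0.05)
  expect_gt(c12$cc_logit_mean, 0.8)
})
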