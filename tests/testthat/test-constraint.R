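mk_mat <- function(vals, ids, samples, species = "sp") {
  m <- matrix(vals, nrow = length(ids), byrow = TRUE,
              dimnames = list(ids, samples))
  expression_matrix(m, species = species)
}

test_that("DNR follows the log10 max/min rule and the two-sample rule", {
  m1 <- mk_mat(c(10, 100), "gA", c("h1", "h2"), "human")
  m2 <- mk_mat(c(1, 50), "gAm", c("m1", "m2"), "mouse")
  orth <- orthology_map("gA", "gAm")
  d <- compute_dnr(m1, m2, orth)
  expect_equal(d$dnr, 2)

  # all non-zero values equal -> DNR 0
  d0 <- compute_dnr(mk_mat(c(5, 5), "gA", c("h1", "h2")),
                    mk_mat(c(5, 5), "gAm", c("m1", "m2")), orth)
  expect_equal(d0$dnr, 0)

  # one species with a single non-zero value -> undefined
  du <- compute_dnr(mk_mat(c(10, 0, 0), "gA", c("h1", "h2", "h3")),
                    mk_mat(c(3, 4), "gAm", c("m1", "m2")), orth)
  expect_true(is.na(du$dnr))

  # id missing from a matrix -> undefined with warning
  expect_warning(
    dm <- compute_dnr(m1, m2, orthology_map(c("gA", "gX"), c("gAm", "gXm"))),
    "missing")
  expect_true(is.na(dm$dnr[2]))
})

test_that("DNR is invariant to sample order, species swap and global scaling", {
  set.seed(11)
  n <- 50
  v1 <- matrix(rlnorm(n * 6), n, dimnames = list(paste0("a", 1:n), paste0("h", 1:6)))
  v2 <- matrix(rlnorm(n * 4), n, dimnames = list(paste0("b", 1:n), paste0("m", 1:4)))
  orth <- orthology_map(rownames(v1), rownames(v2))
  d <- compute_dnr(expression_matrix(v1, "h"), expression_matrix(v2, "m"), orth)
  # sample relabelling/reordering
  perm <- sample(6)
  d_p <- compute_dnr(expression_matrix(v1[, perm], "h"),
                     expression_matrix(v2, "m"), orth)
  expect_equal(d_p$dnr, d$dnr)
  # species swap
  d_s <- compute_dnr(expression_matrix(v2, "m"), expression_matrix(v1, "h"),
                     orthology_map(rownames(v2), rownames(v1)))
  expect_equal(d_s$dnr, d$dnr)
  # global rescaling
  d_k <- compute_dnr(expression_matrix(7 * v1, "h"),
                     expression_matrix(7 * v2, "m"), orth)
  expect_equal(d_k$dnr, d$dnr, tolerance = 1e-12)
  # oracle equality
  orc <- sapply(1:n, function(i) oracle_dnr(v1[i, ], v2[i, ]))
  expect_equal(d$dnr, orc)
})

test_that("constraint calls partition defined DNR at the threshold boundary", {
  tab <- structure(data.frame(id1 = c("a", "b", "c"), id2 = c("x", "y", "z"),
                              n_expressed1 = c(3, 3, 1), n_expressed2 = c(3, 3, 3),
                              max_rpkm = NA, min_rpkm = NA,
                              dnr = c(2.0, 2.01, NA)),
                   class = c("dnr_table", "data.frame"))
  calls <- classify_constraint(tab, threshold = 2)
  expect_equal(as.character(calls$call), c("constrained", "unconstrained", "undefined"))
  cnt <- attr(calls, "counts")
  expect_equal(unname(cnt["constrained"] + cnt["unconstrained"]),
               sum(!is.na(tab$dnr)))
  expect_error(classify_constraint(tab, threshold = -1), "threshold")
})

test_that("expression matching produces equal-size subsets with matched distributions", {
  set.seed(1)
  n <- 800
  ids <- paste0("g", 1:n)
  cls <- rep(c("constrained", "unconstrained"), each = n / 2)
  # shifted means between classes
  e1 <- rnorm(n, ifelse(cls == "constrained", 1.5, 0.5), 1)
  e2 <- e1 + rnorm(n, 0, 0.3)
  names(e1) <- names(e2) <- ids
  tab <- data.frame(id1 = ids, id2 = ids, dnr = 1,
                    call = factor(cls, levels = c("constrained", "unconstrained", "undefined")))
  sets <- match_by_expression(tab, e1, e2, bins = 10, seed = 1)
  expect_equal(length(sets$constrained), length(sets$unconstrained))
  expect_gt(length(sets$constrained), 50)
  expect_equal(anyDuplicated(sets$constrained), 0L)
  ks1 <- suppressWarnings(ks.test(e1[sets$constrained], e1[sets$unconstrained]))
  ks2 <- suppressWarnings(ks.test(e2[sets$constrained], e2[sets$unconstrained]))
  expect_lte(unname(ks1$statistic), 0.05)
  expect_lte(unname(ks2$statistic), 0.05)

  # identical class-wise expression values: everything is kept
  vals <- rnorm(n / 2)
  e_same <- c(vals, vals); names(e_same) <- ids   # class multisets coincide
  sets2 <- match_by_expression(tab, e_same, e_same, bins = 4, seed = 1)
  expect_equal(length(sets2$constrained), n / 2)

  # disjoint ranges: both subsets empty (equal class sizes put a decile edge
  # in the gap between the clusters)
  e_dis <- c(rnorm(n / 2, -10), rnorm(n / 2, 10)); names(e_dis) <- ids
  expect_warning(sets3 <- match_by_expression(tab, e_dis, e_dis, bins = 10, seed = 1),
                 "empty")
  expect_equal(length(sets3$constrained), 0L)
})

test_that("output fraction is the length-weighted constrained share of expression", {
  m <- mk_mat(c(4, 4, 6, 6), c("g1", "g2"), c("s1", "s2"))
  lens <- c(g1 = 10, g2 = 15)
  # constrained output 4*10 = 40 of total 4*10 + 6*15 = 130
  fr <- output_fraction(m, lens, "g1")
  expect_equal(unname(fr), rep(40 / 130, 2))
  expect_equal(unname(output_fraction(m, lens, c("g1", "g2"))), c(1, 1))
  expect_equal(unname(output_fraction(m, lens, character(0))), c(0, 0))
  # additivity over disjoint subsets
  expect_equal(output_fraction(m, lens, "g1") + output_fraction(m, lens, "g2"),
               output_fraction(m, lens, c("g1", "g2")))
  # nothing expressed -> undefined
  m0 <- mk_mat(c(0, 0, 5, 0), c("g1", "g2"), c("s1", "s2"))
  expect_true(is.na(output_fraction(m0, lens, "g1")["s2"]))
  expect_error(output_fraction(m, c(g1 = 10), "g1"), "length missing")
})

test_that("two-way variance decomposition matches aov and sums to one", {
  m_gene <- matrix(c(1, 1, 3, 3), 2, byrow = TRUE,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  fr <- anova_decomposition(m_gene)
  expect_equal(unname(fr["gene"]), 1)
  expect_equal(unname(fr["sample"]), 0)

  m_sample <- matrix(c(1, 2, 1, 2), 2, byrow = TRUE,
                     dimnames = list(c("g1", "g2"), c("s1", "s2")))
  fr2 <- anova_decomposition(m_sample)
  expect_equal(unname(fr2["sample"]), 1)
  expect_equal(unname(fr2["gene"]), 0)

  set.seed(50)
  m <- matrix(rnorm(500), 50, 10,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:10)))
  fr3 <- anova_decomposition(m)
  expect_equal(sum(fr3), 1, tolerance = 1e-10)
  expect_true(all(fr3 >= 0 & fr3 <= 1))
  expect_equal(fr3, oracle_anova_aov(m), tolerance = 1e-10)
  expect_error(anova_decomposition(m[1, , drop = FALSE]), "at least 2")
})

test_that("expression breadth counts non-zero samples", {
  m <- mk_mat(c(1, 0, 2, 0, 0, 0), c("g1", "g2"), c("s1", "s2", "s3"))
  b <- expression_breadth(m)
  expect_equal(unname(b), c(2L, 0L))
})

test_that("breadth of constrained genes is stochastically higher on generator truth", {
  cfg <- sim_config(n_genes = 800L, n_samples = 10L)
  sim <- simulate_expression(cfg, seed = 4L)
  b <- expression_breadth(sim$m1) + expression_breadth(sim$m2)[match(
    sim$orth$id2, rownames(sim$m2))]
  cls <- sim$truth$class[names(expression_breadth(sim$m1))]
  # constrained genes avoid the extreme-low tissue states that drop out
  wt <- wilcox.test(b[cls == "constrained"], b[cls == "unconstrained"],
                    alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("cross-species correlation behaves on exact and sampled data", {
  avg <- setNames(rnorm(100), paste0("g", 1:100))
  expect_equal(cross_species_corr(avg, avg), 1)
  set.seed(3)
  n <- 5000
  x <- rnorm(n)
  y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(n)
  names(x) <- names(y) <- paste0("g", 1:n)
  cc <- cross_species_corr(x, y)
  expect_true(cc >= 0.78 && cc <= 0.82)
  expect_error(cross_species_corr(x[1:2], y[1:2]), "at least 3")
  const <- setNames(rep(1, 10), paste0("g", 1:10))
  expect_warning(ccc <- cross_species_corr(const, x[1:10]), "zero variance")
  expect_true(is.na(ccc))
})

test_that("antisense ratio summarises a/(a+s) per gene", {
  s <- matrix(5, 2, 3, dimnames = list(c("g1", "g2"), c("x", "y", "z")))
  a <- s
  r <- antisense_ratio(s, a)
  expect_equal(r$mean_ratio, c(0.5, 0.5))
  expect_equal(r$sd_ratio, c(0, 0))
  a0 <- a * 0
  expect_equal(antisense_ratio(s, a0)$mean_ratio, c(0, 0))
  both0 <- antisense_ratio(s * 0, a0)
  expect_true(all(is.na(both0$mean_ratio)))
})

test_that("cross-species antisense correlation matches the analytic attenuation", {
  set.seed(11)
  n_genes <- 2000; n_samples <- 12; depth <- 60
  p_true <- rbeta(n_genes, 2, 6)      # shared true antisense fraction
  sim_species <- function() {
    a <- matrix(rbinom(n_genes * n_samples, depth, p_true), n_genes)
    s <- depth - a
    dimnames(a) <- dimnames(s) <- list(paste0("g", 1:n_genes), paste0("s", 1:n_samples))
    antisense_ratio(s, a)$mean_ratio
  }
  r1 <- sim_species(); r2 <- sim_species()
  cc <- cor(r1, r2)
  # attenuation: cc = var(p) / (var(p) + E[p(1-p)/depth]/n_samples)
  v_t <- var(p_true)
  v_n <- mean(p_true * (1 - p_true) / depth) / n_samples
  expect_lt(abs(cc - v_t / (v_t + v_n)), 0.05)
})

test_that("localization statistics recover the log-ratio moments", {
  ids <- paste0("g", 1:5)
  N <- matrix(4, 5, 6, dimnames = list(ids, paste0("s", 1:6)))
  C <- N
  st <- localization_stats(N, C)
  expect_equal(st$mean_log_ratio, rep(0, 5))
  expect_equal(st$sd_log_ratio, rep(0, 5))
  st10 <- localization_stats(10 * C, C)
  expect_equal(st10$mean_log_ratio, rep(1, 5))
  expect_false(any(st10$cytosolic))

  # lognormal N and C with known log10-ratio s.d., 50 samples, many genes
  set.seed(5)
  n_genes <- 400; S <- 50; true_sd <- 0.3
  idsg <- paste0("g", 1:n_genes)
  lr <- matrix(rnorm(n_genes * S, 0.2, true_sd), n_genes)
  Cm <- matrix(10^rnorm(n_genes * S, 0, 0.4), n_genes,
               dimnames = list(idsg, paste0("s", 1:S)))
  Nm <- Cm * 10^lr
  dimnames(Nm) <- dimnames(Cm)
  st2 <- localization_stats(Nm, Cm)
  expect_lt(abs(mean(st2$sd_log_ratio) / true_sd - 1), 0.05)
})
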