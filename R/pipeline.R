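# End-to-end driver: simulate a two-species panel, run every analysis stage
# and write the standard-format outputs. Deterministic given (cfg, seed).

#' Run the full constraint-detection pipeline on simulated data
#'
#' Generates a synthetic two-species panel, applies npIDR replicate
#' filtering, computes DNR, fits the mixture and classifies genes, builds
#' expression-matched sets, computes output fractions, the ANOVA variance
#' decomposition, cross-species correlations, the junction psi/theta panel
#' with constrained-junction calls, the isoform Vls/Vt cohort, and the
#' bin-pair and metagene conservation analyses. All outputs are returned
#' and, when `outdir` is given, written as TSV/JSON.
#'
#' @param seed master RNG seed; every stage derives its own sub-seed from it.
#' @param cfg `sim_config`.
#' @param outdir optional output directory (created if missing).
#' @return list of stage results (invisibly when writing).
#' @export
run_pipeline <- function(seed = 1L, cfg = sim_config(), outdir = NULL) {
  sim <- simulate_expression(cfg, seed)

  # replicate filtering on each species' measured panel
  filt <- lapply(list(sp1 = sim$m1, sp2 = sim$m2), function(m) {
    reps <- simulate_replicates(unclass(m), noise_sd = cfg$replicate_noise_sd,
                                dropout_mid = cfg$dropout_mid,
                                dropout_scale = cfg$dropout_scale,
                                seed = sub_seed(seed, match(attr(m, "species"), c("sp1", "sp2"))))
    both <- cbind(reps$rep1, reps$rep2)
    colnames(both) <- names(reps$replicate_of)
    em <- expression_matrix(both, species = attr(m, "species"),
                            replicate_of = reps$replicate_of)
    filter_reproducible(em, threshold = 0.1)
  })

  dnr <- compute_dnr(filt$sp1, filt$sp2, sim$orth)
  fit <- fit_dnr_mixture(dnr$dnr[!is.na(dnr$dnr)], seed = sub_seed(seed, 11L))
  calls <- classify_constraint(dnr, fit$threshold)

  truth_class <- sim$truth$class[calls$id1]
  defined <- calls$call != "undefined"
  accuracy <- mean(as.character(calls$call[defined]) == truth_class[defined])

  avg1 <- log_avg_expression(filt$sp1)
  avg2 <- log_avg_expression(filt$sp2)
  names(avg2) <- calls$id1[match(names(avg2), calls$id2)]
  matched <- match_by_expression(calls, avg1, avg2, seed = sub_seed(seed, 12L))

  lengths1 <- setNames(rep(1500, nrow(filt$sp1)), rownames(filt$sp1))
  out_frac <- output_fraction(filt$sp1, lengths1,
                              calls$id1[calls$call == "constrained"])

  aov_frac <- lapply(filt, function(m) {
    anova_decomposition(log10(replace_zeros(unclass(m))))
  })

  cons_ids <- intersect(matched$constrained, names(avg1))
  uncons_ids <- intersect(matched$unconstrained, names(avg1))
  cc <- list(
    constrained = cross_species_corr(avg1, avg2, cons_ids),
    unconstrained = cross_species_corr(avg1, avg2, uncons_ids))

  jx <- simulate_junctions(cfg, seed)
  prof1 <- compute_theta(compute_psi(jx$junctions1), jx$boundaries1)
  prof2 <- compute_theta(compute_psi(jx$junctions2), jx$boundaries2)
  pooled_tab <- junction_table(rbind(
    as.data.frame(jx$junctions1)[, 1:6], as.data.frame(jx$junctions2)[, 1:6]))
  pooled_prof <- compute_psi(pooled_tab)
  species_map <- setNames(
    sub("_j.*", "", unique(pooled_prof$per_sample$sample)),
    unique(pooled_prof$per_sample$sample))
  jcls <- constrained_junctions(classify_junctions(pooled_prof, species_map))
  # restrict to the main (orthologous) junctions
  jcls_main <- jcls[jcls$junction_id %in% jx$orth$id1, ]
  concord <- ortho_junction_concordance(prof1, prof2, jx$orth)

  iso <- simulate_isoforms(cfg, seed)
  iso_calls <- setNames(ifelse(iso$regimes == "expression_driven",
                               "constrained", "unconstrained"),
                        names(iso$regimes))
  vls <- vls_cohort(iso$matrices, iso_calls, B = 50L, seed = sub_seed(seed, 13L))

  trk <- simulate_tracks(cfg, seed)
  bin_cc <- binpair_correlation(trk$bin_pairs)
  groups <- split(names(trk$mark_class), trk$mark_class)
  prof_meta <- metagene_profile(list(trk$mark_cov1), trk$gm1, groups,
                                anchor = "TSS", mark = "H3K4me3")
  wm1 <- gene_window_means(list(trk$mark_cov1), trk$gm1)
  wm2 <- gene_window_means(list(trk$mark_cov2), trk$gm2)
  div <- mark_divergence(wm1, wm2, trk$orth_marks, classes = trk$mark_class)

  res <- list(
    sim = sim, filtered = filt, dnr = dnr, mixture = fit, calls = calls,
    accuracy = accuracy, matched = matched, output_fraction = out_frac,
    anova = aov_frac, cross_species_cc = cc,
    junction_classes = jcls_main, junction_concordance = concord,
    vls = vls, bin_correlation = bin_cc, metagene = prof_meta,
    mark_divergence = div, seed = seed)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, f) {
      num <- vapply(df, is.numeric, logical(1))
      df[num] <- lapply(df[num], function(v) sprintf("%.6g", v))
      write.table(df, file.path(outdir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    w(as.data.frame(calls), "dnr_calls.tsv")
    jsonlite::write_json(
      list(w = fit$w, mu = fit$mu, sigma = fit$sigma,
           threshold = fit$threshold, loglik = fit$loglik, n = fit$n),
      file.path(outdir, "mixture.json"), auto_unbox = FALSE, digits = 10)
    w(data.frame(sample = names(out_frac), fraction = unname(out_frac)),
      "output_fraction.tsv")
    w(jcls_main, "junction_classes.tsv")
    w(vls$per_gene, "vls.tsv")
    w(as.data.frame(prof_meta), "metagene.tsv")
    w(div$per_gene, "mark_divergence.tsv")
    write_matrix(unclass(filt$sp1), file.path(outdir, "expression_sp1.tsv"),
                 id_col = "gene_id")
    return(invisible(res))
  }
  res
}
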