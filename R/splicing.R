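# Intron-centric splicing metrics. For a junction joining donor D to
# acceptor A with split-read count n(D,A):
#   psi5 = n(D,A) / sum_{A'} n(D,A')          (donor-side inclusion)
#   psi3 = n(D,A) / sum_{D'} n(D',A)          (acceptor-side inclusion)
#   psi  = 2 n(D,A) / (sum_{A'} n(D,A') + sum_{D'} n(D',A))   (pooled)
#   theta = split / (split + e(D) + e(A))     (completeness of splicing)
# where e() counts reads spanning the exon-intron boundary of a splice site.
# Estimates from fewer than `min_count` denominator reads are NA.

#' Percent-spliced-in from junction split-read counts
#'
#' @param junctions `junction_table` (see [read_junctions()]).
#' @param min_count minimum denominator read count below which a proportion
#'   is `NA` rather than a noisy estimate (default 10).
#' @return object of class `psi_profile`: list with `per_sample` (data.frame
#'   `junction_id, sample, n, den5, den3, psi5, psi3, psi, theta`) and
#'   `junctions` (unique junction metadata). `theta` is `NA` until
#'   [compute_theta()] fills it.
#' @export
compute_psi <- function(junctions, min_count = 10L) {
  df <- as.data.frame(junctions)
  if (any(df$n < 0)) stop("negative split-read count")
  donor_key <- paste(df$chrom, df$donor, df$strand, df$sample, sep = ":")
  acc_key <- paste(df$chrom, df$acceptor, df$strand, df$sample, sep = ":")
  den5 <- stats::ave(df$n, donor_key, FUN = sum)
  den3 <- stats::ave(df$n, acc_key, FUN = sum)
  psi5 <- ifelse(den5 >= min_count, df$n / den5, NA_real_)
  psi3 <- ifelse(den3 >= min_count, df$n / den3, NA_real_)
  # pooled psi needs adequate evidence on both sides, not just in the sum
  psi <- ifelse(den5 >= min_count & den3 >= min_count,
                2 * df$n / (den5 + den3), NA_real_)
  per_sample <- data.frame(
    junction_id = df$junction_id, sample = df$sample, n = df$n,
    den5 = den5, den3 = den3, psi5 = psi5, psi3 = psi3, psi = psi,
    theta = NA_real_, stringsAsFactors = FALSE)
  jmeta <- unique(df[, c("junction_id", "chrom", "donor", "acceptor", "strand")])
  rownames(jmeta) <- NULL
  structure(list(per_sample = per_sample, junctions = jmeta,
                 min_count = as.integer(min_count)),
            class = "psi_profile")
}

#' @export
print.psi_profile <- function(x, ...) {
  cat(sprintf("psi profile: %d junctions x %d samples (min_count = %d)\n",
              nrow(x$junctions), length(unique(x$per_sample$sample)), x$min_count))
  invisible(x)
}

#' Completeness-of-splicing index
#'
#' Adds `theta` to a psi profile: split reads at a junction's two splice
#' sites as a fraction of split plus exon-intron boundary reads. Junctions
#' whose splice sites lack a boundary record get boundary count 0 with a
#' warning.
#'
#' @param profile `psi_profile` from [compute_psi()].
#' @param boundaries boundary-read table (see [read_boundaries()]).
#' @param min_count minimum total (split + boundary) reads, below which
#'   `theta` is `NA` (defaults to the profile's `min_count`).
#' @return the profile with `theta` filled in.
#' @export
compute_theta <- function(profile, boundaries, min_count = profile$min_count) {
  ps <- profile$per_sample
  jm <- profile$junctions[match(ps$junction_id, profile$junctions$junction_id), ]
  bkey <- paste(boundaries$chrom, boundaries$pos, boundaries$sample, sep = ":")
  e_of <- function(chrom, pos, sample) {
    i <- match(paste(chrom, pos, sample, sep = ":"), bkey)
    e <- boundaries$e[i]
    e[is.na(e)] <- NA_real_
    e
  }
  eD <- e_of(jm$chrom, jm$donor, ps$sample)
  eA <- e_of(jm$chrom, jm$acceptor, ps$sample)
  n_missing <- sum(is.na(eD)) + sum(is.na(eA))
  if (n_missing > 0L) {
    warning(n_missing, " splice-site boundary record(s) missing; treated as 0")
    eD[is.na(eD)] <- 0; eA[is.na(eA)] <- 0
  }
  split_tot <- ps$den5 + ps$den3
  tot <- split_tot + eD + eA
  ps$theta <- ifelse(tot >= min_count, split_tot / tot, NA_real_)
  profile$per_sample <- ps
  profile
}

#' Summarise psi per junction across samples
#'
#' @param profile `psi_profile`.
#' @return data.frame `junction_id, mean_psi, var_psi, n_usable` (mean and
#'   unbiased variance of pooled psi over non-`NA` samples).
#' @export
psi_summary <- function(profile) {
  ps <- profile$per_sample
  sp <- split(ps$psi, ps$junction_id)
  data.frame(
    junction_id = names(sp),
    mean_psi = vapply(sp, function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE), numeric(1)),
    var_psi = vapply(sp, function(v) if (sum(!is.na(v)) < 2L) NA_real_ else var(v, na.rm = TRUE), numeric(1)),
    n_usable = vapply(sp, function(v) sum(!is.na(v)), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify junctions by inclusion across all samples of both species
#'
#' `constitutive_high` junctions are included at psi above `hi` in every
#' usable sample of both species; `constitutive_low` below `lo` everywhere;
#' anything else with enough usable samples is `variable`. Junctions with
#' fewer than 2 usable samples in either species are `unclassified`.
#'
#' @param profile `psi_profile` over the pooled samples of both species.
#' @param species named character vector mapping each sample id to its
#'   species label (exactly 2 species).
#' @param hi,lo inclusion bounds (defaults 0.85 and 0.15).
#' @return data.frame `junction_id, class` with the per-junction pooled
#'   mean/variance columns of [psi_summary()].
#' @export
classify_junctions <- function(profile, species, hi = 0.85, lo = 0.15) {
  ps <- profile$per_sample
  if (!all(ps$sample %in% names(species))) stop("sample missing from species map")
  sp_lab <- unique(species[ps$sample])
  if (length(sp_lab) != 2L) stop("need samples from exactly 2 species")
  ps$species <- species[ps$sample]
  usable <- !is.na(ps$psi)
  n_by <- table(ps$junction_id[usable], ps$species[usable])
  per_j <- split(ps[usable, c("psi", "species")], ps$junction_id[usable])
  sm <- psi_summary(profile)
  cls <- vapply(sm$junction_id, function(j) {
    if (!(j %in% rownames(n_by)) || any(n_by[j, sp_lab] < 2L)) return("unclassified")
    v <- per_j[[j]]$psi
    if (all(v > hi)) "constitutive_high"
    else if (all(v < lo)) "constitutive_low"
    else "variable"
  }, character(1))
  sm$class <- factor(unname(cls),
                     levels = c("constitutive_high", "constitutive_low",
                                "variable", "unclassified"))
  sm
}

#' Junctions with constrained intermediate inclusion
#'
#' Among `variable` junctions, flags those whose pooled mean inclusion m lies
#' in (`lo`, `hi`) and whose sample variance does not exceed `frac` of the
#' maximum possible variance of a Bernoulli variable with that mean,
#' `m (1 - m)` — junctions held at a similar intermediate inclusion level in
#' every sample of both species.
#'
#' @param classified output of [classify_junctions()].
#' @param frac variance threshold as a fraction of the Bernoulli maximum
#'   (default 0.2).
#' @param lo,hi mean-inclusion interval (defaults 0.15, 0.85).
#' @return the input with a logical `constrained` column.
#' @export
constrained_junctions <- function(classified, frac = 0.2, lo = 0.15, hi = 0.85) {
  m <- classified$mean_psi
  v <- classified$var_psi
  classified$constrained <- classified$class == "variable" &
    !is.na(m) & !is.na(v) & m > lo & m < hi & v <= frac * m * (1 - m)
  classified
}

#' Cross-species concordance of orthologous junction usage
#'
#' Pearson correlation across orthologous junction pairs of (i) the logit of
#' mean pooled psi and (ii) the s.d. of psi over samples. Junction pairs at
#' constant complete inclusion or exclusion (all psi beyond the clipping
#' bound in either species) are excluded.
#'
#' @param profileA,profileB `psi_profile` per species.
#' @param orth orthology map of junction ids (`id1` in A, `id2` in B).
#' @param eps clipping bound applied before the logit (default `1e-3`).
#' @return list `cc_logit_mean`, `cc_sd`, `n_pairs`.
#' @export
ortho_junction_concordance <- function(profileA, profileB, orth, eps = 1e-3) {
  sA <- psi_summary(profileA); sB <- psi_summary(profileB)
  iA <- match(orth$id1, sA$junction_id)
  iB <- match(orth$id2, sB$junction_id)
  mA <- sA$mean_psi[iA]; mB <- sB$mean_psi[iB]
  vA <- sA$var_psi[iA]; vB <- sB$var_psi[iB]
  constant_extreme <- function(m, v) {
    !is.na(m) & !is.na(v) & v == 0 & (m >= 1 - eps | m <= eps)
  }
  keep <- is.finite(mA) & is.finite(mB) & is.finite(vA) & is.finite(vB) &
    !constant_extreme(mA, vA) & !constant_extreme(mB, vB)
  if (sum(keep) < 3L) stop("fewer than 3 usable orthologous junction pairs")
  list(cc_logit_mean = cor(logit(mA[keep], eps), logit(mB[keep], eps)),
       cc_sd = cor(sqrt(vA[keep]), sqrt(vB[keep])),
       n_pairs = sum(keep))
}
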