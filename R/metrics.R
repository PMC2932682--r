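#' Minor allele frequency of one marker
#'
#' @param column integer genotype codes (0/1/2/NA) for one marker.
#' @return `min(p, 1 - p)` where `p` is the frequency of `allele_b` over
#'   non-missing calls, or `NA` if every call is missing.
#' @export
minor_allele_freq <- function(column) {
  x <- column[!is.na(column)]
  if (!length(x)) return(NA_real_)
  p <- sum(x) / (2 * length(x))
  min(p, 1 - p)
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test on one biallelic marker's genotype counts: the
#' p-value sums the conditional probabilities (given the allele counts
#' and sample size) of every heterozygote count whose probability does
#' not exceed that of the observed count. Monomorphic markers return 1 by
#' convention.
#'
#' @param n_hom_a,n_het,n_hom_b genotype counts.
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_a, n_het, n_hom_b) {
  n <- n_hom_a + n_het + n_hom_b
  if (n < 1L) stop("need at least one genotype")
  n_a <- 2L * n_hom_a + n_het
  n_b <- 2L * n_hom_b + n_het
  rare <- min(n_a, n_b)
  if (rare == 0L) return(1)
  # heterozygote counts share the parity of the rare allele count
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(n_het = h | rare allele count, n), up to a shared constant:
  # C(n; homA, h, homB) * 2^h / C(2n, rare)
  logp <- vapply(hets, function(h) {
    ra <- (rare - h) / 2
    ca <- (2L * n - rare - h) / 2
    lgamma(n + 1) - lgamma(ra + 1) - lgamma(h + 1) - lgamma(ca + 1) +
      h * log(2)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  if (is.na(obs)) stop("observed het count inconsistent with allele counts")
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Observed heterozygosity
#'
#' Proportion of non-missing calls that are heterozygous, computed per
#' marker and averaged over markers.
#'
#' @param g a `geno_matrix`.
#' @return fraction in \[0, 1\].
#' @export
observed_heterozygosity <- function(g) {
  het <- colMeans(g$calls == 1L, na.rm = TRUE)
  mean(het[!is.nan(het)])
}

#' Individual inbreeding coefficients
#'
#' Method-of-moments F comparing the observed to the expected number of
#' homozygous genotypes: `F = (O_hom - E_hom) / (L - E_hom)` over each
#' individual's non-missing polymorphic markers, with expected
#' homozygosity `E_hom = sum(1 - 2 p q)` from plug-in colony allele
#' frequencies. F is negative under excess heterozygosity. Individuals
#' with no information (`E_hom = L`) are returned as `NA`.
#'
#' @param g a `geno_matrix` for one colony.
#' @param freqs optional vector of `allele_b` frequencies per marker;
#'   computed from `g` by default.
#' @return A tibble with `sample_id`, `f` and `n_markers_used`.
#' @export
inbreeding_coefficients <- function(g, freqs = NULL) {
  if (is.null(freqs)) {
    freqs <- colMeans(g$calls, na.rm = TRUE) / 2
  }
  poly <- !is.na(freqs) & freqs > 0 & freqs < 1
  e_marker <- 1 - 2 * freqs * (1 - freqs)
  calls <- g$calls[, poly, drop = FALSE]
  e_marker <- e_marker[poly]
  f <- numeric(n_samples(g)); l_used <- integer(n_samples(g))
  for (i in seq_len(nrow(calls))) {
    ok <- !is.na(calls[i, ])
    l <- sum(ok)
    l_used[i] <- l
    if (!l) { f[i] <- NA_real_; next }
    o_hom <- sum(calls[i, ok] != 1L)
    e_hom <- sum(e_marker[ok])
    denom <- l - e_hom
    f[i] <- if (denom <= 0) NA_real_ else (o_hom - e_hom) / denom
  }
  tibble::tibble(sample_id = g$samples, f = f, n_markers_used = l_used)
}

#' Per-colony inbreeding and diversity battery
#'
#' Aggregates the marker- and individual-level statistics into one row of
#' colony metrics: mean MAF (monomorphic markers contribute 0), mean
#' observed heterozygosity, percent of markers with MAF < 0.05, percent
#' of polymorphic markers failing the HWE exact test at `alpha`
#' (monomorphic markers cannot fail HWE and are excluded from that
#' denominator), and the mean individual inbreeding coefficient on the
#' x100 scale.
#'
#' @param colony a `colony_panel` (or plain `geno_matrix`).
#' @param alpha significance level for the HWE failure percentage
#'   (default 0.05).
#' @return A one-row tibble of class `colony_metrics`.
#' @export
colony_metrics <- function(colony, alpha = 0.05) {
  g <- colony
  if (n_samples(g) < 2L) stop("need at least 2 samples")
  maf <- apply(g$calls, 2L, minor_allele_freq)
  informative <- !is.na(maf)
  if (!any(informative)) stop("no marker with a non-missing call")
  poly <- informative & maf > 0
  hwe_p <- rep(NA_real_, n_markers(g))
  for (j in which(poly)) {
    x <- g$calls[, j]; x <- x[!is.na(x)]
    hwe_p[j] <- hwe_exact_test(sum(x == 0L), sum(x == 1L), sum(x == 2L))
  }
  fs <- inbreeding_coefficients(g)
  out <- tibble::tibble(
    colony_id = if (!is.null(g$colony_id)) g$colony_id else NA_character_,
    n_samples = n_samples(g),
    n_markers = n_markers(g),
    mean_maf = mean(maf[informative]),
    mean_het = observed_heterozygosity(g),
    pct_low_maf = 100 * mean(maf[informative] < 0.05),
    pct_fail_hwe = if (any(poly)) 100 * mean(hwe_p[poly] < alpha) else 0,
    mean_inbreeding_coef_pct = 100 * mean(fs$f, na.rm = TRUE),
    hwe_alpha = alpha
  )
  class(out) <- c("colony_metrics", class(out))
  out
}

#' Suitability classification for association mapping
#'
#' Applies the survey cut-offs to a colony's metrics: heterozygosity
#' below 5\% marks an almost-inbred colony; 5-10\% het is too low to be
#' useful; mean inbreeding above 20 (x100 scale) is disqualifying and
#' 10-20 is flagged as elevated; evidence of population structure is
#' carried through. A colony is usable for mapping when none of
#' almost_inbred, low_het_5_10 or high_inbreeding_gt20 applies.
#'
#' @param metrics a one-row [colony_metrics()] tibble.
#' @param structured logical: population structure detected (see
#'   [flag_structure()]).
#' @return A one-row tibble with logical flag columns and
#'   `usable_for_mapping`.
#' @export
classify_suitability <- function(metrics, structured = FALSE) {
  het <- metrics$mean_het
  fpct <- metrics$mean_inbreeding_coef_pct
  flags <- tibble::tibble(
    colony_id = metrics$colony_id,
    almost_inbred = het < 0.05,
    low_het_5_10 = het >= 0.05 & het < 0.10,
    high_inbreeding_gt20 = fpct > 20,
    elevated_inbreeding_gt10 = fpct > 10 & fpct <= 20,
    structured = isTRUE(structured)
  )
  flags$usable_for_mapping <- !(flags$almost_inbred | flags$low_het_5_10 |
                                  flags$high_inbreeding_gt20)
  flags
}
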