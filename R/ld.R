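#' Genotypic (composite) r-squared between two markers
#'
#' Squared Pearson correlation of genotype dosages over pairwise-complete
#' samples. Phase-free, so it applies directly to unphased colony data.
#'
#' @param col_i,col_j genotype code vectors (0/1/2/NA) of equal length.
#' @return r-squared in \[0, 1\], or `NA` if either marker is
#'   monomorphic in the complete-pairs subset or fewer than 2 complete
#'   pairs exist.
#' @export
pairwise_r2 <- function(col_i, col_j) {
  ok <- !is.na(col_i) & !is.na(col_j)
  if (sum(ok) < 2L) return(NA_real_)
  x <- col_i[ok]; y <- col_j[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' All intra-chromosomal LD pairs
#'
#' @param g a `geno_matrix`.
#' @param chrom optional chromosome to restrict to.
#' @param max_dist_bp only form pairs up to this separation (default all).
#' @return A tibble with marker_i, marker_j, chrom, distance_bp, r2
#'   (pairs with undefined r2 are excluded). Pairs never span
#'   chromosomes.
#' @export
ld_pairs <- function(g, chrom = NULL, max_dist_bp = Inf) {
  chroms <- if (is.null(chrom)) unique(g$map$chrom) else chrom
  res <- lapply(chroms, function(ch) {
    idx <- which(g$map$chrom == ch)
    if (length(idx) < 2L) return(NULL)
    pos <- g$map$pos_bp[idx]
    # dosage correlation over all columns at once; per-pair complete-case
    # handling via pairwise.complete.obs
    cc <- suppressWarnings(
      stats::cor(g$calls[, idx, drop = FALSE],
                 use = "pairwise.complete.obs"))
    ut <- which(upper.tri(cc), arr.ind = TRUE)
    d <- abs(pos[ut[, 2L]] - pos[ut[, 1L]])
    keep <- d <= max_dist_bp & !is.na(cc[ut])
    tibble::tibble(
      marker_i = g$map$marker_id[idx][ut[keep, 1L]],
      marker_j = g$map$marker_id[idx][ut[keep, 2L]],
      chrom = ch,
      distance_bp = d[keep],
      r2 = cc[ut][keep]^2
    )
  })
  dplyr::bind_rows(res)
}

# weighted pool-adjacent-violators for a non-increasing fit
pava_decreasing <- function(y, w) {
  n <- length(y)
  val <- y; wt <- w; size <- rep(1L, n); m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    val[m] <- y[i]; wt[m] <- w[i]; size[m] <- 1L
    while (m > 1L && val[m - 1L] < val[m]) {
      tw <- wt[m - 1L] + wt[m]
      val[m - 1L] <- (val[m - 1L] * wt[m - 1L] + val[m] * wt[m]) / tw
      wt[m - 1L] <- tw
      size[m - 1L] <- size[m - 1L] + size[m]
      m <- m - 1L
    }
  }
  rep(val[seq_len(m)], times = size[seq_len(m)])
}

#' LD decay profile and decay radius
#'
#' Bins marker pairs by physical separation, averages r-squared per bin,
#' smooths the binned means with a weighted non-increasing isotonic fit
#' (binned means are noisy and "drops below" is otherwise ill-defined),
#' and reports the radius: the distance at which the smoothed curve first
#' crosses 0.5, found by linear interpolation between bin midpoints.
#'
#' @param pairs tibble from [ld_pairs()].
#' @param bin_width_bp bin width (default 100 Kb).
#' @param min_pairs_per_bin bins with fewer pairs are discarded
#'   (default 10).
#' @return An object of class `ld_decay`: list with `profile` (tibble of
#'   bin_mid_bp, mean_r2, smoothed_r2, n_pairs), `radius_bp` (NA when
#'   the curve never crosses 0.5 or starts below it) and `status`
#'   (`"ok"`, `"gt_span"` when the curve stays above 0.5, `"lt_first_bin"`
#'   when it starts below, `"insufficient"`).
#' @export
ld_decay <- function(pairs, bin_width_bp = 1e5, min_pairs_per_bin = 10) {
  bin <- floor(pairs$distance_bp / bin_width_bp)
  agg <- tibble::tibble(bin = bin, r2 = pairs$r2) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_r2 = mean(.data$r2), n_pairs = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$n_pairs >= min_pairs_per_bin) |>
    dplyr::arrange(.data$bin)
  out <- list(profile = tibble::tibble(), radius_bp = NA_real_,
              status = "insufficient")
  class(out) <- "ld_decay"
  if (nrow(agg) < 2L) return(out)
  mid <- (agg$bin + 0.5) * bin_width_bp
  sm <- pava_decreasing(agg$mean_r2, agg$n_pairs)
  out$profile <- tibble::tibble(bin_mid_bp = mid, mean_r2 = agg$mean_r2,
                                smoothed_r2 = sm, n_pairs = agg$n_pairs)
  if (sm[1L] < 0.5) {
    out$status <- "lt_first_bin"
    out$radius_bp <- NA_real_
    attr(out$radius_bp, "bound_bp") <- mid[1L]
  } else if (sm[length(sm)] >= 0.5) {
    out$status <- "gt_span"
    out$radius_bp <- NA_real_
    attr(out$radius_bp, "bound_bp") <- mid[length(mid)]
  } else {
    k <- which(sm < 0.5)[1L]
    x0 <- mid[k - 1L]; x1 <- mid[k]
    y0 <- sm[k - 1L]; y1 <- sm[k]
    out$radius_bp <- if (y0 == y1) x1 else x0 + (y0 - 0.5) / (y0 - y1) * (x1 - x0)
    out$status <- "ok"
  }
  out
}

#' @rdname ld_decay
#' @param ... passed to [ld_decay()].
#' @export
ld_decay_radius <- function(pairs, ...) {
  ld_decay(pairs, ...)$radius_bp
}

#' @export
print.ld_decay <- function(x, ...) {
  cat("<ld_decay> ", nrow(x$profile), " bins; status=", x$status, sep = "")
  if (x$status == "ok") cat(sprintf("; radius = %.0f bp", x$radius_bp))
  cat("\n")
  invisible(x)
}

# --- two-locus haplotype EM and D' ------------------------------------

# haplotype frequencies (p00, p01, p10, p11 for allele_b doses at the two
# loci) by EM over unphased genotype pairs; only the double heterozygote
# has ambiguous phase
haplotype_em <- function(x, y, max_iter = 50, tol = 1e-8) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) return(NULL)
  cnt <- matrix(0, 3L, 3L)
  for (i in seq_len(n)) cnt[x[i] + 1L, y[i] + 1L] <- cnt[x[i] + 1L, y[i] + 1L] + 1
  h <- rep(0.25, 4L)  # linkage-equilibrium start is overwritten below
  pB1 <- sum(x) / (2 * n); pB2 <- sum(y) / (2 * n)
  h <- c((1 - pB1) * (1 - pB2), (1 - pB1) * pB2, pB1 * (1 - pB2), pB1 * pB2)
  ll_of <- function(h) {
    pg <- two_locus_geno_probs(h)
    sum(cnt * log(pmax(pg, 1e-300)))
  }
  ll <- ll_of(h)
  for (it in seq_len(max_iter)) {
    e <- numeric(4L)
    for (g1 in 0:2) for (g2 in 0:2) {
      m <- cnt[g1 + 1L, g2 + 1L]
      if (!m) next
      if (g1 == 1L && g2 == 1L) {
        w_cis <- h[1L] * h[4L]; w_trans <- h[2L] * h[3L]
        tot <- w_cis + w_trans
        if (tot <= 0) { w_cis <- w_trans <- 0.5; tot <- 1 }
        e[c(1L, 4L)] <- e[c(1L, 4L)] + m * w_cis / tot
        e[c(2L, 3L)] <- e[c(2L, 3L)] + m * w_trans / tot
      } else {
        # unambiguous: haplotype doses follow from the genotypes
        h1 <- c(ifelse(g1 >= 1L, 1L, 0L), ifelse(g2 >= 1L, 1L, 0L))
        h2 <- c(ifelse(g1 == 2L, 1L, 0L), ifelse(g2 == 2L, 1L, 0L))
        e[1L + 2L * h1[1L] + h1[2L]] <- e[1L + 2L * h1[1L] + h1[2L]] + m
        e[1L + 2L * h2[1L] + h2[2L]] <- e[1L + 2L * h2[1L] + h2[2L]] + m
      }
    }
    h_new <- e / (2 * n)
    ll_new <- ll_of(h_new)
    h <- h_new
    if (abs(ll_new - ll) < tol) { ll <- ll_new; break }
    ll <- ll_new
  }
  list(h = h, loglik = ll, counts = cnt, n = n)
}

# genotype-pair probabilities under HWE from haplotype frequencies
two_locus_geno_probs <- function(h) {
  # h = (p00, p01, p10, p11); hap index = allele_b dose at locus 1, 2
  pg <- matrix(0, 3L, 3L)
  haps <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  for (a in 1:4) for (b in 1:4) {
    g1 <- haps[a, 1L] + haps[b, 1L]
    g2 <- haps[a, 2L] + haps[b, 2L]
    pg[g1 + 1L, g2 + 1L] <- pg[g1 + 1L, g2 + 1L] + h[a] * h[b]
  }
  pg
}

dprime_from_h <- function(h) {
  pB1 <- h[3L] + h[4L]; pB2 <- h[2L] + h[4L]
  d <- h[4L] - pB1 * pB2
  dmax <- if (d >= 0) {
    min(pB1 * (1 - pB2), (1 - pB1) * pB2)
  } else {
    min(pB1 * pB2, (1 - pB1) * (1 - pB2))
  }
  if (dmax <= 0) return(NA_real_)
  abs(d) / dmax
}

#' D-prime with a likelihood-based confidence interval
#'
#' Estimates two-locus haplotype frequencies by EM, then profiles the
#' likelihood of |D'| on a 101-point grid in \[0, 1\] (allele frequencies
#' and the sign of D held at their MLEs); the CI endpoints are the 5th
#' and 95th percentiles of the normalized likelihood mass, the standard
#' confidence-interval block construction.
#'
#' @param x,y genotype code vectors for the two markers.
#' @return list with `d_prime`, `ci_low`, `ci_high` (or NULL when
#'   inestimable).
#' @export
dprime_ci <- function(x, y) {
  fit <- haplotype_em(x, y)
  if (is.null(fit)) return(NULL)
  h <- fit$h
  pB1 <- h[3L] + h[4L]; pB2 <- h[2L] + h[4L]
  if (pB1 <= 0 || pB1 >= 1 || pB2 <= 0 || pB2 >= 1) return(NULL)
  d_mle <- h[4L] - pB1 * pB2
  sgn <- if (d_mle >= 0) 1 else -1
  dmax <- if (sgn > 0) min(pB1 * (1 - pB2), (1 - pB1) * pB2) else
    min(pB1 * pB2, (1 - pB1) * (1 - pB2))
  if (dmax <= 0) return(NULL)
  grid <- seq(0, 1, length.out = 101L)
  ll <- vapply(grid, function(dp) {
    d <- sgn * dp * dmax
    hh <- c((1 - pB1) * (1 - pB2) + d, (1 - pB1) * pB2 - d,
            pB1 * (1 - pB2) - d, pB1 * pB2 + d)
    hh <- pmax(hh, 1e-12)
    pg <- two_locus_geno_probs(hh / sum(hh))
    sum(fit$counts * log(pmax(pg, 1e-300)))
  }, numeric(1))
  w <- exp(ll - max(ll)); w <- w / sum(w)
  cdf <- cumsum(w)
  list(d_prime = dprime_from_h(h),
       ci_low = grid[which(cdf >= 0.05)[1L]],
       ci_high = grid[which(cdf >= 0.95)[1L]])
}

#' Haplotype LD blocks (confidence-interval rule)
#'
#' Detects blocks with the confidence-interval definition used in human
#' LD studies: a marker pair is in "strong LD" when the D' CI has lower
#' bound >= `strong_low` and upper bound >= `strong_high`, and shows
#' "strong recombination" when the upper bound is below `recomb_high`.
#' Maximal marker runs in which at least `frac_strong` of the informative
#' pairs are strong LD form candidate blocks; candidates are accepted
#' greedily, longest span first, without overlap.
#'
#' @param g a `geno_matrix`.
#' @param chrom chromosome to analyse (default: first in the map).
#' @param strong_low,strong_high,recomb_high,frac_strong rule thresholds
#'   (defaults 0.70, 0.98, 0.90, 0.95).
#' @param max_pair_dist_bp pairs farther apart are not classified
#'   (default Inf).
#' @return A tibble of blocks: chrom, start_bp, end_bp, n_markers,
#'   length_bp.
#' @export
find_blocks <- function(g, chrom = NULL, strong_low = 0.70,
                        strong_high = 0.98, recomb_high = 0.90,
                        frac_strong = 0.95, max_pair_dist_bp = Inf) {
  if (is.null(chrom)) chrom <- g$map$chrom[1L]
  idx <- which(g$map$chrom == chrom)
  maf <- apply(g$calls[, idx, drop = FALSE], 2L, minor_allele_freq)
  idx <- idx[!is.na(maf) & maf > 0]
  m <- length(idx)
  empty <- tibble::tibble(chrom = character(), start_bp = integer(),
                          end_bp = integer(), n_markers = integer(),
                          length_bp = integer())
  if (m < 2L) return(empty)
  pos <- g$map$pos_bp[idx]
  strong <- matrix(FALSE, m, m); inform <- matrix(FALSE, m, m)
  for (a in seq_len(m - 1L)) for (b in seq.int(a + 1L, m)) {
    if (pos[b] - pos[a] > max_pair_dist_bp) next
    ci <- dprime_ci(g$calls[, idx[a]], g$calls[, idx[b]])
    if (is.null(ci) || is.na(ci$d_prime)) next
    if (ci$ci_low >= strong_low && ci$ci_high >= strong_high) {
      strong[a, b] <- TRUE; inform[a, b] <- TRUE
    } else if (ci$ci_high < recomb_high) {
      inform[a, b] <- TRUE
    }
  }
  cand <- block_candidates(strong, inform, frac_strong)
  if (!nrow(cand)) return(empty)
  span <- pos[cand$j] - pos[cand$i]
  ord <- order(-span, cand$i)
  taken <- rep(FALSE, m)
  out <- list()
  for (k in ord) {
    i <- cand$i[k]; j <- cand$j[k]
    if (any(taken[i:j])) next
    taken[i:j] <- TRUE
    out[[length(out) + 1L]] <- tibble::tibble(
      chrom = chrom, start_bp = pos[i], end_bp = pos[j],
      n_markers = j - i + 1L, length_bp = pos[j] - pos[i] + 1L)
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start_bp)
}

# all spans [i, j] in which >= frac of informative pairs are strong LD
# (requiring at least one informative pair)
block_candidates <- function(strong, inform, frac) {
  m <- nrow(strong)
  # prefix counts over the upper triangle for O(m^2) span evaluation
  cs <- t(apply(strong, 1L, cumsum)); ci <- t(apply(inform, 1L, cumsum))
  vs <- apply(cs, 2L, cumsum); vi <- apply(ci, 2L, cumsum)
  res_i <- integer(); res_j <- integer()
  for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
    up_s <- vs[j, j] - if (i > 1L) vs[i - 1L, j] else 0
    up_i <- vi[j, j] - if (i > 1L) vi[i - 1L, j] else 0
    if (up_i > 0 && up_s / up_i >= frac) {
      res_i <- c(res_i, i); res_j <- c(res_j, j)
    }
  }
  tibble::tibble(i = res_i, j = res_j)
}

#' Mean haplotype-block length
#'
#' @param blocks tibble from [find_blocks()].
#' @return A one-row tibble with n_blocks, mean_bp and sd_bp
#'   (sd 0 for a single block).
#' @export
mean_block_length <- function(blocks) {
  if (!nrow(blocks)) stop("no blocks")
  len <- blocks$end_bp - blocks$start_bp + 1L
  tibble::tibble(n_blocks = length(len), mean_bp = mean(len),
                 sd_bp = if (length(len) > 1L) stats::sd(len) else 0)
}
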