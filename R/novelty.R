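#' Read-level filters for reduced-representation SNP calls
#'
#' Applies the three conjunctive confidence filters used for
#' reduced-representation sequencing: calls within `min_end_dist` bases
#' of a read end are discarded (end-of-read calls are unreliable), calls
#' farther than `max_site_dist` bases from a known restriction site are
#' discarded, and calls require read depth strictly greater than
#' `min_depth`. Calls with an unknown restriction-site distance are
#' discarded. Order of application does not matter.
#'
#' @param calls tibble with columns chrom, pos_bp, ref, alt, depth,
#'   dist_to_read_end_bp, dist_to_site_bp.
#' @param min_depth depth must exceed this (default 10).
#' @param min_end_dist calls at distance <= this from a read end are
#'   dropped (default 3).
#' @param max_site_dist maximum distance to a restriction site
#'   (default 32).
#' @return The filtered tibble; attribute `n_input` holds the input
#'   count.
#' @export
filter_calls <- function(calls, min_depth = 10L, min_end_dist = 3L,
                         max_site_dist = 32L) {
  keep <- calls$dist_to_read_end_bp > min_end_dist &
    !is.na(calls$dist_to_site_bp) & calls$dist_to_site_bp <= max_site_dist &
    calls$depth > min_depth
  out <- calls[keep & !is.na(keep), , drop = FALSE]
  attr(out, "n_input") <- nrow(calls)
  out
}

#' Fraction of variants absent from an inbred-strain catalogue
#'
#' The raw novelty rate is the fraction of filtered calls whose position
#' and alternate allele are absent from the catalogue (variant sets are
#' compared, not genotypes). Because reduced-representation calling has
#' a known false-discovery rate, the adjusted rate subtracts `fdr` from
#' the raw rate (floored at zero).
#'
#' @param filtered tibble from [filter_calls()] (chrom, pos_bp, alt).
#' @param catalogue tibble of known variants (chrom, pos_bp, alt).
#' @param fdr false-discovery rate of the calling pipeline (default
#'   0.08).
#' @return A one-row tibble: n_input, n_pass_filters, n_novel, raw_rate,
#'   adjusted_rate.
#' @export
novelty_rate <- function(filtered, catalogue, fdr = 0.08) {
  n_input <- attr(filtered, "n_input")
  if (is.null(n_input)) n_input <- nrow(filtered)
  if (!nrow(filtered)) stop("no calls after filtering")
  key <- function(d) paste(d$chrom, d$pos_bp, d$alt, sep = ":")
  novel <- !(key(filtered) %in% key(catalogue))
  raw <- mean(novel)
  tibble::tibble(n_input = n_input, n_pass_filters = nrow(filtered),
                 n_novel = sum(novel), raw_rate = raw,
                 adjusted_rate = max(0, raw - fdr))
}
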