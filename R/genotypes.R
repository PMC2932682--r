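#' Marker map
#'
#' Builds and validates the marker map used for all physical-distance
#' computations. Positions are 1-based physical coordinates in bp; markers
#' are sorted by chromosome then position on ingest and must be uniquely
#' named.
#'
#' @param marker_id character vector of unique marker names.
#' @param chrom chromosome labels (coerced to character).
#' @param pos_bp integer 1-based physical positions.
#' @param allele_a,allele_b single-character allele labels; genotype codes
#'   count copies of `allele_b`.
#' @return A tibble with class `marker_map`, sorted by (chrom, pos_bp).
#' @export
marker_map <- function(marker_id, chrom, pos_bp, allele_a = "A", allele_b = "B") {
  map <- tibble::tibble(
    marker_id = as.character(marker_id),
    chrom = as.character(chrom),
    pos_bp = as.integer(pos_bp),
    allele_a = rep_len(as.character(allele_a), length(marker_id)),
    allele_b = rep_len(as.character(allele_b), length(marker_id))
  )
  if (anyDuplicated(map$marker_id)) {
    stop("duplicate marker_id in map: ",
         paste(unique(map$marker_id[duplicated(map$marker_id)]), collapse = ", "))
  }
  if (any(is.na(map$pos_bp)) || any(map$pos_bp < 1)) {
    stop("marker positions must be positive 1-based integers")
  }
  map <- dplyr::arrange(map, .data$chrom, .data$pos_bp)
  for (ch in unique(map$chrom)) {
    p <- map$pos_bp[map$chrom == ch]
    if (anyDuplicated(p)) {
      stop("duplicate positions on chromosome ", ch)
    }
  }
  class(map) <- c("marker_map", class(map))
  map
}

#' Genotype matrix
#'
#' Container for diploid biallelic genotypes: an integer matrix of
#' samples x markers with codes 0 (hom `allele_a`), 1 (het), 2
#' (hom `allele_b`) and `NA` for missing, plus the marker map. Column
#' order always matches the map order.
#'
#' @param calls integer matrix (samples x markers), entries in
#'   \{0, 1, 2, NA\}.
#' @param map a [marker_map()] with one row per column of `calls`.
#' @param samples sample identifiers; defaults to rownames of `calls`.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, map, samples = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (ncol(calls) != nrow(map)) {
    stop("calls has ", ncol(calls), " columns but map has ", nrow(map), " markers")
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && any(bad < 0L | bad > 2L)) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(calls)))
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  dimnames(calls) <- list(samples, map$marker_id)
  structure(list(calls = calls, map = map, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", n_samples(x), " samples x ", n_markers(x), " markers",
      " (", sum(is.na(x$calls)), " missing calls)\n", sep = "")
  invisible(x)
}

#' Number of samples / markers in a genotype container
#' @param g a `geno_matrix`, `founder_panel` or `colony_panel`.
#' @return integer count.
#' @export
n_samples <- function(g) nrow(g$calls)

#' @rdname n_samples
#' @export
n_markers <- function(g) ncol(g$calls)

#' Subset a genotype matrix
#'
#' @param g a `geno_matrix`.
#' @param samples sample ids or indices to keep (NULL keeps all).
#' @param markers marker ids or indices to keep (NULL keeps all).
#' @return A `geno_matrix` restricted to the requested rows/columns;
#'   marker order follows the map order of the retained markers.
#' @export
subset_geno <- function(g, samples = NULL, markers = NULL) {
  calls <- g$calls
  map <- g$map
  if (!is.null(markers)) {
    idx <- if (is.character(markers)) match(markers, map$marker_id) else markers
    if (anyNA(idx)) stop("unknown marker id(s)")
    idx <- sort(idx)
    calls <- calls[, idx, drop = FALSE]
    map <- map[idx, ]
  }
  if (!is.null(samples)) {
    sidx <- if (is.character(samples)) match(samples, g$samples) else samples
    if (anyNA(sidx)) stop("unknown sample id(s)")
    calls <- calls[sidx, , drop = FALSE]
  }
  out <- g
  out$calls <- calls
  out$map <- map
  out$samples <- rownames(calls)
  out
}

#' Founder panel of homozygous inbred haplotypes
#'
#' Wraps a genotype matrix of candidate inbred ancestors. Real inbred
#' panels carry residual heterozygosity, so a founder is accepted when its
#' heterozygous-call rate is at or below `het_tol`; founders above the
#' tolerance are rejected at load with an error (contamination would
#' silently corrupt the mosaic HMM emissions). Residual het calls are set
#' to missing.
#'
#' @param g a `geno_matrix` of founder genotypes.
#' @param het_tol maximum tolerated per-founder heterozygous fraction
#'   (default 0.01).
#' @return An object of class `founder_panel` (a `geno_matrix` whose
#'   non-missing calls are all 0 or 2), with `founders = samples`.
#' @export
founder_panel <- function(g, het_tol = 0.01) {
  stopifnot(inherits(g, "geno_matrix"))
  het_rate <- rowMeans(g$calls == 1L, na.rm = TRUE)
  het_rate[is.nan(het_rate)] <- 0
  bad <- het_rate > het_tol
  if (any(bad)) {
    stop("founder(s) exceed heterozygosity tolerance ", het_tol, ": ",
         paste0(g$samples[bad], " (", sprintf("%.3f", het_rate[bad]), ")",
                collapse = ", "))
  }
  calls <- g$calls
  calls[calls == 1L] <- NA_integer_
  out <- geno_matrix(calls, g$map, g$samples)
  out$founders <- g$samples
  class(out) <- c("founder_panel", class(out))
  out
}

#' Colony panel
#'
#' A genotype matrix tagged with colony-level metadata: the supplier's
#' breeding scheme, census size and sampling date where known.
#'
#' @param g a `geno_matrix`.
#' @param colony_id non-empty colony identifier.
#' @param scheme breeding scheme, one of `"random"`, `"circular"`,
#'   `"rotational"`, `"poiley"`, `"robertson"`, `"igs"`, `"unknown"`.
#' @param colony_size census size, or `NA` if unknown.
#' @param sampling_date a `Date` or `NA`.
#' @return An object of class `colony_panel`.
#' @export
colony_panel <- function(g, colony_id, scheme = "unknown",
                         colony_size = NA_integer_, sampling_date = NA) {
  stopifnot(inherits(g, "geno_matrix"))
  if (!is.character(colony_id) || length(colony_id) != 1L || !nzchar(colony_id)) {
    stop("colony_id must be a non-empty string")
  }
  scheme <- match.arg(scheme, c("random", "circular", "rotational", "poiley",
                                "robertson", "igs", "unknown"))
  out <- g
  out$colony_id <- colony_id
  out$scheme <- scheme
  out$colony_size <- as.integer(colony_size)
  out$sampling_date <- sampling_date
  class(out) <- c("colony_panel", class(g))
  out
}

#' @export
print.colony_panel <- function(x, ...) {
  cat("<colony_panel> ", x$colony_id, ": ", n_samples(x), " samples x ",
      n_markers(x), " markers, scheme=", x$scheme, "\n", sep = "")
  invisible(x)
}

#' Genotypes as a long tibble
#'
#' @param x a `geno_matrix`.
#' @param ... unused.
#' @return A tibble with columns sample_id, marker_id, chrom, pos_bp, dose.
#' @method tidy geno_matrix
#' @export
tidy.geno_matrix <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(x$samples, times = n_markers(x)),
    marker_id = rep(x$map$marker_id, each = n_samples(x)),
    chrom = rep(x$map$chrom, each = n_samples(x)),
    pos_bp = rep(x$map$pos_bp, each = n_samples(x)),
    dose = as.integer(x$calls)
  )
}
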