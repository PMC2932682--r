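comp_allele <- function(a) {
  chartr("ACGTacgt", "TGCAtgca", a)
}

is_strand_ambiguous <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Align a genotype matrix to a founder panel
#'
#' Restricts both objects to their shared markers (in founder map order)
#' and reconciles allele labels so that dosage codes count the same
#' allele in both. Labels are matched directly, by swapping, or by strand
#' complement (with or without swap); swapped matches recode genotypes
#' 0<->2. Strand-ambiguous A/T and C/G markers whose MAF in `g` lies in
#' (0.4, 0.6) cannot be oriented reliably and are dropped (count
#' reported); ambiguous markers outside that band are matched on the
#' labels as written. Aligning already-aligned inputs is a no-op.
#'
#' @param g a `geno_matrix` of colony genotypes.
#' @param f a [founder_panel()].
#' @return A list with elements `genotypes`, `founders` (both restricted
#'   and reconciled) and `dropped` (tibble of dropped markers and
#'   reasons).
#' @export
align_to_founders <- function(g, f) {
  shared <- intersect(f$map$marker_id, g$map$marker_id)
  if (!length(shared)) stop("no shared markers between genotypes and founders")
  g2 <- subset_geno(g, markers = shared)
  f2 <- subset_geno(f, markers = shared)
  ord <- f2$map$marker_id
  g2 <- subset_geno(g2, markers = match(ord, g2$map$marker_id))
  stopifnot(identical(g2$map$marker_id, f2$map$marker_id))

  drop_id <- character(); drop_reason <- character()
  flip <- logical(length(ord)); keep <- rep(TRUE, length(ord))
  for (j in seq_along(ord)) {
    ga <- g2$map$allele_a[j]; gb <- g2$map$allele_b[j]
    fa <- f2$map$allele_a[j]; fb <- f2$map$allele_b[j]
    amb <- is_strand_ambiguous(ga, gb)
    if (amb) {
      maf <- minor_allele_freq(g2$calls[, j])
      if (!is.na(maf) && maf > 0.4 && maf < 0.6) {
        keep[j] <- FALSE
        drop_id <- c(drop_id, ord[j])
        drop_reason <- c(drop_reason, "strand-ambiguous, MAF in (0.4, 0.6)")
        next
      }
    }
    if (ga == fa && gb == fb) {
      flip[j] <- FALSE
    } else if (ga == fb && gb == fa) {
      flip[j] <- TRUE
    } else if (!amb && comp_allele(ga) == fa && comp_allele(gb) == fb) {
      flip[j] <- FALSE
    } else if (!amb && comp_allele(ga) == fb && comp_allele(gb) == fa) {
      flip[j] <- TRUE
    } else {
      keep[j] <- FALSE
      drop_id <- c(drop_id, ord[j])
      drop_reason <- c(drop_reason, "irreconcilable allele labels")
    }
  }
  if (any(flip)) {
    g2$calls[, flip] <- 2L - g2$calls[, flip, drop = FALSE]
  }
  # adopt founder allele labels so re-alignment is the identity
  g2$map$allele_a <- f2$map$allele_a
  g2$map$allele_b <- f2$map$allele_b
  if (!all(keep)) {
    g2 <- subset_geno(g2, markers = which(keep))
    f2 <- subset_geno(f2, markers = which(keep))
    message("align_to_founders: dropped ", sum(!keep), " marker(s)")
  }
  if (!n_markers(g2)) stop("no markers left after allele reconciliation")
  f2$founders <- f2$samples
  if (!inherits(f2, "founder_panel")) class(f2) <- c("founder_panel", class(f2))
  list(genotypes = g2, founders = f2,
       dropped = tibble::tibble(marker_id = drop_id, reason = drop_reason))
}
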