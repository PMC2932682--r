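#' Read genotypes from PED/MAP or VCF
#'
#' Reads diploid biallelic SNP genotypes into a [geno_matrix()]. Only
#' biallelic sites are kept: multi-allelic VCF records are dropped with a
#' message giving the count. Half-missing PED genotypes (one allele `0`)
#' are treated as fully missing. For VCF only the GT field is consumed;
#' phased (`|`) and unphased (`/`) separators are both accepted and
#' treated as unphased.
#'
#' @param path path to the `.ped` file (its `.map` companion is found by
#'   substituting the extension, or supplied via `map_path`) or to a VCF.
#' @param format `"pedmap"` or `"vcf"`.
#' @param map_path optional explicit path to the MAP file.
#' @return A `geno_matrix`; its `$map` carries the marker map.
#' @export
read_genotypes <- function(path, format = c("pedmap", "vcf"), map_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pedmap") {
    if (is.null(map_path)) map_path <- sub("\\.ped$", ".map", path)
    if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
    read_pedmap(path, map_path)
  } else {
    read_vcf_genotypes(path)
  }
}

# MAP: chrom, marker_id, cM, pos_bp; a 6-column variant with allele_a,
# allele_b appended (as written by write_genotypes) pins the code polarity.
read_pedmap <- function(ped_path, map_path) {
  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = "character")
  if (ncol(map_raw) < 4L) stop("MAP file must have >= 4 columns")
  have_alleles <- ncol(map_raw) >= 6L
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty PED file: ", ped_path)
  n_mark <- nrow(map_raw)
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * n_mark
  nt <- lengths(toks)
  if (any(nt != want)) {
    stop("malformed PED line ", which(nt != want)[1L], ": expected ", want,
         " fields, found ", nt[nt != want][1L])
  }
  tok <- do.call(rbind, toks)
  samples <- tok[, 2L]
  a1 <- tok[, 6L + 2L * seq_len(n_mark) - 1L, drop = FALSE]
  a2 <- tok[, 6L + 2L * seq_len(n_mark), drop = FALSE]
  # half-missing records are treated as missing (the field standard leaves
  # them undefined)
  half <- (a1 == "0") != (a2 == "0")
  a1[half] <- "0"; a2[half] <- "0"
  allele_a <- character(n_mark); allele_b <- character(n_mark)
  calls <- matrix(NA_integer_, nrow(tok), n_mark)
  for (j in seq_len(n_mark)) {
    obs <- c(a1[, j], a2[, j])
    obs <- obs[obs != "0"]
    als <- sort(unique(obs))
    if (length(als) > 2L) {
      stop("marker ", map_raw[j, 2L], " has >2 alleles in PED file")
    }
    if (have_alleles) {
      aa <- map_raw[j, 5L]; ab <- map_raw[j, 6L]
      if (length(als) && !all(als %in% c(aa, ab))) {
        stop("marker ", map_raw[j, 2L], " allele(s) not in MAP columns 5-6")
      }
    } else {
      aa <- if (length(als) >= 1L) als[1L] else "A"
      ab <- if (length(als) == 2L) als[2L] else "B"
    }
    allele_a[j] <- aa; allele_b[j] <- ab
    dose <- (a1[, j] == ab) + (a2[, j] == ab)
    dose[a1[, j] == "0"] <- NA_integer_
    calls[, j] <- as.integer(dose)
  }
  map <- marker_map(map_raw[, 2L], map_raw[, 1L], as.integer(map_raw[, 4L]),
                    allele_a, allele_b)
  ord <- match(map$marker_id, map_raw[, 2L])
  geno_matrix(calls[, ord, drop = FALSE], map, samples)
}

read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt) & nchar(fix[, "REF"]) == 1L &
    nchar(alt) == 1L
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message("dropped ", n_drop, " multi-allelic or non-SNP record(s)")
  }
  if (!any(keep)) stop("no biallelic SNP records left after filtering")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- fix[, "ID"]
  if (any(is.na(ids) | ids == ".")) {
    ids[is.na(ids) | ids == "."] <-
      paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  }
  map <- marker_map(ids, fix[, "CHROM"], as.integer(fix[, "POS"]),
                    fix[, "REF"], fix[, "ALT"])
  dose_of <- function(x) {
    x <- sub(":.*", "", x)
    a <- strsplit(x, "[/|]")
    vapply(a, function(al) {
      if (length(al) != 2L || any(al == ".") || any(is.na(al))) return(NA_integer_)
      as.integer(sum(al == "1"))
    }, integer(1))
  }
  calls <- apply(gt, 1L, dose_of)
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = ncol(gt))
  ord <- match(map$marker_id, ids)
  geno_matrix(calls[, ord, drop = FALSE], map, colnames(gt))
}

#' Write genotypes to PED/MAP or VCF
#'
#' The PED writer emits a 6-column MAP (chrom, id, 0 cM, pos, allele_a,
#' allele_b) so that code polarity survives a round trip even at
#' monomorphic markers; the VCF writer emits a minimal VCF 4.2 with GT
#' only (REF = allele_a, ALT = allele_b).
#'
#' @param g a `geno_matrix`.
#' @param path output path (for `pedmap`, the `.ped` path; the `.map` is
#'   written alongside).
#' @param format `"pedmap"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("pedmap", "vcf")) {
  format <- match.arg(format)
  stopifnot(inherits(g, "geno_matrix"))
  if (format == "pedmap") {
    map_path <- sub("\\.ped$", ".map", path)
    utils::write.table(
      data.frame(g$map$chrom, g$map$marker_id, 0, g$map$pos_bp,
                 g$map$allele_a, g$map$allele_b),
      map_path, quote = FALSE, sep = "\t",
      row.names = FALSE, col.names = FALSE)
    n <- n_samples(g); m <- n_markers(g)
    al <- matrix("0", n, 2L * m)
    for (j in seq_len(m)) {
      d <- g$calls[, j]
      aa <- g$map$allele_a[j]; ab <- g$map$allele_b[j]
      a1 <- ifelse(is.na(d), "0", ifelse(d >= 1L, ab, aa))
      a2 <- ifelse(is.na(d), "0", ifelse(d == 2L, ab, aa))
      al[, 2L * j - 1L] <- a1; al[, 2L * j] <- a2
    }
    lead <- cbind("FAM", g$samples, "0", "0", "0", "-9")
    utils::write.table(cbind(lead, al), path, quote = FALSE, sep = " ",
                       row.names = FALSE, col.names = FALSE)
  } else {
    hdr <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", g$samples), collapse = "\t"))
    gt_of <- function(d) {
      out <- rep("./.", length(d))
      out[!is.na(d) & d == 0L] <- "0/0"
      out[!is.na(d) & d == 1L] <- "0/1"
      out[!is.na(d) & d == 2L] <- "1/1"
      out
    }
    body <- vapply(seq_len(n_markers(g)), function(j) {
      paste(c(g$map$chrom[j], g$map$pos_bp[j], g$map$marker_id[j],
              g$map$allele_a[j], g$map$allele_b[j], ".", "PASS", ".", "GT",
              gt_of(g$calls[, j])), collapse = "\t")
    }, character(1))
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Header-bearing delimited text keyed on a sample-id column. All other
#' columns are traits or covariates; character columns become factors.
#'
#' @param path path to a TSV/CSV file (delimiter sniffed from the header).
#' @param id_col name of the sample-id column (default `"sample_id"`, or
#'   the first column if absent).
#' @return A tibble with `sample_id` first.
#' @export
read_phenotypes <- function(path, id_col = "sample_id") {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else if (grepl(",", hdr)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!id_col %in% names(df)) id_col <- names(df)[1L]
  names(df)[names(df) == id_col] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  df <- dplyr::relocate(df, "sample_id")
  tibble::as_tibble(df)
}

#' Match phenotype rows to a genotype matrix
#'
#' @param pheno a phenotype tibble with a `sample_id` column.
#' @param g a `geno_matrix`.
#' @return The phenotype rows whose ids resolve in `g`, in `g`'s sample
#'   order; unmatched ids are reported with a warning.
#' @export
match_phenotypes <- function(pheno, g) {
  unmatched <- setdiff(pheno$sample_id, g$samples)
  if (length(unmatched)) {
    warning(length(unmatched), " phenotype id(s) not in genotypes: ",
            paste(utils::head(unmatched, 5L), collapse = ", "),
            if (length(unmatched) > 5L) ", ..." else "")
  }
  keep <- pheno[pheno$sample_id %in% g$samples, , drop = FALSE]
  keep[order(match(keep$sample_id, g$samples)), , drop = FALSE]
}
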