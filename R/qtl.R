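#' Prepare a trait for mapping
#'
#' Applies a rank-based inverse-normal transform to the raw trait (ties
#' broken by average rank) within each colony, standardizes the result
#' to mean 0, sd 1 within colony, and screens each candidate covariate
#' with a one-way ANOVA: covariates explaining a significant fraction of
#' the transformed trait's variance at `alpha` (default 0.01) are
#' retained for all subsequent models.
#'
#' @param pheno phenotype tibble with `sample_id`, the trait column and
#'   covariate columns.
#' @param trait name of the trait column.
#' @param covariates character vector of candidate covariate columns
#'   (default none).
#' @param colony_col optional column holding colony labels; absent means
#'   a single colony.
#' @param alpha covariate screening level (default 0.01).
#' @param min_n minimum number of phenotyped samples (default 20).
#' @return An object of class `trait_model`: list with `data` (tibble of
#'   sample_id, trait, colony and retained covariates) and `screen`
#'   (per-covariate ANOVA p-values and retention).
#' @export
prepare_trait <- function(pheno, trait, covariates = character(),
                          colony_col = NULL, alpha = 0.01, min_n = 20L) {
  df <- pheno[!is.na(pheno[[trait]]), , drop = FALSE]
  if (nrow(df) < min_n) {
    stop("need at least ", min_n, " phenotyped samples, have ", nrow(df))
  }
  colony <- if (is.null(colony_col)) factor(rep("colony", nrow(df))) else
    factor(df[[colony_col]])
  y <- rep(NA_real_, nrow(df))
  for (lv in levels(colony)) {
    i <- which(colony == lv)
    z <- stats::qnorm((rank(df[[trait]][i], ties.method = "average") - 0.5) /
                        length(i))
    y[i] <- (z - mean(z)) / stats::sd(z)
  }
  screen <- tibble::tibble(covariate = character(), p_value = numeric(),
                           retained = logical())
  kept <- character()
  for (cv in covariates) {
    x <- df[[cv]]
    if (is.character(x)) x <- factor(x)
    p <- tryCatch({
      fit <- stats::lm(y ~ x)
      an <- stats::anova(fit)
      an[["Pr(>F)"]][1L]
    }, error = function(e) NA_real_)
    keep <- !is.na(p) && p < alpha
    if (keep) kept <- c(kept, cv)
    screen <- dplyr::bind_rows(screen, tibble::tibble(
      covariate = cv, p_value = p, retained = keep))
  }
  data <- tibble::tibble(sample_id = as.character(df$sample_id),
                         trait = y, colony = colony)
  for (cv in kept) data[[cv]] <- df[[cv]]
  structure(list(data = data, trait_name = trait, covariates = kept,
                 screen = screen, alpha = alpha),
            class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat("<trait_model> '", x$trait_name, "': ", nrow(x$data), " samples, ",
      length(levels(x$data$colony)), " colony(ies); covariates retained: ",
      if (length(x$covariates)) paste(x$covariates, collapse = ", ") else
        "none", "\n", sep = "")
  invisible(x)
}

# covariate-only design matrix (intercept + retained covariates + colony
# when >1 level)
null_design <- function(tm, extra = NULL) {
  d <- tm$data
  terms <- c("1", tm$covariates,
             if (nlevels(d$colony) > 1L) "colony")
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X0 <- stats::model.matrix(fml, data = d)
  if (!is.null(extra)) X0 <- cbind(X0, extra)
  X0
}

# partial F of the columns in Z added to X0, computed for every column
# of Y at once (Frisch-Waugh residualization; exact partial F). When Z is
# complete, a precomputed qr(X0) and residualized Y can be shared across
# positions.
partial_f_core <- function(Y, X0, Z, cap = 300, shared = NULL) {
  ok <- stats::complete.cases(Z)
  nr <- sum(ok)
  out <- list(logP = rep(NA_real_, ncol(Y)), varexp = rep(NA_real_, ncol(Y)),
              df1 = NA_integer_, df2 = NA_integer_, note = NA_character_)
  if (nr < 3L) { out$note <- "too few complete cases"; return(out) }
  if (all(ok) && !is.null(shared)) {
    qr0 <- shared$qr0
    p <- qr0$rank
    Ey <- shared$Ey
  } else {
    X0s <- X0[ok, , drop = FALSE]
    qr0 <- qr(X0s)
    p <- qr0$rank
    Ey <- qr.resid(qr0, Y[ok, , drop = FALSE])
  }
  Ez <- qr.resid(qr0, Z[ok, , drop = FALSE])
  # columns fully absorbed by the covariates leave only rounding noise;
  # zero them so the rank reflects genuine added information
  scale_z <- sqrt(colSums(Z[ok, , drop = FALSE]^2))
  dead <- sqrt(colSums(Ez^2)) < 1e-8 * (1 + scale_z)
  Ez[, dead] <- 0
  qrz <- qr(Ez)
  q <- qrz$rank
  if (q == 0L) { out$note <- "design rank-deficient after covariates"; return(out) }
  df2 <- nr - p - q
  if (df2 < 1L) { out$note <- "no residual df"; return(out) }
  Qz <- qr.Q(qrz)[, seq_len(q), drop = FALSE]
  rss0 <- colSums(Ey^2)
  proj <- crossprod(Qz, Ey)
  rss1 <- pmax(rss0 - colSums(proj^2), 0)
  fstat <- ((rss0 - rss1) / q) / (rss1 / df2)
  fstat[rss1 == 0] <- Inf
  logp <- -stats::pf(fstat, q, df2, lower.tail = FALSE, log.p = TRUE) / log(10)
  out$logP <- pmin(ifelse(is.finite(logp), logp, cap), cap)
  out$varexp <- ifelse(rss0 > 0, (rss0 - rss1) / rss0, NA_real_)
  out$df1 <- q; out$df2 <- df2
  out
}

scan_over_positions <- function(Y, X0, z_list, cap = 300) {
  qr0 <- qr(X0)
  shared <- list(qr0 = qr0, Ey = qr.resid(qr0, Y))
  lapply(z_list, function(Z) partial_f_core(Y, X0, Z, cap, shared = shared))
}

genotype_design <- function(d) {
  cbind(het = as.numeric(d == 1L), hom_b = as.numeric(d == 2L),
        deparse.level = 0)[, , drop = FALSE] |>
    (\(m) { m[is.na(d), ] <- NA_real_; m })()
}

as_scan_result <- function(map_rows, res, Ycol = 1L) {
  out <- tibble::tibble(
    marker_id = map_rows$marker_id,
    chrom = map_rows$chrom,
    pos_bp = map_rows$pos_bp,
    logP = vapply(res, function(r) r$logP[Ycol], numeric(1)),
    df1 = vapply(res, function(r) as.integer(r$df1), integer(1)),
    df2 = vapply(res, function(r) as.integer(r$df2), integer(1)),
    variance_explained = vapply(res, function(r) r$varexp[Ycol], numeric(1)),
    note = vapply(res, function(r) r$note, character(1))
  )
  class(out) <- c("scan_result", class(out))
  out
}

align_tm_geno <- function(tm, g) {
  keep <- tm$data$sample_id %in% g$samples
  if (!all(keep)) {
    warning(sum(!keep), " phenotyped sample(s) without genotypes dropped")
  }
  d <- tm$data[keep, , drop = FALSE]
  idx <- match(d$sample_id, g$samples)
  list(tm = structure(c(list(data = d),
                        tm[setdiff(names(tm), "data")]),
                      class = "trait_model"),
       rows = idx)
}

#' Single-marker association scan
#'
#' Per marker, an F test of the genotype factor added to the
#' covariate-only model; logP is the negative base-10 log of the F-test
#' p-value (capped at 300) and variance explained is the partial
#' R-squared.
#'
#' @param tm a [prepare_trait()] model.
#' @param g a `geno_matrix` containing the phenotyped samples.
#' @param cap logP cap (default 300).
#' @return A `scan_result` tibble: marker_id, chrom, pos_bp, logP, df1,
#'   df2, variance_explained, note.
#' @export
single_marker_scan <- function(tm, g, cap = 300) {
  al <- align_tm_geno(tm, g)
  X0 <- null_design(al$tm)
  Y <- matrix(al$tm$data$trait, ncol = 1L)
  calls <- g$calls[al$rows, , drop = FALSE]
  z_list <- lapply(seq_len(ncol(calls)), function(j) genotype_design(calls[, j]))
  res <- scan_over_positions(Y, X0, z_list, cap)
  as_scan_result(g$map, res)
}

#' Conditional single-marker scan
#'
#' Identical to [single_marker_scan()] except that the conditioning
#' marker's genotype enters the covariate model as a factor, so
#' remaining logP measures association not explained by that marker.
#'
#' @inheritParams single_marker_scan
#' @param conditioning_marker marker id to condition on.
#' @return A `scan_result` tibble.
#' @export
conditional_scan <- function(tm, g, conditioning_marker, cap = 300) {
  j <- match(conditioning_marker, g$map$marker_id)
  if (is.na(j)) stop("unknown conditioning marker: ", conditioning_marker)
  al <- align_tm_geno(tm, g)
  cond <- g$calls[al$rows, j]
  keep <- !is.na(cond)
  d <- al$tm$data[keep, , drop = FALSE]
  tm2 <- structure(c(list(data = d), al$tm[setdiff(names(al$tm), "data")]),
                   class = "trait_model")
  X0 <- null_design(tm2, extra = genotype_design(cond[keep]))
  Y <- matrix(d$trait, ncol = 1L)
  calls <- g$calls[al$rows, , drop = FALSE][keep, , drop = FALSE]
  z_list <- lapply(seq_len(ncol(calls)), function(jj) genotype_design(calls[, jj]))
  res <- scan_over_positions(Y, X0, z_list, cap)
  as_scan_result(g$map, res)
}

#' Founder-dosage (haplotype) association scan
#'
#' Per marker, regression of the trait on the expected founder dosages
#' from the mosaic posteriors (one founder column dropped for
#' identifiability; the dosages sum to 2) added to the covariate-only
#' model; the partial F against the covariate-only model is reported.
#' Positions whose dosage design is rank-deficient after covariates are
#' skipped with a diagnostic note.
#'
#' @param tm a [prepare_trait()] model.
#' @param mp a [mosaic_posteriors()] object covering the phenotyped
#'   samples.
#' @param cap logP cap (default 300).
#' @return A `scan_result` tibble.
#' @export
haplotype_scan <- function(tm, mp, cap = 300) {
  idx <- match(tm$data$sample_id, mp$samples)
  if (anyNA(idx)) stop("phenotyped sample(s) without mosaic posteriors: ",
                       paste(utils::head(tm$data$sample_id[is.na(idx)], 5L),
                             collapse = ", "))
  dos <- founder_dosages(mp)[idx]
  X0 <- null_design(tm)
  Y <- matrix(tm$data$trait, ncol = 1L)
  s <- length(mp$founders)
  m <- nrow(mp$map)
  z_list <- lapply(seq_len(m), function(t) {
    Z <- t(vapply(dos, function(d) d[t, ], numeric(s)))
    Z[, -s, drop = FALSE]
  })
  res <- scan_over_positions(Y, X0, z_list, cap)
  as_scan_result(mp$map, res)
}

permute_within_colony <- function(trait, colony, n_perm) {
  Y <- matrix(NA_real_, length(trait), n_perm)
  for (r in seq_len(n_perm)) {
    idx <- seq_along(trait)
    for (lv in levels(colony)) {
      i <- which(colony == lv)
      idx[i] <- i[sample.int(length(i))]
    }
    Y[, r] <- trait[idx]
  }
  Y
}

#' Region-wide permutation significance threshold
#'
#' Permutes the transformed trait across samples (within colony when the
#' model spans several colonies, preserving colony-level trait
#' differences; covariates stay attached to their samples), rescans the
#' region for each permutation, and returns the 95th percentile of the
#' per-permutation region-wide maximum logP.
#'
#' @param tm a [prepare_trait()] model.
#' @param scan_input a `geno_matrix` (single-marker scan) or
#'   `mosaic_posterior` (founder-dosage scan).
#' @param n_perm number of permutations (>= 100; the survey convention
#'   is 1000).
#' @param seed RNG seed.
#' @param level threshold quantile (default 0.95).
#' @param cap logP cap.
#' @return threshold logP (scalar); attribute `max_logP` holds the
#'   permutation maxima.
#' @export
permutation_threshold <- function(tm, scan_input, n_perm = 1000L, seed = 1L,
                                  level = 0.95, cap = 300) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (inherits(scan_input, "mosaic_posterior")) {
    mp <- scan_input
    idx <- match(tm$data$sample_id, mp$samples)
    dos <- founder_dosages(mp)[idx]
    s <- length(mp$founders)
    z_list <- lapply(seq_len(nrow(mp$map)), function(t) {
      Z <- t(vapply(dos, function(d) d[t, ], numeric(s)))
      Z[, -s, drop = FALSE]
    })
    X0 <- null_design(tm)
    trait <- tm$data$trait; colony <- tm$data$colony
  } else {
    al <- align_tm_geno(tm, scan_input)
    calls <- scan_input$calls[al$rows, , drop = FALSE]
    z_list <- lapply(seq_len(ncol(calls)), function(j)
      genotype_design(calls[, j]))
    X0 <- null_design(al$tm)
    trait <- al$tm$data$trait; colony <- al$tm$data$colony
  }
  Y <- withr::with_seed(seed, permute_within_colony(trait, colony, n_perm))
  res <- scan_over_positions(Y, X0, z_list, cap)
  mx <- apply(do.call(rbind, lapply(res, `[[`, "logP")), 2L, max, na.rm = TRUE)
  thr <- stats::quantile(mx, level, names = FALSE)
  attr(thr, "max_logP") <- mx
  thr
}

#' Shared founder-effect partial F test across colonies
#'
#' At the peak interval of the pooled founder-dosage scan, compares a
#' null model with one trait effect per founder strain shared by all
#' colonies (plus covariates and a colony main effect) against a full
#' model in which each colony has its own founder effects. A small
#' partial-F p-value indicates the colonies do not share QTL allele
#' effects; non-rejection supports mapping on the shared-ancestor
#' assumption.
#'
#' @param tms list of [prepare_trait()] models, one per colony.
#' @param mps list of matching [mosaic_posteriors()] objects (same
#'   founder panel and marker map).
#' @param peak_marker optional marker id; default is the argmax of the
#'   pooled scan's logP.
#' @return A one-row tibble: peak_marker, f_statistic, df1, df2,
#'   p_value.
#' @export
shared_effect_test <- function(tms, mps, peak_marker = NULL) {
  if (length(tms) < 2L || length(tms) != length(mps)) {
    stop("need matched trait models and posteriors for >= 2 colonies")
  }
  map <- mps[[1L]]$map
  for (mp in mps[-1L]) {
    if (!identical(mp$map$marker_id, map$marker_id)) {
      stop("posteriors must share a marker map")
    }
  }
  s <- length(mps[[1L]]$founders)
  y <- unlist(lapply(tms, function(tm) tm$data$trait))
  colony <- factor(rep(seq_along(tms),
                       vapply(tms, function(tm) nrow(tm$data), integer(1))))
  dos_all <- vector("list", length(tms))
  for (k in seq_along(tms)) {
    idx <- match(tms[[k]]$data$sample_id, mps[[k]]$samples)
    dos_all[[k]] <- founder_dosages(mps[[k]])[idx]
  }
  dose_at <- function(t) {
    do.call(rbind, lapply(dos_all, function(dd)
      t(vapply(dd, function(d) d[t, ], numeric(s)))))
  }
  if (is.null(peak_marker)) {
    X0 <- stats::model.matrix(~colony)
    Y <- matrix(y, ncol = 1L)
    z_list <- lapply(seq_len(nrow(map)), function(t)
      dose_at(t)[, -s, drop = FALSE])
    res <- scan_over_positions(Y, X0, z_list)
    logp <- vapply(res, function(r) r$logP[1L], numeric(1))
    t_peak <- which.max(logp)
  } else {
    t_peak <- match(peak_marker, map$marker_id)
    if (is.na(t_peak)) stop("unknown peak marker: ", peak_marker)
  }
  D <- dose_at(t_peak)[, -s, drop = FALSE]
  X_null <- cbind(stats::model.matrix(~colony), D)
  inter <- stats::model.matrix(~ colony:D - 1)
  fit0 <- stats::lm.fit(X_null, y)
  X_full <- cbind(X_null, inter)
  fit1 <- stats::lm.fit(X_full, y)
  rss0 <- sum(fit0$residuals^2); rss1 <- sum(fit1$residuals^2)
  df1 <- fit0$df.residual - fit1$df.residual
  df2 <- fit1$df.residual
  if (df1 < 1L || df2 < 1L) stop("degenerate design at peak interval")
  fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  tibble::tibble(peak_marker = map$marker_id[t_peak], f_statistic = fstat,
                 df1 = df1, df2 = df2,
                 p_value = stats::pf(fstat, df1, df2, lower.tail = FALSE))
}

#' @method glance scan_result
#' @export
glance.scan_result <- function(x, ...) {
  ok <- !is.na(x$logP)
  pk <- if (any(ok)) which.max(x$logP) else NA_integer_
  tibble::tibble(
    n_positions = nrow(x),
    peak_marker = if (!is.na(pk)) x$marker_id[pk] else NA_character_,
    peak_pos_bp = if (!is.na(pk)) x$pos_bp[pk] else NA_integer_,
    peak_logP = if (!is.na(pk)) x$logP[pk] else NA_real_,
    peak_variance_explained = if (!is.na(pk)) x$variance_explained[pk]
      else NA_real_)
}
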