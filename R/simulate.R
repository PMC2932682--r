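#' Simulation configuration
#'
#' Collects the knobs of the forward-in-time colony simulator. Defaults
#' describe a desk-scale outbred colony: 8 inbred founders, 351 markers
#' in a 5 Mb region (the sparse survey panel density), 30 generations of
#' random mating at census size 100, a uniform 0.5 cM/Mb genetic map,
#' 1\% per-allele genotyping error and 2\% missing calls.
#'
#' @param n_founders number of inbred founder strains (>= 2).
#' @param n_markers markers in the region.
#' @param region_span_bp physical span of the region.
#' @param divergence target mean pairwise allele difference between
#'   founders (0-1; values above 0.5 only with 2 founders).
#' @param scheme breeding scheme: `"random"`, `"circular"`,
#'   `"rotational"` or `"igs_bottleneck"`.
#' @param generations breeding generations G (>= 1).
#' @param census breeding population size N (>= 2).
#' @param mutation_rate per-allele per-generation mutation rate
#'   (creates alleles private to the colony).
#' @param genotype_error per-allele genotyping error rate.
#' @param missing_rate per-call missing rate.
#' @param cM_per_Mb uniform genetic map density.
#' @param n_groups groups for the rotational scheme.
#' @param igs_reservoir,igs_period,igs_frac reservoir size, period
#'   (generations) and fraction of parents drawn from the reservoir for
#'   the IGS-style scheme.
#' @param chrom chromosome label for the simulated region.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 8L, n_markers = 351L,
                       region_span_bp = 5e6, divergence = 0.35,
                       scheme = c("random", "circular", "rotational",
                                  "igs_bottleneck"),
                       generations = 30L, census = 100L,
                       mutation_rate = 0, genotype_error = 0.01,
                       missing_rate = 0.02, cM_per_Mb = 0.5,
                       n_groups = 4L, igs_reservoir = 8L, igs_period = 5L,
                       igs_frac = 0.5, chrom = "1") {
  scheme <- match.arg(scheme)
  stopifnot(n_founders >= 2L, generations >= 1L, census >= 2L,
            divergence >= 0, divergence <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            genotype_error >= 0, genotype_error <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (divergence > 0.5 && n_founders > 2L) {
    stop("divergence above 0.5 is only attainable with 2 founders")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a founder panel of homozygous inbred strains
#'
#' Per-marker allele frequencies across founders are drawn from a
#' symmetric Beta whose parameter is chosen so that the expected mean
#' pairwise allele difference equals `divergence`; each founder's
#' (homozygous) allele is then a Bernoulli draw. `divergence = 0` gives
#' identical founders; values above 0.5 (2 founders only) make the two
#' founders differ at each marker with that probability.
#'
#' @param S number of founders.
#' @param n_markers markers.
#' @param divergence target mean pairwise difference.
#' @param seed RNG seed.
#' @param region_span_bp region length (positions drawn uniformly).
#' @param chrom chromosome label.
#' @param ensure_polymorphic flip one strain's allele at any marker fixed
#'   across the panel, so every marker segregates (default FALSE).
#' @return A [founder_panel()].
#' @export
simulate_founders <- function(S, n_markers, divergence = 0.35, seed = 1L,
                              region_span_bp = 5e6, chrom = "1",
                              ensure_polymorphic = FALSE) {
  stopifnot(S >= 2L)
  withr::with_seed(seed, {
    pos <- sort(sample.int(region_span_bp, n_markers))
    map <- marker_map(sprintf("m%04d", seq_len(n_markers)), chrom, pos,
                      "A", "G")
    if (divergence == 0) {
      hap <- stats::rbinom(n_markers, 1L, 0.5)
      al <- matrix(rep(hap, each = S), S, n_markers)
    } else if (divergence > 0.5) {
      h1 <- stats::rbinom(n_markers, 1L, 0.5)
      flip <- stats::rbinom(n_markers, 1L, divergence)
      al <- rbind(h1, ifelse(flip == 1L, 1L - h1, h1))
    } else if (divergence == 0.5) {
      al <- matrix(stats::rbinom(S * n_markers, 1L, 0.5), S, n_markers)
    } else {
      a <- divergence / (1 - 2 * divergence)
      p <- stats::rbeta(n_markers, a, a)
      al <- matrix(stats::rbinom(S * n_markers, 1L, rep(p, each = S)),
                   S, n_markers)
    }
    if (ensure_polymorphic && S > 2L) {
      mono <- colSums(al) %in% c(0L, S)
      if (any(mono)) {
        flip <- sample.int(S, sum(mono), replace = TRUE)
        al[cbind(flip, which(mono))] <- 1L - al[cbind(flip, which(mono))]
      }
    }
    g <- geno_matrix(2L * al, map, sprintf("F%02d", seq_len(S)))
    founder_panel(g)
  })
}

# one gamete: vector of 0/1 indicating which parental haplotype each
# marker comes from, with Poisson crossovers on a uniform map
gamete_pattern <- function(pos, span_bp, morgans) {
  k <- stats::rpois(1L, morgans)
  start <- sample.int(2L, 1L) - 1L
  if (k == 0L) return(rep(start, length(pos)))
  xo <- sort(stats::runif(k, 0, span_bp))
  (findInterval(pos, xo) + start) %% 2L
}

parent_pairs <- function(N, scheme, gen, cfg) {
  switch(scheme,
    random = t(vapply(seq_len(N), function(i) sample.int(N, 2L), integer(2))),
    circular = cbind(seq_len(N), c(seq_len(N)[-1L], 1L)),
    rotational = {
      grp <- ((seq_len(N) - 1L) %% cfg$n_groups) + 1L
      p1 <- integer(N); p2 <- integer(N)
      for (i in seq_len(N)) {
        g1 <- grp[i]
        g2 <- ((g1 - 1L + gen) %% cfg$n_groups) + 1L
        p1[i] <- sample(which(grp == g1), 1L)
        p2[i] <- sample(which(grp == g2), 1L)
        if (p2[i] == p1[i]) p2[i] <- sample(which(grp == g2), 1L)
      }
      cbind(p1, p2)
    },
    stop("unknown scheme"))
}

#' Breed a colony forward in time
#'
#' Forward simulation from a founder panel under a named breeding
#' scheme: random pair mating, circular (ring-neighbour) mating, group
#' rotation, or an IGS-style scheme in which a small reservoir
#' population is bred in parallel and periodically supplies a fraction
#' of the parents (spreading few chromosomes widely and inflating LD).
#' Meiosis places Poisson crossovers on the uniform genetic map (no
#' interference), matching the mapping model's assumptions. Genotypes
#' are emitted with per-allele error and per-call missingness; the
#' founder-label mosaic, pedigree of the final generation, observed
#' heterozygosity trajectory and offspring-number variance (for Ne
#' estimation) are recorded as ground truth.
#'
#' @param founders a [founder_panel()].
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @param colony_id label for the resulting panel.
#' @return list with `colony` (a [colony_panel()]) and `truth` (list:
#'   `hap_labels` 2N x m founder indices, `hap_alleles`, `genotypes`
#'   pre-error codes, `founder_fractions`, `het_trajectory`,
#'   `offspring_var`, `parents`, `parent_hap_alleles`, `qtl`).
#' @export
breed_colony <- function(founders, cfg, seed = 1L, colony_id = "sim") {
  stopifnot(inherits(founders, "geno_matrix"), inherits(cfg, "sim_config"))
  m <- n_markers(founders)
  S <- n_samples(founders)
  pos <- founders$map$pos_bp
  span <- cfg$region_span_bp
  morgans <- span * cfg$cM_per_Mb / 1e6 / 100
  N <- cfg$census
  if (cfg$scheme %in% c("circular", "rotational") && N %% 2L == 1L) {
    warning("census adjusted to even size for paired scheme")
    N <- N + 1L
  }
  withr::with_seed(seed, {
    fal <- founders$calls / 2L
    fal[is.na(fal)] <- stats::rbinom(sum(is.na(fal)), 1L, 0.5)
    init <- sample.int(S, 2L * N, replace = TRUE)
    H <- fal[init, , drop = FALSE]          # 2N x m haplotype alleles
    L <- matrix(rep(init, m), 2L * N, m)    # founder labels
    res_H <- res_L <- NULL
    if (cfg$scheme == "igs_bottleneck") {
      ri <- sample.int(S, 2L * cfg$igs_reservoir, replace = TRUE)
      res_H <- fal[ri, , drop = FALSE]
      res_L <- matrix(rep(ri, m), 2L * cfg$igs_reservoir, m)
    }
    het_traj <- numeric(cfg$generations)
    vk <- numeric(cfg$generations)
    parents <- NULL; parent_H <- NULL
    base_scheme <- if (cfg$scheme == "igs_bottleneck") "random" else cfg$scheme
    make_gen <- function(H, L, pairs, mu) {
      n_off <- nrow(pairs)
      H2 <- matrix(0L, 2L * n_off, ncol(H))
      L2 <- matrix(0L, 2L * n_off, ncol(L))
      for (i in seq_len(n_off)) {
        for (w in 1:2) {
          p <- pairs[i, w]
          use <- gamete_pattern(pos, span, morgans)
          rows <- c(2L * p - 1L, 2L * p)
          pick <- rows[use + 1L]
          sel <- cbind(pick, seq_len(ncol(H)))
          H2[2L * i - 2L + w, ] <- H[sel]
          L2[2L * i - 2L + w, ] <- L[sel]
        }
      }
      if (mu > 0) {
        flip <- matrix(stats::runif(length(H2)) < mu, nrow(H2), ncol(H2))
        H2[flip] <- 1L - H2[flip]
      }
      list(H = H2, L = L2)
    }
    for (g in seq_len(cfg$generations)) {
      pairs <- parent_pairs(N, base_scheme, g, cfg)
      if (cfg$scheme == "igs_bottleneck") {
        # reservoir breeds randomly at its own small size
        rp <- parent_pairs(cfg$igs_reservoir, "random", g, cfg)
        nxt_res <- make_gen(res_H, res_L, rp, cfg$mutation_rate)
        if (g %% cfg$igs_period == 0L) {
          # a fraction of parent slots are filled from the reservoir:
          # encode reservoir parents as negative indices
          repl <- matrix(stats::runif(length(pairs)) < cfg$igs_frac,
                         nrow(pairs), 2L)
          pairs[repl] <- -sample.int(cfg$igs_reservoir, sum(repl),
                                     replace = TRUE)
        }
      }
      if (any(pairs < 0L)) {
        Hc <- rbind(H, res_H); Lc <- rbind(L, res_L)
        off <- abs(pairs) + ifelse(pairs < 0L, N, 0L)
        nxt <- make_gen(Hc, Lc, off, cfg$mutation_rate)
      } else {
        nxt <- make_gen(H, L, pairs, cfg$mutation_rate)
      }
      vk[g] <- stats::var(tabulate(abs(pairs), nbins = N +
                                     if (cfg$scheme == "igs_bottleneck")
                                       cfg$igs_reservoir else 0L)[seq_len(N)])
      if (g == cfg$generations) { parents <- pairs; parent_H <- H }
      H <- nxt$H; L <- nxt$L
      if (cfg$scheme == "igs_bottleneck") {
        res_H <- nxt_res$H; res_L <- nxt_res$L
      }
      odd <- seq(1L, 2L * N, by = 2L)
      het_traj[g] <- mean(H[odd, , drop = FALSE] != H[odd + 1L, , drop = FALSE])
    }
    odd <- seq(1L, 2L * N, by = 2L)
    geno_true <- H[odd, , drop = FALSE] + H[odd + 1L, , drop = FALSE]
    calls <- geno_true
    if (cfg$genotype_error > 0) {
      # per-allele flips, matching the HMM emission model
      e1 <- matrix(stats::runif(length(calls)) < cfg$genotype_error,
                   nrow(calls), ncol(calls))
      e2 <- matrix(stats::runif(length(calls)) < cfg$genotype_error,
                   nrow(calls), ncol(calls))
      a1 <- H[odd, , drop = FALSE]; a2 <- H[odd + 1L, , drop = FALSE]
      a1[e1] <- 1L - a1[e1]; a2[e2] <- 1L - a2[e2]
      calls <- a1 + a2
    }
    if (cfg$missing_rate > 0) {
      miss <- matrix(stats::runif(length(calls)) < cfg$missing_rate,
                     nrow(calls), ncol(calls))
      calls[miss] <- NA_integer_
    }
    ids <- sprintf("%s_I%03d", colony_id, seq_len(N))
    g <- geno_matrix(calls, founders$map, ids)
    scheme_label <- switch(cfg$scheme, igs_bottleneck = "igs",
                           cfg$scheme)
    colony <- colony_panel(g, colony_id, scheme = scheme_label,
                           colony_size = N)
    truth <- list(
      hap_labels = L, hap_alleles = H, genotypes = geno_true,
      founder_fractions = as.numeric(
        tabulate(L, nbins = S) / length(L)),
      founder_names = founders$samples,
      het_trajectory = het_traj, offspring_var = vk,
      parents = parents, parent_hap_alleles = parent_H, qtl = NULL)
    list(colony = colony, truth = truth)
  })
}

#' Plant a quantitative phenotype with a QTL
#'
#' Builds a trait from the colony's true (pre-error) genotypes: a
#' genetic value from either the additive dosage at one marker
#' (`marker_additive`) or per-founder allele effects at one marker
#' (`founder_allele`, for shared-vs-colony-specific effect designs),
#' standardized and scaled so the genetic component explains
#' `target_variance` of the non-covariate trait variance; optional
#' covariate effects are added on top of Gaussian noise.
#'
#' @param sim result of [breed_colony()].
#' @param target_variance variance fraction explained by the QTL
#'   (0-0.9).
#' @param effect_type `"marker_additive"` or `"founder_allele"`.
#' @param qtl_marker marker id (default: most central marker with
#'   MAF >= 0.1, or maximal MAF).
#' @param founder_effects numeric vector of per-founder effects
#'   (founder_allele mode; default a standard-normal draw).
#' @param covariates named list of covariate effect sizes (in trait sd
#'   units); each becomes a balanced two-level factor.
#' @param seed RNG seed.
#' @return A phenotype tibble (sample_id, trait, covariates) with
#'   attribute `qtl` describing the planted effect.
#' @export
plant_phenotype <- function(sim, target_variance = 0.15,
                            effect_type = c("marker_additive",
                                            "founder_allele"),
                            qtl_marker = NULL, founder_effects = NULL,
                            covariates = NULL, seed = 1L) {
  effect_type <- match.arg(effect_type)
  stopifnot(target_variance >= 0, target_variance <= 0.9)
  colony <- sim$colony; truth <- sim$truth
  m <- n_markers(colony); n <- n_samples(colony)
  withr::with_seed(seed, {
    maf <- apply(truth$genotypes, 2L, minor_allele_freq)
    if (is.null(qtl_marker)) {
      ok <- which(!is.na(maf) & maf >= 0.1)
      if (!length(ok)) ok <- which.max(maf)
      j <- ok[which.min(abs(ok - m / 2))]
    } else {
      j <- match(qtl_marker, colony$map$marker_id)
      if (is.na(j)) stop("unknown qtl marker")
    }
    gval <- if (effect_type == "marker_additive") {
      as.numeric(truth$genotypes[, j])
    } else {
      S <- length(truth$founder_names)
      if (is.null(founder_effects)) founder_effects <- stats::rnorm(S)
      lab1 <- truth$hap_labels[seq(1L, 2L * n, 2L), j]
      lab2 <- truth$hap_labels[seq(2L, 2L * n, 2L), j]
      founder_effects[lab1] + founder_effects[lab2]
    }
    noise <- stats::rnorm(n)
    if (target_variance > 0 && stats::sd(gval) > 0) {
      trait <- scale(gval)[, 1L] * sqrt(target_variance) +
        noise * sqrt(1 - target_variance)
    } else {
      trait <- noise
    }
    out <- tibble::tibble(sample_id = colony$samples, trait = trait)
    if (!is.null(covariates)) {
      for (nm in names(covariates)) {
        lev <- factor(sample(c("a", "b"), n, replace = TRUE))
        out[[nm]] <- lev
        out$trait <- out$trait + covariates[[nm]] * (as.integer(lev) - 1L)
      }
    }
    attr(out, "qtl") <- list(marker_id = colony$map$marker_id[j],
                             index = j, effect_type = effect_type,
                             target_variance = target_variance,
                             founder_effects = if (effect_type ==
                                                   "founder_allele")
                               founder_effects else NULL)
    out
  })
}

#' Simulate a catalogue of known variant positions
#'
#' @param n_variants catalogue size.
#' @param chrom chromosome label.
#' @param span_bp positions drawn uniformly in 1..span_bp.
#' @param seed RNG seed.
#' @return tibble with chrom, pos_bp, ref, alt.
#' @export
simulate_catalogue <- function(n_variants = 5000L, chrom = "1",
                               span_bp = 5e6, seed = 1L) {
  withr::with_seed(seed, {
    pos <- sort(sample.int(span_bp, n_variants))
    tibble::tibble(chrom = chrom, pos_bp = pos,
                   ref = sample(c("A", "C", "G", "T"), n_variants, TRUE),
                   alt = sample(c("A", "C", "G", "T"), n_variants, TRUE))
  })
}

#' Simulate a variant-call table with read-level metadata
#'
#' Draws calls from the catalogue, replacing a fraction with novel
#' positions absent from it; depths are Poisson, read-end and
#' restriction-site distances uniform within the given ranges.
#'
#' @param catalogue tibble from [simulate_catalogue()] (chrom, pos_bp,
#'   alt).
#' @param n_calls number of calls to emit.
#' @param novel_fraction expected fraction of calls at novel positions.
#' @param depth_mean Poisson mean read depth.
#' @param end_dist_range,site_dist_range uniform integer ranges for the
#'   read-level distances.
#' @param seed RNG seed.
#' @return tibble with chrom, pos_bp, ref, alt, depth,
#'   dist_to_read_end_bp, dist_to_site_bp.
#' @export
simulate_variant_table <- function(catalogue, n_calls = 1000L,
                                   novel_fraction = 0, depth_mean = 30,
                                   end_dist_range = c(0L, 45L),
                                   site_dist_range = c(0L, 32L),
                                   seed = 1L) {
  stopifnot(novel_fraction >= 0, novel_fraction <= 1)
  withr::with_seed(seed, {
    is_novel <- stats::runif(n_calls) < novel_fraction
    rows <- sample.int(nrow(catalogue), n_calls, replace = TRUE)
    out <- catalogue[rows, c("chrom", "pos_bp", "ref", "alt")]
    if (any(is_novel)) {
      span <- max(catalogue$pos_bp)
      free <- setdiff(seq_len(span), catalogue$pos_bp)
      out$pos_bp[is_novel] <- sample(free, sum(is_novel), replace = TRUE)
    }
    out$depth <- stats::rpois(n_calls, depth_mean)
    out$dist_to_read_end_bp <- sample(end_dist_range[1L]:end_dist_range[2L],
                                      n_calls, replace = TRUE)
    out$dist_to_site_bp <- sample(site_dist_range[1L]:site_dist_range[2L],
                                  n_calls, replace = TRUE)
    tibble::as_tibble(out)
  })
}

#' Sparse-panel validation by marker subsampling
#'
#' Repeatedly samples sparse marker panels (a few contiguous windows of
#' matched span, mirroring multi-locus survey panels) from a dense
#' genotype set, computes the colony metric battery on each replicate,
#' and locates a supplied sparse-panel estimate on the replicate
#' distribution.
#'
#' @param dense a `geno_matrix`/`colony_panel` with a dense marker set.
#' @param n_markers total markers per replicate.
#' @param n_regions number of contiguous windows per replicate.
#' @param n_reps replicates.
#' @param seed RNG seed.
#' @param sparse_estimate optional named numeric (columns of
#'   [colony_metrics()]) whose percentile positions are reported.
#' @param alpha HWE alpha passed through.
#' @return tibble of per-replicate metrics; attribute `percentiles` when
#'   `sparse_estimate` is given.
#' @export
subsample_markers <- function(dense, n_markers = 351L, n_regions = 4L,
                              n_reps = 100L, seed = 1L,
                              sparse_estimate = NULL, alpha = 0.05) {
  m <- n_markers(dense)
  if (m < n_markers) stop("dense set smaller than requested subsample")
  per <- ceiling(n_markers / n_regions)
  reps <- withr::with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      starts <- sample.int(m - per + 1L, n_regions, replace = TRUE)
      idx <- sort(unique(unlist(lapply(starts, function(s)
        seq.int(s, length.out = per)))))
      sub <- subset_geno(dense, markers = idx)
      dplyr::mutate(colony_metrics(sub, alpha = alpha), replicate = r)
    })
  })
  out <- dplyr::bind_rows(reps)
  if (!is.null(sparse_estimate)) {
    pct <- vapply(names(sparse_estimate), function(nm) {
      100 * mean(out[[nm]] <= sparse_estimate[[nm]])
    }, numeric(1))
    attr(out, "percentiles") <- pct
  }
  out
}
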