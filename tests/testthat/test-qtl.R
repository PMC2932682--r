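sim_trait_fixture <- function(n = 120, m = 60, seed = 1, tv = 0.2) {
  f <- simulate_founders(4, m, divergence = 0.4, seed = seed)
  cfg <- sim_config(n_founders = 4, n_markers = m, generations = 15,
                    census = n, genotype_error = 0, missing_rate = 0)
  sim <- breed_colony(f, cfg, seed = seed + 1)
  ph <- plant_phenotype(sim, target_variance = tv, seed = seed + 2)
  list(sim = sim, ph = ph, founders = f)
}

test_that("trait preparation standardizes within colony and is rank
           invariant", {
  withr::with_seed(30, {
    ph <- tibble::tibble(sample_id = paste0("s", 1:60),
                         y = rexp(60),
                         colony = rep(c("A", "B"), each = 30))
  })
  tm <- prepare_trait(ph, "y", colony_col = "colony")
  for (lv in c("A", "B")) {
    v <- tm$data$trait[tm$data$colony == lv]
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(sd(v) - 1), 1e-6)
  }
  # monotone recoding leaves the transformed values unchanged
  ph2 <- dplyr::mutate(ph, y = log(y))
  tm2 <- prepare_trait(ph2, "y", colony_col = "colony")
  expect_equal(tm$data$trait, tm2$data$trait)
})

test_that("covariate screening keeps real covariates and drops noise at
           the nominal rate", {
  withr::with_seed(31, {
    n <- 200
    sex <- factor(sample(c("m", "f"), n, TRUE))
    y <- rnorm(n) + 2 * (sex == "m")
    ph <- tibble::tibble(sample_id = paste0("s", 1:n), y = y, sex = sex,
                         junk = rnorm(n))
  })
  tm <- prepare_trait(ph, "y", covariates = c("sex", "junk"))
  expect_true("sex" %in% tm$covariates)
  # pure-noise covariates retained at ~ the screening level
  hits <- withr::with_seed(32, {
    vapply(1:300, function(i) {
      ph$junk <- rnorm(200)
      "junk" %in% prepare_trait(ph, "y", covariates = "junk")$covariates
    }, logical(1))
  })
  expect_lt(mean(hits), 0.04)
})

test_that("a noise-free monogenic trait saturates the scan at the causal
           marker", {
  fx <- sim_trait_fixture(n = 80, seed = 40)
  qtl <- attr(fx$ph, "qtl")
  ph <- fx$ph
  ph$trait <- as.numeric(fx$sim$truth$genotypes[, qtl$index])
  tm <- prepare_trait(ph, "trait")
  sc <- single_marker_scan(tm, fx$sim$colony)
  j <- match(qtl$marker_id, sc$marker_id)
  expect_gt(sc$variance_explained[j], 0.99)
  expect_gte(sc$logP[j], 30)
})

test_that("null-scan p-values are uniform", {
  withr::with_seed(41, {
    n <- 150
    calls <- sapply(runif(1000, 0.1, 0.5), function(p) rbinom(n, 2, p))
    ph <- tibble::tibble(sample_id = sprintf("S%03d", 1:n), y = rnorm(n))
  })
  g <- geno_matrix(calls, marker_map(paste0("m", 1:1000), "1",
                                     seq_len(1000) * 1000),
                   sprintf("S%03d", 1:150))
  tm <- prepare_trait(ph, "y")
  sc <- single_marker_scan(tm, g)
  p <- 10^(-sc$logP[!is.na(sc$logP)])
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("variance explained of a 15% QTL is recovered without gross
           bias", {
  ve <- vapply(1:40, function(r) {
    f <- simulate_founders(4, 40, divergence = 0.4, seed = 300 + r)
    cfg <- sim_config(n_founders = 4, n_markers = 40, generations = 10,
                      census = 200, genotype_error = 0, missing_rate = 0)
    sim <- breed_colony(f, cfg, seed = 600 + r)
    ph <- plant_phenotype(sim, target_variance = 0.15, seed = 900 + r)
    qtl <- attr(ph, "qtl")
    tm <- prepare_trait(ph, "trait")
    sc <- single_marker_scan(tm, sim$colony)
    sc$variance_explained[match(qtl$marker_id, sc$marker_id)]
  }, numeric(1))
  expect_gte(median(ve), 0.10)
  expect_lte(median(ve), 0.20)
})

test_that("conditional scans remove linked signal but not independent
           QTLs", {
  fx <- sim_trait_fixture(n = 200, seed = 50, tv = 0.4)
  qtl <- attr(fx$ph, "qtl")
  tm <- prepare_trait(fx$ph, "trait")
  sc <- single_marker_scan(tm, fx$sim$colony)
  csc <- conditional_scan(tm, fx$sim$colony, qtl$marker_id)
  # conditioning marker against itself: the genotype term is exactly
  # collinear with the covariates, so no evidence remains
  self_row <- match(qtl$marker_id, csc$marker_id)
  expect_true(is.na(csc$logP[self_row]) || csc$logP[self_row] < 0.8)
  # linked markers lose their signal
  linked <- which(sc$logP > 4 & sc$marker_id != qtl$marker_id)
  if (length(linked)) {
    expect_lt(max(csc$logP[linked], na.rm = TRUE),
              max(sc$logP[linked], na.rm = TRUE))
  }
  # two independent QTLs: conditioning on one leaves the other
  withr::with_seed(51, {
    n <- 200
    g1 <- rbinom(n, 2, 0.5); g2 <- rbinom(n, 2, 0.5)
    y <- scale(g1)[, 1] * 0.6 + scale(g2)[, 1] * 0.6 + rnorm(n)
    filler <- sapply(runif(20, 0.2, 0.5), function(p) rbinom(n, 2, p))
  })
  g <- geno_matrix(cbind(g1, filler[, 1:10], g2, filler[, 11:20]),
                   marker_map(paste0("m", 1:22), "1", (1:22) * 5e4),
                   sprintf("S%03d", 1:n))
  ph <- tibble::tibble(sample_id = sprintf("S%03d", 1:n), y = y)
  tm2 <- prepare_trait(ph, "y")
  c2 <- conditional_scan(tm2, g, "m1")
  expect_true(is.na(c2$logP[1]) || c2$logP[1] < 0.8)
  expect_gt(c2$logP[12], 4)       # the second causal marker survives
})

test_that("permutation thresholds are deterministic, grow with marker
           count, and sit in the survey's order of magnitude", {
  withr::with_seed(52, {
    n <- 200
    calls <- sapply(runif(351, 0.1, 0.5), function(p) rbinom(n, 2, p))
    ph <- tibble::tibble(sample_id = sprintf("S%03d", 1:n), y = rnorm(n))
  })
  g351 <- geno_matrix(calls, marker_map(paste0("m", 1:351), "1",
                                        seq_len(351) * 1e4),
                      sprintf("S%03d", 1:200))
  tm <- prepare_trait(ph, "y")
  thr <- permutation_threshold(tm, g351, n_perm = 300, seed = 9)
  expect_gt(as.numeric(thr), 1.5)
  expect_lt(as.numeric(thr), 4.0)
  thr_same <- permutation_threshold(tm, g351, n_perm = 300, seed = 9)
  expect_identical(as.numeric(thr), as.numeric(thr_same))
  g100 <- subset_geno(g351, markers = 1:100)
  thr100 <- permutation_threshold(tm, g100, n_perm = 300, seed = 9)
  expect_lt(as.numeric(thr100), as.numeric(thr))
})

test_that("founder-dosage scans find a planted founder effect and flag
           degenerate designs", {
  f <- simulate_founders(4, 80, divergence = 0.45, seed = 60)
  cfg <- sim_config(n_founders = 4, n_markers = 80, generations = 10,
                    census = 150, genotype_error = 0, missing_rate = 0)
  sim <- breed_colony(f, cfg, seed = 61)
  ph <- plant_phenotype(sim, target_variance = 0.8,
                        effect_type = "founder_allele", seed = 62)
  qtl <- attr(ph, "qtl")
  tm <- prepare_trait(ph, "trait")
  model <- mosaic_model(f, G = 10, error = 0.01)
  mp <- mosaic_posteriors(sim$colony, model)
  sc <- haplotype_scan(tm, mp)
  peak <- which.max(sc$logP)
  expect_lt(abs(peak - qtl$index), 4)
  # a posterior concentrated on one pair everywhere gives a rank-deficient
  # design and a diagnostic note
  mp0 <- mp
  for (i in seq_along(mp0$posteriors)) {
    po <- mp0$posteriors[[i]] * 0
    po[, 1] <- 1
    mp0$posteriors[[i]] <- po
  }
  sc0 <- haplotype_scan(tm, mp0)
  expect_true(all(is.na(sc0$logP)))
  expect_true(all(sc0$note == "design rank-deficient after covariates"))
})

test_that("the shared-effect partial F test rejects opposite effects and
           spares shared ones", {
  make_colony_fit <- function(seed, effects) {
    f <- simulate_founders(4, 60, divergence = 0.45, seed = 70)
    cfg <- sim_config(n_founders = 4, n_markers = 60, generations = 12,
                      census = 120, genotype_error = 0, missing_rate = 0)
    sim <- breed_colony(f, cfg, seed = seed)
    ph <- plant_phenotype(sim, target_variance = 0.3,
                          effect_type = "founder_allele",
                          qtl_marker = "m0030",
                          founder_effects = effects, seed = seed + 1)
    tm <- prepare_trait(ph, "trait")
    mp <- mosaic_posteriors(sim$colony, mosaic_model(f, G = 12,
                                                     error = 0.01))
    list(tm = tm, mp = mp)
  }
  eff <- c(1, -1, 0.5, -0.5)
  shared <- lapply(c(71, 73, 75), function(s) make_colony_fit(s, eff))
  res_s <- shared_effect_test(lapply(shared, `[[`, "tm"),
                              lapply(shared, `[[`, "mp"))
  expect_gt(res_s$p_value, 0.01)
  flipped <- list(make_colony_fit(81, eff), make_colony_fit(83, -2 * eff))
  res_f <- shared_effect_test(lapply(flipped, `[[`, "tm"),
                              lapply(flipped, `[[`, "mp"),
                              peak_marker = "m0030")
  expect_lt(res_f$p_value, 0.01)
})
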