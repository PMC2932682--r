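test_that("founder simulation hits the divergence target and is
           deterministic", {
  f0 <- simulate_founders(4, 200, divergence = 0, seed = 1)
  expect_equal(length(unique(split(f0$calls, row(f0$calls)))), 1L)
  f1 <- simulate_founders(2, 400, divergence = 1, seed = 2)
  expect_true(all(f1$calls[1, ] != f1$calls[2, ]))
  f <- simulate_founders(6, 1000, divergence = 0.3, seed = 3)
  pw <- combn(6, 2, function(ij)
    mean(f$calls[ij[1], ] != f$calls[ij[2], ]))
  expect_lt(abs(mean(pw) - 0.3), 0.02)
  # same seed, bit-identical output
  expect_identical(f$calls, simulate_founders(6, 1000, divergence = 0.3,
                                              seed = 3)$calls)
})

test_that("F1s of two fully diverged founders are heterozygous everywhere", {
  f <- simulate_founders(2, 100, divergence = 1, seed = 5)
  cfg <- sim_config(n_founders = 2, n_markers = 100, generations = 1,
                    census = 20, genotype_error = 0, missing_rate = 0)
  sim <- breed_colony(f, cfg, seed = 6)
  # wherever the two inherited haplotypes come from different founders,
  # the (error-free) genotype must be heterozygous
  lab1 <- sim$truth$hap_labels[seq(1, 39, 2), ]
  lab2 <- sim$truth$hap_labels[seq(2, 40, 2), ]
  mixed <- lab1 != lab2
  expect_true(all(sim$truth$genotypes[mixed] == 1L))
})

test_that("offspring genotypes are Mendelian-consistent with the recorded
           parents", {
  f <- simulate_founders(4, 150, divergence = 0.4, seed = 7)
  cfg <- sim_config(n_founders = 4, n_markers = 150, generations = 5,
                    census = 24, genotype_error = 0, missing_rate = 0,
                    mutation_rate = 0)
  sim <- breed_colony(f, cfg, seed = 8)
  ph <- sim$truth$parent_hap_alleles
  for (i in seq_len(6)) {
    for (w in 1:2) {
      child <- sim$truth$hap_alleles[2 * i - 2 + w, ]
      p <- sim$truth$parents[i, w]
      a <- ph[2 * p - 1, ]; b <- ph[2 * p, ]
      expect_true(all(child == a | child == b),
                  label = sprintf("offspring %d haplotype %d", i, w))
    }
  }
})

test_that("heterozygosity decays like (1 - 1/(2Ne))^G under random mating", {
  f <- simulate_founders(8, 300, divergence = 0.4, seed = 9)
  cfg <- sim_config(n_founders = 8, n_markers = 300, generations = 60,
                    census = 30, genotype_error = 0, missing_rate = 0)
  reps <- lapply(1:6, function(r) breed_colony(f, cfg, seed = 100 + r))
  traj <- sapply(reps, function(s) s$truth$het_trajectory)
  # Ne from the variance of offspring number (Crow & Kimura)
  vk <- mean(sapply(reps, function(s) mean(s$truth$offspring_var)))
  ne <- (4 * cfg$census - 2) / (vk + 2)
  g0 <- 5                                  # compare after HW settling
  ratio_obs <- rowMeans(traj)[60] / rowMeans(traj)[g0]
  ratio_exp <- (1 - 1 / (2 * ne))^(60 - g0)
  mc_sd <- sd(traj[60, ] / traj[g0, ])
  expect_lt(abs(ratio_obs - ratio_exp), 3 * mc_sd + 0.02)
})

test_that("planted phenotypes carry the requested variance share", {
  f <- simulate_founders(8, 200, divergence = 0.4, seed = 11)
  cfg <- sim_config(n_founders = 8, n_markers = 200, generations = 20,
                    census = 200, genotype_error = 0, missing_rate = 0)
  sim <- breed_colony(f, cfg, seed = 12)
  ph <- plant_phenotype(sim, target_variance = 0.15, seed = 13)
  qtl <- attr(ph, "qtl")
  g <- sim$truth$genotypes[, qtl$index]
  r2 <- summary(lm(ph$trait ~ g))$r.squared
  expect_gt(r2, 0.08); expect_lt(r2, 0.25)
  # null trait is independent of genotype
  ph0 <- plant_phenotype(sim, target_variance = 0, seed = 14)
  r20 <- summary(lm(ph0$trait ~ g))$r.squared
  expect_lt(r20, 0.05)
  # covariate effects appear in the table
  phc <- plant_phenotype(sim, target_variance = 0.1,
                         covariates = list(sex = 1), seed = 15)
  expect_true("sex" %in% names(phc))
  expect_lt(anova(lm(trait ~ sex, data = phc))[["Pr(>F)"]][1], 1e-4)
})

test_that("variant tables round-trip the planted novelty fraction", {
  cat <- simulate_catalogue(4000, span_bp = 4e6, seed = 16)
  v0 <- simulate_variant_table(cat, n_calls = 800, novel_fraction = 0,
                               seed = 17)
  nr0 <- novelty_rate(filter_calls(v0), cat, fdr = 0)
  expect_equal(nr0$raw_rate, 0)
  v5 <- simulate_variant_table(cat, n_calls = 4000, novel_fraction = 0.05,
                               seed = 18)
  nr5 <- novelty_rate(filter_calls(v5), cat, fdr = 0)
  expect_lt(abs(nr5$raw_rate - 0.05), 3 * sqrt(0.05 * 0.95 / 4000) + 0.01)
  # shallow depth fails the coverage filter for most calls
  shallow <- simulate_variant_table(cat, n_calls = 500, depth_mean = 5,
                                    seed = 19)
  expect_lt(nrow(filter_calls(shallow)) / 500, 0.1)
})

test_that("marker subsampling centres on the dense-set metrics", {
  dense <- hwe_colony(60, 1200, seed = 20, maf_range = c(0.1, 0.5))
  full <- colony_metrics(dense)
  reps <- subsample_markers(dense, n_markers = 240, n_regions = 4,
                            n_reps = 60, seed = 21,
                            sparse_estimate = c(mean_het = full$mean_het))
  expect_lt(abs(mean(reps$mean_het) - full$mean_het),
            0.1 * full$mean_het)
  pct <- attr(reps, "percentiles")
  expect_gt(pct[["mean_het"]], 5); expect_lt(pct[["mean_het"]], 95)
  # replicate means tighten toward the dense value as reps grow
  reps2 <- subsample_markers(dense, n_markers = 240, n_regions = 4,
                             n_reps = 120, seed = 22)
  expect_lt(abs(mean(reps2$mean_het) - full$mean_het), 0.015)
})

test_that("same seed gives bit-identical colonies", {
  f <- simulate_founders(4, 100, seed = 23)
  cfg <- sim_config(n_founders = 4, n_markers = 100, generations = 10,
                    census = 20)
  s1 <- breed_colony(f, cfg, seed = 24)
  s2 <- breed_colony(f, cfg, seed = 24)
  expect_identical(s1$colony$calls, s2$colony$calls)
  expect_identical(s1$truth$hap_labels, s2$truth$hap_labels)
})
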