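two_founder_model <- function(n_mark = 5, G = 20, error = 0.01,
                              spacing = 5e5) {
  f <- founder_panel(make_geno(rbind(rep(0L, n_mark), rep(2L, n_mark)),
                               spacing = spacing))
  mosaic_model(f, G = G, error = error)
}

test_that("interval switch probabilities follow the exponential map
           function", {
  map <- make_map(3, spacing = 2e6)      # 2 Mb = 1 cM at 0.5 cM/Mb
  r <- interval_recombination(map, G = 50)
  expect_equal(r, rep(1 - exp(-0.5), 2))
  # zero-length limit
  map0 <- marker_map(c("a", "b"), "1", c(100L, 101L))
  expect_lt(interval_recombination(map0, G = 10), 1e-6)
  # monotone in G
  expect_true(all(interval_recombination(map, G = 100) >
                    interval_recombination(map, G = 50)))
})

test_that("emissions match the hand-expanded per-allele error model", {
  # matching call, eps = 0
  e <- emission_probability(0L, c(0, 1), 0)
  expect_equal(e[1, 1], 1)   # (f1,f1) -> genotype 0
  expect_equal(e[2, 2], 0)
  # het under an identical-founder pair is impossible without error
  e1 <- emission_probability(1L, c(0, 1), 0)
  expect_equal(e1[1, 1], 0)
  expect_equal(e1[1, 2], 1)
  # eps = 0.01 fixture vs the independent expansion
  eps <- 0.01
  for (call in 0:2) {
    e <- emission_probability(call, c(0, 1), eps)
    for (i in 1:2) for (j in 1:2) {
      expect_equal(e[i, j],
                   emission_oracle(call, c(0, 1)[i], c(0, 1)[j], eps),
                   tolerance = 1e-12)
    }
  }
  # missing call emits 1 everywhere
  expect_equal(emission_probability(NA, c(0, 1), 0.05),
               matrix(1, 2, 2))
})

test_that("forward-backward equals the exhaustive path-sum oracle", {
  # 2 founders x up to 6 markers, 3 founders x 4 markers, with missing
  # data and genotype error
  cases <- list(
    list(S = 2, m = 4, geno = c(0L, 1L, 2L, 2L), error = 0.01),
    list(S = 2, m = 6, geno = c(0L, NA, 2L, 1L, 0L, 0L), error = 0.05),
    list(S = 3, m = 4, geno = c(2L, 1L, 0L, 2L), error = 0.02),
    list(S = 3, m = 4, geno = c(1L, 1L, NA, 0L), error = 0)
  )
  for (cs in cases) {
    withr::with_seed(cs$S * 100 + cs$m, {
      fal <- matrix(rbinom(cs$S * cs$m, 1, 0.5), cs$S, cs$m)
    })
    f <- founder_panel(make_geno(2L * fal, spacing = 8e5))
    model <- mosaic_model(f, G = 25, error = cs$error)
    got <- forward_backward(cs$geno, model)
    want <- fb_enum_oracle(cs$geno, model)
    expect_lt(max(abs(got$posterior - want$posterior)), 1e-10)
    expect_equal(got$log_likelihood, want$log_likelihood,
                 tolerance = 1e-10)
    # forward and backward likelihoods agree
    expect_equal(got$log_likelihood, got$log_likelihood_backward,
                 tolerance = 1e-8)
    # normalization at every marker
    expect_lt(max(abs(rowSums(got$posterior) - 1)), 1e-9)
  }
})

test_that("a pure founder line is assigned to its own pair", {
  withr::with_seed(77, {
    fal <- matrix(rbinom(2 * 40, 1, 0.5), 2, 40)
  })
  fal[1, ] <- 0L; fal[2, ] <- 1L   # fully distinguishable founders
  f <- founder_panel(make_geno(2L * fal, spacing = 2e5))
  model <- mosaic_model(f, G = 10, error = 0)
  fit <- forward_backward(rep(0L, 40), model)
  aa_col <- which(fit$pairs$first == "S01" & fit$pairs$second == "S01")
  expect_true(all(fit$posterior[, aa_col] >= 0.99))
})

test_that("simulated mosaics are recovered at >= 90% argmax accuracy", {
  founders <- simulate_founders(4, 500, divergence = 0.4, seed = 3,
                                region_span_bp = 5e6)
  cfg <- sim_config(n_founders = 4, n_markers = 500, generations = 10,
                    census = 30, genotype_error = 0.005,
                    missing_rate = 0)
  sim <- breed_colony(founders, cfg, seed = 4)
  model <- mosaic_model(founders, G = 10, error = 0.005)
  n_check <- 8
  acc <- vapply(seq_len(n_check), function(i) {
    fit <- forward_backward(sim$colony$calls[i, ], model)
    lab <- sort(c(sim$truth$hap_labels[2 * i - 1, 1],
                  sim$truth$hap_labels[2 * i, 1]))
    hit <- vapply(seq_len(nrow(sim$colony$map)), function(t) {
      k <- which.max(fit$posterior[t, ])
      true_pair <- sort(c(sim$truth$hap_labels[2 * i - 1, t],
                          sim$truth$hap_labels[2 * i, t]))
      identical(match(fit$pairs$first[k], model$founders$samples),
                true_pair[1]) &&
        identical(match(fit$pairs$second[k], model$founders$samples),
                  true_pair[2])
    }, logical(1))
    mean(hit)
  }, numeric(1))
  expect_gte(mean(acc), 0.9)
})

test_that("founder contributions are normalized and recover design
           fractions", {
  # colony of pure founder-1 individuals
  withr::with_seed(5, {
    fal <- matrix(rbinom(3 * 60, 1, 0.5), 3, 60)
  })
  f <- founder_panel(make_geno(2L * fal, spacing = 1e5))
  model <- mosaic_model(f, G = 5, error = 0.01)
  g <- geno_matrix(matrix(2L * fal[1, ], 4, 60, byrow = TRUE), f$map,
                   paste0("I", 1:4))
  mp <- mosaic_posteriors(g, model)
  fc <- founder_contributions(mp, "pure")
  expect_equal(sum(fc$fraction), 1, tolerance = 1e-6)
  expect_gt(fc$fraction[1], 0.9)
  # balanced F1 of founders 1 x 2: both parents contribute ~1/2
  f1 <- geno_matrix(matrix(2L * fal[1, ], 6, 60, byrow = TRUE) / 2 +
                      matrix(2L * fal[2, ], 6, 60, byrow = TRUE) / 2,
                    f$map, paste0("H", 1:6))
  mp2 <- mosaic_posteriors(f1, model)
  fc2 <- founder_contributions(mp2, "f1")
  expect_equal(fc2$fraction[1], 0.5, tolerance = 0.05)
  expect_equal(fc2$fraction[2], 0.5, tolerance = 0.05)
})
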