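# Weir-style nested ANOVA oracle for the variance components at one locus
# (mean-squares route, independent of the package's direct components)
wc_anova_components <- function(calls_list) {
  pops <- rep(seq_along(calls_list), vapply(calls_list, length, 1L))
  x <- unlist(calls_list) / 2
  het <- unlist(calls_list) == 1
  ni <- vapply(calls_list, length, 1L)
  r <- length(ni)
  pbar_p <- vapply(seq_len(r), function(k) mean(x[pops == k]), numeric(1))
  pbar <- sum(ni * pbar_p) / sum(ni)
  nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
  msp <- 2 * sum(ni * (pbar_p - pbar)^2) / (r - 1)
  msi <- 2 * sum((x - pbar_p[pops])^2) / sum(ni - 1)
  msg <- sum(het * 0.5) / sum(ni)
  c(a = (msp - msi) / (2 * nc), b = (msi - msg) / 2, c = msg)
}

test_that("IBS distances match allele-sharing hand counts", {
  g <- make_geno(rbind(rep(0L, 10), rep(0L, 10)))
  expect_equal(unname(ibs_distance_matrix(g)[1, 2]), 0)
  g <- make_geno(rbind(rep(0L, 6), rep(2L, 6)))
  expect_equal(unname(ibs_distance_matrix(g)[1, 2]), 1)
  # hom vs het at one marker out of 10: 1 mismatched allele of 20
  a <- rep(0L, 10); b <- a; b[1] <- 1L
  d <- ibs_distance_matrix(make_geno(rbind(a, b)))
  expect_equal(unname(d[1, 2]), 0.05)
  expect_equal(unname(diag(d)), rep(0, 2))
  expect_equal(unname(d), unname(t(d)))
})

test_that("MDS recovers planted 2-D geometry", {
  withr::with_seed(4, {
    pts <- matrix(runif(20, 0, 1), 10, 2)
  })
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("S", 1:10), paste0("S", 1:10))
  class(d) <- c("ibs_matrix", class(d))
  co <- mds_coordinates(d, dims = 2)
  rec <- as.matrix(dist(cbind(co$mds1, co$mds2)))
  expect_lt(max(abs(rec - unclass(d))), 1e-6)
})

test_that("structure flag separates planted clusters from panmixia", {
  c1 <- hwe_colony(30, 120, seed = 21, maf_range = c(0.35, 0.5))
  expect_false(as.logical(
    flag_structure(mds_coordinates(ibs_distance_matrix(c1)))))
  # two strongly diverged halves
  withr::with_seed(22, {
    p1 <- runif(120, 0.05, 0.95)
    p2 <- 1 - p1
    calls <- rbind(sapply(p1, function(p) rbinom(15, 2, p)),
                   sapply(p2, function(p) rbinom(15, 2, p)))
  })
  mix <- make_geno(calls)
  flag <- flag_structure(mds_coordinates(ibs_distance_matrix(mix)))
  expect_true(as.logical(flag))
  expect_equal(attr(flag, "best_k"), 2L)
  # determinism
  f2 <- flag_structure(mds_coordinates(ibs_distance_matrix(mix)))
  expect_identical(as.logical(flag), as.logical(f2))
})

test_that("Weir-Cockerham theta matches the nested-ANOVA oracle", {
  mk <- function(calls, id) {
    colony_panel(geno_matrix(calls,
                             marker_map(paste0("m", seq_len(ncol(calls))),
                                        "1", seq_len(ncol(calls)) * 100)),
                 id)
  }
  # printed one-locus toy
  a <- matrix(c(rep(0L, 5), rep(1L, 3), rep(2L, 2)), ncol = 1)
  b <- matrix(c(0L, rep(1L, 4), rep(2L, 7)), ncol = 1)
  th <- pairwise_fst(mk(a, "A"), mk(b, "B"))$theta
  comp <- wc_anova_components(list(a[, 1], b[, 1]))
  expect_equal(th, unname(comp["a"] / sum(comp)), tolerance = 1e-12)
  expect_equal(th, 0.2355978, tolerance = 1e-6)
  # multi-locus random fixtures, ratio-of-sums combination
  for (seed in 1:3) {
    withr::with_seed(seed, {
      c1 <- sapply(1:6, function(j) rbinom(15, 2, runif(1, 0.1, 0.9)))
      c2 <- sapply(1:6, function(j) rbinom(22, 2, runif(1, 0.1, 0.9)))
    })
    th <- pairwise_fst(mk(c1, "A"), mk(c2, "B"))$theta
    comps <- sapply(seq_len(6), function(j)
      wc_anova_components(list(c1[, j], c2[, j])))
    expect_equal(th, sum(comps["a", ]) / sum(comps),
                 tolerance = 1e-10, label = paste("seed", seed))
  }
})

test_that("theta is ~0 for a colony against itself and 1 at fixation", {
  cc <- hwe_colony(40, 50, seed = 31)
  # for duplicated samples the estimator is slightly negative (a known
  # small-sample property), not exactly zero
  expect_lt(abs(pairwise_fst(cc, colony_panel(subset_geno(cc), "dup"))$theta),
            0.02)
  a <- colony_panel(make_geno(matrix(0L, 20, 30)), "A")
  b <- colony_panel(make_geno(matrix(2L, 20, 30)), "B")
  expect_equal(pairwise_fst(a, b)$theta, 1)
})

test_that("theta grows with divergence time and near-identical colonies
           merge first in the tree", {
  base <- hwe_colony(600, 80, seed = 41)
  drift <- function(g, gens, seed, id) {
    # cheap drift: resample allele frequencies by binomial sampling
    withr::with_seed(seed, {
      p <- colMeans(g$calls, na.rm = TRUE) / 2
      for (t in seq_len(gens)) p <- rbinom(length(p), 40, p) / 40
      colony_panel(make_geno(sapply(p, function(pp) rbinom(40, 2, pp))), id)
    })
  }
  aa <- drift(base, 1, 1, "A")
  bb <- drift(base, 1, 2, "B")
  cc5 <- drift(base, 25, 3, "C")
  th_ab <- pairwise_fst(aa, bb)$theta
  th_ac <- pairwise_fst(aa, cc5)$theta
  expect_lt(th_ab, th_ac)
  tree <- colony_tree(fst_matrix(list(aa, bb, cc5)))
  expect_s3_class(tree, "phylo")
  # A and B merge first: C attaches at the root
  nwk <- ape::write.tree(tree)
  expect_true(grepl("\\(A:.*,B:", nwk) || grepl("\\(B:.*,A:", nwk))
})

test_that("admixture EM: K=1 is forced, the log-likelihood never decreases,
           and a 2-source mixture is recovered", {
  cc <- hwe_colony(25, 60, seed = 51)
  f1 <- admixture_em(cc, K = 1)
  expect_equal(unname(f1$Q[, 1]), rep(1, 25))
  withr::with_seed(52, {
    m <- 200
    p1 <- runif(m, 0.05, 0.95)
    # strong divergence between the two sources
    p2 <- plogis(qlogis(p1) + rnorm(m, 0, 3))
    q_true <- c(rep(1, 20), rep(0, 20), runif(10))
    calls <- t(sapply(q_true, function(q)
      rbinom(m, 2, q * p1 + (1 - q) * p2)))
  })
  g <- make_geno(calls)
  fit <- admixture_em(g, K = 2, seed = 7, max_iter = 2000, n_restarts = 3)
  expect_true(all(diff(fit$ll_trace) > -1e-8))
  expect_equal(unname(rowSums(fit$Q)), rep(1, 50), tolerance = 1e-6)
  # align label switching by correlation with truth
  q1 <- fit$Q[, 1]
  est <- if (cor(q1, q_true) >= 0) q1 else fit$Q[, 2]
  expect_lt(mean(abs(est - q_true)), 0.1)
  gl <- glance(fit)
  expect_equal(gl$K, 2L)
})
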