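# small in-code fixtures shared across test files

make_map <- function(n, chrom = "1", spacing = 1e5, start = 1e5) {
  marker_map(sprintf("m%03d", seq_len(n)), chrom,
             seq(start, by = spacing, length.out = n), "A", "G")
}

make_geno <- function(calls, chrom = "1", spacing = 1e5) {
  calls <- rbind(calls)
  geno_matrix(calls, make_map(ncol(calls), chrom, spacing),
              sprintf("S%02d", seq_len(nrow(calls))))
}

# a quick random colony without breeding history, genotypes drawn at HWE
hwe_colony <- function(n, m, seed = 1, id = "hwe", maf_range = c(0.1, 0.5)) {
  withr::with_seed(seed, {
    p <- runif(m, maf_range[1], maf_range[2])
    calls <- sapply(p, function(pp) rbinom(n, 2, pp))
    colony_panel(make_geno(calls), id)
  })
}

# independent full-enumeration HWE oracle (closed-form conditional
# probabilities via choose(); distinct from the package's log-gamma
# recurrence)
hwe_enum_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  if (min(n_a, 2 * n - n_a) == 0) return(1)
  hs <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  pr <- vapply(hs, function(h) {
    naa <- (n_a - h) / 2
    nbb <- n - naa - h
    if (naa < 0 || nbb < 0) return(0)
    choose(n, naa) * choose(n - naa, h) * 2^h / choose(2 * n, n_a)
  }, numeric(1))
  obs <- pr[match(n_ab, hs)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# independent per-marker emission oracle: enumerate the 4 allele-error
# configurations explicitly
emission_oracle <- function(call, f1_allele, f2_allele, eps) {
  if (is.na(call)) return(1)
  tot <- 0
  for (e1 in 0:1) for (e2 in 0:1) {
    a1 <- if (e1) 1 - f1_allele else f1_allele
    a2 <- if (e2) 1 - f2_allele else f2_allele
    p <- (if (e1) eps else 1 - eps) * (if (e2) eps else 1 - eps)
    if (a1 + a2 == call) tot <- tot + p
  }
  tot
}

# exhaustive path-sum oracle over ordered founder-pair paths; feasible
# for S <= 3 and few markers
fb_enum_oracle <- function(genotypes, model) {
  f <- model$founders
  s <- nrow(f$calls)
  m <- length(genotypes)
  r <- interval_recombination(f$map, model$G, model$cM_per_Mb)
  alle <- f$calls / 2
  # per-haplotype single-step transition probability
  step <- function(from, to, rr) {
    (1 - rr) * (from == to) + rr / s
  }
  states <- as.matrix(expand.grid(a = 1:s, b = 1:s))
  ns <- nrow(states)
  paths <- as.matrix(expand.grid(rep(list(seq_len(ns)), m)))
  post <- matrix(0, m, ns)
  total <- 0
  for (k in seq_len(nrow(paths))) {
    pw <- 1 / s^2
    for (t in seq_len(m)) {
      st <- states[paths[k, t], ]
      a1 <- alle[st[1], t]; a2 <- alle[st[2], t]
      if (is.na(a1)) a1 <- 0.5
      if (is.na(a2)) a2 <- 0.5
      em <- if (is.na(genotypes[t])) 1 else {
        # marginalize haplotype alleles when the founder call is missing
        sum(sapply(c(0, 1), function(x1) sum(sapply(c(0, 1), function(x2) {
          w1 <- if (x1 == 1) a1 else 1 - a1
          w2 <- if (x2 == 1) a2 else 1 - a2
          w1 * w2 * emission_oracle(genotypes[t], x1, x2, model$error)
        }))))
      }
      pw <- pw * em
      if (t < m) {
        nx <- states[paths[k, t + 1], ]
        pw <- pw * step(st[1], nx[1], r[t]) * step(st[2], nx[2], r[t])
      }
      if (pw == 0) break
    }
    if (pw > 0) {
      total <- total + pw
      for (t in seq_len(m)) post[t, paths[k, t]] <- post[t, paths[k, t]] + pw
    }
  }
  post <- post / total
  # fold ordered states to unordered pairs in the package's column order
  pair_cols <- list()
  for (a in 1:s) for (b in a:s) pair_cols[[length(pair_cols) + 1]] <- c(a, b)
  unord <- sapply(pair_cols, function(pp) {
    i1 <- which(states[, 1] == pp[1] & states[, 2] == pp[2])
    i2 <- which(states[, 1] == pp[2] & states[, 2] == pp[1])
    if (pp[1] == pp[2]) post[, i1, drop = FALSE] else
      post[, i1, drop = FALSE] + post[, i2, drop = FALSE]
  })
  list(posterior = matrix(unord, nrow = m),
       log_likelihood = unname(log(total)))
}
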