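#' Founder-mosaic model specification
#'
#' Parameters of the hidden Markov model that represents each outbred
#' genome as a mosaic of homozygous inbred founder haplotypes: the
#' founder panel, the expected number of breeding generations since
#' founding `G` (controls how fast ancestry switches along the
#' chromosome), a per-allele genotyping error rate, and a uniform
#' genetic map in cM/Mb (no hotspot data is used).
#'
#' @param founders a [founder_panel()] with S >= 2 strains.
#' @param G expected breeding generations since founding (default 30).
#' @param error per-allele genotype error probability (default 0.01,
#'   must be in \[0, 0.2\]).
#' @param cM_per_Mb uniform genetic map density (default 0.5).
#' @return An object of class `mosaic_model`.
#' @export
mosaic_model <- function(founders, G = 30, error = 0.01, cM_per_Mb = 0.5) {
  stopifnot(inherits(founders, "geno_matrix"))
  if (n_samples(founders) < 2L) stop("need at least 2 founders")
  if (G < 1) stop("G must be >= 1")
  if (error < 0 || error > 0.2) stop("error must be in [0, 0.2]")
  structure(list(founders = founders, G = G, error = error,
                 cM_per_Mb = cM_per_Mb),
            class = "mosaic_model")
}

#' Per-interval ancestry switch probabilities
#'
#' Converts inter-marker physical distances to genetic distances on a
#' uniform map and then to the probability that a haplotype's founder
#' ancestry switches across the interval after `G` generations:
#' `1 - exp(-G d / 100)` for `d` in cM. A switch lands on any founder
#' with uniform probability, so the probability saturates at the
#' stationary (uniform) regime as distances grow.
#'
#' @param map a [marker_map()] (single chromosome).
#' @param G generations.
#' @param cM_per_Mb map density.
#' @return numeric vector of length `nrow(map) - 1`.
#' @export
interval_recombination <- function(map, G, cM_per_Mb = 0.5) {
  if (length(unique(map$chrom)) > 1L) {
    stop("interval_recombination expects a single chromosome")
  }
  d_bp <- diff(map$pos_bp)
  d_cM <- d_bp * cM_per_Mb / 1e6
  1 - exp(-G * d_cM / 100)
}

# per-haplotype allele emission probabilities: founder allele a in {0, 1}
# (NA -> 1/2), transmitted allele flips with probability eps
hap_allele_prob <- function(founder_allele, eps) {
  a <- ifelse(is.na(founder_allele), 0.5, founder_allele)
  a * (1 - eps) + (1 - a) * eps
}

#' Emission probabilities for one marker
#'
#' P(observed genotype | ordered founder pair) under the per-allele error
#' model: each transmitted allele matches its founder's allele with
#' probability `1 - error`. A missing call emits 1 for every state.
#'
#' @param call observed genotype code (0/1/2 or NA).
#' @param founder_alleles per-founder allele doses at the marker
#'   (0 or 1 per haplotype; founder calls are homozygous so 0/2 codes map
#'   to 0/1; NA allowed).
#' @param error per-allele error rate.
#' @return S x S matrix of emission probabilities over ordered pairs.
#' @export
emission_probability <- function(call, founder_alleles, error) {
  s <- length(founder_alleles)
  if (is.na(call)) return(matrix(1, s, s))
  q <- hap_allele_prob(founder_alleles, error)
  switch(as.character(call),
         "0" = outer(1 - q, 1 - q),
         "1" = outer(q, 1 - q) + outer(1 - q, q),
         "2" = outer(q, q),
         stop("genotype code must be 0, 1 or 2"))
}

# transition operator applied on both haplotypes: T = (1-r) I + (r/S) J,
# applied as T %*% F %*% T without forming T
transition_apply <- function(f, r, s) {
  tf <- (1 - r) * f + (r / s) * matrix(rep(colSums(f), each = s), s, s)
  (1 - r) * tf + (r / s) * matrix(rep(rowSums(tf), times = s), s, s)
}

#' Forward-backward founder-pair posteriors for one individual
#'
#' Exact scaled forward-backward over founder-pair ancestry states along
#' each chromosome. Transitions factorize per haplotype: each haplotype
#' switches ancestry across an interval independently and a switch lands
#' on any founder uniformly. Posteriors are reported at markers over the
#' S(S+1)/2 unordered founder pairs (genotypes are unphased so ordered
#' pairs are unidentifiable).
#'
#' @param genotypes genotype code vector over the model's markers.
#' @param model a [mosaic_model()].
#' @return list: `posterior` (markers x pairs matrix, rows sum to 1),
#'   `pairs` (tibble mapping columns to founder pairs), `log_likelihood`,
#'   `log_likelihood_backward` (cross-check).
#' @export
forward_backward <- function(genotypes, model) {
  f <- model$founders
  if (length(genotypes) != n_markers(f)) {
    stop("genotype vector length does not match founder panel markers")
  }
  s <- n_samples(f)
  alle <- f$calls / 2L   # founders are homozygous: 0/2 -> 0/1 per haplotype
  chroms <- unique(f$map$chrom)
  pair_i <- pair_j <- integer(0)
  for (a in seq_len(s)) for (b in seq.int(a, s)) {
    pair_i <- c(pair_i, a); pair_j <- c(pair_j, b)
  }
  post <- matrix(NA_real_, length(genotypes), length(pair_i))
  ll <- 0; llb <- 0
  for (ch in chroms) {
    idx <- which(f$map$chrom == ch)
    m <- length(idx)
    r <- if (m > 1L) interval_recombination(f$map[idx, ], model$G,
                                            model$cM_per_Mb) else numeric(0)
    emis <- lapply(seq_len(m), function(t) {
      emission_probability(genotypes[idx[t]], alle[, idx[t]], model$error)
    })
    # forward
    fs <- vector("list", m); logc <- numeric(m)
    cur <- emis[[1L]] / s^2
    z <- sum(cur)
    if (z <= 0) stop("forward underflow at marker ", f$map$marker_id[idx[1L]])
    fs[[1L]] <- cur / z; logc[1L] <- log(z)
    if (m > 1L) for (t in 2:m) {
      cur <- transition_apply(fs[[t - 1L]], r[t - 1L], s) * emis[[t]]
      z <- sum(cur)
      if (z <= 0) stop("forward underflow at marker ", f$map$marker_id[idx[t]])
      fs[[t]] <- cur / z; logc[t] <- log(z)
    }
    ll <- ll + sum(logc)
    # backward
    bs <- vector("list", m); logd <- numeric(m)
    bs[[m]] <- matrix(1, s, s)
    if (m > 1L) for (t in seq.int(m - 1L, 1L)) {
      cur <- transition_apply(bs[[t + 1L]] * emis[[t + 1L]], r[t], s)
      z <- sum(cur)
      bs[[t]] <- cur / z; logd[t] <- log(z)
    }
    llb <- llb + log(sum((emis[[1L]] / s^2) * bs[[1L]])) + sum(logd)
    for (t in seq_len(m)) {
      po <- fs[[t]] * bs[[t]]
      po <- po / sum(po)
      up <- po[cbind(pair_i, pair_j)]
      lo <- po[cbind(pair_j, pair_i)]
      post[idx[t], ] <- ifelse(pair_i == pair_j, up, up + lo)
    }
  }
  list(posterior = post,
       pairs = tibble::tibble(first = f$samples[pair_i],
                              second = f$samples[pair_j]),
       log_likelihood = ll, log_likelihood_backward = llb)
}

#' Mosaic posteriors for every individual in a colony
#'
#' @param g a `geno_matrix` aligned to the model's founder panel (same
#'   markers, same order; see [align_to_founders()]).
#' @param model a [mosaic_model()].
#' @return An object of class `mosaic_posterior`: list with `posteriors`
#'   (one markers x pairs matrix per individual), `pairs`, `samples`,
#'   `map`, `founders`, `log_likelihoods`.
#' @export
mosaic_posteriors <- function(g, model) {
  if (!identical(g$map$marker_id, model$founders$map$marker_id)) {
    stop("genotypes are not aligned to the founder panel")
  }
  fits <- lapply(seq_len(n_samples(g)), function(i) {
    forward_backward(g$calls[i, ], model)
  })
  structure(list(
    posteriors = lapply(fits, `[[`, "posterior"),
    pairs = fits[[1L]]$pairs,
    samples = g$samples,
    map = g$map,
    founders = model$founders$samples,
    log_likelihoods = vapply(fits, `[[`, numeric(1), "log_likelihood")
  ), class = "mosaic_posterior")
}

#' @export
print.mosaic_posterior <- function(x, ...) {
  cat("<mosaic_posterior> ", length(x$samples), " individuals x ",
      nrow(x$map), " markers, ", length(x$founders), " founders\n", sep = "")
  invisible(x)
}

#' Expected founder dosages
#'
#' Expected number of haplotypes (0-2) each individual carries from each
#' founder at each marker, from the pair posteriors.
#'
#' @param mp a [mosaic_posteriors()] object.
#' @return list of markers x founders matrices, one per individual.
#' @export
founder_dosages <- function(mp) {
  s <- length(mp$founders)
  cnt <- matrix(0, nrow(mp$pairs), s,
                dimnames = list(NULL, mp$founders))
  for (k in seq_len(nrow(mp$pairs))) {
    cnt[k, mp$pairs$first[k]] <- cnt[k, mp$pairs$first[k]] + 1
    cnt[k, mp$pairs$second[k]] <- cnt[k, mp$pairs$second[k]] + 1
  }
  lapply(mp$posteriors, function(po) po %*% cnt)
}

# interval-length weights for markers: half the flanking gaps (midpoint
# rule), per chromosome; a lone marker gets weight 1
marker_weights <- function(map) {
  w <- numeric(nrow(map))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    if (length(idx) == 1L) { w[idx] <- 1; next }
    gaps <- diff(map$pos_bp[idx])
    w[idx] <- c(gaps[1L] / 2, (utils::head(gaps, -1L) + gaps[-1L]) / 2,
                gaps[length(gaps)] / 2)
  }
  w
}

#' Per-colony founder contribution profile
#'
#' Expected genome fraction contributed by each founder: the posterior
#' founder dosages divided by 2, averaged over individuals and markers
#' with markers weighted by the physical length they represent (half the
#' flanking inter-marker gaps).
#'
#' @param mp a [mosaic_posteriors()] object.
#' @param colony_id label for the output (default `"colony"`).
#' @return A tibble with colony_id, founder, fraction; fractions sum
#'   to 1.
#' @export
founder_contributions <- function(mp, colony_id = "colony") {
  dos <- founder_dosages(mp)
  w <- marker_weights(mp$map)
  w <- w / sum(w)
  acc <- Reduce(`+`, lapply(dos, function(d) colSums(d * w) / 2))
  frac <- acc / length(dos)
  frac <- frac / sum(frac)
  tibble::tibble(colony_id = colony_id, founder = mp$founders,
                 fraction = as.numeric(frac))
}
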