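#' Identity-by-state pairwise distance matrix
#'
#' `distance(i, j) = 1 - (shared allele count / (2 * complete markers))`,
#' where at each pairwise-complete marker the shared allele count is
#' `2 - |dose_i - dose_j|`.
#'
#' @param g a `geno_matrix`.
#' @return A symmetric n x n matrix of class `ibs_matrix` with zero
#'   diagonal and entries in \[0, 1\].
#' @export
ibs_distance_matrix <- function(g) {
  n <- n_samples(g)
  if (n < 2L) stop("need at least 2 samples")
  x <- g$calls
  d <- matrix(0, n, n, dimnames = list(g$samples, g$samples))
  for (i in seq_len(n - 1L)) {
    xi <- x[i, ]
    for (j in seq.int(i + 1L, n)) {
      ok <- !is.na(xi) & !is.na(x[j, ])
      if (!any(ok)) {
        stop("samples ", g$samples[i], " and ", g$samples[j],
             " share no complete marker")
      }
      d[i, j] <- d[j, i] <- sum(abs(xi[ok] - x[j, ok])) / (2 * sum(ok))
    }
  }
  class(d) <- c("ibs_matrix", class(d))
  d
}

#' Classical multidimensional scaling of an IBS matrix
#'
#' Classical metric scaling (double-centering plus eigendecomposition),
#' deterministic up to axis sign.
#'
#' @param d an [ibs_distance_matrix()] (or any distance matrix).
#' @param dims number of dimensions (default 2).
#' @return A tibble with sample_id and mds1..mds`dims`, plus an
#'   `eigenvalues` attribute.
#' @export
mds_coordinates <- function(d, dims = 2L) {
  if (dims >= nrow(d)) stop("dims must be smaller than the number of samples")
  fit <- stats::cmdscale(stats::as.dist(unclass(d)), k = dims, eig = TRUE)
  pts <- fit$points
  if (is.null(pts) || ncol(pts) < dims) {
    pts <- cbind(pts, matrix(0, nrow(d), dims - ncol(pts)))
  }
  out <- tibble::tibble(sample_id = rownames(d))
  for (k in seq_len(dims)) out[[paste0("mds", k)]] <- pts[, k]
  attr(out, "eigenvalues") <- fit$eig
  out
}

#' Flag population structure from MDS coordinates
#'
#' k-means (fixed seed, 10 restarts) for k in 2..4 on the MDS
#' coordinates; the colony is flagged as structured when the best mean
#' silhouette width exceeds `threshold`. The survey this mirrors judged
#' cluster plots visually; the silhouette rule makes that judgement
#' explicit and reproducible. The default cut-off of 0.50 is the usual
#' silhouette criterion for a "reasonable" partition: unstructured
#' genotype clouds routinely reach widths of 0.4-0.47 under k-means, so
#' a lower cut-off would flag panmictic colonies.
#'
#' @param coords tibble from [mds_coordinates()].
#' @param threshold silhouette cut-off (default 0.50).
#' @param ks candidate cluster numbers (default 2:4).
#' @param seed RNG seed for the k-means restarts.
#' @return logical; attributes `best_k` and `best_silhouette`.
#' @export
flag_structure <- function(coords, threshold = 0.50, ks = 2:4, seed = 1L) {
  xy <- as.matrix(coords[, grep("^mds", names(coords)), drop = FALSE])
  if (nrow(xy) < 10L) stop("need at least 10 samples to assess structure")
  if (all(apply(xy, 2L, stats::var) < 1e-12)) {
    out <- FALSE
    attr(out, "best_k") <- NA_integer_
    attr(out, "best_silhouette") <- NA_real_
    return(out)
  }
  dmat <- stats::dist(xy)
  best <- -Inf; best_k <- NA_integer_
  for (k in ks) {
    if (k >= nrow(xy)) next
    km <- withr::with_seed(seed, stats::kmeans(xy, centers = k, nstart = 10))
    if (length(unique(km$cluster)) < 2L) next
    sil <- cluster::silhouette(km$cluster, dmat)
    s <- mean(sil[, "sil_width"])
    if (s > best) { best <- s; best_k <- k }
  }
  out <- is.finite(best) && best > threshold
  attr(out, "best_k") <- best_k
  attr(out, "best_silhouette") <- if (is.finite(best)) best else NA_real_
  out
}

#' Weir-Cockerham Fst between colonies
#'
#' Per-locus variance components a (between populations), b (between
#' individuals within populations) and c (within individuals) of the
#' Weir-Cockerham estimator, combined across loci as a ratio of sums
#' (not a mean of ratios, which is biased at small counts). Slightly
#' negative estimates are possible for undifferentiated populations.
#'
#' @param a,b `colony_panel`s (or `geno_matrix`s) sharing marker ids.
#' @return A one-row tibble: colony_a, colony_b, theta, n_loci_used.
#' @export
pairwise_fst <- function(a, b) {
  shared <- intersect(a$map$marker_id, b$map$marker_id)
  if (!length(shared)) stop("no shared markers")
  ga <- subset_geno(a, markers = shared)
  gb <- subset_geno(b, markers = match(shared, b$map$marker_id))
  gb <- subset_geno(gb, markers = match(ga$map$marker_id, gb$map$marker_id))
  comp <- wc_components(list(ga$calls, gb$calls))
  tibble::tibble(
    colony_a = if (!is.null(a$colony_id)) a$colony_id else "a",
    colony_b = if (!is.null(b$colony_id)) b$colony_id else "b",
    theta = comp$theta, n_loci_used = comp$n_loci)
}

# Weir & Cockerham (1984) components for r populations at biallelic loci
wc_components <- function(call_list) {
  r <- length(call_list)
  m <- ncol(call_list[[1L]])
  sum_a <- 0; sum_abc <- 0; used <- 0L
  for (j in seq_len(m)) {
    ni <- pi <- hi <- numeric(r)
    for (k in seq_len(r)) {
      x <- call_list[[k]][, j]; x <- x[!is.na(x)]
      ni[k] <- length(x)
      if (length(x)) {
        pi[k] <- mean(x) / 2
        hi[k] <- mean(x == 1L)
      }
    }
    keep <- ni > 0
    if (sum(keep) < 2L) next
    ni <- ni[keep]; pi <- pi[keep]; hi <- hi[keep]
    ri <- length(ni)
    nbar <- mean(ni)
    nc <- (ri * nbar - sum(ni^2) / (ri * nbar)) / (ri - 1)
    pbar <- sum(ni * pi) / (ri * nbar)
    if (pbar <= 0 || pbar >= 1) next
    s2 <- sum(ni * (pi - pbar)^2) / ((ri - 1) * nbar)
    hbar <- sum(ni * hi) / (ri * nbar)
    a_j <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (ri - 1) / ri * s2 - hbar / 4) / (nbar - 1))
    b_j <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (ri - 1) / ri * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    c_j <- hbar / 2
    sum_a <- sum_a + a_j
    sum_abc <- sum_abc + a_j + b_j + c_j
    used <- used + 1L
  }
  if (!used || sum_abc == 0) stop("no informative locus for Fst")
  list(theta = sum_a / sum_abc, n_loci = used)
}

#' Fst matrix over a set of colonies
#'
#' @param colonies list of `colony_panel`s.
#' @return A symmetric matrix of pairwise Weir-Cockerham theta values.
#' @export
fst_matrix <- function(colonies) {
  ids <- vapply(colonies, function(cc) cc$colony_id, character(1))
  n <- length(colonies)
  if (anyDuplicated(ids)) stop("colony ids must be unique")
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    m[i, j] <- m[j, i] <- pairwise_fst(colonies[[i]], colonies[[j]])$theta
  }
  m
}

#' Colony dendrogram from Fst distances
#'
#' Average-linkage agglomerative clustering on the Fst matrix (negative
#' estimates clamped to zero); ties broken deterministically by the
#' lexicographic ordering of colony ids in the input matrix.
#'
#' @param fst symmetric Fst matrix from [fst_matrix()].
#' @return An `ape::phylo` tree (serializable with [ape::write.tree()]).
#' @export
colony_tree <- function(fst) {
  if (nrow(fst) < 3L) stop("need at least 3 colonies")
  m <- pmax(unclass(fst), 0)
  ord <- order(rownames(m))
  m <- m[ord, ord]
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  ape::as.phylo(hc)
}

#' Admixture proportions by maximum-likelihood EM
#'
#' Models each genotype as a binomial draw of 2 alleles with success
#' probability `sum_k q_ik p_kj` (K ancestral populations with ancestry
#' proportions Q and ancestral allele frequencies P) and maximizes the
#' likelihood by EM. The log-likelihood is non-decreasing across
#' iterations; the best of `n_restarts` random initializations is
#' returned. Estimates from markers in LD are biased; an optional
#' thinning to one marker per haplotype block is available upstream.
#'
#' @param g a `geno_matrix`.
#' @param K number of ancestral populations (>= 1).
#' @param seed RNG seed for the restarts.
#' @param max_iter maximum EM iterations (default 10000).
#' @param tol stop when the log-likelihood gain falls below this
#'   (default 1e-6).
#' @param n_restarts random restarts (default 5).
#' @return An object of class `admixture_fit`: list with `K`, `Q`
#'   (n x K), `P` (K x m), `log_likelihood` and `ll_trace`.
#' @export
admixture_em <- function(g, K, seed = 1L, max_iter = 10000L, tol = 1e-6,
                         n_restarts = 5L) {
  if (K < 1L) stop("K must be >= 1")
  if (K > n_samples(g)) stop("K exceeds the number of samples")
  x <- g$calls
  if (any(rowSums(!is.na(x)) == 0L)) stop("sample with no genotype call")
  n <- nrow(x); m <- ncol(x)
  obs <- !is.na(x)
  xs <- x; xs[!obs] <- 0L
  if (K == 1L) {
    p <- colSums(xs) / (2 * colSums(obs))
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    ll <- sum(xs * log(p)[col(xs)] * obs) +
      sum((2 - xs) * log(1 - p)[col(xs)] * obs)
    fit <- list(K = 1L, Q = matrix(1, n, 1L, dimnames = list(g$samples, "pop1")),
                P = matrix(p, 1L, m, dimnames = list("pop1", g$map$marker_id)),
                log_likelihood = ll, ll_trace = ll)
    class(fit) <- "admixture_fit"
    return(fit)
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- withr::with_seed(seed + r - 1L, {
      q0 <- matrix(stats::rexp(n * K), n, K)
      q0 <- q0 / rowSums(q0)
      p0 <- matrix(stats::runif(K * m, 0.05, 0.95), K, m)
      list(q = q0, p = p0)
    })
    fit <- admixture_em_once(xs, obs, init$q, init$p, max_iter, tol)
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
  }
  dimnames(best$Q) <- list(g$samples, paste0("pop", seq_len(K)))
  dimnames(best$P) <- list(paste0("pop", seq_len(K)), g$map$marker_id)
  best$K <- K
  class(best) <- "admixture_fit"
  best
}

admixture_em_once <- function(xs, obs, q, p, max_iter, tol) {
  n <- nrow(xs); m <- ncol(xs); K <- ncol(q)
  eps <- 1e-6
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    mu <- q %*% p                       # n x m, P(allele_b)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    ll <- sum(obs * (xs * log(mu) + (2 - xs) * log1p(-mu)))
    ll_trace <- c(ll_trace, ll)
    if (ll - ll_old < tol && it > 1L) break
    ll_old <- ll
    # expected allele-copy counts attributed to each ancestral population
    a_q <- matrix(0, n, K); a_p <- matrix(0, K, m); b_p <- matrix(0, K, m)
    wb <- obs * xs / mu                  # n x m weights for allele_b copies
    wa <- obs * (2 - xs) / (1 - mu)
    for (k in seq_len(K)) {
      contrib_b <- (q[, k, drop = FALSE] %*% p[k, , drop = FALSE]) * wb
      contrib_a <- (q[, k, drop = FALSE] %*% (1 - p[k, , drop = FALSE])) * wa
      a_q[, k] <- rowSums(contrib_b + contrib_a)
      a_p[k, ] <- colSums(contrib_b)
      b_p[k, ] <- colSums(contrib_a)
    }
    q <- a_q / rowSums(a_q)
    p <- a_p / (a_p + b_p)
    p[!is.finite(p)] <- 0.5
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  list(Q = q, P = p, log_likelihood = ll_trace[length(ll_trace)],
       ll_trace = ll_trace)
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("<admixture_fit> K=", x$K, ", ", nrow(x$Q), " samples, logL=",
      sprintf("%.2f", x$log_likelihood), "\n", sep = "")
  invisible(x)
}

#' @rdname tidy.geno_matrix
#' @method tidy admixture_fit
#' @export
tidy.admixture_fit <- function(x, ...) {
  tibble::as_tibble(x$Q, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "population",
                        values_to = "proportion")
}

#' @method glance admixture_fit
#' @export
glance.admixture_fit <- function(x, ...) {
  tibble::tibble(K = x$K, n_samples = nrow(x$Q), n_markers = ncol(x$P),
                 log_likelihood = x$log_likelihood,
                 n_iter = length(x$ll_trace))
}
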