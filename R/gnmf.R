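#' Collapse a segmented cohort to non-redundant probe columns
#'
#' Consecutive probes whose value vectors are identical across every sample
#' carry no extra information for clustering; they collapse to one column
#' spanning their bp range. Any sample's probe-level profile is exactly
#' reconstructible from the reduced columns.
#'
#' @param seg Segment tibble.
#' @param samples Sample sheet.
#' @param map Genome map.
#' @return List of class `reduced_matrix`: `coords` (tibble `chrom`, `start`,
#'   `end`, `n_probes`) and `values` (samples x columns matrix).
#' @export
reduce_matrix <- function(seg, samples, map) {
  v <- seg_to_probe_matrix(seg, samples, map)   # probes x samples
  new_col <- c(TRUE, vapply(seq_len(nrow(map))[-1], function(i) {
    map$chrom[i] != map$chrom[i - 1] || any(v[i, ] != v[i - 1, ])
  }, logical(1)))
  col_id <- cumsum(new_col)
  firsts <- which(new_col)
  lasts <- c(firsts[-1] - 1L, nrow(map))
  next_pos <- if_else(lasts < nrow(map) & map$chrom[pmin(lasts + 1L, nrow(map))] == map$chrom[lasts],
                      map$pos[pmin(lasts + 1L, nrow(map))], map$pos[lasts] + 1)
  coords <- tibble(chrom = map$chrom[firsts], start = map$pos[firsts],
                   end = next_pos, n_probes = lasts - firsts + 1L)
  values <- t(v[firsts, , drop = FALSE])   # samples x columns
  colnames(values) <- NULL
  structure(list(coords = coords, values = values, samples = as_sample_sheet(samples)),
            class = "reduced_matrix")
}

#' Split a signed matrix into non-negative gain/loss channels
#'
#' Each feature becomes two: `max(x, 0)` (gain channel) and `max(-x, 0)`
#' (loss channel), preserving sign information for NMF; the input is
#' recoverable as gain minus loss.
#'
#' @param reduced A `reduced_matrix` (or plain samples x features matrix).
#' @return Samples x (2 features) non-negative matrix; attribute `"channel"`
#'   marks columns `"gain"`/`"loss"`, `"feature"` the source column index.
#' @export
nonneg_transform <- function(reduced) {
  x <- if (inherits(reduced, "reduced_matrix")) reduced$values else as.matrix(reduced)
  if (any(!is.finite(x))) abort("values must be finite")
  out <- cbind(pmax(x, 0), pmax(-x, 0))
  attr(out, "channel") <- rep(c("gain", "loss"), each = ncol(x))
  attr(out, "feature") <- rep(seq_len(ncol(x)), 2)
  out
}

#' Factorize a non-negative matrix by KL-divergence NMF
#'
#' Brunet-style multiplicative updates minimizing the generalized
#' Kullback-Leibler divergence D(V || WH), from seeded random-uniform
#' initialization. Iteration stops when the sample connectivity implied by W
#' (cluster = argmax row of W) has not changed for `conn_stop` checks, or at
#' `max_iter`.
#'
#' @param V Non-negative samples x features matrix.
#' @param k Factorization rank (1 <= k < min(dim(V))).
#' @param max_iter Maximum iterations.
#' @param conn_stop Consecutive stable connectivity checks required to stop.
#' @param seed Integer seed for the initialization.
#' @return List of class `nmf_model`: `W` (samples x k), `H` (k x features),
#'   `k`, `divergence` (trace, non-increasing), `iterations`, `seed`.
#' @export
nmf_factorize <- function(V, k, max_iter = 2000, conn_stop = 40, seed = NULL) {
  V <- as.matrix(V)
  if (any(V < 0)) abort("V must be non-negative")
  n <- nrow(V); m <- ncol(V)
  if (k < 1 || k >= min(n, m)) abort("need 1 <= k < min(dim(V))")
  eps <- .Machine$double.eps
  with_seed(seed, {
    W <- matrix(runif(n * k), n, k)
    H <- matrix(runif(k * m), k, m)
    div_trace <- numeric(0)
    cluster_old <- rep(0L, n)
    stable <- 0L
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      WH <- W %*% H
      H <- H * (t(W) %*% (V / (WH + eps))) / (pmax(colSums(W), eps))
      WH <- W %*% H
      W <- W * ((V / (WH + eps)) %*% t(H)) / rep(pmax(rowSums(H), eps), each = n)
      if (it %% 10 == 0 || it == max_iter) {
        WH <- W %*% H
        d <- sum(ifelse(V > 0, V * log(V / (WH + eps)), 0) - V + WH)
        div_trace <- c(div_trace, d)
        cluster <- max.col(W, ties.method = "first")
        if (identical(cluster, cluster_old)) stable <- stable + 10L else stable <- 0L
        cluster_old <- cluster
        if (stable >= conn_stop) break
      }
    }
    structure(list(W = W, H = H, k = k, divergence = div_trace,
                   iterations = it, seed = seed),
              class = "nmf_model")
  })
}

#' Consensus NMF clustering with cophenetic rank assessment
#'
#' NMF is restarted `n_runs` times; each run assigns every sample to the
#' factor with its largest W weight, and the run connectivity matrices are
#' averaged into a consensus matrix (entry i,j = fraction of runs co-clustering
#' samples i and j). Final assignments come from average-linkage hierarchical
#' clustering of 1 - consensus cut at `k`; the cophenetic correlation between
#' the consensus distances and the dendrogram summarizes cluster stability
#' (near 1 = stable rank).
#'
#' @param V Non-negative samples x features matrix (see [nonneg_transform()]).
#' @param k Rank.
#' @param n_runs NMF restarts (>= 2).
#' @param seed Integer seed.
#' @param ... Passed to [nmf_factorize()].
#' @return List of class `gnmf_consensus`: `consensus` (samples x samples),
#'   `assignments` tibble (`sample_id`, `cluster`), `rho` (cophenetic
#'   correlation), `k`, `n_runs`.
#' @export
consensus_cluster <- function(V, k, n_runs = 100, seed = NULL, ...) {
  if (n_runs < 2) abort("n_runs must be at least 2 to build a consensus")
  V <- as.matrix(V)
  n <- nrow(V)
  ids <- rownames(V) %||% sprintf("S%03d", seq_len(n))
  consensus <- matrix(0, n, n)
  for (b in seq_len(n_runs)) {
    fit <- nmf_factorize(V, k, seed = derive_seed(seed, b), ...)
    cl <- max.col(fit$W, ties.method = "first")
    consensus <- consensus + outer(cl, cl, "==")
  }
  consensus <- consensus / n_runs
  dimnames(consensus) <- list(ids, ids)
  d <- as.dist(1 - consensus)
  hc <- hclust(d, method = "average")
  assignments <- tibble(sample_id = ids, cluster = unname(cutree(hc, k = k)))
  rho <- suppressWarnings(cor(as.vector(d), as.vector(cophenetic(hc))))
  if (!is.finite(rho)) rho <- 1   # perfectly uniform consensus: degenerate but stable
  structure(list(consensus = consensus, assignments = assignments,
                 rho = rho, k = k, n_runs = n_runs, hclust = hc),
            class = "gnmf_consensus")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-chromosome permutation test of consensus cluster significance
#'
#' Null cohorts are built by independently shuffling, for every chromosome,
#' which sample each chromosome-profile belongs to, destroying cross-
#' chromosome co-segregation while keeping per-chromosome marginals. Each
#' permuted cohort is re-reduced, non-negativized and consensus-clustered,
#' and the observed cophenetic correlation is compared with the null ones.
#'
#' @param seg Segment tibble.
#' @param samples Sample sheet.
#' @param map Genome map.
#' @param k Rank to test.
#' @param n_perm Number of permutations (>= 1).
#' @param n_runs NMF restarts per consensus.
#' @param seed Integer seed.
#' @param ... Passed to [nmf_factorize()].
#' @return List: `rho_observed`, `rho_null` (length `n_perm`), `p`
#'   (`(1 + #null >= observed) / (n_perm + 1)`).
#' @export
permutation_rank_test <- function(seg, samples, map, k, n_perm = 100,
                                  n_runs = 20, seed = NULL, ...) {
  if (n_perm < 1) abort("n_perm must be at least 1")
  samples <- as_sample_sheet(samples)
  chroms <- unique(map$chrom)
  if (length(chroms) < 2) {
    warn("single-chromosome input: permutation degenerates to a whole-profile shuffle")
  }
  v <- seg_to_probe_matrix(seg, samples, map)   # probes x samples
  consensus_rho <- function(mat, sub_seed) {
    new_col <- c(TRUE, vapply(seq_len(nrow(map))[-1], function(i) {
      map$chrom[i] != map$chrom[i - 1] || any(mat[i, ] != mat[i - 1, ])
    }, logical(1)))
    red <- t(mat[new_col, , drop = FALSE])
    V <- cbind(pmax(red, 0), pmax(-red, 0))
    consensus_cluster(V, k, n_runs = n_runs, seed = sub_seed, ...)$rho
  }
  rho_obs <- consensus_rho(v, derive_seed(seed, 0L))
  rho_null <- with_seed(derive_seed(seed, 1L), {
    vapply(seq_len(n_perm), function(b) {
      vb <- v
      for (chr in chroms) {
        idx <- map$chrom == chr
        vb[idx, ] <- vb[idx, sample(ncol(vb)), drop = FALSE]
      }
      consensus_rho(vb, derive_seed(seed, 1000L + b))
    }, numeric(1))
  })
  list(rho_observed = rho_obs, rho_null = rho_null,
       p = (1 + sum(rho_null >= rho_obs)) / (n_perm + 1))
}
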