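# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately brute-force / hand-rolled so it shares no
# code path with the package implementation it checks.

# regular probe map: n probes per chromosome, fixed spacing, positions
# spacing, 2*spacing, ...
make_map <- function(n_per_chr, chroms = 1L, spacing = 1000) {
  as_genome_map(purrr::map_dfr(chroms, function(chr) {
    tibble::tibble(probe_id = sprintf("c%d_p%04d", chr, seq_len(n_per_chr)),
                   chrom = chr, pos = spacing * seq_len(n_per_chr))
  }))
}

make_samples <- function(n_primary, n_metastatic) {
  tibble::tibble(
    sample_id = c(sprintf("P%02d", seq_len(n_primary)),
                  sprintf("M%02d", seq_len(n_metastatic))),
    group = c(rep("primary", n_primary), rep("metastatic", n_metastatic))
  )
}

# build a segment tibble from a probes x samples value matrix: consecutive
# equal probe values become one segment (run-length encoding, per chromosome)
seg_from_values <- function(map, values) {
  purrr::map_dfr(colnames(values), function(sid) {
    purrr::map_dfr(unique(map$chrom), function(chr) {
      sel <- which(map$chrom == chr)
      r <- rle(values[sel, sid])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      tibble::tibble(
        sample_id = sid, chrom = chr,
        start = map$pos[sel[starts]],
        end = c(map$pos[sel[starts[-1]]], map$pos[max(sel)] + 1),
        n_probes = r$lengths, seg_mean = r$values
      )
    })
  })
}

# exhaustive max-|t| over circular arcs, plain R double loop
oracle_max_t <- function(x, min_width = 2) {
  n <- length(x)
  best <- list(i = -1L, j = -1L, t = 0)
  if (n < 2 * min_width) return(best)
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      k <- j - i; m <- n - k
      if (k < min_width || m < min_width) next
      arc <- x[(i + 1):j]
      comp <- x[-((i + 1):j)]
      W <- sum((arc - mean(arc))^2) + sum((comp - mean(comp))^2)
      tt <- if (n > 2 && W > 1e-12) {
        abs(mean(arc) - mean(comp)) / sqrt(W / (n - 2) * (1 / k + 1 / m))
      } else if (abs(mean(arc) - mean(comp)) > 1e-12) {
        1e12 * abs(mean(arc) - mean(comp))
      } else 0
      if (tt > best$t) best <- list(i = i, j = j, t = tt)
    }
  }
  best
}

# recursive single-split oracle segmentation: accepts the max-|t| split when
# its own R permutation p-value is <= alpha; returns sorted cut indices
oracle_cbs_cuts <- function(x, min_width = 2, alpha = 0.01, n_perm = 100) {
  cuts <- integer(0)
  rec <- function(lo, hi) {
    m <- hi - lo + 1
    if (m < 2 * min_width) return()
    xs <- x[lo:hi]
    best <- oracle_max_t(xs, min_width)
    if (best$t <= 0) return()
    exceed <- sum(replicate(n_perm, oracle_max_t(sample(xs), min_width)$t) >= best$t)
    if ((exceed + 1) / (n_perm + 1) > alpha) return()
    new_cuts <- setdiff(unique(c(best$i, best$j)), c(0, m)) + lo - 1L
    cuts <<- c(cuts, as.integer(new_cuts))
    bounds <- c(lo - 1L, sort(as.integer(new_cuts)), hi)
    for (b in seq_len(length(bounds) - 1L)) rec(bounds[b] + 1L, bounds[b + 1L])
  }
  rec(1L, length(x))
  sort(cuts)
}

# two-sided Fisher exact p by full hypergeometric enumeration over tables
# with the observed margins, minimum-likelihood rule
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, function(k) {
    choose(r1, k) * choose(r2, c1 - k) / choose(n, c1)
  }, numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hand Benjamini-Hochberg q-values
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in rev(seq_len(m))) {
    running <- min(running, m * p[ord[i]] / i)
    q[ord[i]] <- running
  }
  q
}
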