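#' Tidy an IGC comparison result
#'
#' @param x An `igc_result` from [igc_compare()].
#' @param ... Unused.
#' @return The per-(R-segment, direction) Fisher/q record tibble.
#' @export
tidy.igc_result <- function(x, ...) x$records

#' One-row summary of an IGC comparison result
#'
#' @param x An `igc_result`.
#' @param ... Unused.
#' @return Tibble with R-segment, test, significant-segment and ROI counts.
#' @export
glance.igc_result <- function(x, ...) {
  tibble(
    n_rsegments = nrow(x$rsegments),
    n_tests = nrow(x$records),
    n_significant = sum(x$records$q <= x$q_threshold),
    n_rois = nrow(x$rois),
    q_threshold = x$q_threshold
  )
}

#' Tidy a consensus NMF clustering
#'
#' @param x A `gnmf_consensus` from [consensus_cluster()].
#' @param ... Unused.
#' @return The sample-to-cluster assignment tibble.
#' @export
tidy.gnmf_consensus <- function(x, ...) x$assignments

#' One-row summary of a consensus NMF clustering
#'
#' @param x A `gnmf_consensus`.
#' @param ... Unused.
#' @return Tibble with rank, restarts and cophenetic correlation.
#' @export
glance.gnmf_consensus <- function(x, ...) {
  tibble(k = x$k, n_runs = x$n_runs, cophenetic_rho = x$rho)
}

#' Tidy a SAM fit
#'
#' @param x A `sam_fit` from [sam_two_class()].
#' @param ... Unused.
#' @return The per-probe record tibble (`d`, `rel_exp`, `q`).
#' @export
tidy.sam_fit <- function(x, ...) x$records

#' One-row summary of a SAM fit
#'
#' @param x A `sam_fit`.
#' @param q_threshold Count calls at this q cutoff.
#' @param ... Unused.
#' @return Tibble with probe count, fudge factor and calls.
#' @export
glance.sam_fit <- function(x, q_threshold = 0.05, ...) {
  tibble(n_probes = nrow(x$records), s0 = x$s0, n_perm = x$n_perm,
         n_called = sum(x$records$q <= q_threshold))
}

#' Tidy an instability test
#'
#' @param x An `instability_result` from [instability_test()].
#' @param ... Unused.
#' @return The per-sample breakpoint-count tibble.
#' @export
tidy.instability_result <- function(x, ...) x$counts

#' One-row summary of an instability test
#'
#' @param x An `instability_result`.
#' @param ... Unused.
#' @return Tibble with Welch t, p and degeneracy flag.
#' @export
glance.instability_result <- function(x, ...) {
  tibble(statistic = x$t, p.value = x$p, degenerate = x$degenerate)
}
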