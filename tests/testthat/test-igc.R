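test_that("R-segments are the breakpoint union of the cohort", {
  map <- make_map(100)
  samples <- tibble::tibble(sample_id = c("A", "B"), group = c("primary", "metastatic"))
  # A breaks after probe 50, B after probe 30
  v <- matrix(0, 100, 2, dimnames = list(NULL, c("A", "B")))
  v[51:100, "A"] <- 0.4
  v[31:100, "B"] <- -0.4
  rseg <- build_rsegments(seg_from_values(map, v), samples, map)
  expect_equal(nrow(rseg), 3)
  expect_equal(rseg$start, map$pos[c(1, 31, 51)])
  expect_equal(rseg$end, c(map$pos[31], map$pos[51], map$pos[100] + 1))
  expect_equal(rseg$A, c(0, 0, 0.4))
  expect_equal(rseg$B, c(0, -0.4, -0.4))

  # single flat sample: one R-segment per chromosome
  s1 <- tibble::tibble(sample_id = "A", group = "primary")
  v1 <- matrix(0.1, 100, 1, dimnames = list(NULL, "A"))
  expect_equal(nrow(build_rsegments(seg_from_values(map, v1), s1, map)), 1)
})

test_that("R-segment count equals distinct breakpoints plus chromosomes", {
  ev <- dplyr::bind_rows(
    planted_event(2, 1e5, 3e5, 0.8, frequency_primary = 0.3, frequency_metastatic = 0.6),
    planted_event(9, 5e4, 2e5, -0.9, frequency_primary = 0.2, frequency_metastatic = 0.5))
  cfg <- sim_config(n_primary = 4, n_metastatic = 5, n_probes = 220,
                    noise_sd = 0.1, planted_events = ev, seed = 33)
  sim <- simulate_cohorts(cfg)
  seg <- cbs_segment(sim$profiles, sim$samples, n_perm = 100, seed = 34)
  rseg <- build_rsegments(seg, sim$samples, sim$map)
  n_breaks <- seg %>%
    dplyr::group_by(sample_id, chrom) %>%
    dplyr::summarise(b = list(start[-1]), .groups = "drop") %>%
    dplyr::group_by(chrom) %>%
    dplyr::summarise(n = length(unique(unlist(b))), .groups = "drop") %>%
    dplyr::pull(n) %>% sum()
  expect_equal(nrow(rseg), n_breaks + 22)
  # every sample constant within every R-segment (checked internally too)
  vals <- seg_to_probe_matrix(seg, sim$samples, sim$map)
  for (i in sample(nrow(rseg), 10)) {
    idx <- sim$map$chrom == rseg$chrom[i] & sim$map$pos >= rseg$start[i] &
      sim$map$pos < rseg$end[i]
    expect_true(all(apply(vals[idx, , drop = FALSE], 2,
                          function(col) diff(range(col)) == 0)))
  }
})

test_that("Fisher p-values match the hypergeometric enumeration oracle", {
  map <- make_map(10)
  mk <- function(n_p, n_m, gain_p, gain_m) {
    samples <- make_samples(n_p, n_m)
    v <- matrix(0, 10, n_p + n_m, dimnames = list(NULL, samples$sample_id))
    if (gain_p > 0) v[, seq_len(gain_p)] <- 0.4
    if (gain_m > 0) v[, n_p + seq_len(gain_m)] <- 0.4
    rseg <- build_rsegments(seg_from_values(map, v), samples, map)
    fisher_compare(rseg, samples)
  }
  # [[2,0],[0,2]]: enumeration gives 2/6
  rec <- mk(2, 2, 2, 0)
  expect_equal(rec$p, 1 / 3)
  expect_equal(rec$p, oracle_fisher_p(2, 0, 0, 2))

  # equal proportions: no association, p = 1
  rec2 <- mk(20, 20, 10, 10)
  expect_equal(rec2$p, 1)

  # 15/20 metastatic gained vs 0/10 primary
  rec3 <- mk(10, 20, 0, 15)
  expect_equal(rec3$p, oracle_fisher_p(0, 10, 15, 5), tolerance = 1e-10)
  expect_lt(rec3$p, 0.001)

  # label swap leaves the two-sided p unchanged
  samples <- make_samples(4, 6)
  v <- matrix(0, 10, 10, dimnames = list(NULL, samples$sample_id))
  v[, c(1, 5, 6, 7)] <- 0.5
  rseg <- build_rsegments(seg_from_values(map, v), samples, map)
  swapped <- samples
  swapped$group <- ifelse(samples$group == "primary", "metastatic", "primary")
  expect_equal(fisher_compare(rseg, samples)$p, fisher_compare(rseg, swapped)$p)
})

test_that("gain tables exclude lost samples and vice versa", {
  map <- make_map(10)
  samples <- make_samples(3, 3)
  v <- matrix(0, 10, 6, dimnames = list(NULL, samples$sample_id))
  v[, 1] <- 0.5; v[, 4] <- 0.5; v[, 5] <- -0.5
  rseg <- build_rsegments(seg_from_values(map, v), samples, map)
  rec <- fisher_compare(rseg, samples)
  gain <- rec[rec$direction == "gain", ]
  expect_equal(gain$alt_primary + gain$norm_primary, 3)       # no lost primaries
  expect_equal(gain$alt_metastatic + gain$norm_metastatic, 2) # lost M excluded
  loss <- rec[rec$direction == "loss", ]
  expect_equal(loss$alt_metastatic, 1)
  expect_equal(loss$norm_primary, 2)  # gained primary excluded
})

test_that("q-value estimation reduces to BH for small families and calibrates pi0", {
  expect_equal(as.numeric(estimate_qvalues(rep(1, 5))), rep(1, 5))
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(as.numeric(estimate_qvalues(p)), rep(0.04, 4))  # hand BH
  set.seed(44)
  p_mix <- c(runif(400), rbeta(100, 0.2, 8))
  expect_equal(as.numeric(estimate_qvalues(p_mix)),
               attr(estimate_qvalues(p_mix), "pi0") * oracle_bh(p_mix))
  pu <- runif(1e4)
  pi0 <- attr(estimate_qvalues(pu), "pi0")
  expect_gte(pi0, 0.9); expect_lte(pi0, 1.1)
  expect_error(estimate_qvalues(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(estimate_qvalues(c(0.5, 1.2)), "\\(0, 1\\]")
  # q monotone non-decreasing in p-rank
  q <- as.numeric(estimate_qvalues(p_mix))
  expect_true(all(diff(q[order(p_mix)]) >= 0))
})

test_that("ROI merging joins adjacent significant segments within chromosomes", {
  records <- tibble::tibble(
    rseg_id = c(1L, 2L, 3L, 4L, 10L, 11L),
    chrom = c(1L, 1L, 1L, 1L, 6L, 7L),
    start = c(0, 100, 200, 300, 0, 0), end = c(100, 200, 300, 400, 500, 500),
    direction = "gain",
    q = c(0.01, 0.05, 0.5, 0.02, 0.01, 0.01)
  )
  rois <- call_rois(records, q_threshold = 0.1)
  # S,S,N,S on chr1 -> two ROIs; chr6/chr7 never merge even if ids adjacent
  expect_equal(nrow(rois), 4)
  chr1 <- rois[rois$chrom == 1, ]
  expect_equal(chr1$n_rsegments, c(2L, 1L))
  expect_equal(chr1$start, c(0, 300))
  expect_equal(nrow(call_rois(records, q_threshold = 1e-6)), 0)
})

test_that("null cohorts stay within the FDR calibration bound", {
  # equal event frequencies in both cohorts: on average <= 10% of tested
  # R-segments may reach q <= 0.1
  fracs <- sapply(1:4, function(s) {
    ev <- dplyr::bind_rows(
      planted_event(3, 1e5, 4e5, 0.8, frequency_primary = 0.4, frequency_metastatic = 0.4),
      planted_event(11, 5e4, 3e5, -0.8, frequency_primary = 0.4, frequency_metastatic = 0.4))
    cfg <- sim_config(n_primary = 12, n_metastatic = 15, n_probes = 440,
                      noise_sd = 0.1, planted_events = ev, seed = 500 + s)
    sim <- simulate_cohorts(cfg)
    seg <- cbs_segment(sim$profiles, sim$samples, n_perm = 100, seed = 600 + s)
    res <- igc_compare(mode_center(seg), sim$samples, sim$map)
    if (nrow(res$records) == 0) return(0)
    mean(res$records$q <= 0.1)
  })
  expect_lte(mean(fracs), 0.10)
})

test_that("igc_compare recovers planted metastasis-enriched gains", {
  ev <- planted_event(5, 1e5, 6e5, 0.9, frequency_primary = 0.04,
                      frequency_metastatic = 0.5)
  cfg <- sim_config(n_primary = 15, n_metastatic = 30, n_probes = 660,
                    noise_sd = 0.12, planted_events = ev, seed = 71)
  sim <- simulate_cohorts(cfg)
  seg <- cbs_segment(sim$profiles, sim$samples, n_perm = 100, seed = 72)
  res <- igc_compare(mode_center(seg), sim$samples, sim$map)
  hit <- res$rois$chrom == 5 & res$rois$start < 6e5 & res$rois$end > 1e5 &
    res$rois$direction == "gain"
  expect_true(any(hit))
  gl <- glance(res)
  expect_equal(gl$n_rois, nrow(res$rois))
  expect_s3_class(tidy(res), "tbl_df")
  expect_s3_class(plot_qvalue_profile(res), "ggplot")
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(plot_recurrence(mode_center(seg), sim$samples, sim$map), "ggplot")
})
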