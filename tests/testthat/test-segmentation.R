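make_profiles <- function(map, values_list) {
  profiles <- map
  for (nm in names(values_list)) profiles[[nm]] <- values_list[[nm]]
  profiles
}

test_that("a constant profile stays one segment with the right median", {
  map <- make_map(200)
  profiles <- make_profiles(map, list(S1 = rep(0.3, 200)))
  samples <- tibble::tibble(sample_id = "S1", group = "primary")
  seg <- cbs_segment(profiles, samples, n_perm = 100, seed = 1)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$seg_mean, 0.3)
  expect_equal(seg$n_probes, 200L)
  expect_equal(c(seg$start, seg$end), c(1000, 200000 + 1))
})

test_that("a clean level shift is split at the planted breakpoint", {
  set.seed(41)
  x <- c(rnorm(50, 0, 0.05), rnorm(50, 1, 0.05))
  map <- make_map(100)
  profiles <- make_profiles(map, list(S1 = x))
  samples <- tibble::tibble(sample_id = "S1", group = "primary")
  seg <- cbs_segment(profiles, samples, n_perm = 100, seed = 2)
  expect_equal(nrow(seg), 2)
  bp_probe <- which(map$pos == seg$end[1])
  expect_lte(abs(bp_probe - 51), 2)  # cut after probe ~50
  expect_lt(abs(seg$seg_mean[1] - 0), 0.05)
  expect_lt(abs(seg$seg_mean[2] - 1), 0.05)
})

test_that("a focal event is isolated into its own segment", {
  set.seed(42)
  x <- rnorm(200, 0, 0.05)
  x[101:110] <- x[101:110] + 1.5
  map <- make_map(200)
  profiles <- make_profiles(map, list(S1 = x))
  samples <- tibble::tibble(sample_id = "S1", group = "primary")
  seg <- cbs_segment(profiles, samples, n_perm = 100, seed = 3)
  expect_equal(nrow(seg), 3)
  expect_gt(seg$seg_mean[2], 1.2)
  expect_equal(seg$start[2], map$pos[101])
  expect_equal(seg$end[2], map$pos[111])
})

test_that("chosen breakpoints match the exhaustive max-|t| oracle", {
  # deterministic equivalence on small instances: same alpha, same statistic,
  # independent R implementation of the scan and the permutation reference
  cases <- list(
    list(seed = 11, n = 120, shifts = c(rep(0, 40), rep(0.9, 40), rep(-0.7, 40))),
    list(seed = 12, n = 150, shifts = c(rep(0, 70), rep(1.2, 15), rep(0, 65))),
    list(seed = 13, n = 80, shifts = rep(0, 80))
  )
  for (cs in cases) {
    set.seed(cs$seed)
    x <- rnorm(cs$n, 0, 0.08) + cs$shifts
    map <- make_map(cs$n)
    profiles <- make_profiles(map, list(S1 = x))
    samples <- tibble::tibble(sample_id = "S1", group = "primary")
    seg <- cbs_segment(profiles, samples, alpha = 0.01, n_perm = 100, seed = 5)
    got <- which(map$pos %in% seg$end[-nrow(seg)])
    set.seed(99)
    want <- oracle_cbs_cuts(x, min_width = 2, alpha = 0.01, n_perm = 100)
    expect_equal(length(got), length(want))
    if (length(want)) expect_true(all(abs(sort(got) - sort(want)) <= 2))
  }
})

test_that("segments always partition each sample's probes", {
  ev <- planted_event(1, 1e5, 3e5, 1.2, frequency_primary = 0.3,
                      frequency_metastatic = 0.7)
  cfg <- sim_config(n_primary = 3, n_metastatic = 3, n_probes = 150,
                    noise_sd = 0.1, planted_events = ev, seed = 8)
  sim <- simulate_cohorts(cfg)
  seg <- cbs_segment(sim$profiles, sim$samples, n_perm = 100, seed = 9)
  per_sample <- tapply(seg$n_probes, seg$sample_id, sum)
  expect_true(all(per_sample == nrow(sim$map)))
  # expansion back to probes must cover everything (errors otherwise)
  expect_silent(seg_to_probe_matrix(seg, sim$samples, sim$map))
})

test_that("null chromosomes rarely split (type-I calibration)", {
  map <- make_map(60)
  samples <- tibble::tibble(sample_id = sprintf("S%02d", 1:40), group = "primary")
  set.seed(123)
  profiles <- map
  for (s in samples$sample_id) profiles[[s]] <- rnorm(60, 0, 0.1)
  seg <- cbs_segment(profiles, samples, alpha = 0.05, n_perm = 100, seed = 10)
  n_split <- sum(tapply(seg$sample_id, seg$sample_id, length) > 1)
  expect_lte(n_split / 40, 0.10)
})

test_that("mode centering shifts by the tallest probe-weighted mode", {
  map <- make_map(100)
  # 80% of probes at 0: untouched
  v <- matrix(c(rep(0, 80), rep(0.8, 20)), ncol = 1, dimnames = list(NULL, "S1"))
  seg <- seg_from_values(map, v)
  expect_equal(mode_center(seg)$seg_mean, seg$seg_mean)

  # uniform +0.3 shift is undone
  seg_shift <- dplyr::mutate(seg, seg_mean = seg_mean + 0.3)
  expect_equal(mode_center(seg_shift)$seg_mean, seg$seg_mean)

  # bimodal 70/30: mode at +0.2 wins, so shift is -0.2
  v2 <- matrix(c(rep(0.2, 70), rep(-0.5, 30)), ncol = 1, dimnames = list(NULL, "S1"))
  seg2 <- mode_center(seg_from_values(map, v2))
  expect_equal(sort(unique(seg2$seg_mean)), c(-0.7, 0))
})

test_that("mode centering is exactly idempotent", {
  map <- make_map(120)
  set.seed(15)
  vals <- round(rnorm(12, 0.2, 0.4), 3)
  v <- matrix(rep(vals, each = 10), ncol = 1, dimnames = list(NULL, "S1"))
  seg <- seg_from_values(map, v)
  once <- mode_center(seg)
  expect_identical(mode_center(once), once)
})

test_that("threshold derivation matches a direct trim-then-SD oracle", {
  set.seed(16)
  values <- rnorm(5000, 0, 0.05)
  th <- derive_thresholds(values)
  qs <- quantile(values, c(0.125, 0.875))
  oracle <- 6 * sd(values[values >= qs[1] & values <= qs[2]])
  expect_lt(abs(th$gain - oracle) / oracle, 0.02)
  expect_equal(th$loss, -th$gain)
  expect_equal(c(th$amp, th$del), c(0.4, -0.4))
  # a trimmed SD of exactly 0.025 gives the canonical 0.15 cutoff
  expect_equal(6 * 0.025, 0.15)
  expect_warning(th0 <- derive_thresholds(rep(0.2, 2000)), "zero-variance")
  expect_equal(th0$gain, 0.15)
  expect_equal(derive_thresholds(values, fixed = TRUE)$gain, 0.15)
  expect_error(derive_thresholds(rnorm(10)), "1000")
})

test_that("state calls use inclusive boundaries and imply direction", {
  th <- cna_thresholds()
  expect_equal(call_state(c(0.20, 0.15, -0.45, 0.45, -0.15, 0), th),
               c("gain", "gain", "deletion", "amplification", "loss", "neutral"))
  expect_equal(state_direction(call_state(c(0.45, -0.45), th)), c("gain", "loss"))
  # monotone: increasing value never demotes the gain-side state
  grid <- seq(-1.5, 1.5, by = 0.01)
  lev <- c(deletion = 1, loss = 2, neutral = 3, gain = 4, amplification = 5)
  expect_true(all(diff(lev[call_state(grid, th)]) >= 0))
  expect_error(cna_thresholds(gain = -0.1), "loss < 0 < gain")
})

test_that("breakpoint instability test behaves like a textbook Welch t", {
  map <- make_map(100)
  samples <- make_samples(5, 5)
  # flat cohorts: degenerate, p reported as 1
  v <- matrix(0, 100, 10, dimnames = list(NULL, samples$sample_id))
  flat <- instability_test(seg_from_values(map, v), samples)
  expect_true(flat$degenerate)
  expect_equal(flat$p, 1)
  expect_true(all(flat$counts$n_breakpoints == 0))

  # planted: metastatic samples get many altered segments, primaries few
  set.seed(17)
  v2 <- matrix(0, 100, 10, dimnames = list(NULL, samples$sample_id))
  for (i in 1:5) {  # primaries: 2 events
    at <- sample(seq(1, 91, by = 10), 2)
    for (a in at) v2[a:(a + 4), i] <- 0.8
  }
  for (i in 6:10) { # metastases: 9 events
    at <- seq(1, 91, by = 10) + (i %% 2)
    for (a in at) v2[a:(a + 4), i] <- 0.8
  }
  res <- instability_test(seg_from_values(map, v2), samples)
  expect_lt(res$p, 0.001)
  # textbook Welch t on the same counts
  x <- res$counts$n_breakpoints[res$counts$group == "metastatic"]
  y <- res$counts$n_breakpoints[res$counts$group == "primary"]
  tw <- (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
  expect_equal(res$t, tw)

  # swapping cohort labels flips the sign, keeps p
  swapped <- samples
  swapped$group <- ifelse(samples$group == "primary", "metastatic", "primary")
  res2 <- instability_test(seg_from_values(map, v2), swapped)
  expect_equal(res2$t, -res$t)
  expect_equal(res2$p, res$p)

  expect_error(instability_test(seg_from_values(map, v2),
                                make_samples(1, 9)[c(1, 2:10), ]), "at least 2")
})
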