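test_that("bin assembly drops sparse bins and subsamples dense ones", {
  set.seed(1)
  b0 <- 1600000200
  times <- c(b0 + sort(runif(99, 0, 299)),        # 99 clicks: dropped
             b0 + 300 + sort(runif(500, 0, 299)), # kept as-is
             b0 + 600 + sort(runif(7200, 0, 299)))  # subsampled to 5000
  det <- bare_detections(sort(times))
  bins <- assemble_bins(det, rng_seed = 1)
  expect_length(bins, 2)
  expect_equal(vapply(bins, function(b) nrow(b$clicks), 0L), c(500L, 5000L))
  expect_equal(bins[[2]]$n_total, 7200L)
  # subsampling preserves time order and is seed-reproducible
  expect_false(is.unsorted(bins[[2]]$clicks$time))
  bins2 <- assemble_bins(det, rng_seed = 1)
  expect_identical(bins[[2]]$clicks$time, bins2[[2]]$clicks$time)
})

test_that("clicks spanning a bin boundary split by timestamp", {
  set.seed(2)
  b0 <- 1600000200
  times <- sort(b0 + runif(350, 250, 350))  # straddles the b0+300 boundary
  det <- bare_detections(times)
  bins <- assemble_bins(det, min_clicks = 1)
  # brute-force histogram oracle
  oracle <- table(floor(times / 300) * 300)
  expect_equal(vapply(bins, function(b) nrow(b$clicks), 0L),
               as.integer(oracle))
  expect_equal(vapply(bins, `[[`, 0, "bin_start"),
               as.numeric(names(oracle)))
  for (b in bins) {
    expect_true(all(b$clicks$time >= b$bin_start &
                      b$clicks$time < b$bin_start + 300))
  }
})

test_that("encounters are bounded by 15-minute silences", {
  mins <- function(m) m * 60
  # clicks 0-10 min and 40-45 min: the 30-min gap splits them
  t1 <- c(seq(0, mins(10), by = 30), seq(mins(40), mins(45), by = 30))
  enc <- compute_encounters(t1)
  expect_equal(nrow(enc), 2)
  expect_equal(enc$duration_min, c(10, 5))
  # a gap of exactly 15 minutes still splits
  t2 <- c(0, 60, mins(16))
  expect_equal(nrow(compute_encounters(t2)), 2)
  t3 <- c(0, 60, mins(16) - 1)
  expect_equal(nrow(compute_encounters(t3)), 1)
  # random stream against a brute-force gap-scan oracle
  set.seed(3)
  tr <- sort(cumsum(rexp(500, 1 / 200)))
  enc <- compute_encounters(tr)
  oracle_n <- 1 + sum(diff(tr) >= mins(15))
  expect_equal(nrow(enc), oracle_n)
  expect_equal(sum(enc$n_clicks), length(tr))
})

test_that("ICI distributions histogram first differences on the fixed grid", {
  # metronomic 0.155-s train: every interval in one bin
  times <- seq(0, by = 0.155, length.out = 60)
  d <- ici_distribution(times)
  expect_equal(sum(d$counts), 59)
  expect_equal(sum(d$counts > 0), 1)
  expect_equal(modal_ici(d), 0.155)
  # intervals beyond 0.5 s fall outside the histogram
  d2 <- ici_distribution(seq(0, by = 0.7, length.out = 20))
  expect_equal(sum(d2$counts), 0)
  expect_error(modal_ici(d2), "undefined")
  # fewer than 2 clicks: empty distribution
  expect_equal(sum(ici_distribution(1.5)$counts), 0)
  # two interleaved 0.155-s trains offset by 0.07 s: intervals alternate
  # 0.07 / 0.085; merge-and-diff oracle
  merged <- sort(c(seq(0, by = 0.155, length.out = 40),
                   seq(0.07, by = 0.155, length.out = 40)))
  d3 <- ici_distribution(merged)
  oracle <- table(cut(diff(merged), ici_grid()$breaks, right = FALSE))
  expect_equal(d3$counts, as.integer(oracle))
  top2 <- ici_grid()$centers[order(d3$counts, decreasing = TRUE)[1:2]]
  expect_setequal(top2, c(0.075, 0.085))
})

test_that("modal ICI follows the argmax rule with first-peak saturation handling", {
  centers <- ici_grid()$centers
  mk <- function(counts) {
    c49 <- integer(49)
    c49[seq_along(counts)] <- counts
    c49
  }
  # unimodal: plain argmax; bin [0.12, 0.13) has center 0.125
  c1 <- integer(49)
  c1[which(centers == 0.125)] <- 50
  c1[which(centers == 0.125) + 1] <- 20
  expect_equal(modal_ici(c1), 0.125)
  # tie: lower bin center wins
  c2 <- integer(49)
  c2[10] <- 30
  c2[20] <- 30
  expect_equal(modal_ici(c2), centers[10])
  # saturation: monotone decay from the first bin plus a bump at 0.065
  c3 <- mk(c(100, 80, 60, 40, 30, 55, 20, 10))
  expect_equal(modal_ici(c3), 0.065)
  # decay without any secondary peak falls back to the global argmax
  c4 <- mk(c(100, 80, 60, 40, 30, 20, 10, 5))
  expect_equal(modal_ici(c4), centers[1])
})

test_that("a single-type bin yields one summary node matching its template", {
  types <- list(click_type_spec("X", peak_khz = 30, bandwidth_khz = 5,
                                modal_ici = 0.065, ici_cv = 0.05,
                                spectral_noise_db = 2, bin_noise_db = 0))
  ds <- synth_detection_dataset(synthetic_dataset_spec(
    types = types, sites = "S1", bins_per_type_per_site = 1,
    clicks_per_bin = c(300, 300), rng_seed = 5))
  bins <- assemble_bins(ds$detections, rng_seed = 1)
  expect_length(bins, 1)
  nodes <- cluster_bin(bins[[1]], config = cw_config(rng_seed = 2))
  expect_equal(nrow(nodes), 1)
  expect_gte(nodes$n_clicks, 250)
  expect_equal(nodes$modal_ici, 0.065)
  # mean spectrum within 1 dB RMS of the planted template (up to the
  # received-level offset)
  tpl <- type_template_db(types[[1]])
  got <- as.numeric(spectrum_matrix(nodes))
  resid <- (got - mean(got)) - (tpl - mean(tpl))
  expect_lt(sqrt(mean(resid^2)), 1)
})

test_that("a bin mixing two distinct types yields two summary nodes", {
  types <- two_toy_types()
  ds <- synth_detection_dataset(synthetic_dataset_spec(
    types = types, sites = "S1", bins_per_type_per_site = 1,
    clicks_per_bin = c(300, 320), mixture_fraction = 1, rng_seed = 6))
  bins <- assemble_bins(ds$detections, rng_seed = 1)
  nodes <- cluster_bin(bins[[1]], config = cw_config(rng_seed = 3))
  expect_equal(nrow(nodes), 2)
  expect_equal(sort(nodes$peak_khz), c(25, 45), tolerance = 0.05)
})

test_that("outlier clicks do not spawn spurious summary nodes", {
  set.seed(7)
  types <- list(click_type_spec("X", peak_khz = 30, bandwidth_khz = 5,
                                modal_ici = 0.065, bin_noise_db = 0))
  ds <- synth_detection_dataset(synthetic_dataset_spec(
    types = types, sites = "S1", bins_per_type_per_site = 1,
    clicks_per_bin = c(120, 120), rng_seed = 8))
  clicks <- ds$detections
  # 60 incoherent outliers: independent random smooth spectra
  grid <- spectrum_grid_khz()
  out_rows <- clicks[rep(1, 60), ]
  for (k in 1:60) {
    knots <- seq(10, 70, by = 6)
    out_rows[k, sprintf("s%g", grid)] <-
      as.list(approx(knots, rnorm(length(knots), 100, 10), xout = grid)$y)
    out_rows$time[k] <- clicks$time[1] + runif(1, 0, 290)
  }
  all_clicks <- rbind(clicks, out_rows)
  all_clicks <- all_clicks[order(all_clicks$time), ]
  all_clicks$detection_id <- seq_len(nrow(all_clicks))
  bins <- assemble_bins(all_clicks, rng_seed = 1)
  nodes <- cluster_bin(bins[[1]], config = cw_config(rng_seed = 4))
  expect_equal(nrow(nodes), 1)
  expect_lte(nodes$n_clicks, 135)  # outliers isolated or subcritical
})

test_that("phase1 output is stable under a fixed seed", {
  types <- two_toy_types()
  ds <- synth_detection_dataset(synthetic_dataset_spec(
    types = types, sites = c("S1", "S2"), bins_per_type_per_site = 2,
    clicks_per_bin = c(120, 160), rng_seed = 9))
  n1 <- phase1(ds$detections, rng_seed = 5)
  n2 <- phase1(ds$detections, rng_seed = 5)
  expect_identical(n1, n2)
  expect_true(all(n1$n_clicks >= 100))
  expect_setequal(unique(n1$site_id), c("S1", "S2"))
})
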