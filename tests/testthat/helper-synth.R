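# Shared test helpers: lightweight generators and independent oracles.

# Rand index between two label vectors (pair-counting oracle).
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  ut <- upper.tri(same_a)
  mean(same_a[ut] == same_b[ut])
}

# Build a summary-node table directly from click-type specs (bypasses
# Phase 1) with smooth per-node spectral noise; fast path for Phase 2 and
# classification tests.
toy_node_table <- function(types, n_per_type = 30, sites = c("S1", "S2"),
                           noise_db = 2) {
  grid <- spectrum_grid_khz()
  centers <- ici_grid()$centers
  rows <- list()
  for (ti in seq_along(types)) {
    spec <- types[[ti]]
    base <- type_template_db(spec)
    for (k in seq_len(n_per_type)) {
      knots <- seq(10, 70, by = 6)
      noise <- approx(knots, rnorm(length(knots), 0, noise_db),
                      xout = grid)$y
      s <- base + noise + 100
      counts <- integer(length(centers))
      mbin <- which.min(abs(centers - spec$modal_ici))
      counts[mbin] <- 120L
      if (mbin > 1) counts[mbin - 1] <- 35L
      if (mbin < length(counts)) counts[mbin + 1] <- 35L
      row <- data.frame(
        node_id = sprintf("%s_n%d", spec$label, k),
        site_id = sites[(k - 1) %% length(sites) + 1],
        deployment_id = "D1",
        bin_start = 1600000200 + 300 * (ti * 1000 + k),
        n_clicks = 150L,
        modal_ici = centers[mbin],
        peak_khz = grid[which.max(s)],
        stringsAsFactors = FALSE
      )
      row[sprintf("s%g", grid)] <- as.list(s)
      row[sprintf("i%g", centers)] <- as.list(counts)
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Two clearly distinct toy click types: well separated in both spectral
# shape and modal ICI, each with the peak/notch structure real click
# types carry (a featureless Gaussian has too little differentiable
# shape to cohere under correlation-distance clustering).
two_toy_types <- function() {
  list(
    X = click_type_spec("X", peak_khz = 25, bandwidth_khz = 4,
                        secondary = list(list(khz = 15, gain_db = 12,
                                              width_khz = 1.5)),
                        modal_ici = 0.155),
    Y = click_type_spec("Y", peak_khz = 45, bandwidth_khz = 6,
                        secondary = list(list(khz = 20, gain_db = 14,
                                              width_khz = 2),
                                         list(khz = 33, gain_db = -8,
                                              width_khz = 2)),
                        modal_ici = 0.045)
  )
}

# Minimal detection table (times only; spectra irrelevant) for binning
# and encounter tests.
bare_detections <- function(times, site_id = "S1") {
  data.frame(detection_id = seq_along(times), time = times,
             site_id = site_id, deployment_id = "D1",
             stringsAsFactors = FALSE)
}

# Direct evaluation oracle for the combined similarity of two summary
# nodes (normalize, first-difference, Pearson, exponentiate, ICI factor).
oracle_s2 <- function(u, v, ici_u, ici_v) {
  nz <- function(x) (x - min(x)) / (max(x) - min(x))
  du <- diff(nz(u)); dv <- diff(nz(v))
  exp(-(1 - cor(du, dv))) * exp(-abs(ici_u - ici_v))
}

# Contingency-table NMI oracle (direct summation, independent of the
# package implementation).
oracle_nmi <- function(a, b) {
  n <- length(a)
  tab <- table(a, b)
  ni <- rowSums(tab); nj <- colSums(tab)
  den <- sum(ni * log(ni / n)) + sum(nj * log(nj / n))
  if (den == 0) return(1)
  num <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    if (tab[i, j] > 0) {
      num <- num - 2 * tab[i, j] * log(tab[i, j] * n / (ni[i] * nj[j]))
    }
  }
  as.numeric(num / den)
}

# Edge data.frame for a block-structured weighted graph.
planted_block_edges <- function(block_sizes, w_in = 0.9, w_between = 0.05) {
  n <- sum(block_sizes)
  block <- rep(seq_along(block_sizes), block_sizes)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             weight = ifelse(block[idx[, 1]] == block[idx[, 2]],
                             w_in, w_between))
}

# Planted-block pruned network (keeps every edge).
planted_block_network <- function(block_sizes, w_in = 0.9,
                                  w_between = 0.05) {
  prune_network(planted_block_edges(block_sizes, w_in, w_between), p_e = 0)
}
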