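#' Assemble clock-aligned five-minute time bins
#'
#' Splits a time-sorted detection table into bins aligned to wall-clock
#' `bin_s`-second boundaries. Bins with fewer than `min_clicks` detections
#' are dropped; bins with more than `max_clicks` are uniformly subsampled
#' to exactly `max_clicks` (seeded, time order preserved).
#'
#' @param detections Detection table (see [measure_clicks()]) with a
#'   numeric `time` column, sorted ascending.
#' @param min_clicks Minimum detections for a click-positive bin. Default
#'   100.
#' @param max_clicks Subsampling cap per bin. Default 5000.
#' @param bin_s Bin duration in seconds. Default 300.
#' @param rng_seed Seed for the subsampling draws.
#' @return List of `time_bin` objects: each has `bin_start` (epoch
#'   seconds, multiple of `bin_s`), `duration`, `clicks` (detection-table
#'   subset), `site_id`, `deployment_id`, `n_total` (pre-subsampling count).
#' @export
assemble_bins <- function(detections, min_clicks = 100, max_clicks = 5000,
                          bin_s = 300, rng_seed = NULL) {
  if (nrow(detections) == 0) return(list())
  if (is.unsorted(detections$time)) {
    stop("detections must be sorted by time")
  }
  bin_start <- floor(detections$time / bin_s) * bin_s
  groups <- split(seq_len(nrow(detections)), bin_start)
  with_seed(rng_seed, {
    bins <- lapply(names(groups), function(bs) {
      idx <- groups[[bs]]
      n_total <- length(idx)
      if (n_total < min_clicks) return(NULL)
      if (n_total > max_clicks) {
        idx <- sort(sample(idx, max_clicks))
      }
      clicks <- detections[idx, , drop = FALSE]
      structure(list(bin_start = as.numeric(bs), duration = bin_s,
                     clicks = clicks,
                     site_id = clicks$site_id[1],
                     deployment_id = clicks$deployment_id[1],
                     n_total = n_total),
                class = "time_bin")
    })
    bins[!vapply(bins, is.null, logical(1))]
  })
}

#' @export
print.time_bin <- function(x, ...) {
  cat(sprintf("<time_bin> %s start %s: %d clicks (%d before subsampling)\n",
              x$site_id,
              format(as.POSIXct(x$bin_start, origin = "1970-01-01", tz = "UTC")),
              nrow(x$clicks), x$n_total))
  invisible(x)
}

#' Delimit click encounters
#'
#' An encounter is a maximal run of detections in which consecutive
#' detections are separated by less than `gap_min` minutes; a gap of
#' exactly `gap_min` minutes splits encounters ("at least `gap_min`
#' minutes without detections" bounds each encounter).
#'
#' @param times Numeric detection times (seconds), sorted ascending, or a
#'   detection table with a `time` column.
#' @param gap_min Bounding gap in minutes. Default 15.
#' @return data.frame with `start`, `end` (seconds), `n_clicks` and
#'   `duration_min`.
#' @export
compute_encounters <- function(times, gap_min = 15) {
  if (is.data.frame(times)) times <- times$time
  if (length(times) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_clicks = integer(0), duration_min = numeric(0)))
  }
  if (is.unsorted(times)) stop("times must be sorted")
  gap_s <- gap_min * 60
  brk <- c(0, cumsum(diff(times) >= gap_s))
  starts <- tapply(times, brk, min)
  ends <- tapply(times, brk, max)
  data.frame(start = as.numeric(starts), end = as.numeric(ends),
             n_clicks = as.integer(table(brk)),
             duration_min = (as.numeric(ends) - as.numeric(starts)) / 60,
             row.names = NULL)
}

#' Inter-click-interval distribution
#'
#' ICIs are the first time differences between sequential clicks;
#' intervals are histogrammed on the fixed 0.01-0.5 s grid (10 ms bins).
#' Intervals outside that range are excluded from the counts.
#'
#' @param times Click times in seconds (one cluster's members); at least 2
#'   required for a nonempty distribution.
#' @return An `ici_distribution`: list with `counts` (49 integers),
#'   `breaks`, `centers`, `n_ici` (intervals counted).
#' @export
ici_distribution <- function(times) {
  g <- ici_grid()
  counts <- integer(length(g$centers))
  if (length(times) >= 2) {
    ici <- diff(sort(times))
    ici <- ici[ici >= g$breaks[1] & ici < g$breaks[length(g$breaks)]]
    if (length(ici) > 0) {
      bin <- findInterval(ici, g$breaks)
      counts <- tabulate(bin, nbins = length(g$centers))
    }
  }
  structure(list(counts = as.integer(counts), breaks = g$breaks,
                 centers = g$centers, n_ici = sum(counts)),
            class = "ici_distribution")
}

#' Modal inter-click interval
#'
#' Returns the bin center of the most populated ICI histogram bin (ties:
#' the lower center). When dense clicking saturates the lowest bins -
#' detected as the global maximum falling in the lowest three bins with
#' counts declining monotonically across them - the mode of an
#' individual's click train is taken as the first local maximum instead
#' (the first bin strictly greater than both neighbors), falling back to
#' the global maximum if no such bin exists.
#'
#' @param dist An [ici_distribution()] (or a 49-vector of counts).
#' @return Modal ICI in seconds (a bin center, odd multiple of 5 ms).
#' @export
modal_ici <- function(dist) {
  counts <- if (inherits(dist, "ici_distribution")) dist$counts else as.numeric(dist)
  centers <- ici_grid()$centers
  if (length(counts) != length(centers)) {
    stop("expected ", length(centers), " ICI bins")
  }
  if (sum(counts) == 0) stop("modal ICI undefined for an empty distribution")
  am <- which.max(counts)  # ties resolve to the lower bin
  saturated <- am <= 3 && all(diff(counts[1:3]) < 0)
  if (saturated) {
    padded <- c(Inf, counts, -Inf)
    for (m in 2:length(counts)) {
      if (counts[m] > padded[m] && counts[m] > padded[m + 2]) {
        return(centers[m])
      }
    }
  }
  centers[am]
}

# Drop clicks whose spectra cannot enter the similarity computation
# (constant spectrum or zero-variance first differences).
usable_spectra <- function(specs) {
  rng <- apply(specs, 1, function(r) diff(range(r)))
  dvar <- apply(t(diff(t(specs))), 1, sd)
  rng > 0 & dvar > 0
}

#' Cluster the clicks of one time bin into summary nodes
#'
#' Builds the within-bin spectral-similarity network
#' ([spectral_similarity()] on the 10-70 kHz grid), prunes the weakest
#' `p_e` fraction of edges, partitions the remainder with Chinese
#' Whispers, and emits one summary node per cluster of at least
#' `min_cluster_size` clicks: the mean of the member dB spectra, the
#' cluster's ICI distribution and its modal ICI.
#'
#' @param bin A `time_bin` (see [assemble_bins()]).
#' @param p_e Edge pruning fraction. Default 0.95.
#' @param config A [cw_config()].
#' @param min_cluster_size Minimum clicks per retained cluster. Default
#'   100.
#' @return A summary-node data.frame (zero rows if no cluster reaches
#'   `min_cluster_size`): `node_id`, `site_id`, `deployment_id`,
#'   `bin_start`, `n_clicks`, `modal_ici`, `peak_khz`, spectrum columns
#'   (mean dB) and ICI count columns.
#' @export
cluster_bin <- function(bin, p_e = 0.95, config = cw_config(),
                        min_cluster_size = 100) {
  stopifnot(inherits(bin, "time_bin"))
  clicks <- bin$clicks
  specs <- spectrum_matrix(clicks)
  ok <- usable_spectra(specs)
  clicks <- clicks[ok, , drop = FALSE]
  specs <- specs[ok, , drop = FALSE]
  empty <- empty_summary_nodes()
  if (nrow(specs) < 2) return(empty)
  sim <- spectral_similarity(normalize_spectrum(specs))
  net <- prune_network(sim, p_e)
  part <- chinese_whispers(net, config)
  if (part$n == 0) return(empty)
  grid <- spectrum_grid_khz()
  rows <- list()
  for (cl in sort(unique(part$labels))) {
    members <- as.integer(names(part$labels)[part$labels == cl])
    if (length(members) < min_cluster_size) next
    mem_clicks <- clicks[members, , drop = FALSE]
    mean_spec <- colMeans(specs[members, , drop = FALSE])
    dist <- ici_distribution(mem_clicks$time)
    mici <- if (dist$n_ici > 0) modal_ici(dist) else NA_real_
    row <- data.frame(
      node_id = NA_character_,
      site_id = bin$site_id,
      deployment_id = bin$deployment_id,
      bin_start = bin$bin_start,
      n_clicks = length(members),
      modal_ici = mici,
      peak_khz = grid[which.max(mean_spec)],
      stringsAsFactors = FALSE
    )
    row[spec_cols()] <- as.list(mean_spec)
    row[ici_cols()] <- as.list(dist$counts)
    rows[[length(rows) + 1]] <- row
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out$node_id <- sprintf("%s_%s_c%d", out$site_id,
                         format(out$bin_start, scientific = FALSE,
                                trim = TRUE),
                         seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

empty_summary_nodes <- function() {
  out <- data.frame(node_id = character(0), site_id = character(0),
                    deployment_id = character(0), bin_start = numeric(0),
                    n_clicks = integer(0), modal_ici = numeric(0),
                    peak_khz = numeric(0), stringsAsFactors = FALSE)
  for (cn in spec_cols()) out[[cn]] <- numeric(0)
  for (cn in ici_cols()) out[[cn]] <- integer(0)
  out
}

#' Run Phase 1 over a detection table
#'
#' Assembles click-positive five-minute bins ([assemble_bins()]) and
#' clusters each ([cluster_bin()]), concatenating the resulting summary
#' nodes. All randomness (subsampling, label propagation) runs from
#' `rng_seed`.
#'
#' @param detections Detection table, time-sorted (typically after
#'   [qc_filter()]).
#' @param p_e Edge pruning fraction. Default 0.95.
#' @param min_clicks,max_clicks,bin_s Bin rules (defaults 100, 5000, 300).
#' @param min_cluster_size Minimum clicks per summary node. Default 100.
#' @param max_iterations Chinese Whispers pass limit. Default 20.
#' @param rng_seed Seed for all randomized steps.
#' @return Summary-node table (see [cluster_bin()]) across all bins.
#' @export
phase1 <- function(detections, p_e = 0.95, min_clicks = 100,
                   max_clicks = 5000, bin_s = 300, min_cluster_size = 100,
                   max_iterations = 20, rng_seed = 1) {
  with_seed(rng_seed, {
    bins <- assemble_bins(detections, min_clicks = min_clicks,
                          max_clicks = max_clicks, bin_s = bin_s)
    cfg <- cw_config(max_iterations = max_iterations)
    nodes <- lapply(bins, cluster_bin, p_e = p_e, config = cfg,
                    min_cluster_size = min_cluster_size)
    nodes <- nodes[vapply(nodes, nrow, integer(1)) > 0]
    if (length(nodes) == 0) return(empty_summary_nodes())
    out <- do.call(rbind, nodes)
    rownames(out) <- NULL
    out$node_id <- make.unique(out$node_id)
    out
  })
}
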