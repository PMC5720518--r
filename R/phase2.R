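#' Phase 2 configuration
#'
#' Defaults are the standard operating point of the pipeline: 1000 summary
#' nodes sampled per site, 20 independent Chinese Whispers runs at
#' `p_e = 0.95`, clusters of at least 20 nodes retained.
#'
#' @param nodes_per_site Summary nodes sampled per site. Default 1000.
#' @param n_runs Number of independent clustering runs for the consensus.
#'   Default 20.
#' @param p_e Edge pruning fraction. Default 0.95.
#' @param min_cluster_size Minimum nodes per retained cluster. Default 20.
#' @param max_iterations Chinese Whispers pass limit. Default 20.
#' @param rng_seed Seed for sampling and clustering.
#' @return A list of class `phase2_config`.
#' @export
phase2_config <- function(nodes_per_site = 1000, n_runs = 20, p_e = 0.95,
                          min_cluster_size = 20, max_iterations = 20,
                          rng_seed = 1) {
  stopifnot(nodes_per_site > 0, n_runs > 0, min_cluster_size > 0,
            p_e >= 0, p_e < 1)
  structure(list(nodes_per_site = nodes_per_site, n_runs = n_runs,
                 p_e = p_e, min_cluster_size = min_cluster_size,
                 max_iterations = max_iterations, rng_seed = rng_seed),
            class = "phase2_config")
}

#' Sample summary nodes evenly across sites
#'
#' Uniform random sample of `nodes_per_site` summary nodes from each site,
#' so that sites with more click-positive bins do not dominate the
#' cross-site network. Sites supplying fewer nodes contribute everything
#' they have, with a warning.
#'
#' @param nodes Summary-node table with a `site_id` column.
#' @param config A [phase2_config()] (supplies `nodes_per_site`; the seed
#'   is only applied here when `seed = TRUE`).
#' @param seed Apply `config$rng_seed` locally (set `FALSE` when called
#'   inside an outer seeded context).
#' @return Row subset of `nodes`.
#' @export
sample_summary_nodes <- function(nodes, config = phase2_config(),
                                 seed = TRUE) {
  if (nrow(nodes) == 0) stop("no summary nodes supplied")
  draw <- function() {
    idx <- unlist(lapply(split(seq_len(nrow(nodes)), nodes$site_id),
                         function(ix) {
      if (length(ix) <= config$nodes_per_site) {
        if (length(ix) < config$nodes_per_site) {
          warning("site ", nodes$site_id[ix[1]], " has only ", length(ix),
                  " summary nodes (requested ", config$nodes_per_site, ")",
                  call. = FALSE)
        }
        ix
      } else {
        sort(sample(ix, config$nodes_per_site))
      }
    }), use.names = FALSE)
    nodes[sort(idx), , drop = FALSE]
  }
  if (seed) with_seed(config$rng_seed, draw()) else draw()
}

#' Build the cross-bin combined-similarity network
#'
#' Pairwise combined similarity `S2 = S_ICI * S_SPEC` between summary
#' nodes: spectral-shape similarity of the (normalized) mean spectra and
#' modal-ICI similarity, multiplied, then pruned at `p_e`. Nodes without a
#' modal ICI are excluded with a warning.
#'
#' @param nodes Summary-node table.
#' @param p_e Edge pruning fraction. Default 0.95.
#' @param quota Edge-count convention for the pruning quota (see
#'   [prune_network()]).
#' @return A [prune_network()] result whose `node_ids` are the `node_id`
#'   values of the retained rows.
#' @export
build_phase2_network <- function(nodes, p_e = 0.95, quota = "pairs") {
  has_ici <- !is.na(nodes$modal_ici)
  if (any(!has_ici)) {
    warning(sum(!has_ici), " summary nodes lack a modal ICI; excluded",
            call. = FALSE)
    nodes <- nodes[has_ici, , drop = FALSE]
  }
  specs <- spectrum_matrix(nodes)
  ok <- usable_spectra(specs)
  nodes <- nodes[ok, , drop = FALSE]
  specs <- specs[ok, , drop = FALSE]
  if (nrow(nodes) < 2) stop("need at least 2 usable summary nodes")
  s_spec <- spectral_similarity(normalize_spectrum(specs))
  s_ici <- ici_similarity(outer(nodes$modal_ici, rep(1, nrow(nodes))),
                          outer(rep(1, nrow(nodes)), nodes$modal_ici))
  s2 <- combined_similarity(s_spec, s_ici)
  prune_network(s2, p_e, node_ids = nodes$node_id, quota = quota)
}

# Build one click-type template from its member summary-node rows.
build_template <- function(members, label = NA_character_) {
  specs <- spectrum_matrix(members)
  norm <- normalize_spectrum(specs)
  pooled_ici <- colSums(ici_matrix(members))
  modal <- tryCatch(modal_ici(pooled_ici), error = function(e) NA_real_)
  member_modal <- members$modal_ici
  # modal of member modal ICIs: most frequent bin center
  tab <- sort(table(member_modal), decreasing = TRUE)
  type_modal <- as.numeric(names(tab)[1])
  structure(list(
    label = label,
    n = nrow(members),
    members = members,
    mean_spectrum = colMeans(norm),
    q25_spectrum = apply(norm, 2, quantile, probs = 0.25, names = FALSE),
    q75_spectrum = apply(norm, 2, quantile, probs = 0.75, names = FALSE),
    pooled_ici = as.integer(pooled_ici),
    pooled_modal_ici = modal,
    modal_ici = type_modal,
    mean_modal_ici = mean(member_modal),
    cv_modal_ici = sd(member_modal) / mean(member_modal),
    peak_khz = spectrum_grid_khz()[which.max(colMeans(norm))],
    mean_peak_khz = mean(members$peak_khz),
    cv_peak_khz = sd(members$peak_khz) / mean(members$peak_khz)
  ), class = "click_type_template")
}

#' @export
print.click_type_template <- function(x, ...) {
  cat(sprintf(
    "<click_type_template> %s: N = %d, peak %.1f kHz (mean %.1f, CV %.2f), modal ICI %.3f s\n",
    x$label, x$n, x$peak_khz, x$mean_peak_khz, x$cv_peak_khz, x$modal_ici))
  invisible(x)
}

#' @export
print.click_type_bundle <- function(x, ...) {
  cat(sprintf("<click_type_bundle> %d click types (%s), %d member nodes\n",
              length(x$templates),
              paste(vapply(x$templates, `[[`, "", "label"), collapse = ", "),
              sum(vapply(x$templates, `[[`, 0L, "n"))))
  invisible(x)
}

#' Discover recurrent click types across bins
#'
#' The full Phase 2 procedure: sample summary nodes evenly per site, build
#' the combined-similarity network, run `n_runs` independent Chinese
#' Whispers partitions, drop clusters below `min_cluster_size` from each,
#' select the Best-of-K partition by mean pairwise NMI (computed over
#' nodes labeled in both partitions of each pair), and build one
#' [click_type_template][build_template] per surviving cluster. Template
#' labels (`A`, `B`, ...) are assigned by descending modal ICI, then
#' descending peak frequency, for a stable human-readable ordering.
#'
#' @param nodes Summary-node table.
#' @param config A [phase2_config()].
#' @param sample_sites Apply the per-site sampling step (disable when the
#'   input is already a balanced sample).
#' @return List with `bundle` (class `click_type_bundle`: `templates`,
#'   `config`, plus the final `partition`), `partition` (Best-of-K,
#'   size-filtered), and `diagnostics` (`nmi_matrix`, `mean_nmi`,
#'   `best_index`, `clusters_per_run`, `isolated_fraction`,
#'   `n_sampled`, `unassigned_fraction`).
#' @export
discover_types <- function(nodes, config = phase2_config(),
                           sample_sites = TRUE) {
  with_seed(config$rng_seed, {
    sampled <- if (sample_sites) {
      sample_summary_nodes(nodes, config, seed = FALSE)
    } else nodes
    if (nrow(sampled) < config$min_cluster_size) {
      stop("fewer summary nodes than min_cluster_size")
    }
    net <- build_phase2_network(sampled, p_e = config$p_e)
    if (nrow(net$edges) == 0) stop("network fully isolated after pruning")
    cw <- cw_config(max_iterations = config$max_iterations)
    raw_parts <- lapply(seq_len(config$n_runs), function(k) {
      chinese_whispers(net, cw)
    })
    parts <- lapply(raw_parts, filter_small_clusters,
                    min_size = config$min_cluster_size)
    keep <- vapply(parts, function(p) p$n > 0, logical(1))
    if (!any(keep)) stop("no clusters of at least min_cluster_size in any run")
    bok <- best_of_k(parts[keep], common = TRUE)
    final <- bok$partition
    # templates from the winning partition
    tpl <- lapply(sort(unique(final$labels)), function(cl) {
      ids <- names(final$labels)[final$labels == cl]
      build_template(sampled[match(ids, sampled$node_id), , drop = FALSE])
    })
    ord <- order(-vapply(tpl, `[[`, 0, "modal_ici"),
                 -vapply(tpl, `[[`, 0, "peak_khz"))
    tpl <- tpl[ord]
    for (k in seq_along(tpl)) tpl[[k]]$label <- LETTERS[k]
    bundle <- structure(list(templates = tpl, config = config,
                             partition = final),
                        class = "click_type_bundle")
    diagnostics <- list(
      nmi_matrix = bok$nmi_matrix,
      mean_nmi = bok$mean_nmi,
      best_index = which(keep)[bok$index],
      clusters_per_run = vapply(parts, function(p) length(p$sizes), 0L),
      isolated_fraction = length(net$isolated) / length(net$node_ids),
      unassigned_fraction = 1 - final$n / nrow(sampled),
      n_sampled = nrow(sampled)
    )
    list(bundle = bundle, partition = final, diagnostics = diagnostics)
  })
}

#' Edge-pruning sensitivity sweep
#'
#' Operator diagnostic for choosing `p_e`. In `"phase1"` mode the input is
#' a list of time bins; each is clustered at every `p_e` and the sweep
#' reports mean clusters per bin, the percentage of nodes isolated and the
#' mean within-cluster similarity. In `"phase2"` mode the input is a
#' summary-node table; at every `p_e` the combined-similarity network is
#' clustered `n_runs` times and the sweep reports mean clusters per run,
#' percent isolated and the mean and SD of pairwise NMI between runs.
#'
#' @param x List of `time_bin`s (phase1 mode) or a summary-node table
#'   (phase2 mode).
#' @param pe_values Grid of pruning fractions in \[0, 0.99\].
#' @param n_runs Clustering runs per `p_e` (phase2 mode). Default 20.
#' @param mode `"phase1"` or `"phase2"`.
#' @param rng_seed Seed.
#' @return data.frame with one row per `p_e`.
#' @export
pe_sweep <- function(x, pe_values = c(0, 0.5, 0.7, 0.8, 0.9, 0.95, 0.99),
                     n_runs = 20, mode = c("phase2", "phase1"),
                     rng_seed = 1) {
  mode <- match.arg(mode)
  stopifnot(all(pe_values >= 0 & pe_values <= 0.99))
  with_seed(rng_seed, {
    if (mode == "phase1") {
      rows <- lapply(pe_values, function(pe) {
        stats <- vapply(x, function(bin) {
          specs <- spectrum_matrix(bin$clicks)
          ok <- usable_spectra(specs)
          specs <- specs[ok, , drop = FALSE]
          sim <- spectral_similarity(normalize_spectrum(specs))
          net <- prune_network(sim, pe)
          part <- chinese_whispers(net, cw_config())
          wcs <- within_cluster_similarity(sim, part)
          c(clusters = length(part$sizes),
            isolated = length(net$isolated) / nrow(specs),
            wcs = wcs)
        }, c(clusters = 0, isolated = 0, wcs = 0))
        data.frame(p_e = pe,
                   mean_clusters = mean(stats["clusters", ]),
                   pct_isolated = 100 * mean(stats["isolated", ]),
                   mean_within_similarity = mean(stats["wcs", ], na.rm = TRUE))
      })
    } else {
      rows <- lapply(pe_values, function(pe) {
        net <- build_phase2_network(x, p_e = pe)
        parts <- lapply(seq_len(n_runs), function(k) {
          chinese_whispers(net, cw_config())
        })
        nclust <- vapply(parts, function(p) length(p$sizes), 0L)
        pair_nmi <- if (n_runs > 1) {
          m <- best_of_k(parts)$nmi_matrix
          m[upper.tri(m)]
        } else NA_real_
        data.frame(p_e = pe,
                   mean_clusters = mean(nclust),
                   pct_isolated = 100 * length(net$isolated) /
                     length(net$node_ids),
                   mean_nmi = mean(pair_nmi),
                   sd_nmi = sd(pair_nmi))
      })
    }
    do.call(rbind, rows)
  })
}

# Mean pairwise similarity among co-clustered nodes (diagnostic).
within_cluster_similarity <- function(sim, part) {
  if (part$n == 0) return(NA_real_)
  vals <- unlist(lapply(unique(part$labels), function(cl) {
    idx <- as.integer(names(part$labels)[part$labels == cl])
    if (length(idx) < 2) return(NULL)
    sub <- sim[idx, idx]
    sub[upper.tri(sub)]
  }))
  if (is.null(vals) || length(vals) == 0) NA_real_ else mean(vals, na.rm = TRUE)
}
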