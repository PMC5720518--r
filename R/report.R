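#' Export per-type cluster reports
#'
#' For each click-type template writes the underlying tables - mean and
#' 25th/75th-percentile normalized spectra, the pooled ICI histogram and
#' the concatenated matrix of member mean spectra (one column per member,
#' members sorted by site) - plus, optionally, a three-panel summary plot
#' per type and a one-row-per-type overview table.
#'
#' @param bundle A `click_type_bundle` (see [discover_types()]).
#' @param dir Output directory (created if absent).
#' @param plots Also write PNG figures (skipped with a warning if no
#'   graphics device is available).
#' @return Character vector of written file paths, invisibly.
#' @export
export_cluster_report <- function(bundle, dir, plots = TRUE) {
  stopifnot(inherits(bundle, "click_type_bundle"))
  if (length(bundle$templates) == 0) stop("empty template bundle")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- spectrum_grid_khz()
  centers <- ici_grid()$centers
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(dir, name)
    data.table::fwrite(df, p, sep = "\t")
    paths <<- c(paths, p)
  }
  overview <- do.call(rbind, lapply(bundle$templates, function(t) {
    data.frame(label = t$label, n = t$n, peak_khz = t$peak_khz,
               mean_peak_khz = t$mean_peak_khz, cv_peak_khz = t$cv_peak_khz,
               modal_ici = t$modal_ici, mean_modal_ici = t$mean_modal_ici,
               cv_modal_ici = t$cv_modal_ici)
  }))
  emit(overview, "types_overview.tsv")
  for (t in bundle$templates) {
    emit(data.frame(freq_khz = grid, mean = unname(t$mean_spectrum),
                    q25 = unname(t$q25_spectrum),
                    q75 = unname(t$q75_spectrum)),
         sprintf("type_%s_spectrum.tsv", t$label))
    emit(data.frame(ici_s = centers, count = t$pooled_ici),
         sprintf("type_%s_ici.tsv", t$label))
    members <- t$members[order(t$members$site_id), , drop = FALSE]
    mat <- t(normalize_spectrum(spectrum_matrix(members)))
    concat <- data.frame(freq_khz = grid)
    concat[make.unique(paste0("m_", members$node_id))] <- as.data.frame(mat)
    emit(concat, sprintf("type_%s_concat.tsv", t$label))
    if (plots) {
      p <- file.path(dir, sprintf("type_%s.png", t$label))
      ok <- tryCatch({
        grDevices::png(p, width = 1400, height = 450)
        old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
        graphics::plot(grid, t$mean_spectrum, type = "l", lwd = 2,
                       xlab = "Frequency (kHz)",
                       ylab = "Normalized SPL",
                       main = sprintf("Type %s (N = %d)", t$label, t$n),
                       ylim = c(0, 1))
        graphics::lines(grid, t$q25_spectrum, lty = 2)
        graphics::lines(grid, t$q75_spectrum, lty = 2)
        graphics::image(seq_len(ncol(mat)), grid, t(mat),
                        xlab = "Member (sorted by site)",
                        ylab = "Frequency (kHz)",
                        main = "Concatenated member spectra")
        graphics::barplot(t$pooled_ici, names.arg = NULL, space = 0,
                          xlab = "ICI (s)", ylab = "Count",
                          main = "Pooled ICI distribution")
        graphics::par(old)
        grDevices::dev.off()
        TRUE
      }, error = function(e) {
        try(grDevices::dev.off(), silent = TRUE)
        warning("plot for type ", t$label, " skipped: ",
                conditionMessage(e), call. = FALSE)
        FALSE
      })
      if (ok) paths <- c(paths, p)
    }
  }
  invisible(paths)
}
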