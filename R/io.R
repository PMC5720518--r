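# Deterministic ISO 8601 UTC with microsecond precision (round-half-up on
# the microsecond, so write -> read -> write is byte-stable).
iso8601 <- function(t) {
  us <- round(t * 1e6)
  sec <- us %/% 1e6
  frac <- us %% 1e6
  paste0(format(as.POSIXct(sec, origin = "1970-01-01", tz = "UTC"),
                "%Y-%m-%dT%H:%M:%S"),
         sprintf(".%06dZ", frac))
}

parse_iso8601 <- function(s) {
  as.numeric(as.POSIXct(strptime(s, "%Y-%m-%dT%H:%M:%OS", tz = "UTC")))
}

write_header_table <- function(df, path, kind) {
  hdr <- c(sprintf("# clicknet %s v1", kind),
           paste0("# spectrum_grid_khz ",
                  paste(spectrum_grid_khz(), collapse = ",")))
  writeLines(hdr, path)
  data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

read_header_table <- function(path, kind) {
  first <- readLines(path, n = 8)
  n_hdr <- sum(startsWith(first, "#"))
  if (n_hdr == 0 || !grepl(paste0("clicknet ", kind), first[1])) {
    stop(path, " is not a clicknet ", kind, " file")
  }
  grid_line <- grep("spectrum_grid_khz", first, value = TRUE)
  if (length(grid_line) == 1) {
    grid <- as.numeric(strsplit(sub(".*spectrum_grid_khz ", "", grid_line),
                                ",")[[1]])
    if (!isTRUE(all.equal(grid, spectrum_grid_khz()))) {
      stop(path, " uses a different spectrum grid than this build")
    }
  }
  as.data.frame(data.table::fread(path, sep = "\t", skip = n_hdr,
                                  header = TRUE))
}

#' Write / read a detection table
#'
#' Tab-separated columnar format with a versioned header declaring the
#' spectrum grid; absolute times stored both as ISO 8601 UTC (human) and
#' numeric epoch seconds (authoritative). Files round-trip byte-stably.
#'
#' @param detections Detection table (see [measure_clicks()]).
#' @param path File path.
#' @return `write_detections`: `path` invisibly; `read_detections`: the
#'   detection table with numeric `time`.
#' @export
write_detections <- function(detections, path) {
  df <- detections
  df$time_iso <- iso8601(df$time)
  # full 17-significant-digit text for the time columns, so the numeric
  # value (and the ISO string derived from it) survives any number of
  # write/read cycles unchanged
  df$time <- sprintf("%.17g", df$time)
  if (!is.null(df$end_time)) df$end_time <- sprintf("%.17g", df$end_time)
  front <- c("detection_id", "time_iso", "time", "end_time", "peak_khz",
             "rl_pp_db", "env_dur_s", "site_id", "deployment_id")
  front <- intersect(front, names(df))
  df <- df[, c(front, setdiff(names(df), front)), drop = FALSE]
  write_header_table(df, path, "detection table")
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  df <- read_header_table(path, "detection table")
  df$time_iso <- NULL
  df
}

#' Write / read a summary-node table
#'
#' Per node: site, ISO 8601 bin start, click count, modal ICI, the mean
#' spectrum on the fixed 10-70 kHz grid (dB) and the 49-bin ICI counts.
#'
#' @param nodes Summary-node table (see [cluster_bin()]).
#' @param path File path.
#' @return `write_summary_nodes`: `path` invisibly; `read_summary_nodes`:
#'   the table.
#' @export
write_summary_nodes <- function(nodes, path) {
  df <- nodes
  df$bin_start_iso <- iso8601(df$bin_start)
  df$bin_start <- sprintf("%.17g", df$bin_start)
  front <- c("node_id", "site_id", "deployment_id", "bin_start_iso",
             "bin_start", "n_clicks", "modal_ici", "peak_khz")
  front <- intersect(front, names(df))
  df <- df[, c(front, setdiff(names(df), front)), drop = FALSE]
  write_header_table(df, path, "summary nodes")
}

#' @rdname write_summary_nodes
#' @export
read_summary_nodes <- function(path) {
  df <- read_header_table(path, "summary nodes")
  df$bin_start_iso <- NULL
  df
}

#' Write / read a click-type template bundle
#'
#' Structured JSON document: per template the label, size, mean and
#' 25th/75th-percentile normalized spectra, pooled ICI histogram,
#' ICI/peak statistics and the member summary nodes, plus an echo of the
#' training configuration. Full numeric precision is preserved, so the
#' file round-trips losslessly.
#'
#' @param bundle A `click_type_bundle` (see [discover_types()]).
#' @param path File path (`.json`).
#' @return `write_template_bundle`: `path` invisibly;
#'   `read_template_bundle`: the bundle.
#' @export
write_template_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "click_type_bundle"))
  doc <- list(
    format = "clicknet_template_bundle",
    version = 1,
    config = unclass(bundle$config),
    templates = lapply(bundle$templates, function(t) {
      list(label = t$label, n = t$n,
           mean_spectrum = unname(t$mean_spectrum),
           q25_spectrum = unname(t$q25_spectrum),
           q75_spectrum = unname(t$q75_spectrum),
           pooled_ici = t$pooled_ici,
           pooled_modal_ici = t$pooled_modal_ici,
           modal_ici = t$modal_ici,
           mean_modal_ici = t$mean_modal_ici,
           cv_modal_ici = t$cv_modal_ici,
           peak_khz = t$peak_khz,
           mean_peak_khz = t$mean_peak_khz,
           cv_peak_khz = t$cv_peak_khz,
           members = t$members)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_template_bundle
#' @export
read_template_bundle <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  if (!identical(doc$format, "clicknet_template_bundle")) {
    stop(path, " is not a clicknet template bundle")
  }
  cfg <- doc$config
  config <- phase2_config(nodes_per_site = cfg$nodes_per_site,
                          n_runs = cfg$n_runs, p_e = cfg$p_e,
                          min_cluster_size = cfg$min_cluster_size,
                          max_iterations = cfg$max_iterations,
                          rng_seed = cfg$rng_seed)
  tdoc <- doc$templates
  templates <- lapply(seq_len(nrow(tdoc)), function(k) {
    t <- lapply(tdoc, function(col) {
      if (is.data.frame(col) || is.matrix(col)) col[k, ] else
        if (is.list(col)) col[[k]] else col[k]
    })
    t$members <- as.data.frame(t$members)
    t$mean_spectrum <- as.numeric(t$mean_spectrum)
    t$q25_spectrum <- as.numeric(t$q25_spectrum)
    t$q75_spectrum <- as.numeric(t$q75_spectrum)
    t$pooled_ici <- as.integer(t$pooled_ici)
    structure(t, class = "click_type_template")
  })
  structure(list(templates = templates, config = config, partition = NULL),
            class = "click_type_bundle")
}

#' Default pipeline configuration
#'
#' All stage parameters at their standard defaults: detector thresholds
#' (95 dB boundary, 120 dBpp received level, 15-85 kHz peak band), bin
#' rules (minimum 100 clicks, cap 5000), per-stage pruning (0.95 for both
#' clustering phases, 0.90 for classification), Phase 2 sampling (1000
#' nodes/site, 20 runs, minimum cluster size 20) and the 0.3 certainty
#' threshold. Every value can be overridden via `...` (named nested
#' lists) or a YAML file ([read_pipeline_config()]).
#'
#' @param ... Named overrides merged recursively onto the defaults, e.g.
#'   `phase1 = list(p_e = 0.9)`.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    detector = unclass(detector_config()),
    phase1 = list(p_e = 0.95, min_clicks = 100, max_clicks = 5000,
                  bin_s = 300, min_cluster_size = 100),
    phase2 = unclass(phase2_config()),
    classify = list(p_e = 0.90, threshold = 0.3),
    encounter_gap_min = 15,
    rng_seed = 1
  )
  overrides <- list(...)
  if (length(overrides) > 0) {
    cfg <- modifyList(cfg, overrides)
  }
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration file (YAML)
#'
#' Values present in the file override the defaults of
#' [pipeline_config()]; everything else keeps its default.
#'
#' @param path YAML file path.
#' @param config A `pipeline_config` to serialize.
#' @return `read_pipeline_config`: a `pipeline_config`;
#'   `write_pipeline_config`: `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  overrides <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  if (length(overrides) > 0) cfg <- modifyList(cfg, overrides)
  structure(cfg, class = "pipeline_config")
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
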