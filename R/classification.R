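#' Classify summary nodes against trained click-type templates
#'
#' For each test summary node, the combined similarity `S2` (spectral
#' shape x modal ICI) is computed against every training summary node
#' across all templates. The pooled test-to-training score set is pruned
#' of its weakest `p_e` fraction (one percentile computation per test
#' node); each template then scores the mean of its surviving
#' similarities (0 if none survive). The node is assigned to the
#' highest-scoring template, with the winning score retained as the
#' classification certainty; a winning score below `threshold` yields
#' `"Unknown"`. A lower `p_e` than in training (default 0.90) keeps more
#' edges so that poorer-quality test nodes can still match.
#'
#' @param nodes Summary-node table of test nodes (spectrum + modal ICI).
#' @param bundle A `click_type_bundle` from [discover_types()].
#' @param p_e Pruning fraction applied to the pooled score set. Default
#'   0.90.
#' @param threshold Certainty threshold below which the label is
#'   `"Unknown"`. Default 0.3.
#' @return data.frame with `node_id`, `label`, `certainty` and one
#'   `score_<label>` column per template. Ties in the winning score are
#'   broken by template label order.
#' @export
classify_nodes <- function(nodes, bundle, p_e = 0.90, threshold = 0.3) {
  stopifnot(inherits(bundle, "click_type_bundle"))
  if (length(bundle$templates) == 0) stop("bundle contains no templates")
  if (nrow(nodes) == 0) {
    out <- data.frame(node_id = character(0), label = character(0),
                      certainty = numeric(0))
    for (t in bundle$templates) out[[paste0("score_", t$label)]] <- numeric(0)
    return(out)
  }
  labels <- vapply(bundle$templates, `[[`, "", "label")
  train <- do.call(rbind, lapply(bundle$templates, `[[`, "members"))
  train_tpl <- rep(labels, vapply(bundle$templates, `[[`, 0L, "n"))
  train_specs <- spectrum_matrix(train)
  test_specs <- spectrum_matrix(nodes)
  s_spec <- spectral_similarity(normalize_spectrum(test_specs),
                                normalize_spectrum(train_specs))
  s_ici <- ici_similarity(outer(nodes$modal_ici, rep(1, nrow(train))),
                          outer(rep(1, nrow(nodes)), train$modal_ici))
  s2 <- combined_similarity(s_spec, s_ici)
  n_train <- nrow(train)
  n_keep <- max(1L, round((1 - p_e) * n_train))
  res <- lapply(seq_len(nrow(nodes)), function(i) {
    w <- s2[i, ]
    ok <- !is.na(w)
    keep_n <- min(n_keep, sum(ok))
    ord <- order(-w, seq_along(w), na.last = TRUE)
    surv <- head(ord[ok[ord]], keep_n)
    scores <- vapply(labels, function(lb) {
      s <- surv[train_tpl[surv] == lb]
      if (length(s) == 0) 0 else mean(w[s])
    }, 0)
    win <- which.max(scores)  # first (label-order) winner on ties
    certainty <- scores[win]
    lab <- if (certainty < threshold) "Unknown" else labels[win]
    c(list(label = lab, certainty = certainty),
      as.list(setNames(scores, paste0("score_", labels))))
  })
  out <- data.frame(node_id = if (!is.null(nodes$node_id)) nodes$node_id
                    else as.character(seq_len(nrow(nodes))),
                    label = vapply(res, `[[`, "", "label"),
                    certainty = vapply(res, `[[`, 0, "certainty"),
                    stringsAsFactors = FALSE)
  for (lb in labels) {
    out[[paste0("score_", lb)]] <- vapply(res, `[[`, 0, paste0("score_", lb))
  }
  rownames(out) <- NULL
  out
}

#' Classify a single summary node
#'
#' Convenience wrapper around [classify_nodes()] for one node.
#'
#' @param node One-row summary-node data.frame.
#' @param bundle,p_e,threshold See [classify_nodes()].
#' @return One-row classification data.frame.
#' @export
classify_node <- function(node, bundle, p_e = 0.90, threshold = 0.3) {
  classify_nodes(node[1, , drop = FALSE], bundle, p_e = p_e,
                 threshold = threshold)
}

#' Confusion matrix between automatic and reference labels
#'
#' Builds the (types + Unknown) x (types + Unknown) confusion matrix (rows
#' = automatic, columns = reference) and summary statistics. Two agreement
#' conventions are reported: the default treats every diagonal cell
#' (including Unknown-Unknown) as agreement; the strict convention counts
#' any node labeled Unknown by either method as a mismatch. Also reported
#' is the share of disagreements in which the automatic classifier
#' assigned a named type while the reference label was Unknown.
#'
#' @param auto_labels,ref_labels Character vectors of equal length.
#' @param types Optional ordered type labels; defaults to the sorted named
#'   labels present in either vector.
#' @param unknown Label used for unclassified nodes. Default `"Unknown"`.
#' @return List of class `confusion_eval`: `confusion` (integer matrix),
#'   `n`, `agreement` (diagonal fraction), `agreement_strict`,
#'   `n_mismatch` (off-diagonal count), `frac_auto_typed_ref_unknown`.
#' @export
evaluate_confusion <- function(auto_labels, ref_labels, types = NULL,
                               unknown = "Unknown") {
  if (length(auto_labels) != length(ref_labels)) {
    stop("auto and reference label vectors differ in length")
  }
  if (is.null(types)) {
    types <- sort(setdiff(unique(c(auto_labels, ref_labels)), unknown))
  }
  lv <- c(types, unknown)
  a <- factor(auto_labels, levels = lv)
  r <- factor(ref_labels, levels = lv)
  if (anyNA(a) || anyNA(r)) stop("labels outside the declared type set")
  cm <- table(auto = a, reference = r)
  n <- sum(cm)
  diag_total <- sum(diag(cm))
  n_mismatch <- n - diag_total
  typed_rows <- rownames(cm) != unknown
  auto_typed_ref_unknown <- sum(cm[typed_rows, unknown])
  strict_agree <- diag_total - cm[unknown, unknown]
  structure(list(
    confusion = unclass(cm),
    n = as.integer(n),
    agreement = diag_total / n,
    agreement_strict = strict_agree / n,
    n_mismatch = as.integer(n_mismatch),
    frac_auto_typed_ref_unknown =
      if (n_mismatch > 0) auto_typed_ref_unknown / n_mismatch else NA_real_
  ), class = "confusion_eval")
}

#' @export
print.confusion_eval <- function(x, ...) {
  cat(sprintf("<confusion_eval> n = %d, agreement %.1f%% (strict %.1f%%)\n",
              x$n, 100 * x$agreement, 100 * x$agreement_strict))
  if (!is.na(x$frac_auto_typed_ref_unknown)) {
    cat(sprintf(
      "  %.0f%% of %d mismatches: automatic typed, reference Unknown\n",
      100 * x$frac_auto_typed_ref_unknown, x$n_mismatch))
  }
  print(x$confusion)
  invisible(x)
}

#' Agreement as a function of classification certainty
#'
#' Bins classifications by certainty score (intervals closed on the left,
#' open on the right; the final interval also includes its right edge) and
#' reports the number of nodes and percent agreement with the reference
#' labels per bin - the operator diagnostic for choosing the Unknown
#' threshold.
#'
#' @param classifications Output of [classify_nodes()] (needs `label` and
#'   `certainty`), or a numeric certainty vector.
#' @param ref_labels Reference labels aligned with the classifications.
#' @param breaks Certainty bin edges. Default `seq(0, 1, 0.1)`.
#' @param auto_labels Automatic labels (only needed when
#'   `classifications` is a bare numeric vector).
#' @return data.frame with `bin_low`, `bin_high`, `n`, `pct_agreement`.
#' @export
certainty_accuracy_curve <- function(classifications, ref_labels,
                                     breaks = seq(0, 1, 0.1),
                                     auto_labels = NULL) {
  if (is.data.frame(classifications)) {
    certainty <- classifications$certainty
    auto_labels <- classifications$label
  } else {
    certainty <- as.numeric(classifications)
    if (is.null(auto_labels)) stop("auto_labels required with a bare certainty vector")
  }
  if (length(certainty) == 0) {
    return(data.frame(bin_low = numeric(0), bin_high = numeric(0),
                      n = integer(0), pct_agreement = numeric(0)))
  }
  if (length(ref_labels) != length(certainty)) stop("length mismatch")
  bin <- findInterval(certainty, breaks, rightmost.closed = TRUE)
  agree <- auto_labels == ref_labels
  nb <- length(breaks) - 1
  out <- data.frame(bin_low = breaks[-length(breaks)],
                    bin_high = breaks[-1],
                    n = tabulate(bin, nbins = nb))
  out$pct_agreement <- vapply(seq_len(nb), function(k) {
    if (out$n[k] == 0) NA_real_ else 100 * mean(agree[bin == k])
  }, 0)
  out
}
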