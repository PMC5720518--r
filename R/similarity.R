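#' Normalize spectral levels to \[0, 1\]
#'
#' Min-max normalization of a spectrum (or of each row of a matrix of
#' spectra): `u_n = (u - min(u)) / max(u - min(u))`. The result has minimum
#' exactly 0 and maximum exactly 1, which removes received-level offsets so
#' that subsequent comparisons see only spectral shape.
#'
#' @param u Numeric vector of spectral levels (dB), or a matrix with one
#'   spectrum per row.
#' @return Normalized vector or matrix. Constant (zero-range) spectra are a
#'   degenerate input and raise an error; callers drop such clicks.
#' @export
normalize_spectrum <- function(u) {
  if (is.matrix(u)) {
    rng <- apply(u, 1, function(r) diff(range(r)))
    if (any(rng == 0)) stop("degenerate spectrum: constant vector cannot be normalized")
    return((u - apply(u, 1, min)) / rng)
  }
  if (length(u) < 2) stop("spectrum must have at least 2 bins")
  r <- range(u)
  if (r[1] == r[2]) stop("degenerate spectrum: constant vector cannot be normalized")
  (u - r[1]) / (r[2] - r[1])
}

#' Spectral-shape similarity matrix
#'
#' For each pair of spectra, takes first differences across frequency bins
#' of the min-max normalized spectra, computes the correlation distance
#' `D = 1 - r` (Pearson) between the difference vectors, and converts it to
#' a similarity `S_SPEC = exp(-D)`. Since `D` lies in \[0, 2\], similarities
#' lie in `[exp(-2), 1]`. Working on first differences of normalized
#' spectra makes the measure invariant to amplitude offset and scale and
#' sensitive to the positions of spectral peaks and notches.
#'
#' @param A Matrix of spectra (one per row) on a common frequency grid;
#'   raw dB levels are accepted (normalization and differencing are affine-
#'   invariant steps applied internally).
#' @param B Optional second matrix on the same grid; when `NULL`, the
#'   within-set similarity of `A` is returned.
#' @return Similarity matrix (`nrow(A)` x `nrow(B)` or square). Rows whose
#'   difference vector has zero variance produce `NA` entries with a
#'   warning; callers drop those nodes.
#' @export
spectral_similarity <- function(A, B = NULL) {
  A <- as.matrix(A)
  if (ncol(A) < 3) stop("spectra need at least 3 bins")
  dA <- t(diff(t(A)))
  sd_a <- apply(dA, 1, sd)
  if (any(sd_a == 0)) {
    warning("dropping ", sum(sd_a == 0),
            " spectra with zero-variance first differences (similarity undefined)")
  }
  if (is.null(B)) {
    r <- suppressWarnings(cor(t(dA)))
    r[sd_a == 0, ] <- NA
    r[, sd_a == 0] <- NA
  } else {
    B <- as.matrix(B)
    if (ncol(B) != ncol(A)) stop("A and B must share one frequency grid")
    dB <- t(diff(t(B)))
    sd_b <- apply(dB, 1, sd)
    if (any(sd_b == 0)) {
      warning("dropping ", sum(sd_b == 0),
              " spectra with zero-variance first differences (similarity undefined)")
    }
    r <- suppressWarnings(cor(t(dA), t(dB)))
    r[sd_a == 0, ] <- NA
    r[, sd_b == 0] <- NA
  }
  exp(-(1 - r))
}

#' Modal-ICI similarity
#'
#' Similarity between two modal inter-click intervals:
#' `S_ICI = exp(-|a - b|)` with ICIs in seconds. On the working ICI range
#' (0.01-0.5 s) this yields values in roughly `[exp(-0.49), 1]`; no
#' rescaling is applied, so the ICI term attenuates the combined score
#' more gently than the spectral term.
#'
#' @param ici_a,ici_b Modal ICIs in seconds (vectorized).
#' @return Similarities in (0, 1].
#' @export
ici_similarity <- function(ici_a, ici_b) {
  exp(-abs(ici_a - ici_b))
}

#' Combined spectral-ICI similarity
#'
#' Product fusion `S2 = S_ICI * S_SPEC`: a pair scores high only when both
#' the spectral shapes and the modal ICIs agree.
#'
#' @param s_spec,s_ici Similarities in (0, 1] (vector/matrix, recycled).
#' @return Elementwise product.
#' @export
combined_similarity <- function(s_spec, s_ici) {
  s_spec * s_ici
}

#' Prune the weakest edges of a similarity network
#'
#' Removes the weakest `p_e` fraction of edges by weight. The percentile is
#' dynamic (computed per network), not an absolute threshold, so strongly
#' and weakly interrelated networks are pruned by the same amount. Nodes
#' left without any surviving edge are reported as isolated.
#'
#' Two edge-counting conventions are supported for the retention quota:
#' `"pairs"` (default) counts distinct unordered node pairs, n(n-1)/2 for a
#' complete network; `"square_half"` uses the self-inclusive halved count
#' n^2/2 sometimes quoted for complete networks (e.g. 5,000 nodes ->
#' 12.5 million edges, 625,000 retained at `p_e = 0.95`). Both counts are
#' recorded on the result. The retained quota is
#' `round((1 - p_e) * edge_count)`, capped at the number of pairs actually
#' present. Ties at the cut are broken by a stable sort on
#' (weight, node pair), so results are deterministic.
#'
#' @param sim Symmetric similarity matrix (diagonal ignored), optionally
#'   with `NA` entries marking dropped pairs, or an edge data.frame with
#'   columns `i`, `j`, `weight`.
#' @param p_e Pruning fraction in \[0, 1).
#' @param node_ids Optional node identifiers (default: matrix rownames or
#'   1..n).
#' @param quota `"pairs"` or `"square_half"` (see above).
#' @return A `pruned_network`: list with `node_ids`, `edges` (data.frame
#'   `i`, `j`, `weight`, indices into `node_ids`), `isolated` (node ids with
#'   no surviving edge), `p_e`, `n_edges_pairs`, `n_edges_square_half`,
#'   `n_retained`.
#' @export
prune_network <- function(sim, p_e, node_ids = NULL,
                          quota = c("pairs", "square_half")) {
  quota <- match.arg(quota)
  if (!(p_e >= 0 && p_e < 1)) stop("p_e must be in [0, 1)")
  if (is.data.frame(sim)) {
    edges <- sim
    if (is.null(node_ids)) {
      node_ids <- sort(unique(c(edges$i, edges$j)))
    }
    n <- length(node_ids)
    ii <- match(edges$i, node_ids)
    jj <- match(edges$j, node_ids)
    w <- edges$weight
  } else {
    sim <- as.matrix(sim)
    n <- nrow(sim)
    if (is.null(node_ids)) {
      node_ids <- if (!is.null(rownames(sim))) rownames(sim) else seq_len(n)
    }
    if (n == 0) {
      return(structure(list(node_ids = node_ids,
                            edges = data.frame(i = integer(0), j = integer(0),
                                               weight = numeric(0)),
                            isolated = node_ids, p_e = p_e,
                            n_edges_pairs = 0, n_edges_square_half = 0,
                            n_retained = 0L),
                       class = "pruned_network"))
    }
    ut <- which(upper.tri(sim), arr.ind = TRUE)
    w <- sim[ut]
    ok <- !is.na(w)
    ut <- ut[ok, , drop = FALSE]
    w <- w[ok]
    ii <- ut[, 1]
    jj <- ut[, 2]
  }
  n_pairs <- length(w)
  n_square_half <- n^2 / 2
  base_count <- if (quota == "pairs") n_pairs else n_square_half
  n_keep <- min(n_pairs, round((1 - p_e) * base_count))
  ord <- order(-w, ii, jj)
  keep <- head(ord, n_keep)
  edges <- data.frame(i = ii[keep], j = jj[keep], weight = w[keep])
  connected <- unique(c(edges$i, edges$j))
  isolated <- node_ids[setdiff(seq_len(n), connected)]
  structure(list(node_ids = node_ids, edges = edges, isolated = isolated,
                 p_e = p_e, n_edges_pairs = n_pairs,
                 n_edges_square_half = n_square_half,
                 n_retained = nrow(edges)),
            class = "pruned_network")
}

#' @export
print.pruned_network <- function(x, ...) {
  cat(sprintf(
    "<pruned_network> %d nodes, %d/%s edges retained (p_e = %.2f), %d isolated\n",
    length(x$node_ids), x$n_retained,
    format(x$n_edges_pairs, big.mark = ","), x$p_e, length(x$isolated)))
  invisible(x)
}
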