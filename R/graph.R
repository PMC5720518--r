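#' Chinese Whispers configuration
#'
#' @param max_iterations Maximum number of full update passes. Default 20.
#' @param rng_seed Optional integer seed making the run bit-reproducible.
#' @param min_cluster_size Minimum cluster size retained by downstream
#'   filtering helpers (within-bin clustering uses 100; cross-bin type
#'   discovery uses 20). The clustering itself labels every connected node.
#' @return A list of class `cw_config`.
#' @export
cw_config <- function(max_iterations = 20, rng_seed = NULL,
                      min_cluster_size = 1) {
  stopifnot(max_iterations >= 1)
  structure(list(max_iterations = max_iterations, rng_seed = rng_seed,
                 min_cluster_size = min_cluster_size),
            class = "cw_config")
}

#' Construct a partition
#'
#' A partition maps node ids to integer cluster labels; unlabeled nodes
#' (isolated, or dropped by size filtering) are simply absent.
#'
#' @param labels Integer cluster labels, named by node id (names coerced to
#'   character).
#' @return Object of class `partition` with elements `labels` (named
#'   integer), `n` (number of labeled nodes), `sizes` (table of cluster
#'   sizes).
#' @export
partition <- function(labels) {
  if (is.null(names(labels))) names(labels) <- seq_along(labels)
  labels <- setNames(as.integer(labels), as.character(names(labels)))
  structure(list(labels = labels, n = length(labels),
                 sizes = table(labels)),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d nodes in %d clusters (sizes: %s)\n",
              x$n, length(x$sizes),
              paste(sort(as.integer(x$sizes), decreasing = TRUE),
                    collapse = ", ")))
  invisible(x)
}

#' Drop clusters below a minimum size from a partition
#'
#' Nodes belonging to clusters smaller than `min_size` become unlabeled
#' (removed from the partition).
#'
#' @param p A [partition()].
#' @param min_size Minimum retained cluster size.
#' @return A [partition()] over the surviving nodes.
#' @export
filter_small_clusters <- function(p, min_size) {
  stopifnot(inherits(p, "partition"))
  if (min_size <= 1) return(p)
  sizes <- table(p$labels)
  big <- as.integer(names(sizes)[sizes >= min_size])
  partition(p$labels[p$labels %in% big])
}

#' Chinese Whispers clustering of a weighted network
#'
#' Randomized label propagation: every connected node starts in its own
#' cluster; in each pass nodes are visited in a fresh random permutation
#' and each node adopts the label carrying the maximum summed incident
#' edge weight among its neighbors (ties broken uniformly at random).
#' Updates are asynchronous (labels change within a pass). Iteration stops
#' when a full pass produces no label change, or after
#' `max_iterations` passes. Isolated nodes are excluded from the result.
#'
#' @param net A [prune_network()] result (or any list with `node_ids` and
#'   an `edges` data.frame of `i`, `j`, `weight` indices into `node_ids`).
#' @param config A [cw_config()]; `rng_seed` makes the run reproducible.
#' @return A [partition()] over the non-isolated nodes, labels renumbered
#'   1..k in order of first appearance.
#' @export
chinese_whispers <- function(net, config = cw_config()) {
  edges <- net$edges
  node_ids <- net$node_ids
  connected <- sort(unique(c(edges$i, edges$j)))
  m <- length(connected)
  if (m == 0) return(partition(setNames(integer(0), character(0))))
  idx <- match(seq_along(node_ids), connected)  # original -> compact
  ei <- idx[edges$i]
  ej <- idx[edges$j]
  w <- edges$weight
  # CSR-style adjacency over compact node indices 1..m
  from <- c(ei, ej)
  to <- c(ej, ei)
  ww <- c(w, w)
  o <- order(from)
  nb_to <- to[o]
  nb_w <- ww[o]
  deg <- tabulate(from, nbins = m)
  ptr <- c(0L, cumsum(deg))
  run <- function() {
    lab <- seq_len(m)
    for (pass in seq_len(config$max_iterations)) {
      changed <- FALSE
      for (v in sample.int(m)) {
        lo <- ptr[v] + 1L
        hi <- ptr[v + 1L]
        if (hi < lo) next
        labs <- lab[nb_to[lo:hi]]
        sums <- rowsum(nb_w[lo:hi], labs)
        best <- as.integer(rownames(sums)[sums == max(sums)])
        new_lab <- if (length(best) == 1) best else best[sample.int(length(best), 1)]
        if (new_lab != lab[v]) {
          lab[v] <- new_lab
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    lab
  }
  lab <- if (is.null(config$rng_seed)) run() else with_seed(config$rng_seed, run())
  lab <- match(lab, unique(lab))
  partition(setNames(lab, as.character(node_ids[connected])))
}

# Align two partitions over a common node set. With common = FALSE (the
# default) mismatched node sets are an error; with common = TRUE the
# comparison is restricted to nodes labeled in both (the convention used
# when size-filtered partitions are compared during consensus selection).
align_partitions <- function(pa, pb, common = FALSE) {
  la <- if (inherits(pa, "partition")) pa$labels else pa
  lb <- if (inherits(pb, "partition")) pb$labels else pb
  if (is.null(names(la))) names(la) <- seq_along(la)
  if (is.null(names(lb))) names(lb) <- seq_along(lb)
  if (common) {
    shared <- intersect(names(la), names(lb))
    la <- la[shared]
    lb <- lb[shared]
  } else if (!setequal(names(la), names(lb))) {
    stop("partitions are over different node sets")
  }
  lb <- lb[names(la)]
  list(a = as.integer(la), b = as.integer(lb))
}

#' Normalized mutual information between two partitions
#'
#' Contingency-table normalized mutual information
#' `NMI = -2 * sum_ij n_ij log(n_ij n / (n_i n_j)) /
#'   (sum_i n_i log(n_i/n) + sum_j n_j log(n_j/n))`,
#' in \[0, 1\] with 1 for identical cluster composition. The degenerate
#' 0/0 form arising when both partitions consist of a single all-node
#' cluster is resolved to 1 (the partitions are identical).
#'
#' @param pa,pb [partition()] objects (or named label vectors) over the
#'   same node set.
#' @param common If `TRUE`, restrict the comparison to nodes labeled in
#'   both partitions (used when comparing size-filtered partitions);
#'   mismatched node sets are otherwise an error.
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(pa, pb, common = FALSE) {
  al <- align_partitions(pa, pb, common = common)
  n <- length(al$a)
  if (n == 0) {
    if (common) return(NA_real_)  # no co-labeled nodes to compare
    stop("empty partitions")
  }
  tab <- table(al$a, al$b)
  ni <- rowSums(tab)
  nj <- colSums(tab)
  den <- sum(ni * log(ni / n)) + sum(nj * log(nj / n))
  if (den == 0) return(1)  # both single-cluster: identical partitions
  nij <- as.numeric(tab)
  outer_n <- as.numeric(outer(ni, nj))
  pos <- nij > 0
  num <- -2 * sum(nij[pos] * log(nij[pos] * n / outer_n[pos]))
  val <- num / den
  min(max(val, 0), 1)
}

#' Best-of-K consensus partition
#'
#' Given K candidate partitions over a common node set, returns the one
#' maximizing the mean pairwise NMI against all others (ties broken by
#' lowest index). The output is always one of the candidates, never a
#' synthesized merge.
#'
#' @param partitions List of [partition()] objects.
#' @param common Passed to [nmi()]: compare size-filtered partitions on
#'   their common labeled nodes instead of requiring identical node sets.
#' @return List with `partition` (the winner), `index`, `mean_nmi`
#'   (per-candidate mean pairwise NMI) and `nmi_matrix` (K x K, diagonal 1).
#' @export
best_of_k <- function(partitions, common = FALSE) {
  K <- length(partitions)
  if (K == 0) stop("no partitions supplied")
  if (K == 1) {
    return(list(partition = partitions[[1]], index = 1L, mean_nmi = 1,
                nmi_matrix = matrix(1, 1, 1)))
  }
  M <- diag(1, K)
  for (a in seq_len(K - 1)) {
    for (b in (a + 1):K) {
      M[a, b] <- M[b, a] <- nmi(partitions[[a]], partitions[[b]], common = common)
    }
  }
  mean_nmi <- (rowSums(M, na.rm = TRUE) - 1) /
    pmax(1, rowSums(!is.na(M)) - 1)
  idx <- which.max(mean_nmi)  # which.max takes the first (lowest-index) tie
  list(partition = partitions[[idx]], index = idx, mean_nmi = mean_nmi,
       nmi_matrix = M)
}
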