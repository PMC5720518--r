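# Build a small trained bundle shared across classification tests.
trained_toy_bundle <- function(seed = 1, n_per_type = 150) {
  set.seed(seed)
  nodes <- toy_node_table(two_toy_types(), n_per_type = n_per_type)
  suppressWarnings(
    discover_types(nodes, phase2_config(nodes_per_site = n_per_type,
                                        rng_seed = 5))$bundle)
}

test_that("a node identical to one template's members matches it with certainty 1", {
  bundle <- trained_toy_bundle()
  tplA <- bundle$templates[[1]]
  # make every member of template A identical to the test node
  node <- tplA$members[1, ]
  bundle2 <- bundle
  bundle2$templates[[1]]$members <-
    tplA$members[rep(1, tplA$n), ]
  cls <- classify_node(node, bundle2)
  expect_equal(cls$label, tplA$label)
  expect_equal(cls$certainty, 1, tolerance = 1e-12)
})

test_that("dissimilar nodes fall below threshold and become Unknown", {
  # single template of identical members; test node with anticorrelated
  # spectral slope and distant ICI
  grid <- spectrum_grid_khz()
  centers <- ici_grid()$centers
  mk_node <- function(id, s, ici) {
    row <- data.frame(node_id = id, site_id = "S1", deployment_id = "D1",
                      bin_start = 1600000200, n_clicks = 150L,
                      modal_ici = ici, peak_khz = grid[which.max(s)],
                      stringsAsFactors = FALSE)
    row[sprintf("s%g", grid)] <- as.list(s)
    row[sprintf("i%g", centers)] <- as.list(rep(1L, 49))
    row
  }
  up <- seq(0, 24, length.out = 121)   # rising ramp + curvature
  base <- up + 8 * sin(seq(0, 3 * pi, length.out = 121))
  members <- do.call(rbind, lapply(1:25, function(k) {
    mk_node(sprintf("m%d", k), base, 0.065)
  }))
  tpl <- list(label = "A", n = 25L, members = members)
  class(tpl) <- "click_type_template"
  bundle <- structure(list(templates = list(tpl),
                           config = phase2_config()),
                      class = "click_type_bundle")
  anti <- -base  # first differences exactly anticorrelated
  cls <- classify_node(mk_node("t", anti, 0.45), bundle)
  # winning score ~ exp(-2) * exp(-0.385): far below 0.3
  expect_equal(cls$label, "Unknown")
  expect_lt(cls$certainty, 0.3)
  expect_gt(cls$certainty, 0)
  # the same node passes when matching (identical spectrum + ICI)
  cls2 <- classify_node(mk_node("t", base, 0.065), bundle)
  expect_equal(cls2$label, "A")
  expect_equal(cls2$certainty, 1, tolerance = 1e-12)
  # empty bundle is an error
  empty <- structure(list(templates = list(), config = phase2_config()),
                     class = "click_type_bundle")
  expect_error(classify_node(mk_node("t", base, 0.065), empty),
               "no templates")
})

test_that("scores equal a brute-force prune-then-mean oracle", {
  set.seed(2)
  bundle <- trained_toy_bundle(seed = 2)
  nodes <- toy_node_table(two_toy_types(), n_per_type = 3)
  p_e <- 0.9
  cls <- classify_nodes(nodes, bundle, p_e = p_e)
  train <- do.call(rbind, lapply(bundle$templates, `[[`, "members"))
  tlab <- rep(vapply(bundle$templates, `[[`, "", "label"),
              vapply(bundle$templates, `[[`, 0L, "n"))
  tspecs <- spectrum_matrix(train)
  nspecs <- spectrum_matrix(nodes)
  for (i in seq_len(nrow(nodes))) {
    s2 <- vapply(seq_len(nrow(train)), function(j) {
      oracle_s2(nspecs[i, ], tspecs[j, ],
                nodes$modal_ici[i], train$modal_ici[j])
    }, 0)
    keep <- max(1, round((1 - p_e) * length(s2)))
    surv <- order(-s2)[seq_len(keep)]
    for (lb in unique(tlab)) {
      s <- s2[surv[tlab[surv] == lb]]
      expected <- if (length(s) == 0) 0 else mean(s)
      expect_equal(cls[[paste0("score_", lb)]][i], expected,
                   tolerance = 1e-10)
    }
    expect_equal(cls$certainty[i],
                 max(cls[i, paste0("score_", unique(tlab))]))
  }
})

test_that("nodes drawn from the training specs classify back to their types", {
  set.seed(3)
  bundle <- trained_toy_bundle(seed = 3)
  fresh <- toy_node_table(two_toy_types(), n_per_type = 40)
  cls <- classify_nodes(fresh, bundle)
  expect_lte(mean(cls$label == "Unknown"), 0.1)
  truth <- substr(fresh$node_id, 1, 1)
  # map each template to its majority truth type, then check recall
  for (tt in unique(truth)) {
    assigned <- cls$label[truth == tt]
    best <- names(sort(table(assigned), decreasing = TRUE))[1]
    expect_false(best == "Unknown")
    expect_gte(mean(assigned == best), 0.9)
  }
  expect_true(all(cls$certainty >= 0 & cls$certainty <= 1))
})

test_that("lowering the threshold never converts a typed call to Unknown", {
  set.seed(4)
  bundle <- trained_toy_bundle(seed = 4)
  fresh <- toy_node_table(two_toy_types(), n_per_type = 15, noise_db = 6)
  hi <- classify_nodes(fresh, bundle, threshold = 0.5)
  lo <- classify_nodes(fresh, bundle, threshold = 0.2)
  typed_hi <- hi$label != "Unknown"
  expect_true(all(lo$label[typed_hi] == hi$label[typed_hi]))
  expect_gte(sum(lo$label != "Unknown"), sum(typed_hi))
})

test_that("template order does not change the winning label", {
  set.seed(5)
  bundle <- trained_toy_bundle(seed = 5)
  fresh <- toy_node_table(two_toy_types(), n_per_type = 10)
  cls1 <- classify_nodes(fresh, bundle)
  flipped <- bundle
  flipped$templates <- rev(bundle$templates)
  cls2 <- classify_nodes(fresh, flipped)
  expect_equal(cls1$label, cls2$label)
  expect_equal(cls1$certainty, cls2$certainty)
})

test_that("confusion statistics reproduce the published evaluation shares", {
  path <- system.file("extdata", "example_confusion_counts.tsv",
                      package = "clicknet")
  cm <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
  auto <- rep(rownames(cm), rowSums(cm))
  ref <- unlist(lapply(seq_len(nrow(cm)), function(i) {
    rep(colnames(cm), cm[i, ])
  }))
  ev <- evaluate_confusion(auto, ref, types = setdiff(rownames(cm), "Unknown"))
  expect_equal(ev$n, 1000L)
  expect_identical(unname(ev$confusion), unname(cm))
  # share of disagreements where the automatic label was a named type but
  # the reference was Unknown: prints as 47%
  expect_equal(round(100 * ev$frac_auto_typed_ref_unknown), 47)
  # strict convention: Unknown-Unknown cells are not agreement
  expect_equal(ev$agreement_strict,
               (sum(diag(cm)) - cm["Unknown", "Unknown"]) / sum(cm))
})

test_that("confusion matrices match a pair-counting oracle", {
  # identical labels: full agreement
  ev <- evaluate_confusion(c("A", "B", "B"), c("A", "B", "B"),
                           types = c("A", "B"))
  expect_equal(ev$agreement, 1)
  expect_equal(ev$n_mismatch, 0L)
  # random 8-label vectors against a direct tabulation
  set.seed(6)
  lv <- c(LETTERS[1:7], "Unknown")
  a <- sample(lv, 500, replace = TRUE)
  r <- sample(lv, 500, replace = TRUE)
  ev <- evaluate_confusion(a, r, types = LETTERS[1:7])
  for (x in lv) for (y in lv) {
    expect_equal(ev$confusion[x, y], sum(a == x & r == y))
  }
  expect_error(evaluate_confusion(a, r[-1]), "length")
})

test_that("certainty-accuracy curves bin left-closed and track agreement", {
  # all-correct: 100% in every occupied bin
  cls <- data.frame(label = rep("A", 20),
                    certainty = seq(0.05, 1, length.out = 20))
  curve <- certainty_accuracy_curve(cls, rep("A", 20))
  expect_true(all(curve$pct_agreement[curve$n > 0] == 100))
  expect_equal(sum(curve$n), 20)
  # boundary values fall in the right-hand bin (left-closed intervals);
  # quarter-step breaks are exactly representable
  cls2 <- data.frame(label = c("A", "A", "A"),
                     certainty = c(0.25, 0.5, 0.75))
  curve2 <- certainty_accuracy_curve(cls2, c("A", "A", "A"),
                                     breaks = seq(0, 1, 0.25))
  expect_equal(curve2$n, c(0L, 1L, 1L, 1L))
  # histogram oracle for counts
  set.seed(7)
  cert <- runif(300)
  lab <- sample(c("A", "B"), 300, replace = TRUE)
  ref <- sample(c("A", "B"), 300, replace = TRUE)
  curve3 <- certainty_accuracy_curve(
    data.frame(label = lab, certainty = cert), ref)
  oracle <- table(cut(cert, seq(0, 1, 0.1), right = FALSE))
  expect_equal(curve3$n, as.integer(oracle))
  # planted noise at low certainty: agreement increases with certainty
  n <- 400
  cert4 <- runif(n)
  ref4 <- rep("A", n)
  lab4 <- ifelse(runif(n) < cert4, "A", "B")
  curve4 <- certainty_accuracy_curve(
    data.frame(label = lab4, certainty = cert4), ref4)
  occ <- which(curve4$n > 0)
  expect_gt(cor(curve4$bin_low[occ], curve4$pct_agreement[occ]), 0.8)
  # empty input: empty table
  expect_equal(nrow(certainty_accuracy_curve(
    data.frame(label = character(0), certainty = numeric(0)),
    character(0))), 0)
})
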