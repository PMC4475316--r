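# CART-style threshold-tree induction on log10 eigenvalue features, plus a
# stratified k-fold cross-validation harness.
#
# Splits are greedy binary thresholds on a single feature chosen by Gini
# impurity, with candidate thresholds at midpoints between consecutive
# sorted feature values. Ties (and zero-gain candidates, which are allowed
# so that interaction structure such as an XOR arrangement over two
# eigenvalues remains learnable at depth 2) resolve to the lowest feature
# index, then the lowest threshold. Growth stops at purity, max_depth, or
# when no candidate leaves min_leaf records on both sides.

FEATURE_COLS <- paste0("log10_lambda", 1:8)

#' Assemble a feature dataset for induction
#'
#' @param spectra list of [eigen_spectrum()] objects, or a numeric matrix
#'   with 8 columns of *linear* eigenvalues (one row per record).
#' @param labels character vector of `"AC"`/`"UN"` reference labels.
#' @param record_ids optional unique identifiers.
#' @return A data frame with columns `record_id`, `log10_lambda1..8`,
#'   `label`.
#' @export
feature_dataset <- function(spectra, labels, record_ids = NULL) {
  if (is.list(spectra))
    spectra <- do.call(rbind, lapply(spectra, as.numeric))
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != 8L)
    stop_input("feature_dataset: expected 8 eigenvalues per record")
  if (nrow(spectra) != length(labels))
    stop_input("feature_dataset: %d spectra vs %d labels", nrow(spectra), length(labels))
  if (!all(labels %in% c("AC", "UN")))
    stop_input("feature_dataset: labels must be AC or UN")
  record_ids <- record_ids %||% sprintf("rec-%04d", seq_len(nrow(spectra)))
  if (anyDuplicated(record_ids))
    stop_input("feature_dataset: duplicate record ids")
  feat <- t(apply(spectra, 1, log10_lambdas))
  colnames(feat) <- FEATURE_COLS
  data.frame(record_id = as.character(record_ids), feat,
             label = as.character(labels), stringsAsFactors = FALSE)
}

gini <- function(n_un, n) {
  if (n == 0) return(0)
  p <- n_un / n
  2 * p * (1 - p)
}

# Best split for one node: list(feature, threshold, score) or NULL.
best_split <- function(x, y, min_leaf) {
  n <- length(y)
  best <- NULL
  for (j in seq_len(ncol(x))) {
    ord <- order(x[, j])
    xs <- x[ord, j]
    un <- cumsum(y[ord] == "UN")
    distinct <- which(diff(xs) > 0)          # split after position i
    valid <- distinct[distinct >= min_leaf & (n - distinct) >= min_leaf]
    if (!length(valid)) next
    nl <- valid
    score <- (nl * vapply(seq_along(valid), function(ii)
                gini(un[valid[ii]], nl[ii]), 0) +
              (n - nl) * vapply(seq_along(valid), function(ii)
                gini(un[n] - un[valid[ii]], n - nl[ii]), 0)) / n
    ii <- which.min(score)                    # lowest threshold among ties
    if (is.null(best) || score[ii] < best$score - 1e-12) {
      best <- list(feature = j,
                   threshold = (xs[valid[ii]] + xs[valid[ii] + 1L]) / 2,
                   score = score[ii])
    }
  }
  best
}

grow_node <- function(x, y, depth, max_depth, min_leaf) {
  n <- length(y)
  n_un <- sum(y == "UN")
  label <- if (n_un * 2 >= n) "UN" else "AC"   # majority; ties resolve to UN
  leaf <- list(type = "leaf", label = label,
               support = n, errors = min(n_un, n - n_un),
               p_un = n_un / n)
  if (depth >= max_depth || n < 2 * min_leaf || n_un == 0L || n_un == n)
    return(leaf)
  sp <- best_split(x, y, min_leaf)
  if (is.null(sp)) return(leaf)
  left <- x[, sp$feature] <= sp$threshold
  list(type = "node", feature = sp$feature, threshold = sp$threshold,
       left = grow_node(x[left, , drop = FALSE], y[left],
                        depth + 1L, max_depth, min_leaf),
       right = grow_node(x[!left, , drop = FALSE], y[!left],
                         depth + 1L, max_depth, min_leaf))
}

#' Induce a threshold tree on eigenvalue features
#'
#' @param data a [feature_dataset()].
#' @param max_depth maximum tree depth (root = depth 0; default 4).
#' @param min_leaf minimum records per leaf (default 5).
#' @return An `induced_tree`: nested nodes
#'   `list(type = "node", feature, threshold, left, right)` with the left
#'   branch taken when `feature value <= threshold`, and leaves carrying
#'   `label`, `support`, `errors` and the UN purity `p_un`.
#' @export
induce_tree <- function(data, max_depth = 4, min_leaf = 5) {
  if (!is.data.frame(data) || nrow(data) < 1L)
    stop_input("induce_tree: empty dataset")
  x <- as.matrix(data[, FEATURE_COLS])
  y <- data$label
  structure(list(root = grow_node(x, y, 0L, max_depth, min_leaf),
                 max_depth = max_depth, min_leaf = min_leaf,
                 n_train = nrow(data)),
            class = "induced_tree")
}

tree_eval <- function(node, feats) {
  while (node$type == "node")
    node <- if (feats[node$feature] <= node$threshold) node$left else node$right
  node
}

#' Predict labels (and UN purity scores) from an induced tree
#'
#' @param tree an [induce_tree()] result.
#' @param data a [feature_dataset()] (labels ignored if present).
#' @return A data frame with `record_id`, `label` and `score` (the training
#'   UN fraction of the deciding leaf, used for ranking/AUC).
#' @export
predict_tree <- function(tree, data) {
  x <- as.matrix(data[, FEATURE_COLS])
  leaves <- lapply(seq_len(nrow(x)), function(i) tree_eval(tree$root, x[i, ]))
  data.frame(record_id = data$record_id,
             label = vapply(leaves, `[[`, "", "label"),
             score = vapply(leaves, `[[`, 0, "p_un"),
             stringsAsFactors = FALSE)
}

#' Flatten an induced tree into a first-match rule set
#'
#' Every root-to-leaf path becomes one conjunctive [threshold_rule()];
#' since the paths partition the feature space, the rule set reproduces the
#' tree's decisions exactly on any input. The default label is the
#' majority-support leaf label (it can never fire).
#'
#' @param tree an [induce_tree()] result (or a bare root node list).
#' @param name model name for the resulting registry entry.
#' @return A [rule_set()].
#' @export
tree_to_rules <- function(tree, name = "induced-tree") {
  root <- if (inherits(tree, "induced_tree")) tree$root else tree
  paths <- list()
  walk <- function(node, conjuncts) {
    if (node$type == "leaf") {
      paths[[length(paths) + 1L]] <<- list(conjuncts = conjuncts,
                                           label = node$label,
                                           support = node$support)
      return(invisible())
    }
    walk(node$left, c(conjuncts, list(list(lambda = node$feature, op = "<=",
                                           log10_threshold = node$threshold))))
    walk(node$right, c(conjuncts, list(list(lambda = node$feature, op = ">",
                                            log10_threshold = node$threshold))))
  }
  if (root$type == "leaf") {
    return(rule_set(list(), default = root$label, name = name,
                    notes = "single-leaf tree"))
  }
  walk(root, list())
  support <- vapply(paths, `[[`, 0, "support")
  labels <- vapply(paths, `[[`, "", "label")
  default <- labels[which.max(support)]
  rule_set(lapply(paths, function(p) threshold_rule(p$conjuncts, p$label)),
           default = default, name = name)
}

#' Stratified k-fold cross-validation of the tree inducer
#'
#' Records are partitioned into k folds preserving class proportions
#' (seeded shuffle within class, folds assigned cyclically); each record
#' appears in exactly one test fold. Fold metrics come from
#' [evaluate_labels()]; pooled metrics and the AUC are computed over the
#' concatenated test-fold predictions, ranking records by the UN purity of
#' the deciding leaf (midranks for ties).
#'
#' @param data a [feature_dataset()].
#' @param k number of folds (2 <= k <= number of records).
#' @param seed integer seed for the fold shuffle.
#' @param max_depth,min_leaf inducer parameters.
#' @return List with `fold_metrics` (data frame, one row per fold),
#'   `pooled` (an `ecg_eval`), `auc`, and `assignments` (fold id per
#'   record, named by record id).
#' @export
cross_validate <- function(data, k = 10, seed = 1, max_depth = 4, min_leaf = 5) {
  n <- nrow(data)
  if (k < 2 || k > n)
    stop_input("cross_validate: k must satisfy 2 <= k <= %d", n)
  fold <- integer(n)
  order_idx <- with_seed(seed, {
    unlist(lapply(c("UN", "AC"), function(cl) sample(which(data$label == cl))))
  })
  fold[order_idx] <- rep_len(seq_len(k), n)
  pred <- character(n); score <- numeric(n)
  fold_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    test <- fold == f
    tree <- induce_tree(data[!test, , drop = FALSE], max_depth, min_leaf)
    p <- predict_tree(tree, data[test, , drop = FALSE])
    pred[test] <- p$label
    score[test] <- p$score
    m <- evaluate_labels(p$label, data$label[test])
    fold_metrics[[f]] <- data.frame(fold = f, n = m$n, accuracy = m$accuracy,
                                    sensitivity = m$sensitivity,
                                    specificity = m$specificity)
  }
  list(fold_metrics = do.call(rbind, fold_metrics),
       pooled = evaluate_labels(pred, data$label),
       auc = auc_from_scores(score, data$label),
       assignments = stats::setNames(fold, data$record_id))
}
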