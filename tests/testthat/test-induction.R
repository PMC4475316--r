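# Builds feature datasets directly from prescribed log10 eigenvalues; the
# lambda2..lambda7 filler keeps every spectrum descending.
make_l8_dataset <- function(l8_un, l8_ac) {
  filler <- 10^seq(4, 2, length.out = 7)
  spectra <- rbind(
    t(vapply(l8_un, function(v) c(filler, 10^v), numeric(8))),
    t(vapply(l8_ac, function(v) c(filler, 10^v), numeric(8))))
  feature_dataset(spectra, c(rep("UN", length(l8_un)), rep("AC", length(l8_ac))))
}

test_that("a separable threshold is recovered exactly at depth 1", {
  set.seed(11)
  ds <- make_l8_dataset(l8_un = runif(20, -2, -0.5), l8_ac = runif(20, 0.5, 1.5))
  tree <- induce_tree(ds)
  expect_identical(tree$root$type, "node")
  expect_equal(tree$root$feature, 8)
  # recovered threshold lies in the gap between the two classes
  expect_gt(tree$root$threshold, max(ds$log10_lambda8[ds$label == "UN"]))
  expect_lt(tree$root$threshold, min(ds$log10_lambda8[ds$label == "AC"]))
  expect_identical(tree$root$left$type, "leaf")
  pred <- predict_tree(tree, ds)
  expect_identical(pred$label, ds$label)
})

test_that("single-class data induces a single leaf", {
  ds <- make_l8_dataset(l8_un = numeric(0), l8_ac = seq(0.5, 1.5, length.out = 12))
  tree <- induce_tree(ds)
  expect_identical(tree$root$type, "leaf")
  expect_identical(tree$root$label, "AC")
  rs <- tree_to_rules(tree)
  expect_length(rs$rules, 0)
  expect_identical(apply_rule_set(rs, random_spectrum())$label, "AC")
})

test_that("an XOR arrangement needs depth 2, which the inducer reaches", {
  filler <- seq(2.9, 1.2, length.out = 6)
  corners <- expand.grid(l1 = c(3, 4), l8 = c(0, 1))
  spectra <- do.call(rbind, lapply(seq_len(4), function(i)
    matrix(10^c(corners$l1[i], filler, corners$l8[i]), 10, 8, byrow = TRUE)))
  labels <- rep(ifelse(corners$l1 - 3 == corners$l8, "UN", "AC"), each = 10)
  ds <- feature_dataset(spectra, labels)
  expect_equal(best_depth1_accuracy(ds), 0.5)   # no depth-1 tree beats chance
  tree <- induce_tree(ds, max_depth = 2, min_leaf = 5)
  expect_identical(predict_tree(tree, ds)$label, ds$label)
})

test_that("training accuracy is non-decreasing in max_depth", {
  set.seed(12)
  coh <- generate_cohort(120, 0.5, template = synthetic_config(duration = 2), seed = 3)
  ds <- feature_dataset(lapply(coh$records, extract_features), coh$labels)
  acc <- vapply(1:4, function(d) {
    tree <- induce_tree(ds, max_depth = d, min_leaf = 2)
    mean(predict_tree(tree, ds)$label == ds$label)
  }, 0)
  expect_true(all(diff(acc) >= 0))
})

test_that("flattened rules reproduce tree decisions everywhere", {
  set.seed(13)
  coh <- generate_cohort(80, 0.5, template = synthetic_config(duration = 2), seed = 8)
  ds <- feature_dataset(lapply(coh$records, extract_features), coh$labels)
  tree <- induce_tree(ds)
  rs <- tree_to_rules(tree)
  # depth-1 tree gives exactly 2 rules
  t1 <- induce_tree(ds, max_depth = 1)
  expect_length(tree_to_rules(t1)$rules, 2)
  # agreement on training data and on fresh random spectra
  pred <- predict_tree(tree, ds)
  agree <- vapply(seq_len(nrow(ds)), function(i)
    apply_rule_set(rs, structure(10^as.numeric(
      ds[i, paste0("log10_lambda", 1:8)]), class = "eigen_spectrum"))$label, "")
  expect_identical(agree, pred$label)
})

test_that("the published CART tree re-encoded as rules matches classify_cart", {
  cart_tree <- list(type = "node", feature = 8, threshold = 0.145,
    left = list(type = "leaf", label = "UN", support = 143, errors = 6, p_un = 137 / 143),
    right = list(type = "node", feature = 1, threshold = 5.08,
      left = list(type = "leaf", label = "AC", support = 788, errors = 67, p_un = 67 / 788),
      right = list(type = "leaf", label = "UN", support = 67, errors = 0, p_un = 1)))
  rs <- tree_to_rules(cart_tree, name = "cart-reencoded")
  expect_length(rs$rules, 3)
  set.seed(14)
  for (i in 1:1000) {
    sp <- random_spectrum()
    expect_identical(apply_rule_set(rs, sp)$label, classify_cart(sp))
  }
})

test_that("the inducer agrees with rpart on cleanly separable data", {
  set.seed(15)
  ds <- make_l8_dataset(l8_un = runif(30, -2, -0.5), l8_ac = runif(30, 0.5, 1.5))
  ours <- predict_tree(induce_tree(ds, max_depth = 1), ds)$label
  fit <- rpart::rpart(factor(label) ~ ., data = ds[, -1],
                      control = rpart::rpart.control(maxdepth = 1, cp = 0, minsplit = 2))
  theirs <- as.character(predict(fit, ds, type = "class"))
  expect_identical(ours, theirs)
})

test_that("cross-validation partitions correctly and is seed-reproducible", {
  set.seed(16)
  coh <- generate_cohort(60, 0.5, template = synthetic_config(duration = 2), seed = 4)
  ds <- feature_dataset(lapply(coh$records, extract_features), coh$labels)
  cv <- cross_validate(ds, k = 5, seed = 2)
  expect_equal(sort(unique(cv$assignments)), 1:5)
  expect_length(cv$assignments, 60)
  expect_equal(cv$pooled$n, 60)
  expect_equal(sum(cv$fold_metrics$n), 60)
  # stratification keeps class balance within one record per fold
  for (f in 1:5) {
    in_f <- cv$assignments == f
    expect_lte(abs(sum(ds$label[in_f] == "UN") - 30 / 5), 1)
  }
  cv2 <- cross_validate(ds, k = 5, seed = 2)
  expect_identical(cv2$assignments, cv$assignments)
  expect_identical(cv2$pooled, cv$pooled)
  expect_false(identical(cross_validate(ds, k = 5, seed = 3)$assignments,
                         cv$assignments))
  expect_error(cross_validate(ds, k = 61), "2 <= k")
  expect_error(cross_validate(ds, k = 1), "2 <= k")
  # leave-one-out: n folds of size 1
  small <- ds[1:10, ]
  cv_loo <- cross_validate(small, k = 10, seed = 1, min_leaf = 1)
  expect_equal(unname(table(cv_loo$assignments)), rep(1L, 10), ignore_attr = TRUE)
})

test_that("cross-validated trees classify a synthetic cohort accurately", {
  coh <- generate_cohort(400, 0.5, seed = 7)
  ds <- feature_dataset(lapply(coh$records, extract_features), coh$labels,
                        record_ids = vapply(coh$records, `[[`, "", "record_id"))
  cv <- cross_validate(ds, k = 10, seed = 7)
  expect_gte(cv$pooled$accuracy, 0.9)
  expect_gte(cv$auc, 0.9)
})
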