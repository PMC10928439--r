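test_that("edge labels partition edges into c/nc/unlabeled by co-membership", {
  pin <- weighted_pin(data.frame(u = c("a", "a", "a"),
                                 v = c("b", "c", "x"),
                                 weight = c(1, 1, 1)))
  gold <- complex_set(list(c("a", "b"), c("c", "d")))
  lab <- label_edges(pin, gold)
  expect_equal(lab$label[lab$v == "b"], "c-edge")
  expect_equal(lab$label[lab$v == "c"], "nc-edge")  # both in universe, never co-members
  expect_equal(lab$label[lab$v == "x"], "unlabeled")
  # the three classes always cover all edges
  expect_equal(nrow(lab), pin_edge_count(pin))
  expect_true(all(lab$label %in% c("c-edge", "nc-edge", "unlabeled")))
})

test_that("classification metrics reproduce hand-computed confusion tables", {
  r <- classification_metrics(list(TP = 10, FP = 0, TN = 10, FN = 0))
  expect_equal(unlist(r[c("ACC", "SEN", "SPE", "PRE", "F1", "MCC")]),
               c(ACC = 1, SEN = 1, SPE = 1, PRE = 1, F1 = 1, MCC = 1))
  # TP=2, FP=1, TN=3, FN=0
  r2 <- classification_metrics(list(TP = 2, FP = 1, TN = 3, FN = 0))
  expect_equal(r2$ACC, 5 / 6)
  expect_equal(r2$SEN, 1)
  expect_equal(r2$SPE, 0.75)
  expect_equal(r2$PRE, 2 / 3)
  expect_equal(r2$F1, 0.8)
  expect_equal(r2$MCC, 6 / sqrt(72))
  # degenerate denominators fall back to 0 with warnings
  w <- capture_warnings(
    r3 <- classification_metrics(list(TP = 0, FP = 0, TN = 5, FN = 2)))
  expect_match(w, "PRE", all = FALSE)
  expect_match(w, "MCC", all = FALSE)
  expect_equal(r3$PRE, 0)
  expect_equal(r3$MCC, 0)
  expect_error(classification_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)),
               "zero")
})

test_that("metric identities hold on random confusion tables", {
  set.seed(5)
  for (i in 1:50) {
    cc <- as.list(stats::setNames(sample(1:30, 4L), c("TP", "FP", "TN", "FN")))
    r <- classification_metrics(cc)
    # F1 = 2 TP / (2 TP + FP + FN)
    expect_equal(r$F1, 2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN))
    # ACC is the prevalence-weighted mix of SEN and SPE
    n_pos <- cc$TP + cc$FN; n_neg <- cc$TN + cc$FP
    expect_equal(r$ACC, (n_pos * r$SEN + n_neg * r$SPE) / (n_pos + n_neg))
    expect_true(r$MCC >= -1 && r$MCC <= 1)
  }
})

test_that("rank-sum AUC behaves at the extremes and near 0.5 for noise", {
  truth <- rep(c(TRUE, FALSE), each = 500)
  perfect <- c(stats::runif(500, 0.6, 1), stats::runif(500, 0, 0.4))
  expect_equal(classification_metrics(list(TP = 1, FP = 0, TN = 1, FN = 0),
                                      scores = perfect, truth = truth)$AUC, 1)
  expect_equal(classification_metrics(list(TP = 1, FP = 0, TN = 1, FN = 0),
                                      scores = -perfect, truth = truth)$AUC, 0)
  set.seed(6)
  random <- stats::runif(1000)
  auc <- classification_metrics(list(TP = 1, FP = 0, TN = 1, FN = 0),
                                scores = random, truth = truth)$AUC
  expect_lt(abs(auc - 0.5), 0.05)
})

test_that("sub-sampled CV balances every training round and holds out each edge once", {
  sim <- generate_edge_feature_data(n_c = 20, n_nc = 200, separation = 3,
                                    seed = 9)
  cv <- subsampled_cv(sim$features, sim$labels, folds = 10L, seed = 1L,
                      classifier = classifier_glm())
  # training rounds: 18 c-edges + an equal draw of nc-edges
  expect_true(all(cv$train_sizes[, "c-edge"] == 18L))
  expect_true(all(cv$train_sizes[, "c-edge"] == cv$train_sizes[, "nc-edge"]))
  # every edge held out exactly once, with a probability recorded
  expect_false(anyNA(cv$heldout_prob))
  expect_equal(sort(unique(cv$fold)), 1:10)
  # per-round test sets are the complement: 2 c-edges + 182 nc-edges
  totals <- vapply(cv$fold_confusion, function(cc) do.call(sum, cc), 0)
  expect_true(all(totals == 220 - 36))
  # determinism under a fixed seed
  cv2 <- subsampled_cv(sim$features, sim$labels, folds = 10L, seed = 1L,
                       classifier = classifier_glm())
  expect_identical(cv$heldout_prob, cv2$heldout_prob)
  expect_identical(cv$fold, cv2$fold)
  # a class smaller than the fold count is rejected with advice
  expect_error(subsampled_cv(sim$features[1:15, ],
                             c(rep("c-edge", 5), rep("nc-edge", 10)),
                             folds = 10L, seed = 1L),
               "fewer folds")
})

test_that("separable features drive CV sensitivity and specificity to 1", {
  sim <- generate_edge_feature_data(n_c = 60, n_nc = 300, separation = 8,
                                    seed = 2)
  cv <- subsampled_cv(sim$features, sim$labels, folds = 10L, seed = 3L,
                      classifier = classifier_glm())
  expect_equal(cv$report$SEN, 1)
  expect_equal(cv$report$SPE, 1)
  expect_equal(cv$report$AUC, 1)
})

test_that("LE-PIN construction replaces weights with c-edge probabilities", {
  pin <- weighted_pin(data.frame(u = c("a", "a", "c"), v = c("b", "c", "d"),
                                 weight = c(1, 1, 1)))
  gold <- complex_set(list(c("a", "b"), c("c", "d")))
  lab <- label_edges(pin, gold)
  feats <- data.frame(u = pin$edges$u, v = pin$edges$v,
                      f1 = c(0.9, 0.1, 0.8), f2 = c(0.8, 0.2, 0.9))
  # constant classifier: every weight becomes p
  fit <- build_lepin(pin, feats, lab, classifier = classifier_constant(0.7))
  expect_true(all(fit$pin$edges$weight == 0.7))
  expect_s3_class(fit$pin, "weighted_pin")
  expect_true(all(fit$pin$edges$weight >= 0 & fit$pin$edges$weight <= 1))
  # pinning labeled edges overrides predictions
  fit2 <- build_lepin(pin, feats, lab, classifier = classifier_constant(0.7),
                      pin_labels = TRUE)
  w <- stats::setNames(fit2$pin$edges$weight,
                       pin_pair_key(fit2$pin$edges$u, fit2$pin$edges$v))
  expect_equal(unname(w[pin_pair_key("a", "b")]), 1)
  expect_equal(unname(w[pin_pair_key("a", "c")]), 0)
  # missing feature rows are reported by pair
  expect_error(build_lepin(pin, feats[-2, ], lab,
                           classifier = classifier_constant(0.7)),
               "no features for 1 edge")
})

test_that("a forest classifier on separable edges recovers c-edges in the LE-PIN", {
  pt <- generate_planted_pin(n_complexes = 10L, sizes = 2:5,
                             background_p = 0.05, seed = 21)
  lab <- pt$labels
  n_c <- sum(lab$label == "c-edge"); n_nc <- sum(lab$label == "nc-edge")
  sim <- generate_edge_feature_data(n_c = n_c, n_nc = n_nc, separation = 8,
                                    seed = 22)
  feats <- cbind(rbind(lab[lab$label == "c-edge", c("u", "v")],
                       lab[lab$label == "nc-edge", c("u", "v")]),
                 sim$features)
  fit <- build_lepin(pt$pin, feats, lab,
                     classifier = classifier_ranger(num.trees = 100L, seed = 5L))
  w <- fit$pin$edges$weight[fit$label == "c-edge"]
  expect_gte(mean(w > 0.5), 0.9)
})
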