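#' Label network edges as within-complex or outside-complex
#'
#' An edge is a *c-edge* when both endpoints co-occur in at least one gold
#' standard complex; an *nc-edge* when both endpoints belong to the gold
#' standard protein universe (appear in some complex) but never co-occur in
#' any single complex; otherwise *unlabeled* (at least one endpoint outside
#' the universe). These labels are the supervised classes for edge
#' weighting.
#'
#' @param pin a [weighted_pin()]
#' @param gold a [complex_set()] of reference complexes (each with >= 2
#'   members)
#' @return data frame `u`, `v`, `label` with `label` in
#'   `c("c-edge", "nc-edge", "unlabeled")`, one row per network edge.
#' @export
label_edges <- function(pin, gold) {
  stopifnot(inherits(pin, "weighted_pin"), inherits(gold, "complex_set"))
  universe <- unique(unlist(gold$members))
  co_keys <- unique(unlist(lapply(gold$members, function(m) {
    if (length(m) < 2L) return(character())
    idx <- utils::combn(sort(m), 2L)
    pin_pair_key(idx[1L, ], idx[2L, ])
  })))
  e <- pin$edges
  lab <- rep("unlabeled", nrow(e))
  in_univ <- e$u %in% universe & e$v %in% universe
  key <- pin_pair_key(e$u, e$v)
  lab[in_univ] <- "nc-edge"
  lab[in_univ & key %in% co_keys] <- "c-edge"
  data.frame(u = e$u, v = e$v, label = lab, stringsAsFactors = FALSE)
}

#' Classifier contracts
#'
#' The edge classifier is pluggable: any object of class `edge_classifier`
#' with a `fit(features, labels)` behavior returning a fitted model and a
#' `predict_prob(model, features)` behavior returning the probability of the
#' c-edge class works. Probabilities must lie in `[0, 1]` and be
#' deterministic for a fixed seed.
#'
#' `classifier_ranger()` wraps a probability random forest (the default);
#' `classifier_glm()` a logistic regression; `classifier_constant()` returns
#' a fixed probability (useful in tests).
#'
#' @param num.trees number of trees for the forest
#' @param seed integer seed making the forest deterministic
#' @param ... extra arguments passed to [ranger::ranger()]
#' @return an `edge_classifier` object.
#' @export
classifier_ranger <- function(num.trees = 300L, seed = 1L, ...) {
  extra <- list(...)
  structure(list(
    fit = function(features, labels) {
      d <- as.data.frame(features)
      d$.label <- factor(labels, levels = c("c-edge", "nc-edge"))
      do.call(ranger::ranger, c(list(
        formula = .label ~ ., data = d, probability = TRUE,
        num.trees = num.trees, seed = seed, num.threads = 1L), extra))
    },
    predict_prob = function(model, features) {
      p <- stats::predict(model, data = as.data.frame(features))$predictions
      as.numeric(p[, "c-edge"])
    },
    label = sprintf("random forest (%d trees)", num.trees)
  ), class = "edge_classifier")
}

#' @rdname classifier_ranger
#' @export
classifier_glm <- function() {
  structure(list(
    fit = function(features, labels) {
      d <- as.data.frame(features)
      d$.label <- as.integer(labels == "c-edge")
      suppressWarnings(stats::glm(.label ~ ., data = d,
                                  family = stats::binomial()))
    },
    predict_prob = function(model, features) {
      as.numeric(stats::predict(model, newdata = as.data.frame(features),
                                type = "response"))
    },
    label = "logistic regression"
  ), class = "edge_classifier")
}

#' @rdname classifier_ranger
#' @param p fixed probability returned by `classifier_constant()`
#' @export
classifier_constant <- function(p = 0.5) {
  stopifnot(p >= 0, p <= 1)
  structure(list(
    fit = function(features, labels) list(p = p),
    predict_prob = function(model, features) rep(model$p, nrow(features)),
    label = sprintf("constant p=%.2f", p)
  ), class = "edge_classifier")
}

#' @export
print.edge_classifier <- function(x, ...) {
  cat("edge_classifier:", x$label, "\n")
  invisible(x)
}

#' Sub-sampled k-fold cross-validation for edge classification
#'
#' Class imbalance (many more nc-edges than c-edges) would dominate plain
#' cross-validation, so each training round is balanced by sub-sampling:
#' c-edges and nc-edges are split into `folds` subsets each; round `i` trains
#' on the nine (for `folds = 10`) held-in c-edge subsets plus an equal-size
#' random draw from the held-in nc-edge subsets (an exact 1:1 class balance),
#' and tests on all remaining edges. Each edge's canonical held-out
#' probability is taken from the round in which its own subset was held out,
#' so every edge is scored exactly once.
#'
#' @param features data frame or matrix of scaled numeric features (rows =
#'   edges)
#' @param labels character vector: `"c-edge"` / `"nc-edge"`
#' @param folds number of folds (default 10)
#' @param seed integer controlling fold assignment and sub-sampling
#' @param classifier an `edge_classifier` (default [classifier_ranger()])
#' @param prob_threshold probability above which a prediction counts as
#'   c-edge (default 0.5)
#' @return object of class `edge_cv`: `heldout_prob` (per input row), `fold`
#'   (per input row), `fold_confusion` (list of per-round confusion counts on
#'   the round's full test set), `train_sizes` (per-round class counts),
#'   `report` (aggregate [classification_metrics()] on the canonical held-out
#'   predictions).
#' @export
subsampled_cv <- function(features, labels, folds = 10L, seed = 1L,
                          classifier = classifier_ranger(seed = seed),
                          prob_threshold = 0.5) {
  stopifnot(inherits(classifier, "edge_classifier"), folds >= 2L)
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("c-edge", "nc-edge")))
  idx_c <- which(labels == "c-edge")
  idx_nc <- which(labels == "nc-edge")
  if (length(idx_c) < folds || length(idx_nc) < folds) {
    stop(sprintf(
      "each class needs at least %d members for %d folds; use fewer folds",
      folds, folds))
  }
  features <- as.data.frame(features)
  fold <- integer(length(labels))
  heldout <- rep(NA_real_, length(labels))
  fold_confusion <- vector("list", folds)
  train_sizes <- matrix(0L, folds, 2L,
                        dimnames = list(NULL, c("c-edge", "nc-edge")))
  with_seed(seed, {
    fold[idx_c] <- sample(rep_len(seq_len(folds), length(idx_c)))
    fold[idx_nc] <- sample(rep_len(seq_len(folds), length(idx_nc)))
    for (i in seq_len(folds)) {
      train_c <- idx_c[fold[idx_c] != i]
      pool_nc <- idx_nc[fold[idx_nc] != i]
      train_nc <- sample(pool_nc, min(length(train_c), length(pool_nc)))
      train <- c(train_c, train_nc)
      test <- setdiff(seq_along(labels), train)
      model <- classifier$fit(features[train, , drop = FALSE], labels[train])
      p_test <- classifier$predict_prob(model,
                                        features[test, , drop = FALSE])
      pred <- ifelse(p_test > prob_threshold, "c-edge", "nc-edge")
      fold_confusion[[i]] <- confusion_counts(labels[test], pred)
      own <- fold[test] == i
      heldout[test[own]] <- p_test[own]
      train_sizes[i, ] <- c(length(train_c), length(train_nc))
    }
  })
  pred_all <- ifelse(heldout > prob_threshold, "c-edge", "nc-edge")
  cc <- confusion_counts(labels, pred_all)
  report <- classification_metrics(cc, scores = heldout,
                                   truth = labels == "c-edge")
  structure(list(heldout_prob = heldout, fold = fold,
                 fold_confusion = fold_confusion,
                 train_sizes = train_sizes, report = report,
                 folds = folds, seed = seed),
            class = "edge_cv")
}

#' @export
print.edge_cv <- function(x, ...) {
  cat(sprintf("edge_cv: %d-fold sub-sampled cross-validation (seed %d)\n",
              x$folds, x$seed))
  cat(sprintf("  balanced training rounds: %s\n",
              if (all(x$train_sizes[, 1L] == x$train_sizes[, 2L]))
                "yes (1:1)" else "NO"))
  print(x$report)
  invisible(x)
}

confusion_counts <- function(truth, pred) {
  list(TP = sum(truth == "c-edge" & pred == "c-edge"),
       FP = sum(truth == "nc-edge" & pred == "c-edge"),
       TN = sum(truth == "nc-edge" & pred == "nc-edge"),
       FN = sum(truth == "c-edge" & pred == "nc-edge"))
}

#' Classification performance metrics
#'
#' Standard binary metrics with c-edges as the positive class: accuracy,
#' sensitivity, specificity, precision, F1, Matthews correlation coefficient
#' and (when ranking scores are supplied) the area under the ROC curve via
#' the rank-sum (Mann-Whitney) formulation. Degenerate denominators yield 0
#' with a warning (PRE when nothing is predicted positive; MCC when any
#' marginal is empty).
#'
#' @param cc list or vector with components `TP`, `FP`, `TN`, `FN`
#' @param scores optional numeric ranking scores (higher = more c-edge-like)
#' @param truth optional logical vector (`TRUE` = c-edge) matching `scores`
#' @return object of class `classification_report` with fields `ACC`, `SEN`,
#'   `SPE`, `PRE`, `F1`, `MCC`, `AUC` and the counts.
#' @export
classification_metrics <- function(cc, scores = NULL, truth = NULL) {
  tp <- as.numeric(cc[["TP"]]); fp <- as.numeric(cc[["FP"]])
  tn <- as.numeric(cc[["TN"]]); fn <- as.numeric(cc[["FN"]])
  if (any(c(tp, fp, tn, fn) < 0)) stop("confusion counts must be >= 0")
  total <- tp + fp + tn + fn
  if (total == 0) stop("all confusion counts are zero")
  acc <- (tp + tn) / total
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spe <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  if (tp + fp > 0) {
    pre <- tp / (tp + fp)
  } else {
    warning("no positive predictions; PRE set to 0")
    pre <- 0
  }
  f1 <- if (!is.na(sen) && sen + pre > 0) 2 * sen * pre / (sen + pre) else 0
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (mcc_den > 0) {
    mcc <- (tp * tn - fp * fn) / mcc_den
  } else {
    warning("degenerate confusion margin; MCC set to 0")
    mcc <- 0
  }
  auc <- NA_real_
  if (!is.null(scores) && !is.null(truth)) {
    auc <- rank_auc(scores, truth)
  }
  structure(list(ACC = acc, SEN = sen, SPE = spe, PRE = pre, F1 = f1,
                 MCC = mcc, AUC = auc,
                 counts = list(TP = tp, FP = fp, TN = tn, FN = fn)),
            class = "classification_report")
}

# Mann-Whitney AUC: P(score_pos > score_neg) + 0.5 P(tie)
rank_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  ok <- !is.na(scores) & !is.na(truth)
  scores <- scores[ok]; truth <- truth[ok]
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "  ACC %.3f  SEN %.3f  SPE %.3f  PRE %.3f  F1 %.3f  MCC %.3f  AUC %s\n",
    x$ACC, x$SEN, x$SPE, x$PRE, x$F1, x$MCC,
    if (is.na(x$AUC)) "-" else sprintf("%.3f", x$AUC)))
  invisible(x)
}

#' Weight every network edge with its predicted c-edge probability
#'
#' Fits the classifier on the labeled edges and replaces every edge weight in
#' the network with the predicted probability that the edge lies within a
#' complex, producing the LE-PIN that complex detection runs on. By default
#' labeled training edges also receive model predictions (uniform
#' treatment); set `pin_labels = TRUE` to pin them to 1 (c-edge) / 0
#' (nc-edge) instead.
#'
#' @param pin a [weighted_pin()]
#' @param features data frame with key columns `u`, `v` plus scaled numeric
#'   features covering every edge of `pin`
#' @param labels data frame from [label_edges()] (or columns `u`, `v`,
#'   `label`)
#' @param classifier an `edge_classifier` (default [classifier_ranger()])
#' @param pin_labels logical; pin training-edge weights to their labels
#' @return a list of class `lepin_fit`: `pin` (the reweighted network),
#'   `model` (the fitted classifier model), `classifier`, and `probability`
#'   (per-edge predicted probabilities, aligned with `pin$edges`).
#' @export
build_lepin <- function(pin, features, labels,
                        classifier = classifier_ranger(),
                        pin_labels = FALSE) {
  stopifnot(inherits(pin, "weighted_pin"),
            inherits(classifier, "edge_classifier"))
  fkey <- pin_pair_key(features$u, features$v)
  ekey <- pin_pair_key(pin$edges$u, pin$edges$v)
  idx <- match(ekey, fkey)
  if (anyNA(idx)) {
    missing <- pin$edges[is.na(idx), c("u", "v")]
    stop(sprintf("no features for %d edge(s), e.g. %s-%s",
                 nrow(missing), missing$u[1L], missing$v[1L]))
  }
  fcols <- setdiff(names(features), c("u", "v"))
  X <- features[idx, fcols, drop = FALSE]
  lkey <- pin_pair_key(labels$u, labels$v)
  lab <- labels$label[match(ekey, lkey)]
  lab[is.na(lab)] <- "unlabeled"
  train <- lab %in% c("c-edge", "nc-edge")
  if (!any(lab[train] == "c-edge") || !any(lab[train] == "nc-edge")) {
    stop("training edges must include both c-edges and nc-edges")
  }
  model <- classifier$fit(X[train, , drop = FALSE], lab[train])
  prob <- classifier$predict_prob(model, X)
  prob <- pmin(pmax(prob, 0), 1)
  if (pin_labels) {
    prob[lab == "c-edge"] <- 1
    prob[lab == "nc-edge"] <- 0
  }
  new_edges <- pin$edges
  new_edges$weight <- prob
  structure(list(pin = weighted_pin(new_edges, nodes = pin$nodes),
                 model = model, classifier = classifier,
                 probability = prob, label = lab),
            class = "lepin_fit")
}

#' @export
print.lepin_fit <- function(x, ...) {
  cat("lepin_fit:", x$classifier$label, "\n")
  cat(sprintf("  %d edges reweighted (%d c-edge, %d nc-edge, %d unlabeled)\n",
              length(x$probability), sum(x$label == "c-edge"),
              sum(x$label == "nc-edge"), sum(x$label == "unlabeled")))
  print(x$pin)
  invisible(x)
}
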