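#' Matching rate between a predicted and a reference complex
#'
#' The neighborhood-affinity overlap statistic
#' \deqn{Rate_{match} = |P \cap G|^2 / (|P| \cdot |G|),}
#' which is 1 exactly when the two member sets are equal and 0 when they are
#' disjoint. A rate of at least 0.2 is the conventional bar for a
#' "successful" match.
#'
#' @param pc,gc non-empty character vectors (member sets)
#' @return a value in `[0, 1]`.
#' @export
matching_rate <- function(pc, gc) {
  pc <- unique(as.character(pc)); gc <- unique(as.character(gc))
  if (!length(pc) || !length(gc)) stop("member sets must be non-empty")
  length(intersect(pc, gc))^2 / (length(pc) * length(gc))
}

# |P∩G| and rate matrices (gold rows x pred cols)
overlap_matrices <- function(pred, gold) {
  t_mat <- matrix(0, length(gold$members), length(pred$members))
  for (g in seq_along(gold$members)) {
    for (p in seq_along(pred$members)) {
      t_mat[g, p] <- length(intersect(gold$members[[g]], pred$members[[p]]))
    }
  }
  sizes_g <- lengths(gold$members)
  sizes_p <- lengths(pred$members)
  rate <- t_mat^2 / outer(sizes_g, sizes_p)
  list(t = t_mat, rate = rate, n_g = sizes_g, n_p = sizes_p)
}

#' Recall, Precision and F-measure of a predicted complex set
#'
#' A gold complex is recovered when some predicted complex matches it at
#' `Rate_match >= threshold`, and a predicted complex is correct when it
#' matches some gold complex. Recall is the fraction of gold complexes
#' recovered, Precision the fraction of predictions that are correct, and
#' the F-measure their harmonic mean.
#'
#' @param pred,gold [complex_set()] objects
#' @param threshold match threshold on [matching_rate()] (default 0.2; use 1
#'   for exact-match counting)
#' @return named numeric vector `recall`, `precision`, `f_measure`.
#' @export
precision_recall_f <- function(pred, gold, threshold = 0.2) {
  stopifnot(inherits(gold, "complex_set"), length(gold) > 0L)
  if (length(pred) == 0L) {
    warning("empty prediction set; Precision set to 0")
    return(c(recall = 0, precision = 0, f_measure = 0))
  }
  om <- overlap_matrices(pred, gold)
  matched <- om$rate >= threshold
  recall <- mean(apply(matched, 1L, any))
  precision <- mean(apply(matched, 2L, any))
  f <- if (recall + precision > 0)
    2 * recall * precision / (recall + precision) else 0
  c(recall = recall, precision = precision, f_measure = f)
}

#' Maximum matching ratio (MMR)
#'
#' Builds the bipartite graph between gold and predicted complexes with
#' matching rates as edge weights (positive rates only), solves the
#' maximum-weight matching exactly, and normalizes the total matched weight
#' by the number of gold complexes. Unlike Recall/Precision, MMR charges each
#' predicted complex to at most one gold complex, penalizing fragmented
#' predictions.
#'
#' @param pred,gold [complex_set()] objects
#' @return a value in `[0, 1]`.
#' @export
mmr <- function(pred, gold) {
  stopifnot(length(gold) > 0L)
  if (length(pred) == 0L) return(0)
  om <- overlap_matrices(pred, gold)
  idx <- which(om$rate > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0)
  el <- data.frame(from = paste0("g", idx[, 1L]),
                   to = paste0("p", idx[, 2L]),
                   weight = om$rate[idx])
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  igraph::V(g)$type <- grepl("^p", igraph::V(g)$name)
  # integer-scaled weights keep the matching solver exact
  m <- igraph::max_bipartite_match(g, weights = round(el$weight * 1e9))
  mates <- m$matching
  matched_from <- names(mates)[!is.na(mates) & grepl("^g", names(mates))]
  total <- sum(vapply(matched_from, function(gn) {
    gi <- as.integer(sub("^g", "", gn))
    pi <- as.integer(sub("^p", "", mates[[gn]]))
    om$rate[gi, pi]
  }, 0))
  total / length(gold)
}

#' Geometric accuracy (GACC)
#'
#' Clustering-wise sensitivity `SN` credits each gold complex with its best
#' per-prediction member coverage, `\Sigma_g max_p t_{g,p} / \Sigma_g N_g`;
#' positive predictive value `PPV` credits each prediction with its best
#' gold assignment relative to all its gold overlaps,
#' `\Sigma_p max_g t_{g,p} / \Sigma_p \Sigma_g t_{g,p}`; GACC is their
#' geometric mean.
#'
#' @param pred,gold [complex_set()] objects
#' @return named numeric vector `sn`, `ppv`, `gacc`.
#' @export
gacc <- function(pred, gold) {
  stopifnot(length(gold) > 0L)
  if (length(pred) == 0L) return(c(sn = 0, ppv = 0, gacc = 0))
  om <- overlap_matrices(pred, gold)
  sn <- sum(apply(om$t, 1L, max)) / sum(om$n_g)
  denom <- sum(om$t)
  if (denom == 0) {
    warning("no shared proteins between predictions and gold; PPV set to 0")
    ppv <- 0
  } else {
    ppv <- sum(apply(om$t, 2L, max)) / denom
  }
  c(sn = sn, ppv = ppv, gacc = sqrt(sn * ppv))
}

#' Evaluate a predicted complex set against a gold standard
#'
#' Computes the five standard complex-prediction metrics — Recall, Precision,
#' F-measure, [mmr()] and [gacc()] — plus successful-match (rate >= the
#' threshold) and exact-match (rate = 1) counts.
#'
#' @inheritParams precision_recall_f
#' @return object of class `complex_evaluation`.
#' @export
evaluate_complexes <- function(pred, gold, threshold = 0.2) {
  prf <- precision_recall_f(pred, gold, threshold)
  ga <- gacc(pred, gold)
  n_success <- 0L; n_exact <- 0L
  rate <- NULL
  if (length(pred) > 0L) {
    rate <- overlap_matrices(pred, gold)$rate
    n_success <- sum(apply(rate, 2L, max) >= threshold)
    n_exact <- sum(apply(rate, 2L, function(r) any(r == 1)))
  }
  structure(list(recall = unname(prf["recall"]),
                 precision = unname(prf["precision"]),
                 f_measure = unname(prf["f_measure"]),
                 mmr = mmr(pred, gold),
                 sn = unname(ga["sn"]), ppv = unname(ga["ppv"]),
                 gacc = unname(ga["gacc"]),
                 n_pred = length(pred), n_gold = length(gold),
                 n_successful = n_success, n_exact = n_exact,
                 threshold = threshold, rate_matrix = rate),
            class = "complex_evaluation")
}

#' @export
print.complex_evaluation <- function(x, ...) {
  cat(sprintf("complex_evaluation: %d predicted vs %d gold (threshold %.2f)\n",
              x$n_pred, x$n_gold, x$threshold))
  cat(sprintf("  Recall %.3f  Precision %.3f  F-measure %.3f\n",
              x$recall, x$precision, x$f_measure))
  cat(sprintf("  MMR %.3f  GACC %.3f (SN %.3f, PPV %.3f)\n",
              x$mmr, x$gacc, x$sn, x$ppv))
  cat(sprintf("  successful matches %d, exact matches %d\n",
              x$n_successful, x$n_exact))
  invisible(x)
}
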