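#' Hypergeometric interaction probability (weighted matrix model)
#'
#' Upper-tail hypergeometric probability of observing at least `k`
#' interactions between two proteins, given that protein A takes part in `n`
#' of the network's `N` interactions and protein B in `m`:
#' \deqn{p(\#int \ge k \mid n, m, N) =
#'   \sum_{i=k}^{\min(n,m)} \binom{n}{i}\binom{N-n}{m-i} / \binom{N}{m}.}
#' A small p-value means the pair co-occurs more often than chance, flagging
#' a likely missed (false-negative) physical interaction — the rationale of
#' the weighted matrix model for spoke-model AP-MS data. The tail sum is
#' evaluated in log space (via the hypergeometric CDF), so genome-scale
#' counts do not overflow.
#'
#' @param k observed interaction count for the pair (non-negative)
#' @param n,m total interaction counts of the two proteins
#' @param N total number of interactions in the network
#' @return probability in `[0, 1]`; vectorized over its arguments.
#' @examples
#' wmm_pvalue(1, 2, 2, 4)  # 5/6
#' @export
wmm_pvalue <- function(k, n, m, N) {
  args <- cbind(k = k, n = n, m = m, N = N)  # recycles
  k <- args[, "k"]; n <- args[, "n"]; m <- args[, "m"]; N <- args[, "N"]
  if (any(args < 0) || any(args != floor(args))) {
    stop("k, n, m, N must be non-negative integers")
  }
  if (any(n > N) || any(m > N)) stop("n and m must not exceed N")
  if (any(k > pmin(n, m))) stop("k must not exceed min(n, m)")
  p <- stats::phyper(k - 1, n, N - n, m, lower.tail = FALSE)
  unname(pmin(pmax(p, 0), 1))
}

#' Recover candidate interactions from co-occurrence evidence
#'
#' Scores every evidence pair with [wmm_pvalue()], drops pairs already present
#' as edges of `pin`, and keeps those with p-value strictly below
#' `p_threshold`, sorted ascending (most significant first).
#'
#' @param evidence data frame with columns `u`, `v`, `k`, `n`, `m`, `N`
#'   (per-pair counts; `N` may be a single repeated value)
#' @param p_threshold keep pairs with p-value strictly below this (in (0, 1])
#' @param pin optional [weighted_pin()]; its edges are excluded
#' @return data frame `u`, `v`, `score` (the p-value), `rank`, ascending by
#'   score.
#' @export
wmm_augment <- function(evidence, p_threshold, pin = NULL) {
  stopifnot(p_threshold > 0, p_threshold <= 1)
  if (is.null(evidence) || nrow(evidence) == 0L) {
    return(data.frame(u = character(), v = character(),
                      score = numeric(), rank = integer()))
  }
  p <- wmm_pvalue(evidence$k, evidence$n, evidence$m, evidence$N)
  out <- data.frame(u = as.character(evidence$u),
                    v = as.character(evidence$v),
                    score = p, stringsAsFactors = FALSE)
  if (!is.null(pin)) out <- out[!pin_has_edge(pin, out$u, out$v), , drop = FALSE]
  out <- out[out$score < p_threshold, , drop = FALSE]
  out <- out[order(out$score, out$u, out$v), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Calibrate the WMM acceptance threshold against a reference network
#'
#' The acceptance threshold for predicted interactions is set to the largest
#' p-value among candidate pairs that are real edges of an independent
#' reference network: predictions at least as confident as the weakest
#' corroborated one are accepted. When no candidate matches the reference, a
#' configured fallback is returned with a warning.
#'
#' @param candidates data frame with columns `u`, `v`, `score` (p-values)
#' @param reference a [weighted_pin()] of trusted interactions
#' @param fallback threshold used when no candidate matches (default 0.05)
#' @return a probability threshold.
#' @export
calibrate_wmm_threshold <- function(candidates, reference, fallback = 0.05) {
  stopifnot(inherits(reference, "weighted_pin"))
  if (pin_edge_count(reference) == 0L) stop("reference network has no edges")
  hit <- pin_has_edge(reference, candidates$u, candidates$v)
  if (!any(hit)) {
    warning(sprintf(
      "no candidate pair found in the reference network; using fallback %.3g",
      fallback))
    return(fallback)
  }
  max(candidates$score[hit])
}

#' Length-3 path (L3) link prediction
#'
#' Scores every non-adjacent pair (X, Y) by the degree-normalized number of
#' paths X-U-V-Y of length three:
#' \deqn{s(X,Y) = \sum_{U,V} A_{XU} A_{UV} A_{VY} / \sqrt{k_U k_V}}
#' on the unweighted skeleton. The motivation is interface complementarity:
#' if X and U bind, and V resembles X's interface by sharing U-like partners,
#' then Y binding V likely also binds X. High-scoring non-edges are candidate
#' missed interactions.
#'
#' @param pin a [weighted_pin()]
#' @param top_k optional; keep only the `top_k` highest-scoring pairs
#'   (the standard operating point is 6000 on a full interactome)
#' @param normalization `"degree"` (default, divide each path by
#'   `sqrt(deg(U) * deg(V))`) or `"none"` (raw path counts)
#' @return data frame `u`, `v`, `score`, `rank`, descending by score.
#' @export
l3_scores <- function(pin, top_k = NULL,
                      normalization = c("degree", "none")) {
  stopifnot(inherits(pin, "weighted_pin"))
  normalization <- match.arg(normalization)
  deg <- pin_degree(pin)
  acc <- new.env(hash = TRUE, parent = emptyenv())
  edges <- pin$edges
  add_paths <- function(U, V) {
    # paths X - U - V - Y for all X in N(U)\{V}, Y in N(V)\{U}
    Xs <- setdiff(names(pin$adj[[U]]), V)
    Ys <- setdiff(names(pin$adj[[V]]), U)
    if (!length(Xs) || !length(Ys)) return(invisible())
    contrib <- if (normalization == "degree") 1 / sqrt(deg[[U]] * deg[[V]]) else 1
    for (X in Xs) {
      for (Y in Ys) {
        if (X == Y) next
        key <- pin_pair_key(X, Y)
        acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + contrib
      }
    }
  }
  # one orientation per middle edge suffices: X and Y range independently
  # over the two endpoints' neighborhoods, so every path X-U-V-Y is
  # enumerated exactly once
  for (i in seq_len(nrow(edges))) {
    add_paths(edges$u[i], edges$v[i])
  }
  keys <- ls(acc)
  if (!length(keys)) {
    return(data.frame(u = character(), v = character(),
                      score = numeric(), rank = integer()))
  }
  parts <- strsplit(keys, "\t", fixed = TRUE)
  out <- data.frame(u = vapply(parts, `[`, "", 1L),
                    v = vapply(parts, `[`, "", 2L),
                    score = vapply(keys, function(k) acc[[k]], 0),
                    stringsAsFactors = FALSE)
  out <- out[!pin_has_edge(pin, out$u, out$v), , drop = FALSE]
  out <- out[order(-out$score, out$u, out$v), , drop = FALSE]
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Merge networks and predicted interactions into one integrated network
#'
#' Node set is the union; on conflicting edge weights the maximum wins.
#' Predicted candidate edges enter with a provisional weight of 1: the edge
#' classification step reweights every edge afterwards, so detection never
#' runs on provisional weights in the intended pipeline order.
#'
#' @param pins list of [weighted_pin()] objects
#' @param extra_edges optional data frame `u`, `v` of predicted interactions
#' @param predicted_weight provisional weight for predicted edges (default 1)
#' @return a [weighted_pin()]
#' @export
integrate_networks <- function(pins, extra_edges = NULL, predicted_weight = 1.0) {
  if (inherits(pins, "weighted_pin")) pins <- list(pins)
  stopifnot(all(vapply(pins, inherits, TRUE, "weighted_pin")))
  edge_frames <- lapply(pins, function(p) p$edges)
  if (!is.null(extra_edges) && nrow(extra_edges) > 0L) {
    edge_frames <- c(edge_frames, list(
      data.frame(u = as.character(extra_edges$u),
                 v = as.character(extra_edges$v),
                 weight = predicted_weight, stringsAsFactors = FALSE)))
  }
  all_edges <- do.call(rbind, edge_frames)
  all_nodes <- unique(unlist(lapply(pins, `[[`, "nodes")))
  weighted_pin(all_edges, nodes = all_nodes)
}

#' Edge overlap ratio between two networks
#'
#' Fraction of the edges of `pin_a` also present in `pin_b`
#' (`|E_a ∩ E_b| / |E_a|`); asymmetric.
#'
#' @param pin_a,pin_b [weighted_pin()] objects
#' @return a proportion in `[0, 1]`.
#' @export
edge_overlap_ratio <- function(pin_a, pin_b) {
  if (pin_edge_count(pin_a) == 0L) return(NA_real_)
  mean(pin_has_edge(pin_b, pin_a$edges$u, pin_a$edges$v))
}
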