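#' Detection parameters
#'
#' @param c_edge_threshold edge weight strictly above which an edge counts as
#'   a c-edge during search (default 0.5)
#' @param high_shell_threshold k-shell value at or above which a seed counts
#'   as high-load for scheduling (default 20)
#' @param min_size smallest complex size emitted (default 2; singletons are
#'   never complexes)
#' @param shrink_rule how the expectation-edges criterion applies to removal
#'   candidates: `"violate"` (default: a node is removable when its actual
#'   edge count into the remaining subgraph falls short of the expected
#'   count — the under-connected nodes are the ones trimmed), `"satisfy"`
#'   (the opposite reading), or `"ignore"` (score improvement alone decides)
#' @return list of class `detection_params`.
#' @export
detection_params <- function(c_edge_threshold = 0.5,
                             high_shell_threshold = 20L,
                             min_size = 2L,
                             shrink_rule = c("violate", "satisfy", "ignore")) {
  stopifnot(c_edge_threshold > 0, c_edge_threshold < 1, min_size >= 1L)
  structure(list(c_edge_threshold = c_edge_threshold,
                 high_shell_threshold = as.integer(high_shell_threshold),
                 min_size = as.integer(min_size),
                 shrink_rule = match.arg(shrink_rule)),
            class = "detection_params")
}

#' Density, modularity and cohesion score of a candidate complex
#'
#' For a node set `S` in a weighted network, density `D` is the mean internal
#' edge weight over all `|S|(|S|-1)/2` possible pairs; modularity `M` is the
#' fraction of incident weight that stays internal,
#' `d_in / (d_in + d_out)` (1 when no weight leaves the set); and the
#' cohesion score combines them as
#' \deqn{F = \frac{1}{1/D + 1/M} + \frac{D + M}{2},}
#' the harmonic-mean term halved plus the arithmetic mean, ranging over
#' `[0, 1.5]` with the maximum attained exactly by an isolated clique of
#' weight-1 edges. Singletons and sets with no internal weight score 0.
#'
#' @param pin a [weighted_pin()]
#' @param members character vector of node ids (subset of the network nodes)
#' @return named numeric vector `D`, `M`, `F`, `d_in`, `d_out`.
#' @examples
#' pin <- weighted_pin(data.frame(u = c("a", "b", "a", "c"),
#'                                v = c("b", "c", "c", "d"),
#'                                weight = c(0.9, 0.9, 0.8, 0.3)))
#' complex_score(pin, c("a", "b", "c"))
#' @export
complex_score <- function(pin, members) {
  stopifnot(inherits(pin, "weighted_pin"))
  members <- unique(as.character(members))
  if (!all(members %in% pin$nodes)) {
    stop(sprintf("member(s) not in network: %s",
                 paste(setdiff(members, pin$nodes), collapse = ", ")))
  }
  score_members(pin, members)
}

# internal scorer without validation (hot path)
score_members <- function(pin, members) {
  n <- length(members)
  if (n < 2L) {
    return(c(D = 0, M = 0, F = 0, d_in = 0, d_out = 0))
  }
  inside <- stats::setNames(rep(TRUE, n), members)
  d_in2 <- 0; d_out <- 0
  for (m in members) {
    w <- pin$adj[[m]]
    if (!length(w)) next
    is_in <- !is.na(match(names(w), members))
    d_in2 <- d_in2 + sum(w[is_in])
    d_out <- d_out + sum(w[!is_in])
  }
  d_in <- d_in2 / 2  # internal edges seen from both endpoints
  if (d_in == 0) {
    return(c(D = 0, M = 0, F = 0, d_in = 0, d_out = d_out))
  }
  D <- d_in / (n * (n - 1) / 2)
  M <- d_in / (d_in + d_out)
  F <- 1 / (1 / D + 1 / M) + (D + M) / 2
  c(D = D, M = M, F = F, d_in = d_in, d_out = d_out)
}

# expectation-edges criterion for a node against a subgraph:
# Actually_edges = |N(ns) ∩ S| must be >= Expectation_edges = F(S) * |S|
meets_expectation <- function(pin, node, members, f_members) {
  actually <- sum(!is.na(match(names(pin$adj[[node]]), members)))
  actually >= f_members * length(members)
}

#' Grow a candidate complex by greedy node addition
#'
#' Repeatedly adds one neighbor of the current node set, chosen by four
#' criteria: (1) the node is connected to the set by at least one edge with
#' weight strictly above the c-edge threshold; (2) its actual edge count into
#' the set is at least the expected count `F * |S|` for the current set;
#' (3) the cohesion score strictly increases after adding it; (4) among
#' nodes passing 1-3, the one maximizing the new score wins (ties broken by
#' ascending node id). Growth stops when no neighbor qualifies.
#'
#' @param pin a [weighted_pin()] (an LE-PIN: weights are c-edge
#'   probabilities)
#' @param members current node set (character vector)
#' @param params a [detection_params()]
#' @return list `members`, `score` (the `c(D, M, F, d_in, d_out)` vector).
#' @export
inflate <- function(pin, members, params = detection_params()) {
  members <- unique(as.character(members))
  sc <- score_members(pin, members)
  repeat {
    pool <- setdiff(unique(unlist(lapply(members,
                                         function(m) names(pin$adj[[m]])))),
                    members)
    if (!length(pool)) break
    # criterion 1: a strong edge into the set
    strong <- vapply(pool, function(ns) {
      w <- pin$adj[[ns]]
      any(w[!is.na(match(names(w), members))] > params$c_edge_threshold)
    }, TRUE)
    pool <- pool[strong]
    if (!length(pool)) break
    # criterion 2: expectation-edges on the current subgraph
    pool <- pool[vapply(pool, meets_expectation, TRUE,
                        pin = pin, members = members,
                        f_members = sc[["F"]])]
    if (!length(pool)) break
    # criterion 3: strict score increase
    cand_scores <- vapply(pool, function(ns)
      score_members(pin, c(members, ns))[["F"]], 0)
    ok <- cand_scores > sc[["F"]]
    if (!any(ok)) break
    pool <- pool[ok]; cand_scores <- cand_scores[ok]
    # criterion 4: maximize F, ties by ascending node id
    best <- pool[order(-cand_scores, pool)][1L]
    members <- sort(c(members, best))
    sc <- score_members(pin, members)
  }
  list(members = members, score = sc)
}

#' Trim a candidate complex by greedy boundary-node removal
#'
#' Repeatedly removes one boundary node (a member with at least one edge to
#' a non-member): the removal must strictly increase the cohesion score, the
#' removed node must be under-connected — fail the expectation-edges
#' criterion against the remaining subgraph (see [detection_params()]
#' `shrink_rule` for the alternative readings) — and among
#' qualifying nodes the one maximizing the post-removal score is removed
#' (ties by ascending node id). Stops when the score is stable.
#'
#' @inheritParams inflate
#' @return list `members`, `score`.
#' @export
shrink <- function(pin, members, params = detection_params()) {
  members <- unique(as.character(members))
  sc <- score_members(pin, members)
  repeat {
    if (length(members) < 2L) break
    boundary <- members[vapply(members, function(m) {
      w <- pin$adj[[m]]
      any(is.na(match(names(w), members)))
    }, TRUE)]
    if (!length(boundary)) break
    cand <- lapply(boundary, function(ns) {
      rest <- setdiff(members, ns)
      s <- score_members(pin, rest)
      ok <- s[["F"]] > sc[["F"]]
      if (ok && params$shrink_rule != "ignore") {
        meets <- meets_expectation(pin, ns, rest, s[["F"]])
        ok <- if (params$shrink_rule == "satisfy") meets else !meets
      }
      list(node = ns, score = s, ok = ok)
    })
    cand <- Filter(function(x) x$ok, cand)
    if (!length(cand)) break
    fs <- vapply(cand, function(x) x$score[["F"]], 0)
    ids <- vapply(cand, function(x) x$node, "")
    pick <- order(-fs, ids)[1L]
    members <- setdiff(members, ids[pick])
    sc <- cand[[pick]]$score
  }
  list(members = sort(members), score = sc)
}

grow_from_seed <- function(pin, seed, params) {
  members <- seed
  f <- 0; f_old <- -1
  while (f > f_old) {
    f_old <- f
    res <- inflate(pin, members, params)
    res <- shrink(pin, res$members, params)
    members <- res$members
    f <- res$score[["F"]]
  }
  list(members = members, F = f)
}

#' Detect protein complexes in a weighted network
#'
#' The core search: every node with degree at least 1 seeds a candidate, in
#' descending k-shell order; each candidate alternates [inflate()] and
#' [shrink()] until its cohesion score stops improving; candidates below
#' `min_size` are dropped and exact duplicates removed. Seeds are independent,
#' so the search parallelizes over `workers` without changing the result:
#' high-shell seeds are scheduled one or two per chunk and low-shell seeds in
#' larger batches, and the merged output is canonically sorted (descending
#' score, then lexicographic member list).
#'
#' @param pin a [weighted_pin()] whose weights are c-edge probabilities
#'   (an LE-PIN)
#' @param params a [detection_params()]
#' @param workers number of parallel workers (forked processes; 1 = serial)
#' @return a [complex_set()] with per-complex cohesion scores.
#' @export
detect_complexes <- function(pin, params = detection_params(), workers = 1L) {
  stopifnot(inherits(pin, "weighted_pin"))
  sq <- build_seed_queue(pin, params$high_shell_threshold)
  deg <- pin_degree(pin)
  seeds <- sq$node[deg[sq$node] >= 1L]
  if (!length(seeds)) return(complex_set())
  run <- function(seed_batch) lapply(seed_batch, grow_from_seed,
                                     pin = pin, params = params)
  if (workers > 1L && .Platform$OS.type == "unix") {
    high <- sq$high[match(seeds, sq$node)]
    chunks <- c(split_chunks(seeds[high], 2L),
                split_chunks(seeds[!high], max(8L, ceiling(sum(!high) / (4L * workers)))))
    res <- unlist(parallel::mclapply(chunks, run, mc.cores = workers),
                  recursive = FALSE)
  } else {
    res <- run(seeds)
  }
  keep <- vapply(res, function(x) length(x$members) >= params$min_size, TRUE)
  res <- res[keep]
  if (!length(res)) return(complex_set())
  cs <- complex_set(lapply(res, `[[`, "members"),
                    vapply(res, `[[`, 0, "F"))
  deduplicate_complexes(cs)
}

split_chunks <- function(x, size) {
  if (!length(x)) return(list())
  split(x, ceiling(seq_along(x) / size))
}

#' Remove duplicate complexes and canonically sort
#'
#' Complexes whose matching rate is exactly 1 — i.e. identical member sets —
#' are collapsed to a single copy. Processing (and output) order is
#' descending score, ties broken by the lexicographic member list, which
#' makes the result independent of search scheduling. Idempotent.
#'
#' @param cs a [complex_set()]
#' @return a [complex_set()] without duplicates.
#' @export
deduplicate_complexes <- function(cs) {
  stopifnot(inherits(cs, "complex_set"))
  if (!length(cs$members)) return(cs)
  key <- vapply(cs$members, paste, "", collapse = "\t")
  ord <- order(-replace(cs$score, is.na(cs$score), -Inf), key)
  keep <- ord[!duplicated(key[ord])]
  complex_set(cs$members[keep], cs$score[keep])
}
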