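# Fixtures and independent brute-force oracles shared across test files.

# the 4-node worked instance: a-b .9, b-c .9, a-c .8, c-d .3
worked_pin <- function() {
  weighted_pin(data.frame(u = c("a", "b", "a", "c"),
                          v = c("b", "c", "c", "d"),
                          weight = c(0.9, 0.9, 0.8, 0.3)))
}

# k-shell by literal iterative peeling: repeatedly delete min-degree nodes
bf_k_shell <- function(edges, nodes) {
  adj <- lapply(stats::setNames(nodes, nodes), function(n) {
    c(edges$v[edges$u == n], edges$u[edges$v == n])
  })
  shell <- stats::setNames(rep(0L, length(nodes)), nodes)
  active <- nodes
  k <- 0L
  while (length(active)) {
    deg <- vapply(active, function(n) sum(adj[[n]] %in% active), 0L)
    if (all(deg > k)) { k <- k + 1L; next }
    peel <- active[deg <= k]
    shell[peel] <- k
    active <- setdiff(active, peel)
  }
  shell
}

# hypergeometric upper tail by exhaustive enumeration of all C(N, m) draws:
# N interactions, the first n belong to protein A; draw the m of protein B
bf_hyper_tail <- function(k, n, m, N) {
  if (m == 0L) return(as.numeric(k <= 0))
  draws <- utils::combn(N, m)
  mean(colSums(draws <= n) >= k)
}

# maximum-weight bipartite matching by recursive enumeration (<= ~6 per side)
bf_max_matching <- function(w) {
  n_g <- nrow(w); n_p <- ncol(w)
  rec <- function(g, used) {
    if (g > n_g) return(0)
    best <- rec(g + 1L, used)  # leave gold complex g unmatched
    for (p in seq_len(n_p)) {
      if (!used[p] && w[g, p] > 0) {
        used2 <- used; used2[p] <- TRUE
        best <- max(best, w[g, p] + rec(g + 1L, used2))
      }
    }
    best
  }
  rec(1L, rep(FALSE, n_p))
}

bf_mmr <- function(pred, gold) {
  w <- matrix(0, length(gold), length(pred))
  for (g in seq_along(gold$members))
    for (p in seq_along(pred$members))
      w[g, p] <- matching_rate(pred$members[[p]], gold$members[[g]])
  bf_max_matching(w) / length(gold)
}

# random complex set over a small protein universe
random_complex_set <- function(n, universe, max_size = 5L) {
  complex_set(lapply(seq_len(n), function(i) {
    sample(universe, sample(2:max_size, 1L))
  }))
}

# Erdos-Renyi weighted_pin on n nodes
random_pin <- function(n, p_edge = 0.2, weights = TRUE) {
  nodes <- sprintf("n%02d", seq_len(n))
  pr <- utils::combn(nodes, 2L)
  keep <- stats::runif(ncol(pr)) < p_edge
  if (!any(keep)) return(weighted_pin(nodes = nodes))
  weighted_pin(data.frame(u = pr[1L, keep], v = pr[2L, keep],
                          weight = if (weights) stats::runif(sum(keep)) else 1),
               nodes = nodes)
}
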