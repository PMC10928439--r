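#' Construct a weighted protein interaction network
#'
#' A `weighted_pin` is an undirected simple graph of protein nodes with edge
#' weights in `[0, 1]`. It is the central container of the package: raw
#' interactomes, augmented networks and classifier-weighted networks (LE-PINs)
#' are all `weighted_pin` objects. Self-loop rows are dropped with a warning
#' and duplicate rows for the same unordered pair are collapsed keeping the
#' maximum weight, so the strongest evidence for an interaction wins.
#'
#' @param edges data frame with columns `u`, `v` and optionally `weight`
#'   (missing weights default to 1). Additional columns are ignored.
#' @param nodes optional character vector of node identifiers to include even
#'   when isolated (no incident edge).
#' @return An object of class `weighted_pin` with components `nodes` (sorted
#'   character vector), `edges` (data frame `u`, `v`, `weight` with `u < v`)
#'   and `adj` (adjacency list of named weight vectors).
#' @examples
#' pin <- weighted_pin(data.frame(u = c("a", "b"), v = c("b", "c"),
#'                                weight = c(0.9, 0.4)))
#' pin_edge_count(pin)
#' @export
weighted_pin <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(u = character(), v = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("u", "v") %in% names(edges))) {
      names(edges)[1:2] <- c("u", "v")
    }
    if (!"weight" %in% names(edges)) edges$weight <- 1.0
    edges <- edges[, c("u", "v", "weight")]
    edges$u <- as.character(edges$u)
    edges$v <- as.character(edges$v)
    edges$weight <- as.numeric(edges$weight)
    if (anyNA(edges$weight) || any(edges$weight < 0) || any(edges$weight > 1)) {
      stop("edge weights must lie in [0, 1]")
    }
    # endpoints stay in the node set even when their only row is dropped
    nodes <- c(nodes, edges$u, edges$v)
    loops <- edges$u == edges$v
    if (any(loops)) {
      warning(sprintf("dropping %d self-loop edge(s)", sum(loops)))
      edges <- edges[!loops, , drop = FALSE]
    }
    if (nrow(edges) > 0L) {
      swap <- edges$u > edges$v
      tmp <- edges$u[swap]
      edges$u[swap] <- edges$v[swap]
      edges$v[swap] <- tmp
      key <- paste(edges$u, edges$v, sep = "\t")
      if (anyDuplicated(key)) {
        message(sprintf("collapsing %d duplicate edge row(s), keeping max weight",
                        sum(duplicated(key))))
        w <- tapply(edges$weight, key, max)
        parts <- strsplit(names(w), "\t", fixed = TRUE)
        edges <- data.frame(u = vapply(parts, `[`, "", 1L),
                            v = vapply(parts, `[`, "", 2L),
                            weight = as.numeric(w),
                            stringsAsFactors = FALSE)
      }
      edges <- edges[order(edges$u, edges$v), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  all_nodes <- sort(unique(c(edges$u, edges$v, as.character(nodes))))
  structure(list(nodes = all_nodes, edges = edges,
                 adj = build_adjacency(all_nodes, edges)),
            class = "weighted_pin")
}

build_adjacency <- function(nodes, edges) {
  adj <- vector("list", length(nodes))
  names(adj) <- nodes
  for (i in seq_along(adj)) adj[[i]] <- numeric(0)
  if (nrow(edges) > 0L) {
    ends <- c(edges$u, edges$v)
    other <- c(edges$v, edges$u)
    w <- c(edges$weight, edges$weight)
    sp <- split(seq_along(ends), ends)
    for (node in names(sp)) {
      idx <- sp[[node]]
      wt <- w[idx]
      names(wt) <- other[idx]
      adj[[node]] <- wt
    }
  }
  adj
}

#' @export
print.weighted_pin <- function(x, ...) {
  cat(sprintf("weighted_pin: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges) > 0L) {
    cat(sprintf("  weights: min %.3f, median %.3f, max %.3f\n",
                min(x$edges$weight), stats::median(x$edges$weight),
                max(x$edges$weight)))
  }
  invisible(x)
}

#' @export
summary.weighted_pin <- function(object, ...) {
  deg <- pin_degree(object)
  out <- list(n_nodes = length(object$nodes),
              n_edges = nrow(object$edges),
              n_isolated = sum(deg == 0L),
              weight_summary = if (nrow(object$edges)) summary(object$edges$weight),
              degree_summary = if (length(deg)) summary(deg))
  class(out) <- "summary.weighted_pin"
  out
}

#' @export
print.summary.weighted_pin <- function(x, ...) {
  cat(sprintf("weighted_pin: %d nodes (%d isolated), %d edges\n",
              x$n_nodes, x$n_isolated, x$n_edges))
  if (!is.null(x$weight_summary)) {
    cat("edge weights:\n"); print(x$weight_summary)
    cat("node degrees:\n"); print(x$degree_summary)
  }
  invisible(x)
}

#' Node degrees of a network
#'
#' @param pin a [weighted_pin()]
#' @return named integer vector of unweighted degrees (isolated nodes 0).
#' @export
pin_degree <- function(pin) {
  stopifnot(inherits(pin, "weighted_pin"))
  vapply(pin$adj, length, 0L)
}

#' @rdname pin_degree
#' @export
pin_edge_count <- function(pin) nrow(pin$edges)

#' Neighbors of a node with edge weights
#'
#' @param pin a [weighted_pin()]
#' @param node node identifier
#' @return named numeric vector of weights keyed by neighbor id.
#' @export
pin_neighbors <- function(pin, node) {
  w <- pin$adj[[node]]
  if (is.null(w)) stop(sprintf("node '%s' not in network", node))
  w
}

#' Test whether unordered pairs are edges of the network
#'
#' @param pin a [weighted_pin()]
#' @param u,v character vectors of endpoints (recycled)
#' @return logical vector.
#' @export
pin_has_edge <- function(pin, u, v) {
  key <- pin_pair_key(u, v)
  key %in% pin_pair_key(pin$edges$u, pin$edges$v)
}

# canonical "min\tmax" key for unordered pairs
pin_pair_key <- function(u, v) {
  paste(pmin(u, v), pmax(u, v), sep = "\t")
}

#' Convert a network to an igraph object
#'
#' @param pin a [weighted_pin()]
#' @return an undirected `igraph` graph with a `weight` edge attribute.
#' @export
pin_to_igraph <- function(pin) {
  stopifnot(inherits(pin, "weighted_pin"))
  igraph::graph_from_data_frame(
    pin$edges[, c("u", "v", "weight")],
    directed = FALSE,
    vertices = data.frame(name = pin$nodes, stringsAsFactors = FALSE))
}

#' Read a protein interaction network from a TSV edge list
#'
#' The expected format is tab-separated with two columns (`protein_a`,
#' `protein_b`) for unweighted networks or three (`protein_a`, `protein_b`,
#' `weight`) for weighted ones. A header row is detected (third field
#' non-numeric) and skipped. Unweighted edges receive weight 1.
#'
#' @param path file path
#' @param weighted logical; if `TRUE` a third numeric column in `[0, 1]` is
#'   required
#' @return a [weighted_pin()]
#' @export
read_edge_list <- function(path, weighted = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(weighted_pin())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  need <- if (weighted) 3L else 2L
  lens <- lengths(parts)
  start <- 1L
  if (lens[1L] >= need) {
    f <- parts[[1L]]
    if (weighted && is.na(suppressWarnings(as.numeric(f[3L])))) start <- 2L
    if (!weighted && (tolower(f[1L]) %in% c("protein_a", "u", "node_a", "source")))
      start <- 2L
  }
  bad <- which(lens[seq(start, length(parts))] < need) + start - 1L
  if (length(bad)) {
    stop(sprintf("malformed row at line %d: expected %d tab-separated fields",
                 bad[1L], need))
  }
  u <- vapply(parts[start:length(parts)], `[`, "", 1L)
  v <- vapply(parts[start:length(parts)], `[`, "", 2L)
  if (weighted) {
    w <- suppressWarnings(as.numeric(vapply(parts[start:length(parts)], `[`, "", 3L)))
    if (anyNA(w)) {
      stop(sprintf("malformed row at line %d: non-numeric weight",
                   start - 1L + which(is.na(w))[1L]))
    }
    if (any(w < 0 | w > 1)) {
      stop(sprintf("weight outside [0, 1] at line %d",
                   start - 1L + which(w < 0 | w > 1)[1L]))
    }
  } else {
    w <- rep(1.0, length(u))
  }
  weighted_pin(data.frame(u = u, v = v, weight = w, stringsAsFactors = FALSE))
}

#' Write a network as a TSV edge list
#'
#' @param pin a [weighted_pin()]
#' @param path output file path
#' @param header logical; write a `protein_a  protein_b  weight` header
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(pin, path, header = FALSE) {
  stopifnot(inherits(pin, "weighted_pin"))
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines("protein_a\tprotein_b\tweight", con)
  if (nrow(pin$edges) > 0L) {
    writeLines(sprintf("%s\t%s\t%s", pin$edges$u, pin$edges$v,
                       formatC(pin$edges$weight, format = "g", digits = 17)),
               con)
  }
  invisible(path)
}

#' k-shell (k-core) decomposition
#'
#' Assigns each node the deepest k-core it belongs to, by iterative peeling of
#' minimum-degree nodes on the unweighted skeleton. Edge weights are ignored:
#' the decomposition is purely topological, which matches its role here of
#' ranking seed nodes by how deeply embedded they are in the interactome.
#' Isolated nodes get shell 0.
#'
#' @param pin a [weighted_pin()]
#' @return named integer vector of shell indices, one per node.
#' @export
k_shell <- function(pin) {
  stopifnot(inherits(pin, "weighted_pin"))
  shells <- stats::setNames(integer(length(pin$nodes)), pin$nodes)
  if (nrow(pin$edges) > 0L) {
    g <- pin_to_igraph(pin)
    core <- igraph::coreness(g)
    shells[names(core)] <- as.integer(core)
  }
  shells
}

#' Build the seed queue for complex detection
#'
#' Orders all nodes by descending k-shell index; ties are broken by ascending
#' lexicographic node id so detection output is deterministic. Nodes with
#' shell at or above `high_shell_threshold` are flagged "high": the parallel
#' scheduler gives such seeds their own worker because growing a complex from
#' a deeply embedded node dominates the run time.
#'
#' @param pin a [weighted_pin()]
#' @param high_shell_threshold shell index at or above which a seed counts as
#'   high-load (default 20)
#' @return data frame with columns `node`, `shell`, `high`, one row per node,
#'   in seed order.
#' @export
build_seed_queue <- function(pin, high_shell_threshold = 20L) {
  shells <- k_shell(pin)
  ord <- order(-shells, names(shells))
  data.frame(node = names(shells)[ord],
             shell = as.integer(shells[ord]),
             high = as.integer(shells[ord]) >= high_shell_threshold,
             stringsAsFactors = FALSE)
}
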