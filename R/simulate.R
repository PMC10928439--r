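# Run code under a local RNG stream, restoring global .Random.seed after.
# All generator randomness flows through an explicit seed argument.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Generate a weighted network with planted complexes
#'
#' Emulates the structure of a classifier-weighted interactome (LE-PIN):
#' complexes are realized as cliques whose edge weights are drawn from a
#' high-mean Beta distribution (the predicted within-complex probabilities),
#' and background edges between complexes appear independently with a small
#' probability and low-mean Beta weights. Complex sizes favor 2-3 members,
#' matching the observation that small complexes dominate real catalogues.
#' All randomness flows from `seed`; the global RNG state is untouched.
#'
#' @param n_complexes number of planted complexes (default 20)
#' @param sizes integer vector of allowed complex sizes (default `2:10`)
#' @param size_weights sampling weights over `sizes` (default geometric-like,
#'   favoring sizes 2-3)
#' @param within_shape1,within_shape2 Beta parameters for within-complex
#'   weights (default `Beta(36, 4)`, mean 0.9, concentrated so essentially
#'   all c-edge weights exceed 0.5)
#' @param background_p probability of a background edge between any
#'   cross-complex protein pair (default 0.01)
#' @param background_shape1,background_shape2 Beta parameters for background
#'   weights (default `Beta(4, 36)`, mean 0.1)
#' @param overlap_fraction fraction of complexes (beyond the first) that
#'   share one protein with a previously planted complex (default 0)
#' @param seed integer seed (required)
#' @return list of class `planted_truth`: `pin` (a [weighted_pin()]),
#'   `complexes` (a [complex_set()] of the planted truth), `labels`
#'   (c-edge/nc-edge labels for every edge, from [label_edges()]).
#' @export
generate_planted_pin <- function(n_complexes = 20L,
                                 sizes = 2:10,
                                 size_weights = 0.5^pmax(sizes - 2L, 0L),
                                 within_shape1 = 36, within_shape2 = 4,
                                 background_p = 0.01,
                                 background_shape1 = 4,
                                 background_shape2 = 36,
                                 overlap_fraction = 0,
                                 seed) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(n_complexes >= 1L, all(sizes >= 2L),
            background_p >= 0, background_p <= 1,
            overlap_fraction >= 0, overlap_fraction < 1)
  within_mean <- within_shape1 / (within_shape1 + within_shape2)
  background_mean <- background_shape1 / (background_shape1 + background_shape2)
  if (within_mean <= 0.5 || background_mean >= 0.5) {
    warning(paste("within-weight mean must exceed 0.5 and background mean",
                  "stay below it for the instance to be resolvable at the",
                  "default c-edge threshold"))
  }
  with_seed(seed, {
    sz <- if (length(sizes) == 1L) rep(sizes, n_complexes) else
      sample(sizes, n_complexes, replace = TRUE, prob = size_weights)
    n_shared <- round(overlap_fraction * (n_complexes - 1L))
    shared_at <- if (n_shared > 0L)
      sample(2:n_complexes, n_shared) else integer()
    members <- vector("list", n_complexes)
    next_id <- 1L
    new_ids <- function(k) {
      ids <- sprintf("P%04d", seq.int(next_id, length.out = k))
      next_id <<- next_id + k
      ids
    }
    for (i in seq_len(n_complexes)) {
      if (i %in% shared_at) {
        prev <- unlist(members[seq_len(i - 1L)])
        members[[i]] <- c(sample(prev, 1L), new_ids(sz[i] - 1L))
      } else {
        members[[i]] <- new_ids(sz[i])
      }
    }
    # within-complex cliques
    edge_frames <- lapply(members, function(m) {
      pr <- utils::combn(sort(m), 2L)
      data.frame(u = pr[1L, ], v = pr[2L, ],
                 weight = stats::rbeta(ncol(pr), within_shape1, within_shape2),
                 stringsAsFactors = FALSE)
    })
    clique_edges <- do.call(rbind, edge_frames)
    clique_keys <- pin_pair_key(clique_edges$u, clique_edges$v)
    # background edges between complexes
    all_prot <- sort(unique(unlist(members)))
    bg <- NULL
    if (background_p > 0 && length(all_prot) > 1L) {
      pr <- utils::combn(all_prot, 2L)
      key <- pin_pair_key(pr[1L, ], pr[2L, ])
      eligible <- !(key %in% clique_keys)
      draw <- eligible & stats::runif(ncol(pr)) < background_p
      if (any(draw)) {
        bg <- data.frame(u = pr[1L, draw], v = pr[2L, draw],
                         weight = stats::rbeta(sum(draw), background_shape1,
                                               background_shape2),
                         stringsAsFactors = FALSE)
      }
    }
    pin <- weighted_pin(rbind(clique_edges, bg), nodes = all_prot)
    truth <- complex_set(members)
    structure(list(pin = pin, complexes = truth,
                   labels = label_edges(pin, truth), seed = seed),
              class = "planted_truth")
  })
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("planted_truth (seed %d): %d complexes\n",
              x$seed, length(x$complexes)))
  print(x$pin)
  lab <- table(x$labels$label)
  cat("  edge labels:", paste(names(lab), lab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Generate separable edge-feature data for classifier tests
#'
#' Draws per-edge feature vectors for the two classes from class-conditional
#' Gaussians clipped to `[0, 1]`. A subset of informative slots has class
#' means separated by `separation` noise standard deviations (c-edges above
#' nc-edges); remaining slots are pure noise. `separation = 0` gives an
#' unlearnable null; `separation >= 5` is near-separable.
#'
#' @param n_c,n_nc number of c-edge / nc-edge rows
#' @param separation class-mean separation in units of `noise_sd`
#' @param n_features total feature slots (default 12)
#' @param n_informative number of informative slots (default 4)
#' @param noise_sd within-class standard deviation (default 0.1)
#' @param seed integer seed (required)
#' @return list: `features` (data frame, values in `[0, 1]`), `labels`
#'   (character, `"c-edge"`/`"nc-edge"`).
#' @export
generate_edge_feature_data <- function(n_c, n_nc, separation,
                                       n_features = 12L, n_informative = 4L,
                                       noise_sd = 0.1, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(separation >= 0, n_informative <= n_features,
            n_c >= 1L, n_nc >= 1L)
  delta <- separation * noise_sd
  with_seed(seed, {
    n <- n_c + n_nc
    labels <- c(rep("c-edge", n_c), rep("nc-edge", n_nc))
    X <- matrix(stats::rnorm(n * n_features, mean = 0.5, sd = noise_sd),
                n, n_features)
    shift <- ifelse(labels == "c-edge", delta / 2, -delta / 2)
    for (j in seq_len(n_informative)) X[, j] <- X[, j] + shift
    X <- pmin(pmax(X, 0), 1)
    colnames(X) <- sprintf("f%02d", seq_len(n_features))
    list(features = as.data.frame(X), labels = labels)
  })
}

#' Split a gold-standard complex set into training and test portions
#'
#' Random complex-level partition: each complex lands in exactly one side, so
#' no complex informs both classifier training and evaluation. (Proteins may
#' still appear on both sides; pair-level redundancy is handled downstream
#' when labels are built per split.)
#'
#' @param gold a [complex_set()]
#' @param fraction proportion of complexes assigned to the training side
#'   (in (0, 1))
#' @param seed integer seed (required)
#' @return list with [complex_set()] components `train` and `test`.
#' @export
split_gold_standard <- function(gold, fraction, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(inherits(gold, "complex_set"), fraction > 0, fraction < 1)
  n <- length(gold)
  with_seed(seed, {
    n_train <- round(fraction * n)
    idx <- sample(n, n_train)
    list(train = gold[sort(idx)], test = gold[sort(setdiff(seq_len(n), idx))])
  })
}
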