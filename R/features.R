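#' Subcellular localization features for a protein pair
#'
#' Four features comparing the localization term sets of two proteins:
#' overlap count, set equality, Jaccard similarity and mutual inclusion.
#' Interacting proteins, and members of one complex in particular, must be
#' co-located, so agreement in localization is evidence for a within-complex
#' edge. Empty-set conventions: two empty sets are equal (Equality = 1) and
#' each trivially includes the other (Inclusion = 1), while Jaccard is 0.
#'
#' @param sl_i,sl_j character vectors of localization terms (possibly empty)
#' @return named numeric vector `overlap_sl`, `equality`, `jaccard`,
#'   `inclusion`.
#' @examples
#' localization_features(c("nucleus", "cytoplasm"), "nucleus")
#' @export
localization_features <- function(sl_i, sl_j) {
  sl_i <- unique(as.character(sl_i)); sl_j <- unique(as.character(sl_j))
  inter <- length(intersect(sl_i, sl_j))
  uni <- length(union(sl_i, sl_j))
  c(overlap_sl = inter,
    equality = as.numeric(setequal(sl_i, sl_j)),
    jaccard = if (uni == 0L) 0 else inter / uni,
    inclusion = as.numeric(all(sl_i %in% sl_j) || all(sl_j %in% sl_i)))
}

#' Pfam domain features for a protein pair
#'
#' Five features from the domain annotations of the two proteins and a set of
#' known domain-domain interactions: shared-domain count, count of
#' cross-interacting domain pairs, total distinct domains, and the two counts
#' normalized by the total. Physical protein interactions are usually
#' mediated by specific domain pairs, so a pair whose domains are known to
#' interact is more likely a genuine interaction.
#'
#' @param pd_i,pd_j character vectors of domain identifiers (possibly empty)
#' @param ddi a [domain_interaction_set()] or `NULL` (no known interactions)
#' @return named numeric vector `overlap_pd`, `interaction`, `total`,
#'   `sim_overlap`, `sim_interaction`; the two ratios are 0 when `total` is 0.
#' @export
domain_features <- function(pd_i, pd_j, ddi = NULL) {
  pd_i <- unique(as.character(pd_i)); pd_j <- unique(as.character(pd_j))
  overlap <- length(intersect(pd_i, pd_j))
  total <- length(union(pd_i, pd_j))
  interaction <- 0L
  if (!is.null(ddi) && length(pd_i) && length(pd_j)) {
    pairs <- expand.grid(d1 = pd_i, d2 = pd_j, stringsAsFactors = FALSE)
    interaction <- sum(pin_pair_key(pairs$d1, pairs$d2) %in% ddi$keys)
  }
  c(overlap_pd = overlap,
    interaction = as.numeric(interaction),
    total = total,
    sim_overlap = if (total == 0L) 0 else overlap / total,
    sim_interaction = if (total == 0L) 0 else interaction / total)
}

#' Construct a domain-domain interaction set
#'
#' @param pairs data frame with two columns of domain identifiers (unordered
#'   pairs; symmetric membership is implied)
#' @return object of class `domain_interaction_set`.
#' @export
domain_interaction_set <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    keys <- character()
  } else {
    keys <- unique(pin_pair_key(as.character(pairs[[1L]]),
                                as.character(pairs[[2L]])))
  }
  structure(list(keys = keys), class = "domain_interaction_set")
}

#' @export
print.domain_interaction_set <- function(x, ...) {
  cat(sprintf("domain_interaction_set: %d interacting domain pairs\n",
              length(x$keys)))
  invisible(x)
}

#' Chain-length difference feature
#'
#' Absolute difference between the amino-acid chain lengths of two proteins.
#' Typical chains run from about 50 to 2000 residues; similar lengths are a
#' weak but cheap signal of functional relatedness.
#'
#' @param len_i,len_j positive chain lengths; `NA` propagates (masked
#'   missing value)
#' @return `|len_i - len_j|`, vectorized.
#' @export
chain_length_feature <- function(len_i, len_j) {
  abs(as.numeric(len_i) - as.numeric(len_j))
}

#' GO semantic-similarity feature
#'
#' A single scalar in `[0, 1]` summarizing functional similarity of two
#' proteins' GO annotation sets. The measure is pluggable: any function
#' mapping two term sets to `[0, 1]` may be supplied (e.g., a wrapper around
#' an ontology-aware semantic-similarity engine). The built-in fallback is
#' the Jaccard index over term sets, which needs no ontology graph. A failing
#' provider yields a masked missing value (`NA`) with a warning.
#'
#' @param go_i,go_j character vectors of GO term identifiers
#' @param provider `NULL` for the Jaccard fallback, or
#'   `function(go_i, go_j) -> numeric(1)`
#' @return similarity in `[0, 1]`, or `NA` on provider failure.
#' @export
go_similarity <- function(go_i, go_j, provider = NULL) {
  if (is.null(provider)) {
    go_i <- unique(as.character(go_i)); go_j <- unique(as.character(go_j))
    uni <- length(union(go_i, go_j))
    return(if (uni == 0L) 0 else length(intersect(go_i, go_j)) / uni)
  }
  res <- tryCatch(provider(go_i, go_j), error = function(e) {
    warning(sprintf("GO similarity provider failed (%s); value masked",
                    conditionMessage(e)))
    NA_real_
  })
  if (!is.na(res) && (res < 0 || res > 1)) {
    stop("GO similarity provider returned a value outside [0, 1]")
  }
  res
}

#' Assemble the per-edge feature table (FE-PIN)
#'
#' Computes, for each protein pair, the self-contained feature blocks:
#' 4 localization features, 5 domain features, the chain-length difference
#' and the GO similarity (11 columns). An optional precomputed block of
#' sequence-profile features (e.g., a 420-dim evolutionary descriptor sum
#' plus a distance scalar, computed externally per pair) can be joined by
#' pair. Missing annotations produce `NA` values; [scale_features()] masks
#' and imputes them.
#'
#' @param pairs data frame with columns `u`, `v` (or a [weighted_pin()],
#'   whose edges are used)
#' @param annotations a [protein_annotations()] object
#' @param ddi optional [domain_interaction_set()]
#' @param go_provider optional provider passed to [go_similarity()]
#' @param extra_block optional data frame keyed by `u`, `v` with additional
#'   precomputed numeric feature columns (e.g., a PSSM-derived block)
#' @return data frame with columns `u`, `v` and one column per feature.
#' @export
compute_edge_features <- function(pairs, annotations, ddi = NULL,
                                  go_provider = NULL, extra_block = NULL) {
  if (inherits(pairs, "weighted_pin")) pairs <- pairs$edges[, c("u", "v")]
  stopifnot(inherits(annotations, "protein_annotations"))
  n <- nrow(pairs)
  loc <- matrix(NA_real_, n, 4L)
  dom <- matrix(NA_real_, n, 5L)
  cld <- numeric(n); gos <- numeric(n)
  ann <- annotations
  get_set <- function(lst, p) if (is.null(lst[[p]])) NULL else lst[[p]]
  for (i in seq_len(n)) {
    u <- pairs$u[i]; v <- pairs$v[i]
    sl_u <- get_set(ann$localization, u); sl_v <- get_set(ann$localization, v)
    loc[i, ] <- if (is.null(sl_u) || is.null(sl_v)) rep(NA_real_, 4L) else
      localization_features(sl_u, sl_v)
    pd_u <- get_set(ann$domains, u); pd_v <- get_set(ann$domains, v)
    dom[i, ] <- if (is.null(pd_u) || is.null(pd_v)) rep(NA_real_, 5L) else
      domain_features(pd_u, pd_v, ddi)
    lu <- ann$chain_length[u]; lv <- ann$chain_length[v]
    cld[i] <- if (is.na(lu) || is.na(lv)) NA_real_ else
      chain_length_feature(lu, lv)
    go_u <- get_set(ann$go, u); go_v <- get_set(ann$go, v)
    gos[i] <- if (is.null(go_u) || is.null(go_v)) NA_real_ else
      go_similarity(go_u, go_v, go_provider)
  }
  out <- data.frame(u = as.character(pairs$u), v = as.character(pairs$v),
                    overlap_sl = loc[, 1L], equality = loc[, 2L],
                    jaccard = loc[, 3L], inclusion = loc[, 4L],
                    overlap_pd = dom[, 1L], interaction = dom[, 2L],
                    total = dom[, 3L], sim_overlap = dom[, 4L],
                    sim_interaction = dom[, 5L],
                    chain_length_diff = cld, go_similarity = gos,
                    stringsAsFactors = FALSE)
  if (!is.null(extra_block)) {
    key <- pin_pair_key(out$u, out$v)
    bkey <- pin_pair_key(as.character(extra_block$u),
                         as.character(extra_block$v))
    bcols <- setdiff(names(extra_block), c("u", "v"))
    idx <- match(key, bkey)
    for (col in bcols) out[[col]] <- extra_block[[col]][idx]
  }
  out
}

#' Protein annotation bundle
#'
#' @param localization named list: protein id -> character vector of
#'   subcellular localization terms
#' @param domains named list: protein id -> character vector of domain ids
#' @param chain_length named numeric vector: protein id -> length in residues
#' @param go named list: protein id -> character vector of GO term ids
#' @return object of class `protein_annotations`.
#' @export
protein_annotations <- function(localization = list(), domains = list(),
                                chain_length = numeric(), go = list()) {
  if (length(chain_length)) {
    bad <- !is.na(chain_length) & chain_length < 1
    if (any(bad)) stop("chain lengths must be >= 1")
  }
  structure(list(localization = localization, domains = domains,
                 chain_length = chain_length, go = go),
            class = "protein_annotations")
}

#' @export
print.protein_annotations <- function(x, ...) {
  cat(sprintf(paste0("protein_annotations: %d localization, %d domain, ",
                     "%d chain-length, %d GO entries\n"),
              length(x$localization), length(x$domains),
              length(x$chain_length), length(x$go)))
  invisible(x)
}

#' Read a per-protein annotation TSV
#'
#' Two tab-separated columns: protein id, then either a `;`-separated term
#' list (`type = "terms"`) or a single number (`type = "numeric"`).
#'
#' @param path file path
#' @param type `"terms"` or `"numeric"`
#' @return named list of character vectors, or a named numeric vector.
#' @export
read_annotation_table <- function(path, type = c("terms", "numeric")) {
  type <- match.arg(type)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(if (type == "terms") list() else numeric())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1L)
  vals <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "", "")
  if (type == "numeric") {
    stats::setNames(as.numeric(vals), ids)
  } else {
    stats::setNames(lapply(vals, function(v) {
      if (!nzchar(v)) character() else strsplit(v, ";", fixed = TRUE)[[1L]]
    }), ids)
  }
}

#' Fit a min-max feature scaler
#'
#' Learns per-column minimum and maximum on a (training) feature table; the
#' resulting transform maps values to `[0, 1]`, clamps out-of-range test
#' values, maps constant columns to 0 and imputes masked (`NA`) values as 0
#' after scaling. Fitting on the training partition only avoids information
#' leaking from test edges into the scaling.
#'
#' @param features data frame as from [compute_edge_features()] (the `u`,
#'   `v` key columns are ignored if present)
#' @return object of class `feature_scaler`.
#' @export
fit_feature_scaler <- function(features) {
  num <- features[, setdiff(names(features), c("u", "v")), drop = FALSE]
  stopifnot(nrow(num) >= 1L)
  mins <- vapply(num, function(x) suppressWarnings(min(x, na.rm = TRUE)), 0)
  maxs <- vapply(num, function(x) suppressWarnings(max(x, na.rm = TRUE)), 0)
  mins[!is.finite(mins)] <- 0; maxs[!is.finite(maxs)] <- 0
  structure(list(min = mins, max = maxs, columns = names(num)),
            class = "feature_scaler")
}

#' Apply (or fit and apply) min-max scaling to a feature table
#'
#' @param features data frame of features, optionally with `u`, `v` key
#'   columns which are carried through unscaled
#' @param scaler a [fit_feature_scaler()] result; when `NULL` one is fitted
#'   on `features` itself
#' @return the scaled data frame, with a logical `missing_mask` attribute
#'   marking values that were `NA` before imputation.
#' @export
scale_features <- function(features, scaler = NULL) {
  if (is.null(scaler)) scaler <- fit_feature_scaler(features)
  stopifnot(inherits(scaler, "feature_scaler"))
  out <- features
  mask <- matrix(FALSE, nrow(features), length(scaler$columns),
                 dimnames = list(NULL, scaler$columns))
  for (col in scaler$columns) {
    x <- features[[col]]
    if (is.null(x)) stop(sprintf("feature column '%s' missing", col))
    rng <- scaler$max[[col]] - scaler$min[[col]]
    sc <- if (rng <= 0) rep(0, length(x)) else (x - scaler$min[[col]]) / rng
    sc <- pmin(pmax(sc, 0), 1)
    mask[, col] <- is.na(sc)
    sc[is.na(sc)] <- 0
    out[[col]] <- sc
  }
  attr(out, "missing_mask") <- mask
  attr(out, "scaler") <- scaler
  out
}
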