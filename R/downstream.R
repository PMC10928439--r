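#' Select high-confidence ("real") complexes by score
#'
#' Keeps complexes whose cohesion score is no less than the threshold,
#' sorted descending. The default 0.5 is the operating point at which exact
#' matches to an independent reference typically appear.
#'
#' @param cs a scored [complex_set()]
#' @param score_threshold inclusive lower bound on the score (default 0.5)
#' @return a [complex_set()]
#' @export
select_real_complexes <- function(cs, score_threshold = 0.5) {
  stopifnot(inherits(cs, "complex_set"))
  if (any(is.na(cs$score))) stop("complexes must carry scores")
  keep <- which(cs$score >= score_threshold)
  keep <- keep[order(-cs$score[keep])]
  complex_set(cs$members[keep], cs$score[keep])
}

#' Calibrate the real-complex score threshold on an independent reference
#'
#' Finds predicted complexes that exactly match (matching rate 1) a complex
#' of an independent reference set and returns the lowest score among them:
#' any prediction scoring at least as high as the weakest exactly-confirmed
#' one is then treated as real.
#'
#' @param cs a scored [complex_set()] of predictions
#' @param independent_gold a [complex_set()] not used in training
#' @return the minimum score among exactly matched predictions.
#' @export
calibrate_score_threshold <- function(cs, independent_gold) {
  stopifnot(inherits(cs, "complex_set"), inherits(independent_gold, "complex_set"))
  if (any(is.na(cs$score))) stop("complexes must carry scores")
  gold_keys <- vapply(independent_gold$members, paste, "", collapse = "\t")
  pred_keys <- vapply(cs$members, paste, "", collapse = "\t")
  hit <- pred_keys %in% gold_keys
  if (!any(hit)) {
    stop(paste("no predicted complex exactly matches the independent set;",
               "choose a threshold manually"))
  }
  min(cs$score[hit])
}

#' Directional sub-complex overlap index
#'
#' `|A ∩ B| / |A|`: the fraction of complex A contained in complex B.
#' Asymmetric — a small complex nested in a large one scores 1 in one
#' direction only.
#'
#' @param a,b character vectors (member sets)
#' @return a value in `[0, 1]`.
#' @export
subcomplex_index <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (!length(a)) stop("first member set must be non-empty")
  length(intersect(a, b)) / length(a)
}

#' Build a limited-overlap complex set
#'
#' Greedy pass in descending score order: a candidate complex is kept only
#' if, against every already-kept complex, both directional
#' [subcomplex_index()] values are strictly below the threshold. Symmetric
#' screening removes both containment directions, so no kept complex is
#' half-contained in another — the precondition for calling multifunctional
#' proteins from membership counts.
#'
#' @param cs a scored [complex_set()]
#' @param idx_threshold strict upper bound on the overlap index (default 0.5)
#' @return a [complex_set()]
#' @export
limited_overlap_set <- function(cs, idx_threshold = 0.5) {
  stopifnot(inherits(cs, "complex_set"))
  if (!length(cs)) return(cs)
  ord <- order(-replace(cs$score, is.na(cs$score), -Inf),
               vapply(cs$members, paste, "", collapse = "\t"))
  kept <- integer()
  for (i in ord) {
    cand <- cs$members[[i]]
    ok <- all(vapply(kept, function(j) {
      k <- cs$members[[j]]
      max(subcomplex_index(cand, k), subcomplex_index(k, cand)) < idx_threshold
    }, TRUE))
    if (ok) kept <- c(kept, i)
  }
  complex_set(cs$members[kept], cs$score[kept])
}

#' Identify multifunctional proteins
#'
#' In a limited-overlap complex set, a protein belonging to two or more
#' complexes participates in genuinely distinct assemblies, the operational
#' signature of a multifunctional (moonlighting-candidate) protein.
#'
#' @param limited a [complex_set()] from [limited_overlap_set()]
#' @return named list: protein id -> integer vector of complex indices
#'   (within `limited`), only for proteins in >= 2 complexes.
#' @export
find_multifunctional <- function(limited) {
  stopifnot(inherits(limited, "complex_set"))
  if (!length(limited)) return(list())
  membership <- data.frame(
    protein = unlist(limited$members),
    complex = rep(seq_along(limited$members), lengths(limited$members)),
    stringsAsFactors = FALSE)
  by_prot <- split(membership$complex, membership$protein)
  Filter(function(x) length(x) >= 2L, by_prot)
}

#' Select complexes affected by an interactor set
#'
#' Flags complexes containing at least one protein from `interactors`
#' (e.g., proteins that bind a viral protein), reporting the interacting
#' members, whether every member interacts, and optionally which members
#' appear in a drug-target list.
#'
#' @param cs a [complex_set()]
#' @param interactors non-empty character vector of protein ids
#' @param targets optional character vector of protein ids (e.g., drug
#'   targets)
#' @return data frame with one row per affected complex: `complex` (index in
#'   `cs`), `size`, `interactor_count`, `all_members_interact`,
#'   `interactor_members`, `target_members` (the last two
#'   comma-separated).
#' @export
affected_complexes <- function(cs, interactors, targets = NULL) {
  stopifnot(inherits(cs, "complex_set"))
  interactors <- unique(as.character(interactors))
  if (!length(interactors)) stop("interactor list must be non-empty")
  rows <- lapply(seq_along(cs$members), function(i) {
    m <- cs$members[[i]]
    hits <- intersect(m, interactors)
    if (!length(hits)) return(NULL)
    tgt <- if (is.null(targets)) character() else intersect(m, targets)
    data.frame(complex = i, size = length(m),
               interactor_count = length(hits),
               all_members_interact = length(hits) == length(m),
               interactor_members = paste(sort(hits), collapse = ","),
               target_members = paste(sort(tgt), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(complex = integer(), size = integer(),
                      interactor_count = integer(),
                      all_members_interact = logical(),
                      interactor_members = character(),
                      target_members = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(-out$interactor_count, out$complex), , drop = FALSE]
}
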