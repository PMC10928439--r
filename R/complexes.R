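#' Construct a complex set
#'
#' A `complex_set` is an ordered collection of protein complexes, each a set
#' of at least two member identifiers, optionally carrying a cohesion score
#' (the detection score F for predicted complexes; `NA` for gold standards).
#'
#' @param members list of character vectors (complex memberships)
#' @param score optional numeric vector of per-complex scores
#' @return object of class `complex_set`.
#' @export
complex_set <- function(members = list(), score = NULL) {
  members <- unname(lapply(members,
                           function(m) sort(unname(unique(as.character(m))))))
  sizes <- lengths(members)
  if (any(sizes < 2L)) stop("every complex must have at least 2 members")
  if (is.null(score)) score <- rep(NA_real_, length(members))
  if (length(score) != length(members)) {
    stop("score must have one value per complex")
  }
  structure(list(members = members, score = unname(as.numeric(score))),
            class = "complex_set")
}

#' @export
length.complex_set <- function(x) length(x$members)

#' @export
`[.complex_set` <- function(x, i) {
  complex_set(x$members[i], x$score[i])
}

#' @export
print.complex_set <- function(x, n = 6L, ...) {
  cat(sprintf("complex_set: %d complexes, %d distinct proteins\n",
              length(x$members), length(unique(unlist(x$members)))))
  if (length(x$members)) {
    sizes <- lengths(x$members)
    cat(sprintf("  sizes: min %d, median %s, max %d\n",
                min(sizes), format(stats::median(sizes)), max(sizes)))
    show <- seq_len(min(n, length(x$members)))
    for (i in show) {
      sc <- if (is.na(x$score[i])) "" else sprintf(" [F=%.3f]", x$score[i])
      cat(sprintf("  %d%s: %s\n", i, sc,
                  paste(x$members[[i]], collapse = " ")))
    }
    if (length(x$members) > n) cat(sprintf("  ... %d more\n",
                                           length(x$members) - n))
  }
  invisible(x)
}

#' @export
summary.complex_set <- function(object, ...) {
  sizes <- lengths(object$members)
  out <- list(n = length(object$members),
              n_proteins = length(unique(unlist(object$members))),
              n_small = sum(sizes <= 3L),
              n_large = sum(sizes > 3L),
              size_summary = if (length(sizes)) summary(sizes),
              score_summary = if (any(!is.na(object$score)))
                summary(object$score[!is.na(object$score)]))
  class(out) <- "summary.complex_set"
  out
}

#' @export
print.summary.complex_set <- function(x, ...) {
  cat(sprintf(
    "complex_set: %d complexes over %d proteins (%d small [size 2-3], %d large)\n",
    x$n, x$n_proteins, x$n_small, x$n_large))
  if (!is.null(x$size_summary)) { cat("sizes:\n"); print(x$size_summary) }
  if (!is.null(x$score_summary)) { cat("scores:\n"); print(x$score_summary) }
  invisible(x)
}

#' @export
plot.complex_set <- function(x, ...) {
  sizes <- lengths(x$members)
  graphics::barplot(table(factor(sizes, levels = seq(2L, max(c(sizes, 2L))))),
                    xlab = "complex size", ylab = "count",
                    main = "Complex size distribution", ...)
  invisible(x)
}

#' Read a complex membership file
#'
#' One complex per line, tab-separated member identifiers (the CORUM-style
#' flat format). When `scores = TRUE` the first field of each line is read as
#' a numeric score.
#'
#' @param path file path
#' @param scores logical; whether a leading score column is present
#' @return a [complex_set()]
#' @export
read_complex_file <- function(path, scores = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(complex_set())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (scores) {
    sc <- as.numeric(vapply(parts, `[`, "", 1L))
    members <- lapply(parts, `[`, -1L)
    complex_set(members, sc)
  } else {
    complex_set(parts)
  }
}

#' Write a complex set to a membership file
#'
#' @param cs a [complex_set()]
#' @param path output file path
#' @param scores logical; prepend each line with the complex score
#' @return `path`, invisibly.
#' @export
write_complex_file <- function(cs, path, scores = !all(is.na(cs$score))) {
  stopifnot(inherits(cs, "complex_set"))
  lines <- vapply(seq_along(cs$members), function(i) {
    body <- paste(cs$members[[i]], collapse = "\t")
    if (scores) paste(formatC(cs$score[i], format = "g", digits = 17),
                      body, sep = "\t") else body
  }, "")
  writeLines(lines, path)
  invisible(path)
}
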