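#' Common profile depth of a sequence set
#'
#' The deepest separation distance usable for every member of a set: the
#' minimum over sequences of floor(n/4) (see
#' \code{\link{max_valid_distance}}).  Profiling every sequence to this
#' shared depth makes all frequency matrices the same shape, so they can be
#' compared cell by cell; longer sequences still contribute all their
#' residues to each layer d <= d0 — sequences are never truncated.
#'
#' @param x a \code{\link{dna_set}} (every member must have n >= 4).
#' @return A positive integer depth.
#' @examples
#' common_depth(beta_globin())  # 21 (shortest member has n = 86)
#' @export
common_depth <- function(x) {
  stopifnot(inherits(x, "dna_set"))
  min(vapply(nchar(unclass(x)), max_valid_distance, integer(1L)))
}

#' City-block distance between two frequency matrices
#'
#' The sum of absolute cell-wise differences over all d0 x 16 cells of two
#' equal-depth frequency matrices.  A genuine metric (non-negative,
#' symmetric, triangle inequality); 0 iff the matrices are identical.
#' Accumulation order is fixed row-major (separation, then pair) so results
#' are bit-stable across runs.
#'
#' @param fa,fb frequency matrices of identical shape
#'   (\code{\link{frequency_matrix}}).
#' @return Non-negative numeric scalar.
#' @export
city_block <- function(fa, fb) {
  a <- unclass(fa); b <- unclass(fb)
  if (!identical(dim(a), dim(b)))
    stop("frequency matrices must share the same depth and width", call. = FALSE)
  sum(abs(as.vector(t(a)) - as.vector(t(b))))
}

#' Cosine distance between two profile vectors
#'
#' One minus the cosine of the angle between two flattened profile vectors.
#' On non-negative vectors the result lies in [0, 1]: 0 for parallel
#' vectors (scale-invariant), 1 for vectors with disjoint support.  Not a
#' metric (no triangle inequality).
#'
#' @param va,vb numeric vectors of equal length (\code{\link{flatten}}).
#' @return Numeric scalar in [0, 1] for non-negative inputs.
#' @export
cosine_distance <- function(va, vb) {
  va <- as.numeric(va); vb <- as.numeric(vb)
  if (length(va) != length(vb))
    stop("profile vectors must have equal length", call. = FALSE)
  na <- sqrt(sum(va * va)); nb <- sqrt(sum(vb * vb))
  if (na == 0 || nb == 0)
    stop("cosine distance is undefined for a zero vector", call. = FALSE)
  1 - sum(va * vb) / (na * nb)
}

#' Pairwise distance matrix for a sequence set
#'
#' Profiles every sequence to a shared depth and computes all pairwise
#' distances: \code{"d1"} is the city-block distance between frequency
#' matrices, \code{"d2"} the cosine distance between flattened profile
#' vectors.  Row/column order is the input order of the set, never
#' alphabetized.
#'
#' @param x a \code{\link{dna_set}} of at least 2 sequences.
#' @param metric \code{"d1"} (city-block, the default) or \code{"d2"}
#'   (cosine); the aliases \code{"cityblock"} and \code{"cosine"} are
#'   accepted.
#' @param d0 depth; \code{NULL} (default) uses \code{\link{common_depth}}.
#'   A fixed depth must satisfy 1 <= d0 <= min(n) - 1.
#' @inheritParams count_pairs
#' @return A \code{dinu_dist}: symmetric numeric matrix with zero diagonal,
#'   labelled rows/columns, and attributes \code{metric} and \code{d0}.
#' @examples
#' D <- pairwise_distances(beta_globin(), metric = "d1")
#' round(D["Human", "Chimpanzee"], 4)  # 2.5567
#' @export
pairwise_distances <- function(x, metric = c("d1", "d2", "cityblock", "cosine"),
                               d0 = NULL, skip_ambiguous = FALSE) {
  stopifnot(inherits(x, "dna_set"))
  metric <- match.arg(metric)
  metric <- c(d1 = "d1", d2 = "d2", cityblock = "d1", cosine = "d2")[[metric]]
  if (length(x) < 2L)
    stop("pairwise comparison needs at least 2 sequences", call. = FALSE)
  auto <- common_depth(x)
  if (is.null(d0)) {
    d0 <- auto
  } else {
    d0 <- as.integer(d0)
    nmin <- min(nchar(unclass(x)))
    if (d0 < 1L || d0 > nmin - 1L)
      stop(sprintf("fixed d0 must satisfy 1 <= d0 <= %d for this set", nmin - 1L),
           call. = FALSE)
  }
  profs <- lapply(names(x),
                  function(id) frequency_matrix(x[id], d0,
                                                skip_ambiguous = skip_ambiguous,
                                                enforce_bound = d0 <= auto))
  k <- length(profs)
  D <- matrix(0, k, k, dimnames = list(names(x), names(x)))
  if (metric == "d2") vecs <- lapply(profs, flatten)
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      D[i, j] <- D[j, i] <- if (metric == "d1")
        city_block(profs[[i]], profs[[j]])
      else
        cosine_distance(vecs[[i]], vecs[[j]])
    }
  }
  structure(D, metric = metric, d0 = d0,
            class = c("dinu_dist", "matrix", "array"))
}

#' @export
print.dinu_dist <- function(x, digits = 4L, ...) {
  cat(sprintf("%s distance matrix (%s), depth d0 = %d, %d sequences\n",
              attr(x, "metric"),
              if (attr(x, "metric") == "d1") "city-block" else "cosine",
              attr(x, "d0"), nrow(x)))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Write a distance matrix to disk
#'
#' Writes a labelled full-square matrix as TSV or CSV (header row of
#' labels, one labelled row per sequence), or in square PHYLIP distance
#' format for downstream tree tools.  \code{precision} controls printed
#' decimals only, never internal arithmetic.
#'
#' @param dm a \code{\link{pairwise_distances}} matrix.
#' @param path destination path.
#' @param format \code{"tsv"} (default), \code{"csv"} or \code{"phylip"}.
#' @param precision printed decimal places (default 4).
#' @param upper if \code{TRUE} (TSV/CSV only) blank the lower triangle so
#'   only the upper triangle is printed.
#' @return \code{path}, invisibly.
#' @export
write_distances <- function(dm, path, format = c("tsv", "csv", "phylip"),
                            precision = 4L, upper = FALSE) {
  format <- match.arg(format)
  labs <- rownames(dm)
  vals <- matrix(formatC(unclass(dm), format = "f", digits = precision),
                 nrow = nrow(dm))
  if (format == "phylip") {
    lines <- c(sprintf("%5d", nrow(dm)),
               vapply(seq_len(nrow(dm)), function(i)
                 paste(formatC(labs[i], width = -10L),
                       paste(vals[i, ], collapse = "  ")),
                 ""))
    writeLines(lines, path)
    return(invisible(path))
  }
  if (upper) vals[lower.tri(vals)] <- ""
  sep <- if (format == "tsv") "\t" else ","
  lines <- c(paste(c("species", labs), collapse = sep),
             vapply(seq_len(nrow(dm)), function(i)
               paste(c(labs[i], vals[i, ]), collapse = sep), ""))
  writeLines(lines, path)
  invisible(path)
}
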