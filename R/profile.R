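#' Largest separation distance for a sequence length
#'
#' When pairs XY at separation d are counted, positions 1..(n-d) act as X
#' and positions (d+1)..n act as Y.  Requiring that at least half of the
#' sequence's positions fall in the overlap of the two windows, i.e.
#' (n - 2d)/n >= 50\%, restricts the separation to d <= floor(n/4).
#'
#' @param n sequence length in nucleotides (>= 4).
#' @return The integer floor(n/4).
#' @examples
#' max_valid_distance(86)  # 21
#' max_valid_distance(7)   # 1
#' @export
max_valid_distance <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 4L)
    stop("sequence length must be a single integer >= 4", call. = FALSE)
  n %/% 4L
}

as_residue_chars <- function(seq) {
  if (inherits(seq, "dna_set")) {
    if (length(seq) != 1L)
      stop("expected a single sequence; subset the dna_set first", call. = FALSE)
    seq <- unclass(seq)[[1L]]
  }
  if (!is.character(seq) || length(seq) != 1L)
    stop("expected a single sequence string", call. = FALSE)
  strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
}

check_distance <- function(d, n) {
  d <- as.integer(d)
  if (length(d) != 1L || is.na(d) || d < 1L)
    stop("separation distance d must be a positive integer", call. = FALSE)
  if (d >= n)
    stop(sprintf("separation distance d = %d must be < sequence length n = %d",
                 d, n), call. = FALSE)
  d
}

#' Count ordered nucleotide pairs at a given separation
#'
#' Counts, for every ordered pair XY of the 16 in \code{\link{dinucleotides}},
#' the positions i in 1..(n-d) with residue X at i and residue Y at i+d
#' (d = 1 means adjacent).  Occurrences overlap freely: one position may
#' serve as X for one pair and as Y for another.  The counts always sum to
#' n - d.
#'
#' @param seq a single sequence: a character string or one-element
#'   \code{\link{dna_set}}.
#' @param d separation distance, 1 <= d <= n - 1.
#' @param skip_ambiguous if \code{TRUE}, pairs in which either position is
#'   not A/C/G/T are dropped (the count sum is then the number of retained
#'   pairs, not n - d).
#' @return Named integer vector of 16 counts in the fixed pair order, with
#'   attributes \code{d}, \code{n} and \code{pairs_counted}.
#' @examples
#' count_pairs("ATCGATC", d = 1)  # AT:2 TC:2 CG:1 GA:1
#' @export
count_pairs <- function(seq, d, skip_ambiguous = FALSE) {
  ch <- as_residue_chars(seq)
  n <- length(ch)
  d <- check_distance(d, n)
  x <- ch[seq_len(n - d)]
  y <- ch[seq.int(d + 1L, n)]
  if (skip_ambiguous) {
    keep <- x %in% BASES & y %in% BASES
    x <- x[keep]
    y <- y[keep]
  } else if (!all(ch %in% BASES)) {
    bad <- which(!ch %in% BASES)[1L]
    stop(sprintf("non-ACGT character '%s' at position %d (use skip_ambiguous = TRUE to drop such pairs)",
                 ch[bad], bad), call. = FALSE)
  }
  counts <- table(factor(paste0(x, y), levels = DINUCLEOTIDES))
  structure(stats::setNames(as.integer(counts), DINUCLEOTIDES),
            d = d, n = n, pairs_counted = length(x))
}

#' Pair frequencies at a given separation
#'
#' The 16 counts of \code{\link{count_pairs}} divided by the number of
#' counted pairs (n - d in the strict default), giving a point on the
#' 16-simplex: frequencies are non-negative and sum to 1.
#'
#' @inheritParams count_pairs
#' @return Named numeric vector of 16 frequencies in the fixed pair order,
#'   with attributes \code{d} and \code{n}.
#' @examples
#' frequency_vector("ATCGATC", d = 1)[c("AT", "TC", "CG", "GA")]  # 2/6 2/6 1/6 1/6
#' @export
frequency_vector <- function(seq, d, skip_ambiguous = FALSE) {
  counts <- count_pairs(seq, d, skip_ambiguous = skip_ambiguous)
  denom <- attr(counts, "pairs_counted")
  if (denom == 0L)
    stop("no countable pairs at this separation", call. = FALSE)
  structure(as.numeric(counts) / denom,
            names = DINUCLEOTIDES, d = attr(counts, "d"), n = attr(counts, "n"))
}

#' Gapped dinucleotide frequency matrix of a sequence
#'
#' Stacks the 16 pair frequencies at separations d = 1..d0 into a d0 x 16
#' matrix: row d is \code{\link{frequency_vector}(seq, d)}, so every row
#' sums to 1.  The depth d0 is bounded by \code{\link{max_valid_distance}}
#' unless \code{enforce_bound = FALSE}, which permits any d0 <= n - 1 for
#' exploration (with a warning, since beyond floor(n/4) fewer than half of
#' the positions contribute to both pair windows).
#'
#' @inheritParams count_pairs
#' @param d0 profile depth (number of separation layers).
#' @param enforce_bound enforce d0 <= floor(n/4) (default \code{TRUE}).
#' @return A \code{dinu_profile}: numeric matrix with rownames
#'   \code{d1..d<d0>}, colnames the 16 pairs, and attributes \code{id}
#'   (when the input carried one) and \code{n}.
#' @examples
#' fm <- frequency_matrix(beta_globin()["Human"], d0 = 21)
#' dim(fm)          # 21 x 16
#' rowSums(fm)      # all 1
#' @export
frequency_matrix <- function(seq, d0, skip_ambiguous = FALSE,
                             enforce_bound = TRUE) {
  id <- if (inherits(seq, "dna_set")) names(seq)[1L] else NULL
  ch <- as_residue_chars(seq)
  n <- length(ch)
  s <- paste(ch, collapse = "")
  d0 <- as.integer(d0)
  if (length(d0) != 1L || is.na(d0) || d0 < 1L)
    stop("d0 must be a positive integer", call. = FALSE)
  dmax <- max_valid_distance(n)
  if (enforce_bound && d0 > dmax)
    stop(sprintf(
      "d0 = %d exceeds floor(n/4) = %d for n = %d; use enforce_bound = FALSE to override",
      d0, dmax, n), call. = FALSE)
  if (!enforce_bound && d0 > dmax) {
    if (d0 > n - 1L)
      stop(sprintf("d0 = %d must be <= n - 1 = %d", d0, n - 1L), call. = FALSE)
    warning(sprintf(
      "d0 = %d exceeds floor(n/4) = %d: fewer than 50%% of positions overlap both pair windows",
      d0, dmax), call. = FALSE)
  }
  rows <- vapply(seq_len(d0),
                 function(d) frequency_vector(s, d, skip_ambiguous = skip_ambiguous),
                 numeric(16L))
  m <- t(rows)
  dimnames(m) <- list(paste0("d", seq_len(d0)), DINUCLEOTIDES)
  structure(m, id = id, n = n, class = c("dinu_profile", "matrix", "array"))
}

#' @export
print.dinu_profile <- function(x, digits = 4L, ...) {
  id <- attr(x, "id")
  cat(sprintf("gapped dinucleotide frequency profile%s: depth %d, n = %d\n",
              if (!is.null(id)) paste0(" of '", id, "'") else "",
              nrow(x), attr(x, "n")))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Flatten a frequency matrix into a profile vector
#'
#' Row-major concatenation of the d0 x 16 frequency matrix, separation 1
#' first, giving the 16*d0-dimensional profile vector.  Its entries sum
#' to d0 (one simplex per row).
#'
#' @param fm a \code{\link{frequency_matrix}} (or any d0 x 16 matrix).
#' @return Named numeric vector of length 16 * d0; names are
#'   \code{"<pair>.d<d>"}.
#' @examples
#' v <- flatten(frequency_matrix("ATCGATCGAT", d0 = 2))
#' length(v)  # 32
#' @export
flatten <- function(fm) {
  m <- unclass(fm)
  stats::setNames(as.vector(t(m)),
                  paste0(rep(colnames(m), times = nrow(m)), ".",
                         rep(rownames(m), each = ncol(m))))
}

#' Long-format profile table for a sequence set
#'
#' One row per (sequence, separation distance) with the 16 pair-frequency
#' columns; the layout written by the CLI \code{profile} subcommand.
#'
#' @param x a \code{\link{dna_set}}.
#' @param d0 depth; \code{NULL} (default) uses the set's common depth
#'   \code{\link{common_depth}}.
#' @inheritParams count_pairs
#' @return A data.frame with columns \code{id}, \code{d} and the 16 pairs.
#' @export
profile_table <- function(x, d0 = NULL, skip_ambiguous = FALSE) {
  stopifnot(inherits(x, "dna_set"))
  if (is.null(d0)) d0 <- common_depth(x)
  out <- do.call(rbind, lapply(names(x), function(id) {
    m <- frequency_matrix(x[id], d0, skip_ambiguous = skip_ambiguous)
    data.frame(id = id, d = seq_len(d0), unclass(m),
               check.names = FALSE, row.names = NULL)
  }))
  out
}
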