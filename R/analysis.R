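#' Relative similarity against a reference pair
#'
#' Rescales one row of a distance matrix by the distance of a chosen
#' reference pair, so the reference partner maps to exactly 1 and every
#' other species is expressed as a multiple of that benchmark distance.
#' With the built-in beta-globin set the customary reference pair is
#' Human-Gorilla.
#'
#' @param dm a \code{\link{pairwise_distances}} matrix.
#' @param reference label of the anchor species (distances are taken from
#'   its row).
#' @param partner label of the reference partner; the pair
#'   (reference, partner) defines the unit.
#' @return A data.frame with columns \code{species}, \code{distance} and
#'   \code{relative}, one row per species other than the reference, in
#'   matrix order.
#' @examples
#' D <- pairwise_distances(beta_globin(), "d1")
#' relative_similarity(D, "Human", "Gorilla")
#' @export
relative_similarity <- function(dm, reference, partner) {
  labs <- rownames(dm)
  for (lab in c(reference, partner))
    if (!lab %in% labs) stop("unknown label: ", lab, call. = FALSE)
  ref <- unclass(dm)[reference, partner]
  if (ref == 0)
    stop("reference pair has zero distance; relative similarity is undefined",
         call. = FALSE)
  others <- setdiff(labs, reference)
  d <- unclass(dm)[reference, others]
  data.frame(species = others, distance = as.numeric(d),
             relative = as.numeric(d) / ref, row.names = NULL)
}

#' PCA projection of profile vectors
#'
#' Projects a set of flattened profile vectors onto their top principal
#' components.  The vectors are mean-centered but not rescaled (all 16*d0
#' features are frequencies on one scale), and the decomposition is the
#' singular value decomposition of the centered matrix, i.e. covariance
#' PCA.  Each component's loading vector is sign-flipped so its
#' largest-magnitude entry is positive, making plots reproducible.
#'
#' @param x either a numeric matrix with one profile vector per row, or a
#'   \code{\link{dna_set}} (vectors are then built at the set's common
#'   depth).
#' @param k number of components to retain (default 2);
#'   k <= min(nrow - 1, ncol).
#' @return A \code{dinu_pca} list: \code{coordinates} (nrow x k scores,
#'   zero column means), \code{explained} (all explained-variance
#'   fractions, non-increasing), \code{loadings} (ncol x k) and \code{k}.
#' @examples
#' p <- pca_project(beta_globin(), k = 2)
#' round(100 * sum(p$explained[1:2]))  # 48
#' @export
pca_project <- function(x, k = 2L) {
  if (inherits(x, "dna_set")) {
    d0 <- common_depth(x)
    x <- t(vapply(names(x),
                  function(id) flatten(frequency_matrix(x[id], d0)),
                  numeric(16L * d0)))
  }
  x <- as.matrix(x)
  if (nrow(x) < 2L)
    stop("PCA needs at least 2 vectors", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k > min(nrow(x) - 1L, ncol(x)))
    stop("k must satisfy 1 <= k <= min(nrow - 1, ncol)", call. = FALSE)
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  ev <- sv$d^2
  total <- sum(ev)
  if (total < .Machine$double.eps * nrow(x))
    stop("total variance is zero: all profile vectors are identical", call. = FALSE)
  # drop the null direction forced by centering
  ncomp <- min(nrow(x) - 1L, ncol(x))
  explained <- (ev / total)[seq_len(ncomp)]
  load <- sv$v[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k),
                 function(j) sign(load[which.max(abs(load[, j])), j]),
                 numeric(1L))
  load <- sweep(load, 2L, flip, `*`)
  scores <- xc %*% load
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(k)))
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(k)))
  structure(list(coordinates = scores, explained = explained,
                 loadings = load, k = k),
            class = "dinu_pca")
}

#' @export
print.dinu_pca <- function(x, ...) {
  cat(sprintf("PCA of %d profile vectors (%d features), %d component(s) retained\n",
              nrow(x$coordinates), nrow(x$loadings), x$k))
  cat("explained variance:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$explained, 6L)),
            collapse = ", "), "\n")
  print(round(x$coordinates, 4), ...)
  invisible(x)
}

#' @export
plot.dinu_pca <- function(x, ...) {
  co <- x$coordinates
  if (ncol(co) < 2L) stop("need at least 2 retained components to plot", call. = FALSE)
  graphics::plot(co[, 1L], co[, 2L], pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained[1L]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained[2L]), ...)
  graphics::text(co[, 1L], co[, 2L], labels = rownames(co), pos = 3, cex = 0.8)
  invisible(x)
}
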