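#' Inverse-MI dissimilarity matrix between sample columns
#'
#' For every unordered pair of sample columns, MI is computed over the given
#' probes (discretized under one shared scheme) and the dissimilarity is
#' `log2(n_probes) / MI`, the maximum entropy for the set size divided by the
#' observed MI. The diagonal is 0 by convention. A pair with zero MI has
#' infinite dissimilarity and aborts construction (capping it would invent
#' geometry); the error names the offending pair.
#'
#' @param g a `gem`
#' @param probes probe ids to use; default all probes (the global view)
#' @param scheme a [disc_scheme()], anchored on `g`
#' @return object of class `"mi_dissimilarity"`: list(labels, d)
#' @export
build_dissimilarity <- function(g, probes = NULL, scheme = disc_scheme()) {
  if (is.null(probes)) probes <- rownames(g$values)
  if (!length(probes)) stop("empty probe set")
  if (ncol(g$values) < 2) stop("need at least 2 sample columns")
  scheme <- anchor_scheme(g, scheme)
  sub <- g$values[probes, , drop = FALSE]
  labels <- colnames(sub)
  bins <- vapply(labels, function(s) discretize(sub[, s], scheme),
                 integer(nrow(sub)))
  bins <- matrix(bins, nrow = nrow(sub), dimnames = list(probes, labels))
  me <- max_entropy(length(probes))
  n <- length(labels)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      mi <- mutual_information(bins[, i], bins[, j])
      if (mi == 0)
        stop("zero mutual information between columns '", labels[i],
             "' and '", labels[j], "'; dissimilarity undefined")
      d[i, j] <- d[j, i] <- me / mi
    }
  }
  structure(list(labels = labels, d = d), class = "mi_dissimilarity")
}

#' @export
print.mi_dissimilarity <- function(x, ...) {
  cat(sprintf("Inverse-MI dissimilarity matrix: %d columns\n", length(x$labels)))
  off <- x$d[upper.tri(x$d)]
  cat(sprintf("  range [%.3f, %.3f]\n", min(off), max(off)))
  invisible(x)
}

#' Classical (Torgerson) multidimensional scaling of a dissimilarity matrix
#'
#' Double-centers the squared dissimilarities and takes the top-k
#' eigenvectors scaled by the square roots of their (nonnegative-clamped)
#' eigenvalues, via [stats::cmdscale()]. Negative eigenvalues — possible
#' because inverse-MI dissimilarities need not be Euclidean — are clamped to
#' zero with a warning, and missing trailing dimensions are zero-padded.
#' Each output dimension is deterministically oriented so that its
#' largest-magnitude coordinate is positive.
#'
#' @param dm an `mi_dissimilarity`, `dist`, or symmetric matrix with zero
#'   diagonal; all entries must be finite
#' @param k target dimension, `1 <= k <= n - 1`
#' @return object of class `"mi_embedding"`: list(labels, coordinates
#'   (n x k, column-centered), eigenvalues (descending), k)
#' @export
cmds_embed <- function(dm, k = 1) {
  if (inherits(dm, "mi_dissimilarity")) dm <- dm$d
  dm <- as.matrix(dm)
  if (!isSymmetric(unname(dm), tol = 1e-8))
    stop("dissimilarity matrix must be symmetric")
  if (any(!is.finite(dm)))
    stop("dissimilarity matrix contains non-finite entries")
  n <- nrow(dm)
  if (k < 1 || k > n - 1) stop("k must be between 1 and n - 1")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  fit <- suppressWarnings(stats::cmdscale(dm, k = k, eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  if (any(eig < -1e-8 * max(abs(eig))))
    warning("negative eigenvalues clamped to zero (non-Euclidean dissimilarity)")
  pts <- fit$points
  if (is.null(pts) || ncol(pts) < k) {  # degenerate spectra: pad zeros
    pad <- matrix(0, n, k - if (is.null(pts)) 0 else ncol(pts))
    pts <- cbind(pts, pad)
  }
  pts <- pts[, seq_len(k), drop = FALSE]
  pts <- sweep(pts, 2, colMeans(pts))
  for (j in seq_len(k)) {
    i_star <- which.max(abs(pts[, j]))
    if (pts[i_star, j] < 0) pts[, j] <- -pts[, j]
  }
  dimnames(pts) <- list(labels, paste0("dim", seq_len(k)))
  structure(list(labels = labels, coordinates = pts,
                 eigenvalues = pmax(eig, 0), k = k),
            class = "mi_embedding")
}

#' @export
print.mi_embedding <- function(x, ...) {
  cat(sprintf("CMDS embedding: %d points in %d dimension(s)\n",
              length(x$labels), x$k))
  ev <- x$eigenvalues[x$eigenvalues > 0]
  cat("  leading eigenvalues:",
      paste(sprintf("%.3f", utils::head(ev, 4)), collapse = ", "), "\n")
  invisible(x)
}

#' Plot a CMDS embedding
#' @param x an `mi_embedding`
#' @param dims which dimensions to plot (1 or 2 of them)
#' @param ... passed to [graphics::plot()]
#' @export
plot.mi_embedding <- function(x, dims = seq_len(min(2, x$k)), ...) {
  co <- x$coordinates
  if (length(dims) == 1) {
    graphics::plot(co[, dims], rep(0, nrow(co)), yaxt = "n", ylab = "",
                   xlab = colnames(co)[dims], pch = 19, ...)
    graphics::text(co[, dims], 0.1, labels = x$labels, srt = 90, adj = 0,
                   xpd = NA, cex = 0.7)
  } else {
    graphics::plot(co[, dims[1]], co[, dims[2]], xlab = colnames(co)[dims[1]],
                   ylab = colnames(co)[dims[2]], pch = 19, ...)
    graphics::text(co[, dims[1]], co[, dims[2]], labels = x$labels,
                   pos = 3, cex = 0.7)
  }
  invisible(x)
}

#' One-dimensional MI ordering of all sample columns
#'
#' Builds the full-transcriptome inverse-MI dissimilarity matrix, embeds it
#' with CMDS at k = 1, and orients the axis so the tumor-role group's mean
#' coordinate is positive. Mirrors the global one-dimensional layout in which
#' redirected replicates sit near normal replicates and away from tumor.
#'
#' @param g a `gem`
#' @param scheme a [disc_scheme()]
#' @return data.frame (sample, group, coord) sorted by coordinate
#' @export
order_samples_1d <- function(g, scheme = disc_scheme()) {
  dm <- build_dissimilarity(g, probes = NULL, scheme = scheme)
  emb <- cmds_embed(dm, k = 1)
  coord <- emb$coordinates[, 1]
  tumor <- g$roles[["tumor"]]
  if (mean(coord[g$groups[emb$labels] == tumor]) < 0) coord <- -coord
  out <- data.frame(sample = emb$labels,
                    group = unname(g$groups[emb$labels]),
                    coord = unname(coord), stringsAsFactors = FALSE)
  out <- out[order(out$coord), ]
  rownames(out) <- NULL
  out
}
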