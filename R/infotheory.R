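#' Discretization scheme for log2 intensities
#'
#' Expression values are binned before any entropy or mutual-information
#' calculation. The default scheme uses unit-width bins on the log2 scale,
#' anchored at the floored global minimum of the data: with the usual post-RMA
#' range of roughly 3.6 to 14 log2 units this yields on the order of 11
#' occupied states, so the maximum-entropy ceiling `log2(n)` for a set of n
#' genes tracks the dynamic range of the data. A fixed-bin alternative
#' partitions the observed global range into `n_bins` equal-width bins.
#'
#' @param kind `"unit_width"` (default) or `"fixed_bins"`
#' @param bin_width bin width in log2 units (unit_width)
#' @param n_bins number of bins (fixed_bins; >= 2)
#' @param origin left edge of the first bin; if `NULL`, set from the data at
#'   first use (floored global minimum for unit_width, exact minimum for
#'   fixed_bins)
#' @param range_width width of the partitioned range (fixed_bins; if `NULL`,
#'   set from the data)
#' @return object of class `"disc_scheme"`
#' @export
disc_scheme <- function(kind = c("unit_width", "fixed_bins"), bin_width = 1,
                        n_bins = NULL, origin = NULL, range_width = NULL) {
  kind <- match.arg(kind)
  if (kind == "unit_width") {
    if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  } else {
    if (is.null(n_bins) || n_bins < 2) stop("fixed_bins needs n_bins >= 2")
  }
  structure(list(kind = kind, bin_width = bin_width, n_bins = n_bins,
                 origin = origin, range_width = range_width),
            class = "disc_scheme")
}

#' Anchor a discretization scheme on a GEM's global data range
#' @param g a `gem`
#' @param scheme a `disc_scheme` (default: unit-width bins)
#' @return the scheme with `origin` (and, for fixed bins, `range_width`) set
#' @export
anchor_scheme <- function(g, scheme = disc_scheme()) {
  lo <- min(g$values); hi <- max(g$values)
  if (is.null(scheme$origin))
    scheme$origin <- if (scheme$kind == "unit_width") floor(lo) else lo
  if (scheme$kind == "fixed_bins" && is.null(scheme$range_width))
    scheme$range_width <- hi - scheme$origin
  scheme
}

#' Discretize values into bin indices
#'
#' Unit-width: `floor((value - origin)/bin_width)`. Fixed-bins: equal-width
#' partition of the anchored range into `n_bins` bins, with boundary values
#' assigned to the right-closed last bin. Deterministic given scheme + value.
#'
#' @param values finite numeric vector of log2 intensities
#' @param scheme a `disc_scheme`
#' @return integer vector of 0-based bin indices
#' @export
discretize <- function(values, scheme = disc_scheme()) {
  if (any(!is.finite(values))) stop("values must be finite")
  origin <- scheme$origin
  if (is.null(origin))
    origin <- if (scheme$kind == "unit_width") floor(min(values)) else min(values)
  if (scheme$kind == "unit_width") {
    as.integer(floor((values - origin) / scheme$bin_width))
  } else {
    rw <- scheme$range_width
    if (is.null(rw)) rw <- max(values) - origin
    if (rw <= 0) return(integer(length(values)))
    idx <- floor((values - origin) / (rw / scheme$n_bins))
    as.integer(pmin(pmax(idx, 0), scheme$n_bins - 1L))
  }
}

#' Shannon entropy of a discrete vector, in bits
#'
#' Plug-in (maximum-likelihood) estimate `H = -sum p_k log2 p_k` over the
#' empirical bin frequencies, with `0 log 0 = 0`.
#'
#' @param bins vector of bin indices (any discrete labels)
#' @return entropy in bits
#' @export
shannon_entropy <- function(bins) {
  if (!length(bins)) stop("entropy of an empty vector is undefined")
  p <- tabulate(match(bins, unique(bins)))
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Mutual information between two discrete vectors, in bits
#'
#' Plug-in estimate `MI = H(X) + H(Y) - H(X,Y)` from the empirical joint
#' frequencies, clamped at 0 against negative floating-point residue. No bias
#' correction is applied.
#'
#' @param x_bins,y_bins equal-length discrete vectors
#' @return mutual information in bits
#' @export
mutual_information <- function(x_bins, y_bins) {
  if (length(x_bins) != length(y_bins))
    stop("x and y must have equal length")
  if (!length(x_bins)) stop("mutual information of empty vectors is undefined")
  xi <- match(x_bins, unique(x_bins))
  yi <- match(y_bins, unique(y_bins))
  joint <- (xi - 1L) * max(yi) + yi
  mi <- shannon_entropy(xi) + shannon_entropy(yi) - shannon_entropy(joint)
  max(mi, 0)
}

#' Maximum entropy for a set of n genes, in bits
#'
#' `log2(n)`: the ceiling on entropy (and hence on MI) of a length-n vector
#' under discrete estimation.
#'
#' @param n set size (>= 1)
#' @return bits
#' @export
max_entropy <- function(n) {
  if (!is.numeric(n) || n < 1) stop("set size must be >= 1")
  log2(n)
}

#' Inverse-MI dissimilarity
#'
#' Maximum entropy for the set size divided by the MI value. An MI of zero
#' maps to `Inf`, which sorts above every finite distance; callers embedding
#' such distances must resolve the sentinel first.
#'
#' @param mi mutual information in bits (>= 0)
#' @param n set size
#' @return dimensionless dissimilarity (>= 1 whenever `mi <= log2(n)`)
#' @export
mi_dissimilarity <- function(mi, n) {
  if (mi < 0) stop("mi must be >= 0")
  me <- max_entropy(n)
  if (mi == 0) return(if (me == 0) 0 else Inf)
  me / mi
}

#' Mutual information between two cell groups over a probe set
#'
#' Restricts the GEM to the given probes, discretizes each replicate column
#' under one shared scheme, and aggregates over replicates:
#' `"pairwise_mean"` (default) averages MI over all cross-group replicate
#' column pairs; `"concatenate"` stacks each group's replicate columns into
#' one long vector and computes a single MI (requires equal replicate counts).
#' With a single replicate per group the two aggregations coincide.
#'
#' @param g a `gem`
#' @param probes non-empty character vector of probe ids present in `g`
#' @param group1,group2 group labels
#' @param scheme a `disc_scheme`; anchored on `g` if unanchored
#' @param aggregation `"pairwise_mean"` or `"concatenate"`
#' @return mutual information in bits
#' @export
group_mi <- function(g, probes, group1, group2, scheme = disc_scheme(),
                     aggregation = c("pairwise_mean", "concatenate")) {
  aggregation <- match.arg(aggregation)
  if (!length(probes)) stop("empty probe set")
  missing <- setdiff(probes, rownames(g$values))
  if (length(missing))
    stop("probes absent from GEM: ", paste(missing[1:min(3, length(missing))],
                                           collapse = ", "))
  scheme <- anchor_scheme(g, scheme)
  s1 <- group_samples(g, group1)
  s2 <- group_samples(g, group2)
  sub <- g$values[probes, , drop = FALSE]
  bins <- vapply(colnames(sub), function(s) discretize(sub[, s], scheme),
                 integer(nrow(sub)))
  bins <- matrix(bins, nrow = nrow(sub),
                 dimnames = list(probes, colnames(sub)))
  if (aggregation == "pairwise_mean") {
    mis <- outer(seq_along(s1), seq_along(s2),
                 Vectorize(function(i, j)
                   mutual_information(bins[, s1[i]], bins[, s2[j]])))
    mean(mis)
  } else {
    if (length(s1) != length(s2))
      stop("concatenate aggregation needs equal replicate counts")
    mutual_information(as.vector(bins[, s1]), as.vector(bins[, s2]))
  }
}
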