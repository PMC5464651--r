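#' Configuration for the MI-ratio signature screen
#'
#' @param min_set_size smallest projected probe count a signature needs to be
#'   tested (default 11: sets of 10 or fewer members are too small for a
#'   reliable MI estimate when the discretized data occupy about 11 states)
#' @param familywise_alpha family-wise error target for the Bonferroni
#'   correction (default 0.01)
#' @param null_model `"gaussian_fit"` (default): upper-tail probability under
#'   a normal fitted to all testable ratios; `"empirical"`:
#'   `(1 + #\{ratios >= r\}) / (1 + N)`
#' @param roles contrast roles (normal, redirected, tumor); `NULL` uses the
#'   roles stored in the GEM
#' @param scheme a [disc_scheme()]; anchored on the GEM at fit time
#' @param aggregation replicate aggregation for group-level MI, see
#'   [group_mi()]
#' @return object of class `"screen_config"`
#' @export
screen_config <- function(min_set_size = 11, familywise_alpha = 0.01,
                          null_model = c("gaussian_fit", "empirical"),
                          roles = NULL, scheme = disc_scheme(),
                          aggregation = c("pairwise_mean", "concatenate")) {
  if (familywise_alpha <= 0 || familywise_alpha >= 1)
    stop("familywise_alpha must be in (0, 1)")
  if (min_set_size < 2) stop("min_set_size must be >= 2")
  structure(list(min_set_size = min_set_size,
                 familywise_alpha = familywise_alpha,
                 null_model = match.arg(null_model),
                 roles = roles, scheme = scheme,
                 aggregation = match.arg(aggregation)),
            class = "screen_config")
}

#' Per-test Bonferroni threshold
#'
#' The family-wise alpha divided by the number of signatures actually tested
#' (those passing the size filter with a defined, nonzero MI ratio).
#'
#' @param familywise_alpha family-wise error target
#' @param n_tested number of testable signatures
#' @return per-test p-value threshold
#' @export
bonferroni_threshold <- function(familywise_alpha, n_tested) {
  if (n_tested < 1) stop("n_tested must be >= 1")
  familywise_alpha / n_tested
}

#' Score one signature by its MI ratio
#'
#' Computes `ratio = MI(normal, redirected) / MI(redirected, tumor)` over the
#' signature's projected probes. Signatures smaller than `min_set_size` are
#' excluded (`too_small`); a zero numerator excludes the signature
#' (`zero_ratio`), and a zero denominator with positive numerator is
#' `undefined_ratio` (kept out of the null distribution rather than treated
#' as infinite).
#'
#' @param g a `gem`
#' @param sig a projected `signature`
#' @param cfg a [screen_config()]
#' @return one-row data.frame: signature, n_probes, mi_AE, mi_EB, ratio,
#'   excluded_reason
#' @export
score_signature <- function(g, sig, cfg = screen_config()) {
  roles <- if (is.null(cfg$roles)) g$roles else
    check_roles(cfg$roles, unique(g$groups))
  scheme <- anchor_scheme(g, cfg$scheme)
  res <- data.frame(signature = sig$name, n_probes = length(sig$probes),
                    mi_AE = NA_real_, mi_EB = NA_real_, ratio = NA_real_,
                    excluded_reason = "none", stringsAsFactors = FALSE)
  if (length(sig$probes) < cfg$min_set_size) {
    res$excluded_reason <- "too_small"
    return(res)
  }
  res$mi_AE <- group_mi(g, sig$probes, roles[["normal"]],
                        roles[["redirected"]], scheme, cfg$aggregation)
  res$mi_EB <- group_mi(g, sig$probes, roles[["redirected"]],
                        roles[["tumor"]], scheme, cfg$aggregation)
  if (res$mi_AE == 0) {
    res$excluded_reason <- "zero_ratio"
  } else if (res$mi_EB == 0) {
    res$excluded_reason <- "undefined_ratio"
  } else {
    res$ratio <- res$mi_AE / res$mi_EB
  }
  res
}

#' Screen a signature database by MI ratio
#'
#' The central fit: every signature is scored by
#' `MI(normal, redirected) / MI(redirected, tumor)` over its projected
#' probes; the testable (non-excluded) ratios form the null distribution;
#' per-signature p-values come from the configured null model, and
#' signatures with `p <= familywise_alpha / N_tested` are called significant.
#'
#' @param g a `gem`
#' @param sigs list of projected `signature` objects
#' @param cfg a [screen_config()]
#' @return an object of class `"mi_screen"` with components `results` (one
#'   row per input signature, sorted by descending ratio, ties broken by
#'   name), `null_mean`, `null_sd`, `n_tested`, `per_test_alpha`,
#'   `ratio_cutoff` (Gaussian null only), and `config`
#' @seealso [ratio_threshold_from_alpha()], [score_signature()]
#' @export
mi_screen <- function(g, sigs, cfg = screen_config()) {
  if (inherits(sigs, "signature")) sigs <- list(sigs)
  rows <- lapply(sigs, score_signature, g = g, cfg = cfg)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  testable <- res$excluded_reason == "none"
  n_tested <- sum(testable)
  if (n_tested < 2)
    stop("need at least 2 testable signatures to model the null distribution")
  ratios <- res$ratio[testable]
  mu <- mean(ratios); sdv <- stats::sd(ratios)
  res$p_value <- NA_real_
  if (cfg$null_model == "gaussian_fit") {
    if (sdv > 0)
      res$p_value[testable] <- stats::pnorm(ratios, mu, sdv, lower.tail = FALSE)
  } else {
    res$p_value[testable] <- vapply(ratios, function(r)
      (1 + sum(ratios >= r)) / (1 + n_tested), numeric(1))
  }
  per_test <- bonferroni_threshold(cfg$familywise_alpha, n_tested)
  res$significant <- !is.na(res$p_value) & res$p_value <= per_test
  ord <- order(-ifelse(is.na(res$ratio), -Inf, res$ratio), res$signature)
  res <- res[ord, c("signature", "n_probes", "mi_AE", "mi_EB", "ratio",
                    "p_value", "significant", "excluded_reason")]
  rownames(res) <- NULL
  cutoff <- if (cfg$null_model == "gaussian_fit" && sdv > 0)
    mu + sdv * stats::qnorm(1 - per_test) else NA_real_
  structure(list(results = res, null_mean = mu, null_sd = sdv,
                 n_tested = n_tested, per_test_alpha = per_test,
                 ratio_cutoff = cutoff, config = cfg,
                 call = match.call()),
            class = "mi_screen")
}

#' MI-ratio cutoff implied by the Bonferroni threshold
#'
#' Inverts the fitted Gaussian null: the ratio whose upper-tail probability
#' equals the per-test Bonferroni threshold, i.e. the lowest ratio that can
#' be called significant.
#'
#' @param results the `results` data.frame of an [mi_screen()] fit (or an
#'   `mi_screen` object)
#' @param cfg the [screen_config()] used (ignored when `results` is an
#'   `mi_screen` object)
#' @return dimensionless ratio cutoff
#' @export
ratio_threshold_from_alpha <- function(results, cfg = screen_config()) {
  if (inherits(results, "mi_screen")) {
    cfg <- results$config
    results <- results$results
  }
  if (cfg$null_model != "gaussian_fit")
    stop("ratio cutoff is defined for the gaussian_fit null model")
  ratios <- results$ratio[results$excluded_reason == "none"]
  if (length(ratios) < 2) stop("need >= 2 testable ratios")
  sdv <- stats::sd(ratios)
  if (sdv == 0) stop("degenerate null: all testable ratios are equal")
  per_test <- bonferroni_threshold(cfg$familywise_alpha, length(ratios))
  mean(ratios) + sdv * stats::qnorm(1 - per_test)
}

#' @export
print.mi_screen <- function(x, n = 6, ...) {
  r <- x$results
  cat("MI-ratio signature screen\n")
  cat(sprintf("  %d signatures: %d tested, %d excluded (%s)\n",
              nrow(r), x$n_tested, sum(r$excluded_reason != "none"),
              paste(names(table(r$excluded_reason[r$excluded_reason != "none"])),
                    collapse = "/")))
  cat(sprintf("  null ratio: mean %.3f, sd %.3f (%s)\n",
              x$null_mean, x$null_sd, x$config$null_model))
  cat(sprintf("  per-test Bonferroni threshold: %.4g (alpha %.3g / %d)\n",
              x$per_test_alpha, x$config$familywise_alpha, x$n_tested))
  if (is.finite(x$ratio_cutoff))
    cat(sprintf("  lowest significant MI ratio: %.3f\n", x$ratio_cutoff))
  cat(sprintf("  significant signatures: %d\n", sum(r$significant)))
  top <- utils::head(r[r$excluded_reason == "none", ], n)
  if (nrow(top)) {
    cat("  top ratios:\n")
    print(top[, c("signature", "n_probes", "ratio", "p_value", "significant")],
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
summary.mi_screen <- function(object, ...) {
  r <- object$results
  out <- list(n_signatures = nrow(r), n_tested = object$n_tested,
              excluded = table(r$excluded_reason[r$excluded_reason != "none"]),
              null_mean = object$null_mean, null_sd = object$null_sd,
              per_test_alpha = object$per_test_alpha,
              ratio_cutoff = object$ratio_cutoff,
              n_significant = sum(r$significant),
              significant = r[r$significant, ])
  class(out) <- "summary.mi_screen"
  out
}

#' @export
print.summary.mi_screen <- function(x, ...) {
  cat(sprintf("Signature screen: %d input, %d tested, %d significant\n",
              x$n_signatures, x$n_tested, x$n_significant))
  cat(sprintf("Fitted null: mean %.3f sd %.3f; per-test alpha %.4g; ratio cutoff %.3f\n",
              x$null_mean, x$null_sd, x$per_test_alpha, x$ratio_cutoff))
  if (nrow(x$significant)) {
    cat("Significant signatures:\n")
    print(x$significant[, c("signature", "n_probes", "ratio", "p_value")],
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
coef.mi_screen <- function(object, ...) {
  r <- object$results[object$results$excluded_reason == "none", ]
  stats::setNames(r$ratio, r$signature)
}

#' @export
as.data.frame.mi_screen <- function(x, ...) x$results

#' Plot the MI-ratio distribution of a screen
#'
#' Histogram of testable ratios with the fitted Gaussian null, the ratio
#' cutoff, and a rug of significant signatures.
#'
#' @param x an `mi_screen`
#' @param ... passed to [graphics::hist()]
#' @export
plot.mi_screen <- function(x, ...) {
  r <- x$results[x$results$excluded_reason == "none", ]
  h <- graphics::hist(r$ratio, breaks = "FD", freq = FALSE,
                      main = "MI ratio distribution",
                      xlab = "MI(normal, redirected) / MI(redirected, tumor)",
                      ...)
  xx <- seq(min(r$ratio), max(r$ratio), length.out = 200)
  graphics::lines(xx, stats::dnorm(xx, x$null_mean, x$null_sd), col = "grey40")
  if (is.finite(x$ratio_cutoff))
    graphics::abline(v = x$ratio_cutoff, col = "red", lty = 2)
  if (any(r$significant))
    graphics::rug(r$ratio[r$significant], col = "red", lwd = 2)
  invisible(h)
}
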