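## Moderated two-sample t with empirical-Bayes variance shrinkage.
##
## Per-probe pooled variances s2 (df dg) are modeled as draws from a scaled
## F around a prior variance s0^2 with prior df d0; (d0, s0^2) are estimated
## by moment matching on log(s2): for z = log(s2),
##   Var(z) = trigamma(dg/2) + trigamma(d0/2)
##   E(z)   = log(s0^2) + digamma(dg/2) - digamma(d0/2) - log(dg/2) + log(d0/2)
## The posterior variance (d0*s0^2 + dg*s2)/(d0+dg) replaces s2 in the t
## statistic, which gains d0 extra degrees of freedom.

trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

fit_variance_prior <- function(s2, dg) {
  ok <- s2 > 0
  if (!any(ok)) return(list(d0 = Inf, s0_sq = 0))
  z <- log(s2[ok])
  if (length(z) < 2) return(list(d0 = Inf, s0_sq = exp(z[1])))
  evar <- stats::var(z) - trigamma(dg / 2)
  base <- mean(z) - digamma(dg / 2) + log(dg / 2)
  if (evar <= 0) {
    ## no excess dispersion beyond chi-square sampling noise: variances are
    ## effectively common, and the mean sample variance estimates it
    list(d0 = Inf, s0_sq = mean(s2[ok]))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    list(d0 = d0, s0_sq = exp(base + digamma(d0 / 2) - log(d0 / 2)))
  }
}

#' Two-group differential expression per probe
#'
#' Moderated two-sample t-statistic with empirical-Bayes variance shrinkage
#' (prior variance and prior degrees of freedom estimated by moment matching
#' on the per-probe log sample variances), p-values from the t distribution
#' with augmented degrees of freedom, and Benjamini-Hochberg adjustment over
#' all probes in the contrast. A plain Welch t-test is available as a
#' cross-check. Sign convention: `log_fc = mean(group1) - mean(group2)`.
#'
#' @param g a `gem`
#' @param group1,group2 group labels, each with >= 2 replicate columns
#' @param method `"moderated"` (default) or `"welch"`
#' @param adjust p-adjustment method (default `"BH"`; any
#'   [stats::p.adjust()] method)
#' @return data.frame of class `"de_result"` with columns probe_id, log_fc,
#'   t_stat, p_value, p_adj, and attributes `contrast`, `prior_df`,
#'   `prior_var`
#' @export
de_contrast <- function(g, group1, group2,
                        method = c("moderated", "welch"), adjust = "BH") {
  method <- match.arg(method)
  x1 <- g$values[, group_samples(g, group1), drop = FALSE]
  x2 <- g$values[, group_samples(g, group2), drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 2 || n2 < 2)
    stop("each group needs >= 2 replicates (got ", n1, " and ", n2, ")")
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  log_fc <- m1 - m2
  ss1 <- rowSums((x1 - m1)^2); ss2 <- rowSums((x2 - m2)^2)
  prior <- list(d0 = NA_real_, s0_sq = NA_real_)
  if (method == "moderated") {
    dg <- n1 + n2 - 2
    s2 <- (ss1 + ss2) / dg
    prior <- fit_variance_prior(s2, dg)
    s2_post <- if (is.infinite(prior$d0)) rep(prior$s0_sq, length(s2)) else
      (prior$d0 * prior$s0_sq + dg * s2) / (prior$d0 + dg)
    se <- sqrt(s2_post * (1 / n1 + 1 / n2))
    ## total df capped at the pooled residual df across all probes
    df <- min(dg + prior$d0, dg * length(s2))
    t_stat <- ifelse(se > 0, log_fc / se, ifelse(log_fc == 0, 0, Inf * sign(log_fc)))
    p <- 2 * stats::pt(-abs(t_stat), df = df)
  } else {
    v1 <- ss1 / (n1 - 1); v2 <- ss2 / (n2 - 1)
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    t_stat <- ifelse(se > 0, log_fc / se, ifelse(log_fc == 0, 0, Inf * sign(log_fc)))
    p <- ifelse(se > 0, 2 * stats::pt(-abs(t_stat), df = df),
                ifelse(log_fc == 0, 1, 0))
    p[se > 0 & is.na(p)] <- 1
  }
  p[!is.finite(t_stat) & log_fc != 0] <- 0
  p[t_stat == 0] <- 1
  out <- data.frame(probe_id = rownames(g$values), log_fc = unname(log_fc),
                    t_stat = unname(t_stat), p_value = unname(p),
                    p_adj = stats::p.adjust(unname(p), method = adjust),
                    stringsAsFactors = FALSE)
  attr(out, "contrast") <- c(group1, group2)
  attr(out, "prior_df") <- prior$d0
  attr(out, "prior_var") <- prior$s0_sq
  class(out) <- c("de_result", "data.frame")
  out
}

#' Select core biomarker genes from significant signatures
#'
#' The core rule: a candidate gene (member of at least one significant
#' signature) is a core biomarker when it is differentially expressed in both
#' tumor contrasts but not between normal and redirected — concretely, at
#' least one of its probes has `p_adj < alpha_adj` in normal-vs-tumor AND
#' redirected-vs-tumor while having `p_adj >= alpha_adj` in
#' normal-vs-redirected, and none of its probes is significant in
#' normal-vs-redirected ("any-qualifying, none-contradicting" probe-to-gene
#' collapse).
#'
#' @param de_AE normal-vs-redirected [de_contrast()] result
#' @param de_AB normal-vs-tumor result
#' @param de_EB redirected-vs-tumor result (all three over the same probe
#'   universe)
#' @param sigs list of significant `signature` objects (the candidate
#'   universe is the union of their gene symbols)
#' @param map a `probe_gene_map`
#' @param alpha_adj adjusted-p cutoff (default 0.0001)
#' @return object of class `"core_biomarkers"`: list(gene_symbols, probe_ids
#'   (qualifying probes), source_signatures (gene -> signature names),
#'   added_by_extension, alpha_adj)
#' @export
select_core_genes <- function(de_AE, de_AB, de_EB, sigs, map,
                              alpha_adj = 1e-4) {
  if (!identical(de_AE$probe_id, de_AB$probe_id) ||
      !identical(de_AE$probe_id, de_EB$probe_id))
    stop("the three contrasts must share one probe universe")
  if (inherits(sigs, "signature")) sigs <- list(sigs)
  candidates <- unique(unlist(lapply(sigs, `[[`, "genes")))
  sig_of_gene <- lapply(stats::setNames(candidates, candidates), function(gn)
    unlist(lapply(sigs, function(s) if (gn %in% s$genes) s$name else NULL)))
  p_AE <- stats::setNames(de_AE$p_adj, de_AE$probe_id)
  p_AB <- stats::setNames(de_AB$p_adj, de_AB$probe_id)
  p_EB <- stats::setNames(de_EB$p_adj, de_EB$probe_id)
  universe <- de_AE$probe_id
  core_genes <- character(); core_probes <- character()
  for (gn in candidates) {
    pr <- intersect(probes_for_genes(map, gn), universe)
    if (!length(pr)) next
    qualifies <- p_AB[pr] < alpha_adj & p_EB[pr] < alpha_adj &
      p_AE[pr] >= alpha_adj
    contradicted <- any(p_AE[pr] < alpha_adj)
    if (any(qualifies) && !contradicted) {
      core_genes <- c(core_genes, gn)
      core_probes <- c(core_probes, pr[qualifies])
    }
  }
  structure(list(gene_symbols = core_genes,
                 probe_ids = unique(core_probes),
                 source_signatures = sig_of_gene[core_genes],
                 added_by_extension = character(),
                 alpha_adj = alpha_adj),
            class = "core_biomarkers")
}

#' @export
print.core_biomarkers <- function(x, ...) {
  cat(sprintf("Core biomarker set: %d genes (%d probes) at adjusted p < %g\n",
              length(x$gene_symbols), length(x$probe_ids), x$alpha_adj))
  if (length(x$added_by_extension))
    cat("  added by interaction extension:",
        paste(x$added_by_extension, collapse = ", "), "\n")
  invisible(x)
}
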