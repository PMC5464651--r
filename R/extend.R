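#' Extend a signature with interacting, differentially expressed genes
#'
#' Candidate genes are the one-hop interaction neighbors (any kind, optional
#' minimum weight) of the signature's members that are not already members.
#' A candidate is added when at least one of its probes has adjusted
#' `p < alpha_adj` in BOTH tumor contrasts (normal-vs-tumor and
#' redirected-vs-tumor). The returned signature keeps all original members,
#' carries `provenance = "extended"`, and is re-projected onto the GEM.
#'
#' @param sig a projected `signature`
#' @param interactions an `interaction_table`
#' @param de_AB normal-vs-tumor [de_contrast()] result
#' @param de_EB redirected-vs-tumor result (same probe universe)
#' @param map a `probe_gene_map`
#' @param g the `gem` (for re-projection)
#' @param alpha_adj adjusted-p stringency (default 0.0001)
#' @param min_weight minimum interaction weight to count as evidence
#' @return the extended `signature`
#' @export
extend_signature <- function(sig, interactions, de_AB, de_EB, map, g,
                             alpha_adj = 1e-4, min_weight = 0) {
  if (!identical(de_AB$probe_id, de_EB$probe_id))
    stop("the two contrasts must share one probe universe")
  cand <- interaction_neighbors(interactions, sig$genes,
                                min_weight = min_weight)
  p_AB <- stats::setNames(de_AB$p_adj, de_AB$probe_id)
  p_EB <- stats::setNames(de_EB$p_adj, de_EB$probe_id)
  keep <- vapply(cand, function(gn) {
    pr <- intersect(probes_for_genes(map, gn), de_AB$probe_id)
    length(pr) > 0 && any(p_AB[pr] < alpha_adj & p_EB[pr] < alpha_adj)
  }, logical(1))
  added <- cand[keep]
  out <- signature_set(sig$name, sig$description, c(sig$genes, added),
                       provenance = "extended")
  project_signature(out, map, g)
}

#' Compare MI ratios of an original and an extended signature
#'
#' Scores both signatures under one screen configuration and reports the
#' change. Errors if either set fails the size filter or has an undefined
#' ratio.
#'
#' @param g a `gem`
#' @param original,extended projected `signature` objects
#' @param cfg a [screen_config()]
#' @param stringency the adjusted-p cutoff used for the extension (recorded
#'   in the report)
#' @return one-row data.frame: signature, stringency, original_ratio,
#'   extended_ratio, n_added, genes_added (comma-joined), improved
#' @export
compare_ratios <- function(g, original, extended, cfg = screen_config(),
                           stringency = NA_real_) {
  s1 <- score_signature(g, original, cfg)
  s2 <- score_signature(g, extended, cfg)
  if (s1$excluded_reason != "none")
    stop("original signature '", original$name, "' excluded: ",
         s1$excluded_reason)
  if (s2$excluded_reason != "none")
    stop("extended signature '", extended$name, "' excluded: ",
         s2$excluded_reason)
  added <- setdiff(extended$genes, original$genes)
  data.frame(signature = original$name, stringency = stringency,
             original_ratio = s1$ratio, extended_ratio = s2$ratio,
             n_added = length(added),
             genes_added = paste(added, collapse = ","),
             improved = s2$ratio > s1$ratio,
             stringsAsFactors = FALSE)
}

#' Extension sweep over signatures and stringency levels
#'
#' Runs [extend_signature()] and [compare_ratios()] for every combination of
#' signature and adjusted-p stringency, one report row each.
#'
#' @param g a `gem`
#' @param sigs list of projected `signature` objects (typically the
#'   significant ones)
#' @param interactions an `interaction_table`
#' @param de_AB,de_EB tumor-contrast [de_contrast()] results
#' @param map a `probe_gene_map`
#' @param stringencies vector of adjusted-p cutoffs (default 0.0001)
#' @param cfg a [screen_config()]
#' @param min_weight minimum interaction weight
#' @return data.frame with one row per (signature, stringency)
#' @export
extension_sweep <- function(g, sigs, interactions, de_AB, de_EB, map,
                            stringencies = 1e-4, cfg = screen_config(),
                            min_weight = 0) {
  if (inherits(sigs, "signature")) sigs <- list(sigs)
  rows <- list()
  for (s in sigs) {
    for (a in stringencies) {
      ext <- extend_signature(s, interactions, de_AB, de_EB, map, g,
                              alpha_adj = a, min_weight = min_weight)
      rows[[length(rows) + 1L]] <- compare_ratios(g, s, ext, cfg,
                                                  stringency = a)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
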