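#' Configuration for the synthetic six-group expression simulator
#'
#' The generator emulates the study design the screen targets: six cell
#' groups (normal A; tumor B; intermediates C, D, F; redirected E), three
#' replicate columns per group, log2 intensities in roughly the 3.6-14 range,
#' weakly bimodal pooled value distributions for normal/redirected groups and
#' unimodal for tumor groups, and planted redirection signatures whose member
#' genes co-vary so that the normal and redirected groups match while the
#' tumor group differs.
#'
#' Each probe gets a baseline mean drawn from a two-component Gaussian
#' mixture (components at the low/high thirds of `value_range`). In
#' tumor-role groups, unplanted high-mode probes drift down by half the
#' inter-mode gap, which merges the pooled distribution into a single peak;
#' planted probes instead take a mean-preserving, variance-shrunk permutation
#' of their member means shifted down by `planted_effect` — the permutation
#' destroys the probe-to-probe correspondence between tumor and
#' normal/redirected columns (a constant shift alone would leave mutual
#' information unchanged) while keeping the mean shift exactly
#' `-planted_effect`. Intermediate groups interpolate the drift and the
#' planted shift at `intermediate_mix` without scrambling.
#'
#' @param n_probes number of probes (default 2000)
#' @param n_replicates replicate columns per group (default 3)
#' @param groups group labels (default A-F)
#' @param value_range log2 bounds; generated values are truncated to it
#' @param bimodal_groups groups with bimodal pooled distributions
#' @param unimodal_groups groups with unimodal pooled distributions (receive
#'   the full tumor drift)
#' @param mode_sd per-mode sd of probe baseline means (log2 units)
#' @param mode_weight probability a probe belongs to the high mode
#' @param n_signatures number of null (unplanted) signatures
#' @param signature_size (min, max) member gene counts for null signatures
#' @param n_planted number of planted redirection signatures
#' @param planted_size member gene count of each planted signature
#' @param planted_effect mean log2 down-shift of planted genes in the tumor
#'   role group (> 0)
#' @param tumor_shrink variance shrink factor applied to planted tumor means
#' @param tumor_drift down-shift of unplanted high-mode probes in tumor-role
#'   groups; `NULL` = half the inter-mode gap; set 0 for a global-null design
#' @param intermediate_mix interpolation coefficient for groups that are
#'   neither normal/redirected nor fully tumor-like
#' @param n_extension_per_planted tumor-shifted genes outside each planted
#'   signature, linked to it in the interaction table (extension truth)
#' @param noise_sd replicate noise sd (log2 units)
#' @param multiprobe_fraction fraction of genes carrying two probes
#' @param roles contrast roles (normal, redirected, tumor group labels)
#' @param seed integer seed; identical seeds give bit-identical bundles
#' @return object of class `"sim_config"`
#' @export
sim_config <- function(n_probes = 2000, n_replicates = 3,
                       groups = LETTERS[1:6],
                       value_range = c(3.582, 14.052),
                       bimodal_groups = c("A", "C", "D", "E"),
                       unimodal_groups = c("B", "F"),
                       mode_sd = 1.0, mode_weight = 0.5,
                       n_signatures = 200, signature_size = c(11, 50),
                       n_planted = 5, planted_size = 50,
                       planted_effect = 3.0, tumor_shrink = 0.5,
                       tumor_drift = NULL, intermediate_mix = 0.5,
                       n_extension_per_planted = 3,
                       noise_sd = 0.3, multiprobe_fraction = 0.1,
                       roles = c(normal = "A", redirected = "E", tumor = "B"),
                       seed = 1) {
  if (length(intersect(bimodal_groups, unimodal_groups)))
    stop("bimodal and unimodal group sets must be disjoint")
  if (value_range[1] >= value_range[2]) stop("value_range must have low < high")
  if (n_probes < 1 || n_replicates < 1 || n_signatures < 0)
    stop("counts must be >= 1 (signatures >= 0)")
  if (n_planted > 0 && planted_effect <= 0)
    stop("planted_effect must be > 0 when signatures are planted")
  if (n_planted * max(planted_size, signature_size[2]) > n_probes)
    stop("n_planted x maximum signature size exceeds n_probes")
  if (!all(c(bimodal_groups, unimodal_groups) %in% groups))
    stop("bimodal/unimodal groups must be drawn from 'groups'")
  structure(list(n_probes = n_probes, n_replicates = n_replicates,
                 groups = groups, value_range = value_range,
                 bimodal_groups = bimodal_groups,
                 unimodal_groups = unimodal_groups,
                 mode_sd = mode_sd, mode_weight = mode_weight,
                 n_signatures = n_signatures, signature_size = signature_size,
                 n_planted = n_planted, planted_size = planted_size,
                 planted_effect = planted_effect, tumor_shrink = tumor_shrink,
                 tumor_drift = tumor_drift,
                 intermediate_mix = intermediate_mix,
                 n_extension_per_planted = n_extension_per_planted,
                 noise_sd = noise_sd,
                 multiprobe_fraction = multiprobe_fraction,
                 roles = roles, seed = seed),
            class = "sim_config")
}

#' Simulate a full synthetic analysis bundle
#'
#' Generates, from one seeded random stream: a GEM with group design, a
#' signature database (planted + null), a probe-gene map, an interaction
#' table linking extension genes to planted signatures, and the planted
#' ground truth.
#'
#' @param config a [sim_config()]
#' @return a list with elements `gem`, `signatures` (named list),
#'   `map`, `interactions`, `truth` (list: `planted_signatures`,
#'   `planted_probes`, `null_signatures`, `planted_genes`,
#'   `extension_genes`), and `config`
#' @export
simulate_bundle <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cf <- config
  lo <- cf$value_range[1]; hi <- cf$value_range[2]
  mu_low <- lo + (hi - lo) / 3
  mu_high <- lo + 2 * (hi - lo) / 3
  drift <- if (is.null(cf$tumor_drift)) (mu_high - mu_low) / 2 else cf$tumor_drift

  probe_ids <- sprintf("P%05d", seq_len(cf$n_probes))
  ## probe-gene map: every gene has one probe; a fraction carry a second probe
  n_second <- floor(cf$n_probes * cf$multiprobe_fraction /
                      (1 + cf$multiprobe_fraction))
  n_genes <- cf$n_probes - n_second
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  gene_of_probe <- c(gene_ids,
                     if (n_second > 0) sample(gene_ids, n_second) else character())
  map <- probe_gene_map(probe_ids, gene_of_probe)

  ## baseline probe means: two-component mixture
  high_mode <- stats::runif(cf$n_probes) < cf$mode_weight
  m <- ifelse(high_mode, mu_high, mu_low) +
    stats::rnorm(cf$n_probes, 0, cf$mode_sd)
  names(m) <- probe_ids

  ## gene pools: planted and extension genes must be all-high-mode so the
  ## tumor shift acts downward on highly expressed members
  probes_by_gene <- split(probe_ids, gene_of_probe)
  all_high <- vapply(probes_by_gene, function(p) all(high_mode[match(p, probe_ids)]),
                     logical(1))
  high_genes <- names(probes_by_gene)[all_high]
  need_high <- cf$n_planted * (cf$planted_size + cf$n_extension_per_planted)
  if (length(high_genes) < need_high)
    stop("not enough high-mode genes for the requested planted structure")
  picked <- if (need_high > 0) sample(high_genes, need_high) else character()
  planted_gene_sets <- if (cf$n_planted > 0)
    split(picked[seq_len(cf$n_planted * cf$planted_size)],
          rep(seq_len(cf$n_planted), each = cf$planted_size)) else list()
  ext_gene_sets <- if (cf$n_planted > 0 && cf$n_extension_per_planted > 0)
    split(picked[-seq_len(cf$n_planted * cf$planted_size)],
          rep(seq_len(cf$n_planted), each = cf$n_extension_per_planted)) else
    replicate(cf$n_planted, character(), simplify = FALSE)
  null_gene_pool <- setdiff(gene_ids, picked)

  ## group-level mean matrix
  tumorlike <- cf$roles[["tumor"]]
  normal_like <- c(cf$roles[["normal"]], cf$roles[["redirected"]])
  mix_of <- vapply(cf$groups, function(gp) {
    if (gp %in% normal_like) 0
    else if (gp %in% cf$unimodal_groups || gp == tumorlike) 1
    else cf$intermediate_mix
  }, numeric(1))
  group_means <- matrix(m, nrow = cf$n_probes, ncol = length(cf$groups),
                        dimnames = list(probe_ids, cf$groups))
  for (gp in cf$groups) {
    mx <- mix_of[[gp]]
    if (mx > 0)
      group_means[high_mode, gp] <- group_means[high_mode, gp] - mx * drift
  }

  ## planted treatment: in fully tumor-like groups, member means are replaced
  ## by a mean-preserving shrunk permutation minus planted_effect
  planted_probe_sets <- lapply(planted_gene_sets, function(gs)
    unlist(probes_by_gene[gs], use.names = FALSE))
  scramble <- function(base) {
    ctr <- mean(base)
    perm <- sample(seq_along(base))
    ctr + cf$tumor_shrink * (base[perm] - ctr) - cf$planted_effect
  }
  for (k in seq_along(planted_probe_sets)) {
    pp <- c(planted_probe_sets[[k]],
            unlist(probes_by_gene[ext_gene_sets[[k]]], use.names = FALSE))
    tumor_means <- scramble(m[pp])
    for (gp in cf$groups) {
      mx <- mix_of[[gp]]
      if (mx >= 1) group_means[pp, gp] <- tumor_means
      else if (mx > 0)
        group_means[pp, gp] <- m[pp] - mx * cf$planted_effect
    }
  }

  ## replicate columns with i.i.d. Gaussian noise, truncated to value_range
  sample_ids <- as.vector(t(outer(cf$groups, seq_len(cf$n_replicates),
                                  function(gp, r) paste0(gp, "_", r))))
  groups_of <- stats::setNames(rep(cf$groups, each = cf$n_replicates), sample_ids)
  vals <- matrix(0, cf$n_probes, length(sample_ids),
                 dimnames = list(probe_ids, sample_ids))
  for (s in sample_ids) {
    mu <- group_means[, groups_of[[s]]]
    x <- mu + if (cf$noise_sd > 0) stats::rnorm(cf$n_probes, 0, cf$noise_sd) else 0
    vals[, s] <- pmin(pmax(x, lo), hi)
  }
  g <- gem(vals, groups_of, cf$roles)

  ## signature database: planted first, then null sets
  sigs <- list()
  for (k in seq_along(planted_gene_sets)) {
    nm <- sprintf("PLANTED_%02d", k)
    sigs[[nm]] <- project_signature(
      signature_set(nm, "planted redirection signature",
                    planted_gene_sets[[k]]), map, g)
  }
  null_names <- sprintf("NULLSET_%03d", seq_len(cf$n_signatures))
  for (nm in null_names) {
    sz <- sample(cf$signature_size[1]:cf$signature_size[2], 1)
    sigs[[nm]] <- project_signature(
      signature_set(nm, "null signature", sample(null_gene_pool, sz)), map, g)
  }

  ## interaction table: true extension edges + low-mode decoys + background
  ea <- character(); eb <- character()
  for (k in seq_along(planted_gene_sets)) {
    members <- planted_gene_sets[[k]]
    for (xg in ext_gene_sets[[k]]) {
      anchors <- sample(members, min(3, length(members)))
      ea <- c(ea, anchors); eb <- c(eb, rep(xg, length(anchors)))
    }
    low_genes <- setdiff(null_gene_pool, high_genes)
    if (length(low_genes) >= 2) {
      decoys <- sample(low_genes, 2)
      ea <- c(ea, sample(members, 2)); eb <- c(eb, decoys)
    }
  }
  n_bg <- min(50, floor(length(null_gene_pool) / 2))
  if (n_bg > 0) {
    bg <- matrix(sample(null_gene_pool, 2 * n_bg), ncol = 2)
    bg <- bg[bg[, 1] != bg[, 2], , drop = FALSE]
    ea <- c(ea, bg[, 1]); eb <- c(eb, bg[, 2])
  }
  interactions <- if (length(ea))
    interaction_table(ea, eb, sample(INTERACTION_KINDS, length(ea), TRUE),
                      stats::runif(length(ea), 0.5, 1)) else
    interaction_table(character(), character(), character(), numeric())

  truth <- list(
    planted_signatures = names(planted_gene_sets <- stats::setNames(
      planted_gene_sets, sprintf("PLANTED_%02d", seq_along(planted_gene_sets)))),
    planted_probes = stats::setNames(planted_probe_sets,
                                     names(planted_gene_sets)),
    planted_genes = planted_gene_sets,
    extension_genes = stats::setNames(ext_gene_sets,
                                      names(planted_gene_sets)),
    null_signatures = null_names)

  list(gem = g, signatures = sigs, map = map, interactions = interactions,
       truth = truth, config = cf)
}

#' Bimodality score of a value distribution
#'
#' Mean per-observation log-likelihood-ratio statistic comparing a
#' two-component Gaussian mixture (fitted by EM) against a single Gaussian:
#' `2 * (ll2 - ll1) / n`. Larger values indicate stronger bimodality; a
#' (near-)constant vector returns the defined minimal score 0.
#'
#' @param values numeric vector, length >= 30
#' @return nonnegative dimensionless score
#' @export
bimodality_score <- function(values) {
  n <- length(values)
  if (n < 30) stop("bimodality score needs at least 30 values")
  s <- stats::sd(values)
  if (!is.finite(s) || s < 1e-8) return(0)
  ll1 <- sum(stats::dnorm(values, mean(values),
                          sqrt(mean((values - mean(values))^2)), log = TRUE))
  ## 2-component EM, deterministic quantile initialization
  mu <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
  sg <- c(s, s) / 2
  w <- c(0.5, 0.5)
  ll2 <- -Inf
  for (it in 1:200) {
    d1 <- w[1] * stats::dnorm(values, mu[1], max(sg[1], 1e-4))
    d2 <- w[2] * stats::dnorm(values, mu[2], max(sg[2], 1e-4))
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d1 / tot
    ll_new <- sum(log(tot))
    if (is.finite(ll2) && abs(ll_new - ll2) < 1e-8) { ll2 <- ll_new; break }
    ll2 <- ll_new
    w <- c(mean(r), 1 - mean(r))
    if (w[1] < 1e-6 || w[2] < 1e-6) break
    mu[1] <- sum(r * values) / sum(r)
    mu[2] <- sum((1 - r) * values) / sum(1 - r)
    sg[1] <- sqrt(sum(r * (values - mu[1])^2) / sum(r))
    sg[2] <- sqrt(sum((1 - r) * (values - mu[2])^2) / sum(1 - r))
  }
  max(0, 2 * (ll2 - ll1) / n)
}
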