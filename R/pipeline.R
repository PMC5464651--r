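#' Configuration for a full pipeline run
#'
#' @param outdir output directory (created if absent)
#' @param stages ordered subset of
#'   `c("simulate", "screen", "embed", "de", "core", "extend")`
#' @param sim a [sim_config()] (used by the `simulate` stage)
#' @param screen a [screen_config()]
#' @param alpha_adj adjusted-p cutoff for the core rule and extension
#' @param stringencies stringency levels for the extension sweep
#' @param seed overrides `sim$seed` when not `NULL`
#' @param paths named list of input paths (`gem`, `design`, `gmt`, `map`,
#'   `interactions`) used when `simulate` is not among the stages
#' @return object of class `"pipeline_config"`
#' @export
pipeline_config <- function(outdir, stages = c("simulate", "screen", "embed",
                                               "de", "core", "extend"),
                            sim = sim_config(), screen = screen_config(),
                            alpha_adj = 1e-4, stringencies = 1e-4,
                            seed = NULL, paths = list()) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(outdir = outdir, stages = stages, sim = sim, screen = screen,
                 alpha_adj = alpha_adj, stringencies = stringencies,
                 paths = paths),
            class = "pipeline_config")
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the screening pipeline end to end
#'
#' Executes the requested stages in dependency order: `simulate` writes a
#' synthetic bundle (or inputs are read from `config$paths`); `screen` fits
#' the MI-ratio screen; `embed` writes the 1D sample ordering; `de` computes
#' the three role contrasts; `core` applies the core biomarker rule over the
#' significant signatures; `extend` runs the interaction extension sweep over
#' the significant signatures. Every stage writes a TSV into `outdir`, and a
#' JSON manifest records the seed, stage output checksums, and headline
#' counts; identical config + seed reproduce identical checksums.
#'
#' @param config a [pipeline_config()]
#' @return the manifest, invisibly
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  deps <- list(core = c("screen", "de"), extend = c("screen", "de"))
  for (stage in intersect(names(deps), st)) {
    miss <- setdiff(deps[[stage]], st)
    if (length(miss))
      stop("stage '", stage, "' requires upstream stage(s): ",
           paste(miss, collapse = ", "))
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  files <- character()
  counts <- list()

  ## --- inputs -------------------------------------------------------------
  if ("simulate" %in% st) {
    bundle <- simulate_bundle(config$sim)
    write_expression_matrix(bundle$gem, out("gem.tsv"), out("design.tsv"))
    write_gmt(bundle$signatures, out("signatures.gmt"))
    write_probe_map(bundle$map, out("probe_map.tsv"))
    write_interactions(bundle$interactions, out("interactions.tsv"))
    files <- c(files, gem = out("gem.tsv"), design = out("design.tsv"),
               gmt = out("signatures.gmt"), map = out("probe_map.tsv"),
               interactions = out("interactions.tsv"))
  } else {
    need <- c("gem", "design", "gmt", "map")
    missing <- setdiff(need, names(config$paths))
    if (length(missing))
      stop("stage(s) ", paste(setdiff(st, "simulate"), collapse = ", "),
           " need input paths: ", paste(missing, collapse = ", "))
    g <- read_expression_matrix(config$paths$gem, config$paths$design)
    sigs <- lapply(read_gmt(config$paths$gmt), project_signature,
                   map = read_probe_map(config$paths$map), g = g)
    bundle <- list(gem = g, signatures = sigs,
                   map = read_probe_map(config$paths$map),
                   interactions = if (!is.null(config$paths$interactions))
                     read_interactions(config$paths$interactions) else NULL)
  }
  g <- bundle$gem
  roles <- g$roles

  scr <- NULL; de <- NULL
  ## --- screen -------------------------------------------------------------
  if (any(c("screen", "core", "extend") %in% st)) {
    scr <- mi_screen(g, bundle$signatures, config$screen)
    if ("screen" %in% st)
      files["screen"] <- write_tsv(scr$results, out("screen.tsv"))
    counts$signatures_tested <- scr$n_tested
    counts$signatures_excluded <- nrow(scr$results) - scr$n_tested
    counts$signatures_significant <- sum(scr$results$significant)
  }
  ## --- embed --------------------------------------------------------------
  if ("embed" %in% st) {
    ord <- order_samples_1d(g, config$screen$scheme)
    files["embedding"] <- write_tsv(ord, out("embedding_1d.tsv"))
  }
  ## --- differential expression --------------------------------------------
  if (any(c("de", "core", "extend") %in% st)) {
    de <- list(
      AE = de_contrast(g, roles[["normal"]], roles[["redirected"]]),
      AB = de_contrast(g, roles[["normal"]], roles[["tumor"]]),
      EB = de_contrast(g, roles[["redirected"]], roles[["tumor"]]))
    if ("de" %in% st) {
      files["de_normal_redirected"] <- write_tsv(de$AE, out("de_normal_redirected.tsv"))
      files["de_normal_tumor"] <- write_tsv(de$AB, out("de_normal_tumor.tsv"))
      files["de_redirected_tumor"] <- write_tsv(de$EB, out("de_redirected_tumor.tsv"))
    }
  }
  sig_names <- if (!is.null(scr))
    scr$results$signature[scr$results$significant] else character()
  sig_sets <- bundle$signatures[sig_names]
  ## --- core biomarker rule ------------------------------------------------
  if ("core" %in% st) {
    core <- select_core_genes(de$AE, de$AB, de$EB, sig_sets, bundle$map,
                              config$alpha_adj)
    core_df <- data.frame(
      gene_symbol = core$gene_symbols,
      source_signatures = vapply(core$source_signatures, paste,
                                 character(1), collapse = ","),
      stringsAsFactors = FALSE)
    files["core"] <- write_tsv(core_df, out("core_genes.tsv"))
    counts$core_genes <- length(core$gene_symbols)
  }
  ## --- extension ----------------------------------------------------------
  if ("extend" %in% st) {
    if (is.null(bundle$interactions))
      stop("stage extend needs an interaction table")
    sweep_df <- if (length(sig_sets))
      extension_sweep(g, sig_sets, bundle$interactions, de$AB, de$EB,
                      bundle$map, config$stringencies, config$screen) else
      data.frame()
    files["extension"] <- write_tsv(sweep_df, out("extension.tsv"))
    counts$extensions_improved <- if (nrow(sweep_df)) sum(sweep_df$improved) else 0L
  }

  manifest <- list(
    seed = config$sim$seed,
    stages = st,
    counts = counts,
    checksums = as.list(tools::md5sum(unname(files[!is.na(files)]))),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("redirectomics")))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
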