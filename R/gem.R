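#' Construct a gene expression matrix (GEM) object
#'
#' A GEM holds log2-normalized intensities (probes x samples) together with the
#' group design mapping each sample column to a cell group, and the contrast
#' roles (normal / redirected / tumor) used throughout the screen.
#'
#' @param values numeric matrix of log2 intensities; rownames are probe ids,
#'   colnames are sample ids. All entries must be finite.
#' @param groups named character vector mapping sample id -> group label; names
#'   must cover exactly the columns of `values`.
#' @param roles named character vector with elements `normal`, `redirected`,
#'   `tumor` giving the group label playing each role. Defaults to A, E, B.
#' @return an object of class `"gem"`.
#' @export
gem <- function(values, groups,
                roles = c(normal = "A", redirected = "E", tumor = "B")) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have probe rownames and sample colnames")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicate probe ids: ", paste(dup, collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("all expression values must be finite (no NA/Inf)")
  absent <- setdiff(colnames(values), names(groups))
  if (length(absent))
    stop("samples missing from design: ", paste(absent, collapse = ", "))
  groups <- stats::setNames(as.character(groups[colnames(values)]),
                            colnames(values))
  roles <- check_roles(roles, unique(groups))
  structure(list(values = values, groups = groups, roles = roles),
            class = "gem")
}

check_roles <- function(roles, group_levels) {
  need <- c("normal", "redirected", "tumor")
  if (!all(need %in% names(roles)))
    stop("roles must name groups for: ", paste(need, collapse = ", "))
  roles <- roles[need]
  if (anyDuplicated(roles))
    stop("contrast roles must map to distinct groups")
  missing <- setdiff(roles, group_levels)
  if (length(missing))
    stop("role group(s) absent from design: ", paste(missing, collapse = ", "))
  roles
}

#' @export
print.gem <- function(x, ...) {
  cat(sprintf("Gene expression matrix: %d probes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$groups)
  cat("Groups:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
  cat(sprintf("Roles: normal=%s redirected=%s tumor=%s\n",
              x$roles[["normal"]], x$roles[["redirected"]], x$roles[["tumor"]]))
  cat(sprintf("Value range: [%.3f, %.3f] (log2 scale)\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.gem <- function(x) dim(x$values)

#' Sample columns belonging to a group
#' @param g a `gem` object
#' @param group group label
#' @return character vector of sample ids (in column order)
#' @export
group_samples <- function(g, group) {
  out <- names(g$groups)[g$groups == group]
  if (!length(out)) stop("no samples in group '", group, "'")
  out
}

#' Read an expression matrix with its group design
#'
#' The matrix file is tab-delimited with a header row of sample ids and a
#' first column of probe ids; the design file is a two-column tab-delimited
#' table (sample_id, group). Column order is preserved as in the file.
#'
#' @param path path to the matrix TSV
#' @param design_path path to the design TSV
#' @param roles contrast roles passed to [gem()]
#' @return a `gem` object
#' @export
read_expression_matrix <- function(path, design_path,
                                   roles = c(normal = "A", redirected = "E",
                                             tumor = "B")) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop("matrix file needs probe column plus >=1 sample")
  probe_ids <- raw[[1]]
  dup <- unique(probe_ids[duplicated(probe_ids)])
  if (length(dup))
    stop("duplicate probe ids in ", path, ": ", paste(dup, collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value at row %d (probe %s), column %d (sample %s)",
                 bad[1], probe_ids[bad[1]], bad[2], colnames(vals)[bad[2]]))
  }
  dimnames(num) <- list(probe_ids, colnames(vals))
  design <- read_design(design_path)
  extra <- setdiff(colnames(num), names(design))
  if (length(extra))
    stop("sample(s) in matrix missing from design: ",
         paste(extra, collapse = ", "))
  extra2 <- setdiff(names(design), colnames(num))
  if (length(extra2))
    stop("sample(s) in design missing from matrix: ",
         paste(extra2, collapse = ", "))
  gem(num, design, roles)
}

#' Read a two-column sample/group design table
#' @param path path to TSV with columns sample_id, group
#' @return named character vector group-by-sample
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", check.names = FALSE)
  if (ncol(d) < 2) stop("design file must have columns sample_id, group")
  if (anyDuplicated(d[[1]]))
    stop("duplicate sample ids in design: ",
         paste(unique(d[[1]][duplicated(d[[1]])]), collapse = ", "))
  stats::setNames(d[[2]], d[[1]])
}

## round-trip-safe decimal rendering (17 significant digits)
fmt_num <- function(x) sprintf("%.17g", x)

#' Write an expression matrix and design to TSV
#' @param g a `gem` object
#' @param path output matrix path
#' @param design_path output design path
#' @return invisibly, `g`
#' @export
write_expression_matrix <- function(g, path, design_path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("probe_id", colnames(g$values)), collapse = "\t"),
             con, sep = "\n")
  body <- apply(g$values, 1, function(r) paste(fmt_num(r), collapse = "\t"))
  writeLines(paste(rownames(g$values), body, sep = "\t"), con, sep = "\n")
  dcon <- file(design_path, open = "wb")
  on.exit(close(dcon), add = TRUE)
  writeLines(c("sample_id\tgroup",
               paste(names(g$groups), g$groups, sep = "\t")), dcon, sep = "\n")
  invisible(g)
}

#' Construct a molecular signature
#'
#' @param name signature name
#' @param description free-text description
#' @param genes character vector of official gene symbols (first-occurrence
#'   order kept, duplicates dropped)
#' @param probes probe ids after projection onto a GEM (empty until projected)
#' @param provenance `"original"` or `"extended"`
#' @return an object of class `"signature"`
#' @export
signature_set <- function(name, description = "", genes,
                          probes = character(), provenance = "original") {
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("signature '", name, "' has no gene symbols")
  provenance <- match.arg(provenance, c("original", "extended"))
  structure(list(name = name, description = description, genes = genes,
                 probes = as.character(probes), provenance = provenance),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("Signature '%s' (%s): %d genes, %d projected probes\n",
              x$name, x$provenance, length(x$genes), length(x$probes)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' MSigDB dialect: one set per line; tab-separated name, description, then
#' gene symbols (blank fields ignored; duplicates within a line deduplicated,
#' first-occurrence order kept).
#'
#' @param path path to GMT file
#' @return named list of `signature` objects, in file order
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  sigs <- vector("list", length(keep))
  nm <- character(length(keep))
  for (i in seq_along(keep)) {
    f <- strsplit(lines[keep[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description, genes",
                   keep[i], length(f)))
    sigs[[i]] <- signature_set(f[1], f[2], f[-(1:2)])
    nm[i] <- f[1]
  }
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    stop("duplicate signature names in GMT: ", paste(dup, collapse = ", "))
  names(sigs) <- nm
  sigs
}

#' Write signatures to a GMT file
#' @param sigs list of `signature` objects
#' @param path output path
#' @return invisibly, `sigs`
#' @export
write_gmt <- function(sigs, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (s in sigs)
    writeLines(paste(c(s$name, s$description, s$genes), collapse = "\t"),
               con, sep = "\n")
  invisible(sigs)
}

#' Construct a probe <-> gene mapping table
#'
#' Many-to-many relation between probe ids and gene symbols, queried in both
#' directions.
#'
#' @param probe_id character vector
#' @param gene_symbol character vector (same length)
#' @return object of class `"probe_gene_map"` (a data.frame)
#' @export
probe_gene_map <- function(probe_id, gene_symbol) {
  d <- unique(data.frame(probe_id = as.character(probe_id),
                         gene_symbol = as.character(gene_symbol),
                         stringsAsFactors = FALSE))
  class(d) <- c("probe_gene_map", "data.frame")
  d
}

#' @rdname probe_gene_map
#' @param path TSV path with columns probe_id, gene_symbol
#' @export
read_probe_map <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", check.names = FALSE)
  if (ncol(d) < 2) stop("probe map must have columns probe_id, gene_symbol")
  probe_gene_map(d[[1]], d[[2]])
}

#' @rdname probe_gene_map
#' @param map a `probe_gene_map`
#' @export
write_probe_map <- function(map, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("probe_id\tgene_symbol",
               paste(map$probe_id, map$gene_symbol, sep = "\t")),
             con, sep = "\n")
  invisible(map)
}

#' Probes mapped from a set of gene symbols (first-occurrence order)
#' @param map a `probe_gene_map`
#' @param genes gene symbols
#' @return character vector of probe ids
#' @export
probes_for_genes <- function(map, genes) {
  unique(map$probe_id[map$gene_symbol %in% genes])
}

#' Gene symbols mapped from a set of probes
#' @param map a `probe_gene_map`
#' @param probes probe ids
#' @return character vector of gene symbols
#' @export
genes_for_probes <- function(map, probes) {
  unique(map$gene_symbol[map$probe_id %in% probes])
}

#' Project a signature's gene symbols onto a GEM's probe space
#'
#' Probe ids become the union of probes mapped from the signature's genes,
#' intersected with the GEM's probes. Genes without probes are silently
#' dropped from the probe projection (their symbols are retained); multi-probe
#' genes contribute all their probes. Idempotent.
#'
#' @param sig a `signature`
#' @param map a `probe_gene_map`
#' @param g a `gem`
#' @return the signature with `probes` filled in
#' @export
project_signature <- function(sig, map, g) {
  p <- intersect(probes_for_genes(map, sig$genes), rownames(g$values))
  sig$probes <- p
  sig
}

INTERACTION_KINDS <- c("genetic", "physical", "coexpression")

#' Construct / read / write an undirected gene interaction table
#'
#' Edges carry a kind (genetic, physical, coexpression) and a nonnegative
#' weight; the relation is undirected (a neighbor query from either endpoint
#' retrieves the edge) and self-loops are rejected.
#'
#' @param gene_a,gene_b endpoint gene symbols
#' @param kind one of `"genetic"`, `"physical"`, `"coexpression"` per edge
#' @param weight nonnegative numeric per edge
#' @return object of class `"interaction_table"` (a data.frame)
#' @export
interaction_table <- function(gene_a, gene_b, kind, weight = 1) {
  d <- data.frame(gene_a = as.character(gene_a),
                  gene_b = as.character(gene_b),
                  kind = as.character(kind),
                  weight = as.numeric(weight),
                  stringsAsFactors = FALSE)
  bad <- which(!d$kind %in% INTERACTION_KINDS)
  if (length(bad))
    stop("unknown interaction kind at row ", bad[1], ": '", d$kind[bad[1]], "'")
  loops <- which(d$gene_a == d$gene_b)
  if (length(loops))
    stop("self-loop interaction at row ", loops[1], ": ", d$gene_a[loops[1]])
  if (any(!is.finite(d$weight)) || any(d$weight < 0))
    stop("interaction weights must be finite and >= 0")
  class(d) <- c("interaction_table", "data.frame")
  d
}

#' @rdname interaction_table
#' @param path 4-column TSV (gene_a, gene_b, kind, weight)
#' @export
read_interactions <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         check.names = FALSE,
                         colClasses = c("character", "character",
                                        "character", "numeric"))
  if (ncol(d) < 4)
    stop("interaction file must have columns gene_a, gene_b, kind, weight")
  loops <- which(d[[1]] == d[[2]])
  if (length(loops))  # +1 for header line
    stop("self-loop interaction at line ", loops[1] + 1L, ": ", d[[1]][loops[1]])
  interaction_table(d[[1]], d[[2]], d[[3]], d[[4]])
}

#' @rdname interaction_table
#' @param tbl an `interaction_table`
#' @export
write_interactions <- function(tbl, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("gene_a\tgene_b\tkind\tweight",
               paste(tbl$gene_a, tbl$gene_b, tbl$kind, fmt_num(tbl$weight),
                     sep = "\t")), con, sep = "\n")
  invisible(tbl)
}

#' Neighbors of a set of genes in an interaction table
#'
#' @param tbl an `interaction_table`
#' @param genes query gene symbols
#' @param kinds restrict to these interaction kinds (default: all)
#' @param min_weight minimum edge weight to count as evidence
#' @return character vector of neighbor gene symbols (excluding the query set)
#' @export
interaction_neighbors <- function(tbl, genes, kinds = INTERACTION_KINDS,
                                  min_weight = 0) {
  keep <- tbl$kind %in% kinds & tbl$weight >= min_weight
  a <- tbl$gene_a[keep]; b <- tbl$gene_b[keep]
  nb <- c(b[a %in% genes], a[b %in% genes])
  setdiff(unique(nb), genes)
}
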