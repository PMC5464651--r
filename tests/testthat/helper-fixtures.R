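## Small simulation bundles and handmade GEMs shared across test files.

tiny_config <- function(seed = 1, ...) {
  sim_config(n_probes = 400, n_signatures = 30, n_planted = 2,
             planted_size = 30, signature_size = c(11, 30), seed = seed, ...)
}

tiny_bundle <- function(seed = 1, ...) simulate_bundle(tiny_config(seed, ...))

## GEM with given per-group mean vectors (one column per replicate + noise)
make_gem <- function(group_means, n_rep = 3, noise_sd = 0, seed = 99,
                     roles = c(normal = "A", redirected = "E", tumor = "B")) {
  set.seed(seed)
  groups <- colnames(group_means)
  sn <- as.vector(t(outer(groups, seq_len(n_rep), paste, sep = "_")))
  v <- matrix(0, nrow(group_means), length(sn),
              dimnames = list(rownames(group_means), sn))
  for (s in sn) {
    gp <- sub("_.*", "", s)
    v[, s] <- group_means[, gp] + rnorm(nrow(group_means), 0, noise_sd)
  }
  gem(v, setNames(rep(groups, each = n_rep), sn), roles)
}

## brute-force MI from the definition, over occupied joint cells
mi_bruteforce <- function(x, y) {
  n <- length(x)
  px <- table(x) / n
  py <- table(y) / n
  pxy <- table(paste(x, y, sep = "\r")) / n
  tot <- 0
  for (cell in names(pxy)) {
    parts <- strsplit(cell, "\r", fixed = TRUE)[[1]]
    p <- pxy[[cell]]
    tot <- tot + p * log2(p / (px[[parts[1]]] * py[[parts[2]]]))
  }
  tot
}
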