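test_that("null probes and contrast symmetry behave as expected", {
  set.seed(20)
  means <- matrix(runif(200, 5, 11), 200, 3,
                  dimnames = list(sprintf("p%03d", 1:200), c("A", "E", "B")))
  g <- make_gem(means, n_rep = 3, noise_sd = 0.4)
  ## make one probe exactly equal across A and B
  g$values["p001", group_samples(g, "B")] <-
    g$values["p001", group_samples(g, "A")]
  de <- de_contrast(g, "A", "B")
  row <- de[de$probe_id == "p001", ]
  expect_equal(row$log_fc, 0)
  expect_equal(row$t_stat, 0)
  expect_equal(row$p_value, 1)

  de_rev <- de_contrast(g, "B", "A")
  expect_equal(de_rev$log_fc, -de$log_fc)
  expect_equal(de_rev$t_stat, -de$t_stat)
  expect_equal(de_rev$p_value, de$p_value)
  expect_error(de_contrast(g, "A", "Z"), "no samples")
})

test_that("raw p-values are calibrated under a global null", {
  set.seed(7)
  sn <- c(paste0("A_", 1:3), paste0("E_", 1:3), paste0("B_", 1:3))
  v <- matrix(rnorm(2000 * 9, 8, 1), 2000, 9,
              dimnames = list(sprintf("P%04d", 1:2000), sn))
  g <- gem(v, setNames(rep(c("A", "E", "B"), each = 3), sn))
  de <- de_contrast(g, "A", "B")
  expect_lt(abs(mean(de$p_value < 0.05) - 0.05), 0.015)
  ## BH monotone in p within the contrast
  ord <- order(de$p_value)
  expect_true(all(diff(de$p_adj[ord]) >= -1e-15))
  expect_true(all(de$p_adj >= de$p_value - 1e-15))
})

test_that("a planted 3-log2-unit shift is detected at adjusted p < 1e-4", {
  hits <- logical(100)
  for (i in 1:100) {
    set.seed(300 + i)
    sn <- c(paste0("A_", 1:3), paste0("E_", 1:3), paste0("B_", 1:3))
    v <- matrix(rnorm(200 * 9, 8, 0.3), 200, 9,
                dimnames = list(sprintf("P%03d", 1:200), sn))
    v[1, 7:9] <- v[1, 7:9] - 3.0  # true delta in the B columns
    g <- gem(v, setNames(rep(c("A", "E", "B"), each = 3), sn))
    de <- de_contrast(g, "A", "B")
    hits[i] <- de$p_adj[de$probe_id == "P001"] < 1e-4
  }
  expect_gte(mean(hits), 0.95)
})

test_that("moderated t agrees with the independent limma oracle", {
  set.seed(23)
  sn <- c(paste0("A_", 1:3), paste0("E_", 1:3), paste0("B_", 1:3))
  v <- matrix(rnorm(300 * 9, 8, 0.5), 300, 9,
              dimnames = list(sprintf("P%03d", 1:300), sn))
  v[1:20, 7:9] <- v[1:20, 7:9] + rep(runif(20, -2, 2), 3)
  g <- gem(v, setNames(rep(c("A", "E", "B"), each = 3), sn))
  de <- de_contrast(g, "A", "B")

  cols <- c(group_samples(g, "A"), group_samples(g, "B"))
  design <- cbind(Intercept = 1, AvsB = rep(c(1, 0), each = 3))
  fit <- limma::lmFit(v[, cols], design)
  fit <- limma::eBayes(fit)
  expect_equal(de$log_fc, unname(fit$coefficients[, "AvsB"]),
               tolerance = 1e-10)
  expect_equal(de$t_stat, unname(fit$t[, "AvsB"]), tolerance = 1e-6)
  expect_equal(de$p_value, unname(fit$p.value[, "AvsB"]), tolerance = 1e-6)
  expect_equal(attr(de, "prior_df"), fit$df.prior, tolerance = 1e-4)
  expect_equal(attr(de, "prior_var"), fit$s2.prior, tolerance = 1e-6)

  ## Welch cross-check against stats::t.test
  dew <- de_contrast(g, "A", "B", method = "welch")
  for (i in c(1, 5, 250)) {
    tt <- t.test(v[i, 1:3], v[i, 7:9])
    expect_equal(dew$t_stat[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(dew$p_value[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("the core rule applies per probe with the required gates", {
  map <- probe_gene_map(c("p1", "p2", "p3"), c("G1", "G2", "G3"))
  mk <- function(ae, ab, eb) {
    f <- function(p) {
      d <- data.frame(probe_id = c("p1", "p2", "p3"), log_fc = 0, t_stat = 0,
                      p_value = p, p_adj = p, stringsAsFactors = FALSE)
      class(d) <- c("de_result", "data.frame"); d
    }
    list(AE = f(ae), AB = f(ab), EB = f(eb))
  }
  sigs <- list(signature_set("SIG", "", c("G1", "G2", "G3")))
  ## G1: both tumor contrasts significant, A-vs-E not -> core
  ## G2: significant in A-vs-E -> excluded
  ## G3: fails one tumor gate -> excluded
  de <- mk(ae = c(0.5, 1e-6, 0.9), ab = c(1e-6, 1e-6, 1e-6),
           eb = c(1e-6, 1e-6, 0.5))
  core <- select_core_genes(de$AE, de$AB, de$EB, sigs, map, 1e-4)
  expect_identical(core$gene_symbols, "G1")
  expect_identical(core$probe_ids, "p1")
  expect_identical(core$source_signatures$G1, "SIG")

  ## probe universe mismatch is rejected
  de2 <- de$AB; de2$probe_id <- c("p1", "p2", "pX")
  expect_error(select_core_genes(de$AE, de2, de$EB, sigs, map), "universe")
})

test_that("core selection recovers planted genes and is order invariant", {
  b <- tiny_bundle(4)
  g <- b$gem
  de_AE <- de_contrast(g, "A", "E")
  de_AB <- de_contrast(g, "A", "B")
  de_EB <- de_contrast(g, "E", "B")
  sigs <- b$signatures[b$truth$planted_signatures]
  core <- select_core_genes(de_AE, de_AB, de_EB, sigs, b$map)
  planted <- unique(unlist(b$truth$planted_genes))
  expect_gte(mean(planted %in% core$gene_symbols), 0.85)
  expect_true(all(core$gene_symbols %in% planted))
  ## provenance is complete
  expect_true(all(lengths(core$source_signatures) >= 1))
  core2 <- select_core_genes(de_AE, de_AB, de_EB, rev(sigs), b$map)
  expect_setequal(core2$gene_symbols, core$gene_symbols)
})
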