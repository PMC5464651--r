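test_that("size filter and degenerate ratios set exclusion reasons", {
  b <- tiny_bundle(1)
  g <- b$gem
  small <- b$signatures[[1]]
  small$probes <- small$probes[1:5]
  res <- score_signature(g, small, screen_config(min_set_size = 11))
  expect_identical(res$excluded_reason, "too_small")
  expect_true(is.na(res$ratio))

  ## identical expression in all groups (zero noise): ratio is exactly 1
  set.seed(5)
  means <- matrix(rep(runif(40, 4, 12), 3), ncol = 3,
                  dimnames = list(sprintf("p%02d", 1:40), c("A", "E", "B")))
  gz <- make_gem(means, n_rep = 2, noise_sd = 0)
  sig <- signature_set("ALL", "", sprintf("g%02d", 1:40),
                       probes = rownames(means))
  res <- score_signature(gz, sig, screen_config(min_set_size = 11))
  expect_identical(res$excluded_reason, "none")
  expect_equal(res$ratio, 1.0, tolerance = 1e-12)
  expect_equal(res$mi_AE, res$mi_EB, tolerance = 1e-12)

  ## constant signature values: MI = 0 in both contrasts -> zero_ratio
  cmeans <- matrix(7, 40, 3, dimnames = dimnames(means))
  gc <- make_gem(cmeans, n_rep = 2, noise_sd = 0)
  res <- score_signature(gc, sig, screen_config(min_set_size = 11))
  expect_identical(res$excluded_reason, "zero_ratio")
})

test_that("planted signatures outscore equal-size null signatures", {
  b <- tiny_bundle(3)
  scr <- mi_screen(b$gem, b$signatures)
  r <- scr$results
  planted <- r$ratio[r$signature %in% b$truth$planted_signatures]
  nulls <- r$ratio[r$signature %in% b$truth$null_signatures &
                     r$excluded_reason == "none"]
  expect_gt(min(planted), max(nulls))
})

test_that("the Bonferroni threshold is alpha over the tested count", {
  b <- tiny_bundle(4)
  cfg <- screen_config(familywise_alpha = 0.01)
  scr <- mi_screen(b$gem, b$signatures, cfg)
  expect_equal(scr$per_test_alpha,
               bonferroni_threshold(0.01, scr$n_tested))
  expect_true(all(scr$results$p_value[scr$results$significant] <=
                    scr$per_test_alpha))
  ## significant implies not excluded
  expect_true(all(scr$results$excluded_reason[scr$results$significant] ==
                    "none"))
})

test_that("a degenerate (constant-ratio) null yields no significant calls", {
  ## two identical signatures over a zero-noise gem: all ratios equal 1
  set.seed(6)
  means <- matrix(rep(runif(60, 4, 12), 3), ncol = 3,
                  dimnames = list(sprintf("p%02d", 1:60), c("A", "E", "B")))
  gz <- make_gem(means, n_rep = 2, noise_sd = 0)
  sigs <- list(
    signature_set("S1", "", sprintf("g%02d", 1:30),
                  probes = rownames(means)[1:30]),
    signature_set("S2", "", sprintf("g%02d", 31:60),
                  probes = rownames(means)[31:60]))
  scr <- mi_screen(gz, sigs, screen_config(min_set_size = 11))
  expect_equal(scr$null_sd, 0)
  expect_false(any(scr$results$significant))
  expect_error(ratio_threshold_from_alpha(scr), "degenerate")
})

test_that("ratio cutoff inverts the fitted null", {
  ## fabricated ratios with mean 1, sd 0.5; per-test p = upper 2-sigma tail
  x <- as.numeric(scale(1:10)) * 0.5 + 1
  res <- data.frame(signature = letters[1:10], n_probes = 20,
                    mi_AE = 1, mi_EB = 1, ratio = x,
                    excluded_reason = "none", stringsAsFactors = FALSE)
  alpha <- pnorm(-2) * 10  # per-test threshold = pnorm(-2)
  cfg <- screen_config(familywise_alpha = alpha)
  expect_equal(ratio_threshold_from_alpha(res, cfg), 1 + 0.5 * 2,
               tolerance = 1e-12)
  ## monotonicity: smaller alpha, strictly larger cutoff
  cut1 <- ratio_threshold_from_alpha(res, screen_config(familywise_alpha = 0.05))
  cut2 <- ratio_threshold_from_alpha(res, screen_config(familywise_alpha = 0.01))
  expect_gt(cut2, cut1)
  ## the cutoff separates significant from non-significant ratios
  b <- tiny_bundle(8)
  scr <- mi_screen(b$gem, b$signatures)
  r <- scr$results[scr$results$excluded_reason == "none", ]
  expect_true(all(r$ratio[r$significant] >= scr$ratio_cutoff))
  expect_true(all(r$ratio[!r$significant] < scr$ratio_cutoff))
})

test_that("screen output is order-invariant and conserves signatures", {
  b <- tiny_bundle(10)
  scr1 <- mi_screen(b$gem, b$signatures)
  set.seed(1)
  perm <- sample(names(b$signatures))
  scr2 <- mi_screen(b$gem, b$signatures[perm])
  expect_setequal(scr1$results$signature, names(b$signatures))
  expect_equal(nrow(scr1$results), length(b$signatures))
  expect_false(anyDuplicated(scr1$results$signature) > 0)
  r1 <- scr1$results[order(scr1$results$signature), ]
  r2 <- scr2$results[order(scr2$results$signature), ]
  rownames(r1) <- rownames(r2) <- NULL
  expect_equal(r1, r2)
})

test_that("scoring ignores probes outside the signature", {
  b <- tiny_bundle(12)
  g <- b$gem
  sch <- disc_scheme(origin = 3)  # fixed origin so the scheme is data-independent
  cfg <- screen_config(scheme = sch)
  sig <- b$signatures$PLANTED_01
  before <- score_signature(g, sig, cfg)
  outside <- setdiff(rownames(g$values), sig$probes)[1:50]
  g$values[outside, ] <- matrix(runif(50 * ncol(g$values), 4, 14),
                                nrow = 50)
  after <- score_signature(g, sig, cfg)
  expect_equal(before, after)
})

test_that("the empirical null model gives valid one-sided p-values", {
  b <- tiny_bundle(14)
  scr <- mi_screen(b$gem, b$signatures,
                   screen_config(null_model = "empirical"))
  p <- scr$results$p_value[scr$results$excluded_reason == "none"]
  expect_true(all(p > 0 & p <= 1))
  ## the largest ratio has the smallest possible empirical p
  top <- scr$results[1, ]
  expect_equal(top$p_value, (1 + 1) / (1 + scr$n_tested))
})

test_that("family-wise error is controlled under a global null", {
  hits <- 0
  for (s in 1:30) {
    b <- simulate_bundle(sim_config(seed = 2000 + s, n_probes = 500,
                                    n_signatures = 40, n_planted = 0,
                                    tumor_drift = 0,
                                    signature_size = c(11, 30)))
    scr <- mi_screen(b$gem, b$signatures)
    hits <- hits + any(scr$results$significant)
  }
  ## alpha = 0.01; allow generous binomial slack around 2*alpha over 30 runs
  expect_lte(hits, 3)
})
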