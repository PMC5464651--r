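test_that("expression matrix round-trips at full precision", {
  b <- tiny_bundle(3)
  mat <- tempfile(fileext = ".tsv"); des <- tempfile(fileext = ".tsv")
  write_expression_matrix(b$gem, mat, des)
  g2 <- read_expression_matrix(mat, des)
  expect_identical(g2$values, b$gem$values)
  expect_identical(g2$groups, b$gem$groups)
})

test_that("matrix reader reports duplicates, design mismatches and bad cells", {
  mat <- tempfile(fileext = ".tsv"); des <- tempfile(fileext = ".tsv")
  writeLines(c("probe_id\tA_1\tE_1\tB_1", "p1\t4.0\t5.0\t6.0",
               "p2\t6.0\t7.0\t8.0", "p3\t8.0\t9.0\t10.0"), mat)
  writeLines(c("sample_id\tgroup", "A_1\tA", "E_1\tE", "B_1\tB"), des)
  g <- read_expression_matrix(mat, des)
  expect_equal(dim(g), c(3L, 3L))
  expect_equal(g$values["p1", "E_1"], 5.0)
  expect_identical(colnames(g$values), c("A_1", "E_1", "B_1"))

  writeLines(c("sample_id\tgroup", "E_1\tE", "B_1\tB"), des)
  expect_error(read_expression_matrix(mat, des), "A_1")

  writeLines(c("sample_id\tgroup", "A_1\tA", "E_1\tE", "B_1\tB",
               "X_9\tA"), des)
  expect_error(read_expression_matrix(mat, des), "X_9")

  writeLines(c("probe_id\tA_1\tE_1\tB_1", "p1\t4.0\t5.0\t6.0",
               "p1\t6.0\t7.0\t8.0", "p3\t8.0\t9.0\t10.0"), mat)
  writeLines(c("sample_id\tgroup", "A_1\tA", "E_1\tE", "B_1\tB"), des)
  expect_error(read_expression_matrix(mat, des), "p1")

  writeLines(c("probe_id\tA_1\tE_1\tB_1", "p1\t4.0\tfoo\t6.0",
               "p2\t6.0\t7.0\t8.0", "p3\t8.0\t9.0\t10.0"), mat)
  expect_error(read_expression_matrix(mat, des), "row 1.*column 2")
})

test_that("GMT parsing dedups, validates, and preserves order", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("SET1\tdesc\tG1\tG2\tG2", "SET2\td2\tG3\tG1\tG4"), f)
  sigs <- read_gmt(f)
  expect_named(sigs, c("SET1", "SET2"))
  expect_identical(sigs$SET1$genes, c("G1", "G2"))
  expect_identical(sigs$SET2$genes, c("G3", "G1", "G4"))  # first-occurrence order

  writeLines(character(), f)
  expect_length(read_gmt(f), 0)

  writeLines(c("SET1\tdesc\tG1", "ONLYNAME\tdesc"), f)
  expect_error(read_gmt(f), "line 2")

  writeLines(c("SET1\tdesc\tG1", "SET1\tdesc\tG2"), f)
  expect_error(read_gmt(f), "duplicate")
})

test_that("GMT round-trips the synthetic signature database", {
  b <- tiny_bundle(5)
  f <- tempfile(fileext = ".gmt")
  write_gmt(b$signatures, f)
  back <- read_gmt(f)
  expect_identical(names(back), names(b$signatures))
  for (nm in names(back)) {
    expect_identical(back[[nm]]$genes, b$signatures[[nm]]$genes)
  }
})

test_that("signature projection is correct, idempotent, and empty-safe", {
  v <- matrix(5, 3, 3, dimnames = list(c("p1", "p3", "p9"),
                                       c("A_1", "E_1", "B_1")))
  g <- gem(v, setNames(c("A", "E", "B"), colnames(v)))
  map <- probe_gene_map(c("p1", "p2", "p3"), c("G1", "G1", "G2"))
  s <- project_signature(signature_set("S", "", c("G1", "G2")), map, g)
  expect_setequal(s$probes, c("p1", "p3"))  # p2 absent from gem
  expect_identical(project_signature(s, map, g), s)

  s9 <- project_signature(signature_set("S9", "", "G9"), map, g)
  expect_length(s9$probes, 0)
})

test_that("projection of the synthetic database stays within the GEM", {
  b <- tiny_bundle(7)
  for (s in b$signatures) {
    ## exhaustive membership oracle
    expect_true(all(s$probes %in% rownames(b$gem$values)))
    expected <- intersect(
      unique(b$map$probe_id[b$map$gene_symbol %in% s$genes]),
      rownames(b$gem$values))
    expect_setequal(s$probes, expected)
  }
})

test_that("interaction tables are undirected, validated, and scannable", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tkind\tweight", "G1\tG2\tphysical\t0.5"), f)
  tbl <- read_interactions(f)
  expect_identical(interaction_neighbors(tbl, "G1"), "G2")
  expect_identical(interaction_neighbors(tbl, "G2"), "G1")

  writeLines(c("gene_a\tgene_b\tkind\tweight", "G1\tG1\tgenetic\t1.0"), f)
  expect_error(read_interactions(f), "line 2")

  writeLines(c("gene_a\tgene_b\tkind\tweight", "G1\tG2\tmagic\t1.0"), f)
  expect_error(read_interactions(f), "magic")

  ## neighbor lookup matches a brute-force scan on a 100-edge table
  set.seed(11)
  genes <- sprintf("G%02d", 1:30)
  a <- sample(genes, 100, TRUE)
  b <- sample(genes, 100, TRUE)
  keep <- a != b
  tbl <- interaction_table(a[keep], b[keep],
                           sample(c("genetic", "physical", "coexpression"),
                                  sum(keep), TRUE), runif(sum(keep)))
  for (gn in genes) {
    brute <- setdiff(unique(c(tbl$gene_b[tbl$gene_a == gn],
                              tbl$gene_a[tbl$gene_b == gn])), gn)
    expect_setequal(interaction_neighbors(tbl, gn), brute)
  }
  ## round-trip
  write_interactions(tbl, f)
  expect_equal(read_interactions(f), tbl, ignore_attr = TRUE)
})

test_that("probe map round-trips and answers both directions", {
  b <- tiny_bundle(2)
  f <- tempfile(fileext = ".tsv")
  write_probe_map(b$map, f)
  back <- read_probe_map(f)
  expect_equal(back, b$map, ignore_attr = TRUE)
  gn <- b$map$gene_symbol[1]
  expect_true(all(probes_for_genes(back, gn) %in%
                    b$map$probe_id[b$map$gene_symbol == gn]))
  pr <- b$map$probe_id[1]
  expect_true(gn %in% genes_for_probes(back, pr))
})
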