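make_dvt <- function(rows) {
  p <- write_tsv_lines(c("diseaseId\tsnpId\tscore",
                         vapply(rows, paste, "", collapse = "\t")))
  suppressMessages(read_disease_variant_table(p))
}

make_vgt <- function(rows) {
  p <- write_tsv_lines(c("snpId\tgeneSymbol",
                         vapply(rows, paste, "", collapse = "\t")))
  suppressMessages(read_variant_gene_table(p))
}

test_that("disease-variant tables deduplicate and validate their schema", {
  dvt <- make_dvt(list(c("C01", "rs1", "0.3"), c("C01", "rs1", "0.5"),
                       c("C02", "rs2", "0.1")))
  expect_equal(nrow(dvt), 2)
  expect_setequal(dvt$cui, c("C01", "C02"))

  p <- write_tsv_lines("diseaseId\tsnpId")
  expect_warning(empty <- suppressMessages(read_disease_variant_table(p)),
                 "empty")
  expect_equal(nrow(empty), 0)

  p <- write_tsv_lines(c("notACui\tsnpId", "x\trs1"))
  expect_error(read_disease_variant_table(p), "diseaseId")
})

test_that("variant-gene tables handle multi-gene variants and duplicates", {
  vgt <- make_vgt(list(c("rs1", "G1"), c("rs1", "G2")))
  expect_setequal(vgt$gene[vgt$variant == "rs1"], c("G1", "G2"))
  vgt <- make_vgt(list(c("rs2", "g1"), c("rs2", "G1")))
  expect_equal(nrow(vgt), 1)
  p <- write_tsv_lines("snpId\tgeneSymbol")
  expect_warning(empty <- suppressMessages(read_variant_gene_table(p)),
                 "empty")
  expect_equal(nrow(empty), 0)
})

test_that("custom column names map onto drifting dump schemas", {
  p <- write_tsv_lines(c("cui_id\tvariant_id", "C07\trs7"))
  dvt <- suppressMessages(read_disease_variant_table(
    p, columns = c(cui = "cui_id", variant = "variant_id")))
  expect_equal(dvt$variant, "rs7")
})

test_that("variant and gene assembly follow the query CUIs", {
  dvt <- make_dvt(list(c("C01", "rs1", "1"), c("C02", "rs2", "1")))
  vgt <- make_vgt(list(c("rs1", "G1"), c("rs1", "G2"), c("rs9", "G9")))

  expect_equal(variants_for_diseases(dvt, disease_query("d", "C01")), "rs1")
  expect_setequal(
    variants_for_diseases(dvt, disease_query("d", c("C01", "C02"))),
    c("rs1", "rs2"))
  expect_message(
    v <- variants_for_diseases(dvt, disease_query("d", "C99")),
    "zero variants")
  expect_length(v, 0)

  gs <- suppressMessages(genes_for_diseases(dvt, vgt, disease_query("d", "C01")))
  expect_setequal(gs$genes, c("G1", "G2"))
  expect_equal(gs$label, "d")
  # a variant with no gene mapping contributes nothing
  gs2 <- suppressMessages(genes_for_diseases(dvt, vgt, disease_query("d", "C02")))
  expect_length(gs2$genes, 0)
})

test_that("gene assembly distributes over query union and is monotone and order-invariant", {
  set.seed(42)
  for (i in 1:20) {
    cuis <- sprintf("C%02d", 1:6)
    variants <- sprintf("rs%d", 1:10)
    genes <- sprintf("G%d", 1:8)
    dvt_rows <- unique(data.frame(
      cui = sample(cuis, 15, replace = TRUE),
      variant = sample(variants, 15, replace = TRUE)))
    vgt_rows <- unique(data.frame(
      variant = sample(variants, 12, replace = TRUE),
      gene = sample(genes, 12, replace = TRUE)))
    dvt <- make_dvt(split(as.matrix(dvt_rows), seq_len(nrow(dvt_rows))))
    vgt <- make_vgt(split(as.matrix(vgt_rows), seq_len(nrow(vgt_rows))))

    q1 <- disease_query("q1", sample(cuis, 2))
    q2 <- disease_query("q2", sample(cuis, 2))
    qu <- disease_query("qu", union(q1$cuis, q2$cuis))
    g1 <- suppressMessages(genes_for_diseases(dvt, vgt, q1))$genes
    g2 <- suppressMessages(genes_for_diseases(dvt, vgt, q2))$genes
    gu <- suppressMessages(genes_for_diseases(dvt, vgt, qu))$genes
    expect_setequal(gu, union(g1, g2))
    expect_true(all(g1 %in% gu))

    # shuffle and duplicate rows: result unchanged
    shuf <- dvt_rows[sample(rep(seq_len(nrow(dvt_rows)), 2)), ]
    dvt_s <- make_dvt(split(as.matrix(shuf), seq_len(nrow(shuf))))
    expect_setequal(
      suppressMessages(genes_for_diseases(dvt_s, vgt, q1))$genes, g1)
  }
})

test_that("variant-set intersection reports shared identifiers only", {
  expect_equal(suppressMessages(intersect_variant_sets(c("rs1", "rs2"), "rs2")),
               "rs2")
  expect_length(suppressMessages(intersect_variant_sets(c("rs1"), c("rs9"))), 0)
  expect_length(suppressMessages(intersect_variant_sets(character(), c("rs1"))), 0)
})

test_that("disease queries validate CUIs and load from text, YAML and JSON", {
  expect_error(disease_query("x", character()), ">= 1 CUI")
  expect_message(disease_query("x", c("C01", "weird")), "pattern")

  txt <- write_tsv_lines(c("# comment", "C0002395", "C0520679"))
  q <- read_disease_query(txt, label = "pair")
  expect_equal(q$cuis, c("C0002395", "C0520679"))

  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(label = "osa", cuis = c("C0520679")), yml)
  expect_equal(read_disease_query(yml)$label, "osa")

  js <- tempfile(fileext = ".json")
  jsonlite::write_json(list(label = "dem", cuis = c("C0497327")), js,
                       auto_unbox = TRUE)
  expect_equal(read_disease_query(js)$cuis, "C0497327")
})

test_that("the shipped reference queries carry 14 dementia and 3 OSA CUIs", {
  q <- reference_disease_queries()
  expect_length(q$dementia$cuis, 14)
  expect_length(q$osa$cuis, 3)
  expect_true("C0002395" %in% q$dementia$cuis)
  expect_true("C0520679" %in% q$osa$cuis)
})
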