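test_that("empirical p-values are the exact occurrence ratio", {
  expect_equal(empirical_pvalue(0, 1000), 0)
  expect_equal(empirical_pvalue(1000, 1000), 1)
  expect_equal(empirical_pvalue(3, 361000), 3 / 361000)
  expect_equal(empirical_pvalue(49, 361000), 49 / 361000)
  expect_equal(empirical_pvalue(0, 99, plus_one = TRUE), 1 / 100)
  expect_error(empirical_pvalue(5, 4), "0 <= x <= iterations")
  expect_error(empirical_pvalue(1, 0), ">= 1")
})

test_that("BH adjustment matches the hand-coded step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(0.05, 0.01)), c(0.05, 0.02))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(303)
  for (i in 1:50) {
    p <- stats::runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("null replicates are size-correct, in-universe and reproducible", {
  u <- c("A", "B", "C")
  set.seed(1); s1 <- sample_null_replicate(u, 1, 1)
  set.seed(1); s2 <- sample_null_replicate(u, 1, 1)
  expect_identical(s1, s2)
  expect_true(s1$a %in% u && s1$b %in% u)
  expect_length(sample_null_replicate(u, 0, 2)$a, 0)
  expect_error(sample_null_replicate(u, 4, 1), "exceeds universe")
})

test_that("a hub adjacent to every other gene is rediscovered whenever it is not itself sampled", {
  # star: HUB is a null candidate iff neither single-gene sample picked HUB
  # (a gene is never its own neighbor), so exact null P = (5/6)^2
  genes <- c("HUB", sprintf("G%d", 1:5))
  net <- gene_network(cbind("HUB", genes[-1]))
  cand <- suppressMessages(find_primary_candidates(
    net, gene_set("G1"), gene_set("G2")))
  iters <- 20000
  cfg <- permutation_config(mode = "gene", iterations = iters, seed = 4)
  res <- suppressMessages(run_permutation(net, gene_set("G1"), gene_set("G2"),
                                          cand, cfg))
  hub <- res$table[res$table$gene == "HUB", ]
  exact <- (5 / 6)^2
  expect_equal(exact, exact_single_draw_prob(net, net$nodes, "HUB"))
  expect_lt(abs(hub$p - exact), 4 * sqrt(exact * (1 - exact) / iters))
})

test_that("gene-mode empirical p approaches the enumerated exact null on the toy universe", {
  net <- toy_universe_net()
  exact <- exact_single_draw_prob(net, net$nodes, "C1")
  expect_equal(exact, 4 / 25)

  cand <- suppressMessages(find_primary_candidates(
    net, gene_set("D1"), gene_set("O1")))
  iters <- 10000
  cfg <- permutation_config(mode = "gene", iterations = iters, seed = 21)
  res <- suppressMessages(run_permutation(net, gene_set("D1"), gene_set("O1"),
                                          cand, cfg))
  p_hat <- res$table$p[res$table$gene == "C1"]
  se <- sqrt(exact * (1 - exact) / iters)
  expect_lt(abs(p_hat - exact), 4 * se)
})

test_that("permutation runs are bit-identical given the same seed and config", {
  set.seed(88)
  net <- random_network(40, 0.1)
  sa <- gene_set(sample(net$nodes, 4)); sb <- gene_set(sample(net$nodes, 4))
  cand <- suppressMessages(find_primary_candidates(net, sa, sb,
                                                   exclude_seeds = FALSE))
  cfg <- permutation_config(mode = "gene", iterations = 300, seed = 12)
  r1 <- suppressMessages(run_permutation(net, sa, sb, cand, cfg))
  r2 <- suppressMessages(run_permutation(net, sa, sb, cand, cfg))
  expect_identical(r1, r2)
  r3 <- suppressMessages(run_permutation(
    net, sa, sb, cand, permutation_config(mode = "gene", iterations = 300,
                                          seed = 13)))
  expect_false(identical(r1$table$x, r3$table$x))
})

test_that("occurrence counts conserve the per-replicate overlap sizes", {
  set.seed(14)
  net <- random_network(30, 0.15)
  sa <- gene_set(sample(net$nodes, 3)); sb <- gene_set(sample(net$nodes, 3))
  cand <- suppressMessages(find_primary_candidates(net, sa, sb,
                                                   exclude_seeds = FALSE))
  cfg <- permutation_config(mode = "gene", iterations = 250, seed = 3)
  res <- suppressMessages(run_permutation(net, sa, sb, cand, cfg))
  expect_equal(sum(res$table$x), sum(res$replicate_overlap_sizes))
  expect_true(all(res$table$x >= 0 & res$table$x <= res$iterations))
  expect_equal(res$table$p, res$table$x / res$iterations)
  expect_true(all(res$table$q >= res$table$p - 1e-15))
})

test_that("disease_id mode samples CUI sets and expands them through the tables", {
  # 10 CUIs, each owning one gene wired to a shared middle gene
  cuis <- sprintf("C%02d", 1:10)
  genes <- sprintf("GENE%02d", 1:10)
  dvt_path <- write_tsv_lines(c("diseaseId\tsnpId",
                                paste(cuis, sprintf("rs%d", 1:10), sep = "\t")))
  vgt_path <- write_tsv_lines(c("snpId\tgeneSymbol",
                                paste(sprintf("rs%d", 1:10), genes, sep = "\t")))
  dvt <- suppressMessages(read_disease_variant_table(dvt_path))
  vgt <- suppressMessages(read_variant_gene_table(vgt_path))
  # MID is wired to the genes of the first five CUIs only; genes of the
  # other five CUIs are absent from the network entirely
  net <- gene_network(cbind("MID", genes[1:5]))
  qa <- disease_query("a", "C01")
  qb <- disease_query("b", "C02")
  ga <- suppressMessages(genes_for_diseases(dvt, vgt, qa))
  gb <- suppressMessages(genes_for_diseases(dvt, vgt, qb))
  cand <- suppressMessages(find_primary_candidates(net, ga, gb))
  expect_equal(cand$gene, "MID")

  iters <- 4000
  cfg <- permutation_config(mode = "disease_id", iterations = iters, seed = 5)
  res <- suppressMessages(run_permutation(net, ga, gb, cand, cfg,
                                          dvt = dvt, vgt = vgt,
                                          query_a = qa, query_b = qb))
  # MID is a null candidate iff both sampled single-CUI sets expand to one
  # of its five neighbor genes: exact null P = (5/10) * (5/10) = 0.25
  exact <- 0.25
  se <- sqrt(exact * (1 - exact) / iters)
  expect_lt(abs(res$table$p - exact), 4 * se)
  expect_error(
    suppressMessages(run_permutation(net, ga, gb, cand, cfg)),
    "disease_id mode requires")
})

test_that("significant drivers are FDR-filtered and ordered by p", {
  net <- toy_universe_net()
  cand <- suppressMessages(find_primary_candidates(
    net, gene_set("D1"), gene_set("O1")))
  cfg <- permutation_config(mode = "gene", iterations = 500, seed = 2)
  res <- suppressMessages(run_permutation(net, gene_set("D1"), gene_set("O1"),
                                          cand, cfg))
  all_q1 <- res
  all_q1$table$q <- rep(1, nrow(res$table))
  expect_equal(nrow(suppressMessages(
    significant_drivers(all_q1, cand, alpha = 0.05))), 0)

  fake <- res
  fake$table$p <- c(0.001)[seq_len(nrow(res$table))]
  fake$table$q <- c(0.01)[seq_len(nrow(res$table))]
  out <- suppressMessages(significant_drivers(fake, cand, alpha = 0.05))
  expect_equal(out$gene, "C1")
  expect_true(all(c("x", "p", "q") %in% names(out)))
})

test_that("permutation TSV export carries counts, p, q and the config sidecar", {
  net <- toy_universe_net()
  sa <- gene_set("D1"); sb <- gene_set("O1")
  cand <- suppressMessages(find_primary_candidates(net, sa, sb))
  cfg <- permutation_config(mode = "gene", iterations = 100, seed = 6)
  res <- suppressMessages(run_permutation(net, sa, sb, cand, cfg))
  p <- tempfile(fileext = ".tsv")
  write_permutation_result(res, cand, p)
  df <- read.delim(p)
  expect_equal(names(df),
               c("gene", "support_a", "support_b", "x", "p", "q",
                 "significant"))
  side <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(side$iterations, 100)
  expect_equal(side$mode, "gene")
})
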