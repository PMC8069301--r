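#' Configuration for a synthetic two-disease scenario
#'
#' Describes a fully self-contained benchmark: an independent-edge random
#' background network, two synthetic "diseases" defined by made-up CUIs
#' with DisGeNET-format variant tables, planted common drivers (genes wired
#' to at least one gene of each disease) and one-sided decoys (genes wired
#' to genes of exactly one disease, with edges to the other disease's genes
#' removed). Ground truth is recorded so pipeline runs can be scored.
#'
#' Defaults emulate the reference study's shape at desk scale: 14 vs 3
#' disease identifiers with strongly asymmetric gene sets, a sparse
#' background graph, a handful of true planted drivers and decoys.
#'
#' @param n_genes Total genes in the universe.
#' @param background_edge_prob Independent edge probability of the
#'   background graph.
#' @param n_cuis_a,n_cuis_b Number of synthetic CUIs per disease.
#' @param genes_per_cui Disease genes assigned to each CUI (disjoint within
#'   and across diseases).
#' @param n_planted_drivers Genes planted adjacent to both disease sets.
#' @param n_decoys_a,n_decoys_b Genes planted adjacent to only one disease
#'   set (edges to the other set are removed).
#' @param variants_per_gene Synthetic rs-variants generated per disease
#'   gene.
#' @param seed Integer RNG seed; generation is deterministic given it.
#' @return An object of class `nicd_scenario_config`.
#' @export
scenario_config <- function(n_genes = 2000, background_edge_prob = 0.002,
                            n_cuis_a = 14, n_cuis_b = 3, genes_per_cui = 3,
                            n_planted_drivers = 5, n_decoys_a = 5,
                            n_decoys_b = 5, variants_per_gene = 2,
                            seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              background_edge_prob = background_edge_prob,
              n_cuis_a = as.integer(n_cuis_a),
              n_cuis_b = as.integer(n_cuis_b),
              genes_per_cui = as.integer(genes_per_cui),
              n_planted_drivers = as.integer(n_planted_drivers),
              n_decoys_a = as.integer(n_decoys_a),
              n_decoys_b = as.integer(n_decoys_b),
              variants_per_gene = as.integer(variants_per_gene),
              seed = as.integer(seed))
  counts <- unlist(cfg[c("n_genes", "n_cuis_a", "n_cuis_b", "genes_per_cui",
                         "n_planted_drivers", "n_decoys_a", "n_decoys_b",
                         "variants_per_gene")])
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("all scenario counts must be >= 0", call. = FALSE)
  }
  if (!(background_edge_prob >= 0 && background_edge_prob <= 1)) {
    stop("background_edge_prob must be in [0, 1]", call. = FALSE)
  }
  n_roles <- (cfg$n_cuis_a + cfg$n_cuis_b) * cfg$genes_per_cui +
    cfg$n_planted_drivers + cfg$n_decoys_a + cfg$n_decoys_b
  if (cfg$n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  if (n_roles > cfg$n_genes) {
    stop(sprintf(
      "infeasible scenario: %d role genes (seeds + drivers + decoys) > %d genes",
      n_roles, cfg$n_genes), call. = FALSE)
  }
  structure(cfg, class = "nicd_scenario_config")
}

#' Generate a synthetic scenario on disk
#'
#' Writes, into `dir`: a background edge-list TSV
#' (`network_edges.tsv`), DisGeNET-format tables
#' (`all_variant_disease_associations.tsv`,
#' `variant_to_gene_mappings.tsv`), two CUI query files (`cuis_a.txt`,
#' `cuis_b.txt`), and a JSON manifest (`manifest.json`) naming every file,
#' the seed and the ground truth. Background edges are drawn independently
#' with `background_edge_prob`; planted-driver and decoy adjacency is then
#' enforced (drivers gain one edge into each disease set if missing; decoys
#' lose every edge into the opposite disease set and gain one into their
#' own). Byte-identical output given the same config.
#'
#' @param cfg A [scenario_config()].
#' @param dir Output directory (created if needed).
#' @return An object of class `nicd_scenario_truth`: list with `planted`,
#'   `decoys_a`, `decoys_b`, `cui_genes_a`, `cui_genes_b` (named lists:
#'   CUI -> genes), `query_a`, `query_b`, `files`, `cfg`.
#' @export
generate_scenario <- function(cfg, dir) {
  stopifnot(inherits(cfg, "nicd_scenario_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)

  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  n_a <- cfg$n_cuis_a * cfg$genes_per_cui
  n_b <- cfg$n_cuis_b * cfg$genes_per_cui
  roles <- sample(genes, n_a + n_b + cfg$n_planted_drivers +
                    cfg$n_decoys_a + cfg$n_decoys_b)
  take <- function(k) {
    out <- roles[seq_len(k)]
    roles <<- roles[-seq_len(k)]
    out
  }
  a_genes <- take(n_a)
  b_genes <- take(n_b)
  planted <- take(cfg$n_planted_drivers)
  decoys_a <- take(cfg$n_decoys_a)
  decoys_b <- take(cfg$n_decoys_b)

  cuis_a <- sprintf("C9%05d", seq_len(cfg$n_cuis_a))
  cuis_b <- sprintf("C8%05d", seq_len(cfg$n_cuis_b))
  cui_genes_a <- split(a_genes, rep(cuis_a, each = cfg$genes_per_cui))[cuis_a]
  cui_genes_b <- split(b_genes, rep(cuis_b, each = cfg$genes_per_cui))[cuis_b]
  if (cfg$n_cuis_a == 0 || cfg$genes_per_cui == 0) {
    cui_genes_a <- stats::setNames(list(), character())
  }
  if (cfg$n_cuis_b == 0 || cfg$genes_per_cui == 0) {
    cui_genes_b <- stats::setNames(list(), character())
  }

  g <- igraph::sample_gnp(cfg$n_genes, cfg$background_edge_prob)
  igraph::V(g)$name <- genes
  el <- igraph::as_edgelist(g, names = TRUE)

  pick1 <- function(v) if (length(v) == 1) v else sample(v, 1)
  add <- NULL
  adjacent_to <- function(el, add, x, set) {
    any(el[, 1] == x & el[, 2] %in% set) ||
      any(el[, 2] == x & el[, 1] %in% set) ||
      (!is.null(add) && any((add[, 1] == x & add[, 2] %in% set) |
                            (add[, 2] == x & add[, 1] %in% set)))
  }
  for (d in planted) {
    if (n_a > 0 && !adjacent_to(el, add, d, a_genes)) {
      add <- rbind(add, c(d, pick1(a_genes)))
    }
    if (n_b > 0 && !adjacent_to(el, add, d, b_genes)) {
      add <- rbind(add, c(d, pick1(b_genes)))
    }
  }
  # decoys: sever every link into the opposite disease set, ensure one into
  # their own
  drop_rows <- function(el, xs, set) {
    bad <- (el[, 1] %in% xs & el[, 2] %in% set) |
      (el[, 2] %in% xs & el[, 1] %in% set)
    el[!bad, , drop = FALSE]
  }
  el <- drop_rows(el, decoys_a, b_genes)
  el <- drop_rows(el, decoys_b, a_genes)
  for (d in decoys_a) {
    if (n_a > 0 && !adjacent_to(el, add, d, a_genes)) {
      add <- rbind(add, c(d, pick1(a_genes)))
    }
  }
  for (d in decoys_b) {
    if (n_b > 0 && !adjacent_to(el, add, d, b_genes)) {
      add <- rbind(add, c(d, pick1(b_genes)))
    }
  }
  el <- rbind(el, add)
  net <- gene_network(el, nodes = genes, provenance = "synthetic scenario")

  # DisGeNET-format tables: variants_per_gene rs tokens per disease gene,
  # linked to every CUI the gene belongs to
  rs_counter <- 0L
  dvt_rows <- list()
  vgt_rows <- list()
  for (side in list(cui_genes_a, cui_genes_b)) {
    for (cui in names(side)) {
      for (gn in side[[cui]]) {
        for (i in seq_len(cfg$variants_per_gene)) {
          rs_counter <- rs_counter + 1L
          rs <- sprintf("rs9%07d", rs_counter)
          dvt_rows[[length(dvt_rows) + 1L]] <- c(cui, rs)
          vgt_rows[[length(vgt_rows) + 1L]] <- c(rs, gn)
        }
      }
    }
  }
  dvt <- as.data.frame(do.call(rbind, dvt_rows) %||%
                         matrix(character(), ncol = 2))
  names(dvt) <- c("diseaseId", "snpId")
  vgt <- as.data.frame(do.call(rbind, vgt_rows) %||%
                         matrix(character(), ncol = 2))
  names(vgt) <- c("snpId", "geneSymbol")

  files <- list(
    network = file.path(dir, "network_edges.tsv"),
    disease_variant = file.path(dir, "all_variant_disease_associations.tsv"),
    variant_gene = file.path(dir, "variant_to_gene_mappings.tsv"),
    cuis_a = file.path(dir, "cuis_a.txt"),
    cuis_b = file.path(dir, "cuis_b.txt"),
    manifest = file.path(dir, "manifest.json")
  )
  write_edge_list(net, files$network)
  utils::write.table(dvt, files$disease_variant, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(vgt, files$variant_gene, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(cuis_a, files$cuis_a)
  writeLines(cuis_b, files$cuis_b)

  truth <- structure(list(
    planted = sort(planted), decoys_a = sort(decoys_a),
    decoys_b = sort(decoys_b),
    cui_genes_a = cui_genes_a, cui_genes_b = cui_genes_b,
    query_a = disease_query("synthetic disease A", cuis_a),
    query_b = disease_query("synthetic disease B", cuis_b),
    files = files, cfg = unclass(cfg)
  ), class = "nicd_scenario_truth")
  jsonlite::write_json(
    list(seed = cfg$seed, config = unclass(cfg),
         files = lapply(files, basename),
         truth = list(planted = truth$planted, decoys_a = truth$decoys_a,
                      decoys_b = truth$decoys_b,
                      cui_genes_a = cui_genes_a, cui_genes_b = cui_genes_b)),
    files$manifest, auto_unbox = TRUE, pretty = TRUE)
  nicd_msg(sprintf(
    "scenario: %d genes, %d edges, |A|=%d, |B|=%d, %d planted, %d+%d decoys",
    cfg$n_genes, nrow(net$edges), n_a, n_b, cfg$n_planted_drivers,
    cfg$n_decoys_a, cfg$n_decoys_b))
  truth
}

#' Verify a generated scenario against its ground truth
#'
#' Reloads every file with the package's own readers and re-checks the
#' construction invariants: files present; every planted driver has at
#' least one edge into each disease gene set and is not itself a disease
#' gene; every decoy has at least one edge into its own disease set and
#' none into the other; the disease gene sets recovered from the
#' DisGeNET-format tables match the truth manifest.
#'
#' @param truth A [generate_scenario()] result.
#' @return A data frame with columns `check` and `pass`; attribute `ok`
#'   is `TRUE` iff all checks pass.
#' @export
verify_truth <- function(truth) {
  stopifnot(inherits(truth, "nicd_scenario_truth"))
  missing <- !vapply(truth$files, file.exists, logical(1))
  if (any(missing)) {
    stop("scenario file(s) missing: ",
         paste(basename(unlist(truth$files[missing])), collapse = ", "),
         call. = FALSE)
  }
  net <- suppressMessages(load_edge_list(truth$files$network))
  dvt <- suppressMessages(read_disease_variant_table(truth$files$disease_variant))
  vgt <- suppressMessages(read_variant_gene_table(truth$files$variant_gene))
  ga <- suppressMessages(genes_for_diseases(dvt, vgt, truth$query_a))
  gb <- suppressMessages(genes_for_diseases(dvt, vgt, truth$query_b))
  a_genes <- unique(unlist(truth$cui_genes_a, use.names = FALSE)) %||% character()
  b_genes <- unique(unlist(truth$cui_genes_b, use.names = FALSE)) %||% character()

  linked <- function(x, set) {
    x %in% names(net$adj) && length(intersect(net$adj[[x]], set)) > 0
  }
  checks <- list(
    `disease A genes match tables` = setequal(ga$genes, a_genes),
    `disease B genes match tables` = setequal(gb$genes, b_genes),
    `drivers not disease genes` =
      length(intersect(truth$planted, c(a_genes, b_genes))) == 0,
    `driver bi-linkage` =
      all(vapply(truth$planted, function(d)
        linked(d, a_genes) && linked(d, b_genes), logical(1))),
    `decoys A linked to A only` =
      all(vapply(truth$decoys_a, function(d)
        linked(d, a_genes) && !linked(d, b_genes), logical(1))),
    `decoys B linked to B only` =
      all(vapply(truth$decoys_b, function(d)
        linked(d, b_genes) && !linked(d, a_genes), logical(1)))
  )
  out <- data.frame(check = names(checks),
                    pass = unlist(checks, use.names = FALSE))
  attr(out, "ok") <- all(out$pass)
  out
}
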