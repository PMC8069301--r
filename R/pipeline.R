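#' Run the full common-driver identification pipeline
#'
#' Orchestrates the whole analysis from a declarative configuration:
#' disease gene/variant assembly from the DisGeNET-format tables, network
#' loading and hub exclusion, primary-candidate identification, the
#' permutation test with BH correction, and (optionally) Fisher-exact
#' pathway enrichment of the significant drivers against GMT libraries.
#' All defaults (UBC exclusion, alpha 0.05, iterations = 100 * candidates,
#' disease_id sampling) are materialized into a provenance sidecar so every
#' under-specified choice is explicit per run.
#'
#' @param config A named list, or a path to a YAML/JSON file, with entries:
#'   \describe{
#'     \item{network}{path to the edge list; optional `network_format`
#'       ("tsv"/"sif") and `network_mapping` (identifier mapping file).}
#'     \item{disease_variant_table, variant_gene_table}{paths to the
#'       DisGeNET-format tables.}
#'     \item{query_a, query_b}{paths to CUI query files (or lists with
#'       `label` and `cuis`).}
#'     \item{excluded_genes}{genes removed from the network; default "UBC".}
#'     \item{permutation}{list of [permutation_config()] arguments.}
#'     \item{gmt}{optional named list of GMT library paths.}
#'     \item{exclude_seeds}{candidate flag; default `TRUE`.}
#'     \item{output_dir}{where reports are written.}
#'   }
#' @param output_dir Overrides `config$output_dir`.
#' @return Invisibly, a list with every intermediate object (`network`,
#'   `genes_a`, `genes_b`, `common_variants`, `candidates`, `permutation`,
#'   `drivers`, `enrichment`, `provenance`) and the report paths.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    ext <- tolower(tools::file_ext(config))
    config <- if (ext == "json") {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  out_dir <- output_dir %||% config$output_dir
  if (is.null(out_dir)) stop("config needs an output_dir", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  as_query <- function(q, label) {
    if (inherits(q, "nicd_disease_query")) q
    else if (is.list(q)) disease_query(q$label %||% label, q$cuis)
    else read_disease_query(q, label = label)
  }

  dvt <- stage("disgenet_io",
               read_disease_variant_table(config$disease_variant_table))
  vgt <- stage("disgenet_io",
               read_variant_gene_table(config$variant_gene_table))
  query_a <- stage("disgenet_io", as_query(config$query_a, "disease A"))
  query_b <- stage("disgenet_io", as_query(config$query_b, "disease B"))
  variants_a <- variants_for_diseases(dvt, query_a)
  variants_b <- variants_for_diseases(dvt, query_b)
  common_variants <- intersect_variant_sets(variants_a, variants_b)
  genes_a <- stage("disgenet_io", genes_for_diseases(dvt, vgt, query_a))
  genes_b <- stage("disgenet_io", genes_for_diseases(dvt, vgt, query_b))

  net <- stage("network_core", {
    n <- load_edge_list(config$network,
                        format = config$network_format %||% "tsv",
                        mapping = config$network_mapping)
    exclude_genes(n, config$excluded_genes %||% "UBC")
  })

  exclude_seeds <- config$exclude_seeds %||% TRUE
  candidates <- stage("candidate_finder",
                      find_primary_candidates(net, genes_a, genes_b,
                                              exclude_seeds = exclude_seeds))

  pc <- config$permutation %||% list()
  cfg <- permutation_config(mode = pc$mode %||% "disease_id",
                            iterations = pc$iterations,
                            seed = pc$seed %||% 1L,
                            alpha = pc$alpha %||% 0.05,
                            plus_one = isTRUE(pc$plus_one),
                            progress_every = pc$progress_every %||% 0L)
  perm <- NULL
  drivers <- candidates[0, ]
  drivers$x <- integer(); drivers$p <- numeric(); drivers$q <- numeric()
  if (nrow(candidates) > 0) {
    perm <- stage("permutation_test",
                  run_permutation(net, genes_a, genes_b, candidates, cfg,
                                  dvt = dvt, vgt = vgt,
                                  query_a = query_a, query_b = query_b))
    drivers <- significant_drivers(perm, candidates)
  } else {
    warning("no primary candidates; driver report will be empty",
            call. = FALSE)
  }

  enrichment <- list()
  flags <- list()
  if (!is.null(config$gmt) && nrow(drivers) > 0) {
    libs <- config$gmt
    if (is.null(names(libs))) {
      names(libs) <- vapply(unlist(libs), function(p)
        tools::file_path_sans_ext(basename(p)), "")
    }
    for (lib_name in names(libs)) {
      lib <- stage("enrichment", read_gmt(libs[[lib_name]], name = lib_name))
      enr <- stage("enrichment", fisher_enrichment(drivers$gene, lib))
      enrichment[[lib_name]] <- enr
      hit_terms <- enr$term[enr$q <= cfg$alpha]
      hit_genes <- unique(unlist(strsplit(
        enr$overlap[enr$term %in% hit_terms], ","), use.names = FALSE))
      flags[[lib_name]] <- drivers$gene %in% hit_genes
    }
  }

  report <- data.frame(
    gene = drivers$gene,
    support_a = vapply(drivers$support_a, paste, "", collapse = ","),
    support_b = vapply(drivers$support_b, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  for (lib_name in names(flags)) report[[lib_name]] <- flags[[lib_name]]
  report$x <- drivers$x
  report$p <- drivers$p
  report$q <- drivers$q

  paths <- list(
    drivers = file.path(out_dir, "drivers.tsv"),
    candidates = file.path(out_dir, "candidates.tsv"),
    variant_intersection = file.path(out_dir, "variant_intersection.tsv"),
    provenance = file.path(out_dir, "provenance.json")
  )
  utils::write.table(report, paths$drivers, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_candidates(candidates, paths$candidates)
  utils::write.table(
    data.frame(variant = common_variants, stringsAsFactors = FALSE),
    paths$variant_intersection, sep = "\t", quote = FALSE, row.names = FALSE)
  for (lib_name in names(enrichment)) {
    p <- file.path(out_dir, sprintf("enrichment_%s.tsv", lib_name))
    write_enrichment(enrichment[[lib_name]], p)
    paths[[paste0("enrichment_", lib_name)]] <- p
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("nicd")),
    seed = cfg$seed, mode = cfg$mode, alpha = cfg$alpha,
    iterations = if (!is.null(perm)) perm$iterations else 0L,
    exclude_seeds = exclude_seeds,
    excluded_genes = as.character(config$excluded_genes %||% "UBC"),
    counts = list(
      network_nodes = length(net$nodes), network_edges = nrow(net$edges),
      variants_a = length(variants_a), variants_b = length(variants_b),
      common_variants = length(common_variants),
      genes_a = length(genes_a$genes), genes_b = length(genes_b$genes),
      candidates = nrow(candidates), drivers = nrow(report))
  )
  jsonlite::write_json(provenance, paths$provenance, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(network = net, query_a = query_a, query_b = query_b,
                 genes_a = genes_a, genes_b = genes_b,
                 variants_a = variants_a, variants_b = variants_b,
                 common_variants = common_variants,
                 candidates = candidates, permutation = perm,
                 drivers = drivers, report = report,
                 enrichment = enrichment, provenance = provenance,
                 paths = paths))
}

#' Count drivers per chromosome
#'
#' Optional tabulation of a driver set by chromosome, given a two-column
#' gene -> chromosome mapping file (TSV, no header required if exactly two
#' columns). Drivers absent from the mapping are counted under `unmapped`.
#'
#' @param drivers A driver data frame (with a `gene` column) or character
#'   vector of genes.
#' @param mapping_path Path to the gene -> chromosome TSV.
#' @return Named integer vector of counts per chromosome label (plus
#'   `unmapped` when needed).
#' @export
chromosome_summary <- function(drivers, mapping_path) {
  genes <- if (is.data.frame(drivers)) drivers$gene else as_gene_vector(drivers)
  map <- utils::read.delim(gzfile(mapping_path), header = FALSE,
                           colClasses = "character")
  lut <- stats::setNames(map[[2]], norm_gene_id(map[[1]]))
  chr <- unname(lut[norm_gene_id(genes)])
  chr[is.na(chr)] <- "unmapped"
  counts <- table(chr)
  out <- stats::setNames(as.integer(counts), names(counts))
  if (length(out) == 0) return(stats::setNames(integer(), character()))
  out[order(names(out))]
}
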