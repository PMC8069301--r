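#' Disease queries: labelled UMLS CUI lists
#'
#' A disease (or disease umbrella) is represented by a set of UMLS Concept
#' Unique Identifiers used to query DisGeNET-style tables. The shipped
#' reference profiles carry 14 dementia-related CUIs and 3 obstructive
#' sleep apnea CUIs (see `system.file("extdata", package = "nicd")`).
#'
#' @param label Free-text disease label, e.g. "dementia".
#' @param cuis Character vector of UMLS CUIs (pattern `C` + digits).
#' @return An object of class `nicd_disease_query`.
#' @export
disease_query <- function(label, cuis) {
  cuis <- unique(trimws(as.character(cuis)))
  cuis <- cuis[nzchar(cuis)]
  if (length(cuis) == 0) stop("disease query needs >= 1 CUI", call. = FALSE)
  bad <- cuis[!grepl("^C[0-9]+$", cuis)]
  if (length(bad) > 0) {
    nicd_msg("CUI(s) not matching C<digits> pattern (kept): ",
             paste(bad, collapse = ", "))
  }
  structure(list(label = as.character(label), cuis = cuis),
            class = "nicd_disease_query")
}

#' @export
print.nicd_disease_query <- function(x, ...) {
  cat(sprintf("<disease query '%s': %d CUIs>\n", x$label, length(x$cuis)))
  invisible(x)
}

#' Read a disease query from a file
#'
#' Accepts a plain text file (one CUI per line, `#` comments allowed), or a
#' YAML/JSON file with fields `label` and `cuis`.
#'
#' @param path Path to the query file.
#' @param label Label used for plain-text files; defaults to the file stem.
#' @return A [disease_query()] object.
#' @export
read_disease_query <- function(path, label = NULL) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("yaml", "yml", "json")) {
    obj <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
           else yaml::read_yaml(path)
    return(disease_query(obj$label %||% label %||% basename(path), obj$cuis))
  }
  lines <- trimws(read_text_lines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  disease_query(label %||% tools::file_path_sans_ext(basename(path)), lines)
}

read_mapping_table <- function(path, columns, what) {
  df <- utils::read.delim(gzfile(path), header = TRUE, sep = "\t",
                          quote = "", comment.char = "",
                          colClasses = "character")
  missing <- setdiff(unname(columns), names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s table %s lacks column(s) %s; found: %s",
                 what, path, paste(missing, collapse = ", "),
                 paste(names(df), collapse = ", ")), call. = FALSE)
  }
  out <- df[, unname(columns), drop = FALSE]
  names(out) <- names(columns)
  out[] <- lapply(out, trimws)
  out <- unique(out[rowSums(out == "") == 0, , drop = FALSE])
  rownames(out) <- NULL
  if (nrow(out) == 0) warning(what, " table is empty: ", path, call. = FALSE)
  out
}

#' Read a DisGeNET-style disease-variant association table
#'
#' Parses a (gzipped) TSV with a header row into a deduplicated
#' (CUI, variant) table. Column names are configurable because DisGeNET
#' dump schemas drift across releases; defaults match the
#' `all_variant_disease_associations.tsv.gz` dump. No filtering on
#' association scores or evidence classes is applied: disease membership
#' is "any record".
#'
#' @param path Path to the TSV(.gz) file.
#' @param columns Named character vector mapping internal names `cui` and
#'   `variant` to the file's column headers.
#' @return A data frame of class `nicd_disease_variant_table` with character
#'   columns `cui` and `variant`, unique rows.
#' @export
read_disease_variant_table <- function(path,
                                       columns = c(cui = "diseaseId",
                                                   variant = "snpId")) {
  out <- read_mapping_table(path, columns, "disease-variant")
  bad <- unique(out$cui[!grepl("^C[0-9]+$", out$cui)])
  if (length(bad) > 0) {
    nicd_msg(length(bad), " disease id(s) not matching the C<digits> CUI ",
             "pattern (kept)")
  }
  nicd_msg(sprintf("disease-variant table: %d unique pairs, %d distinct CUIs",
                   nrow(out), length(unique(out$cui))))
  class(out) <- c("nicd_disease_variant_table", class(out))
  out
}

#' Read a DisGeNET-style variant-gene mapping table
#'
#' As [read_disease_variant_table()], for (variant, gene) pairs; defaults
#' match the `variant_to_gene_mappings.tsv.gz` dump. A variant may map to
#' several genes. Gene identifiers are case-normalized.
#'
#' @param path Path to the TSV(.gz) file.
#' @param columns Named character vector mapping internal names `variant`
#'   and `gene` to the file's column headers.
#' @return A data frame of class `nicd_variant_gene_table` with character
#'   columns `variant` and `gene`, unique rows.
#' @export
read_variant_gene_table <- function(path,
                                    columns = c(variant = "snpId",
                                                gene = "geneSymbol")) {
  out <- read_mapping_table(path, columns, "variant-gene")
  out$gene <- norm_gene_id(out$gene)
  out <- unique(out)
  rownames(out) <- NULL
  nicd_msg(sprintf("variant-gene table: %d unique pairs, %d distinct genes",
                   nrow(out), length(unique(out$gene))))
  class(out) <- c("nicd_variant_gene_table", class(out))
  out
}

#' Variants associated with a disease query
#'
#' Union of variant ids over all CUIs of the query. Variants are compared
#' as exact identifier strings (typically rsIDs); no liftover or allele
#' handling.
#'
#' @param dvt A [read_disease_variant_table()] result.
#' @param query A [disease_query()].
#' @return Sorted character vector of variant ids.
#' @export
variants_for_diseases <- function(dvt, query) {
  stopifnot(inherits(query, "nicd_disease_query"))
  hit <- dvt$cui %in% query$cuis
  empty <- setdiff(query$cuis, dvt$cui)
  if (length(empty) > 0) {
    nicd_msg("CUI(s) with zero variants for '", query$label, "': ",
             paste(empty, collapse = ", "))
  }
  sort(unique(dvt$variant[hit]))
}

#' Disease gene set for a disease query
#'
#' A gene belongs to a disease if any of the disease's variants has a
#' variant-gene mapping record for it: the set
#' \{g : exists v with (cui in query, v) in dvt and (v, g) in vgt\}.
#'
#' @param dvt A [read_disease_variant_table()] result.
#' @param vgt A [read_variant_gene_table()] result.
#' @param query A [disease_query()].
#' @return A [gene_set()] labelled with the query's label.
#' @export
genes_for_diseases <- function(dvt, vgt, query) {
  v <- variants_for_diseases(dvt, query)
  genes <- vgt$gene[vgt$variant %in% v]
  gs <- gene_set(genes, label = query$label)
  nicd_msg(sprintf("'%s': %d variants -> %d genes", query$label,
                   length(v), length(gs$genes)))
  gs
}

#' Intersect two variant sets
#'
#' Reports variants shared by both diseases (in the reference study the
#' intersection is empty: the gene-level overlap is not driven by shared
#' SNPs).
#'
#' @param a,b Character vectors of variant ids.
#' @return Sorted character vector `a` intersect `b`.
#' @export
intersect_variant_sets <- function(a, b) {
  common <- sort(intersect(a, b))
  nicd_msg(sprintf("variant intersection: |a|=%d, |b|=%d, common=%d",
                   length(unique(a)), length(unique(b)), length(common)))
  common
}
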