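#' @keywords internal
"_PACKAGE"

# Gene identifiers are treated as opaque, case-normalized (uppercased) strings.
# No symbol <-> Entrez translation is attempted; see gene_id_map for remapping.
norm_gene_id <- function(x) toupper(trimws(as.character(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

nicd_msg <- function(...) message("[nicd] ", ...)

#' Construct a labelled gene set
#'
#' A gene set is a label plus a unique, case-normalized vector of gene
#' identifiers. Used for disease gene sets, candidate supports and
#' enrichment queries throughout the package.
#'
#' @param genes Character vector of gene identifiers (case-insensitive).
#' @param label Free-text label, e.g. a disease name.
#' @return An object of class `nicd_gene_set` with elements `label` and
#'   `genes` (sorted, unique, uppercased).
#' @export
gene_set <- function(genes = character(), label = "") {
  genes <- unique(norm_gene_id(genes))
  genes <- genes[nzchar(genes) & !is.na(genes)]
  structure(list(label = as.character(label), genes = sort(genes)),
            class = "nicd_gene_set")
}

#' @export
print.nicd_gene_set <- function(x, ...) {
  cat(sprintf("<gene set '%s': %d genes>\n", x$label, length(x$genes)))
  invisible(x)
}

#' @export
length.nicd_gene_set <- function(x) length(x$genes)

# Accept either an nicd_gene_set or a bare character vector of genes.
as_gene_vector <- function(x) {
  if (inherits(x, "nicd_gene_set")) x$genes else unique(norm_gene_id(x))
}

# Read text lines through a connection that transparently handles gzip.
read_text_lines <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read file (does not exist): ", path, call. = FALSE)
  }
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}
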