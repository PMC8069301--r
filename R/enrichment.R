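#' Read a GMT gene-set library
#'
#' Standard Gene Matrix Transposed format: one term per line as
#' `term <TAB> description <TAB> gene1 <TAB> gene2 ...`. Gene identifiers
#' are case-normalized and deduplicated within each term.
#'
#' @param path Path to the GMT file (plain or gzipped).
#' @param name Library name; defaults to the file stem.
#' @param background_size Background universe size for the Fisher test;
#'   default (`NULL`) is the number of distinct genes across the library.
#'   Override to e.g. the network node count for sensitivity analyses.
#' @return An object of class `nicd_gmt`: list with `name`, `terms` (named
#'   list of gene vectors) and `background_size`.
#' @export
read_gmt <- function(path, name = tools::file_path_sans_ext(basename(path)),
                     background_size = NULL) {
  lines <- read_text_lines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  terms <- list()
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(tok) < 3) {
      stop(sprintf("malformed GMT line %d (need term, description, >=1 gene)",
                   line_no[i]), call. = FALSE)
    }
    genes <- unique(norm_gene_id(tok[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (length(genes) > 0) terms[[tok[1]]] <- genes
  }
  if (length(terms) == 0) warning("empty GMT library: ", path, call. = FALSE)
  all_genes <- unique(unlist(terms, use.names = FALSE))
  bg <- background_size %||% length(all_genes)
  if (length(terms) > 0 && bg < max(lengths(terms))) {
    stop("background_size smaller than the largest term", call. = FALSE)
  }
  nicd_msg(sprintf("GMT '%s': %d terms, %d distinct genes, background %d",
                   name, length(terms), length(all_genes), bg))
  structure(list(name = name, terms = terms, background_size = bg,
                 genes = all_genes),
            class = "nicd_gmt")
}

#' @export
print.nicd_gmt <- function(x, ...) {
  cat(sprintf("<GMT library '%s': %d terms, background %d>\n",
              x$name, length(x$terms), x$background_size))
  invisible(x)
}

#' Fisher-exact gene-set enrichment against a GMT library
#'
#' For each term the one-sided (upper-tail) hypergeometric p-value of the
#' overlap between the query and the term on the 2x2 table
#' (k, n - k, K - k, N - K - n + k) is computed, where k = overlap size,
#' K = term size, n = query size after restriction to the background, and
#' N = background size. P-values are BH-adjusted across the library's
#' terms. This is the exact-test core of Enrichr-style enrichment (the
#' rank-combined z-score correction is intentionally not computed).
#'
#' @param query A [gene_set()] or character vector of query genes. Genes
#'   outside the background are dropped with a logged count.
#' @param lib A [read_gmt()] library.
#' @return A data frame of class `nicd_enrichment`, sorted by ascending p,
#'   with columns `term`, `k`, `K`, `n`, `N`, `p`, `q` and `overlap`
#'   (comma-joined sorted overlap genes).
#' @export
fisher_enrichment <- function(query, lib) {
  stopifnot(inherits(lib, "nicd_gmt"))
  qg <- as_gene_vector(query)
  if (length(qg) == 0) stop("query gene set is empty", call. = FALSE)
  in_bg <- intersect(qg, lib$genes)
  dropped <- length(qg) - length(in_bg)
  if (dropped > 0) {
    nicd_msg(dropped, " query gene(s) outside the '", lib$name,
             "' background, dropped")
  }
  n <- length(in_bg)
  N <- lib$background_size
  if (N < n) stop("background smaller than query after restriction",
                  call. = FALSE)

  rows <- lapply(names(lib$terms), function(tm) {
    tg <- lib$terms[[tm]]
    ov <- sort(intersect(in_bg, tg))
    k <- length(ov)
    K <- length(tg)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, p = p,
               overlap = paste(ov, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      overlap = character(), stringsAsFactors = FALSE)
  }
  out$q <- if (nrow(out) > 0) bh_adjust(out$p) else numeric()
  out <- out[order(out$p, out$term),
             c("term", "k", "K", "n", "N", "p", "q", "overlap")]
  rownames(out) <- NULL
  class(out) <- c("nicd_enrichment", class(out))
  out
}

#' Write an enrichment table to TSV
#'
#' @param enr A [fisher_enrichment()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(enr, path) {
  df <- enr
  df$k_over_K <- sprintf("%d/%d", df$k, df$K)
  df <- df[, c("term", "k_over_K", "p", "q", "overlap")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
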