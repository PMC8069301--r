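# Core of the candidate step on a plain adjacency list; shared with the
# permutation engine, where it runs once per replicate.
candidate_genes_core <- function(adj, nodes, genes_a, genes_b, exclude_seeds) {
  a_in <- intersect(genes_a, nodes)
  b_in <- intersect(genes_b, nodes)
  nbr_a <- unique(unlist(adj[a_in], use.names = FALSE))
  nbr_b <- unique(unlist(adj[b_in], use.names = FALSE))
  cand <- intersect(nbr_a, nbr_b)
  if (exclude_seeds) cand <- setdiff(cand, c(genes_a, genes_b))
  cand
}

#' Find primary candidate driver genes
#'
#' A primary candidate is a gene with at least one direct network neighbor
#' in *each* disease gene set. Candidacy is binary and purely topological
#' (distance-1 links only; no propagation, weights or expression data).
#' By default genes that themselves belong to either disease set are not
#' reported as candidates.
#'
#' @param net A [gene_network()] object.
#' @param set_a,set_b Disease gene sets ([gene_set()] or character vectors).
#' @param exclude_seeds If `TRUE` (default), a candidate must not be a
#'   member of either disease set.
#' @return A data frame of class `nicd_candidates`, one row per candidate
#'   sorted by gene identifier, with columns `gene`, `support_a` and
#'   `support_b` (list columns of the disease-set neighbors backing the
#'   candidacy). Attributes record the labels, the flag and the seed counts.
#' @examples
#' net <- gene_network(rbind(c("D1", "C1"), c("O1", "C1"), c("D1", "C2")))
#' find_primary_candidates(net, gene_set("D1", "a"), gene_set("O1", "b"))
#' @export
find_primary_candidates <- function(net, set_a, set_b, exclude_seeds = TRUE) {
  stopifnot(inherits(net, "nicd_network"))
  if (length(net$nodes) == 0) stop("network is empty", call. = FALSE)
  ga <- as_gene_vector(set_a)
  gb <- as_gene_vector(set_b)
  a_in <- intersect(ga, net$nodes)
  b_in <- intersect(gb, net$nodes)
  n_skip <- (length(ga) - length(a_in)) + (length(gb) - length(b_in))
  if (n_skip > 0) nicd_msg(n_skip, " seed gene(s) not in network, skipped")
  if (length(a_in) == 0 && length(b_in) == 0) {
    stop("both disease gene sets are empty after network restriction",
         call. = FALSE)
  }

  cand <- sort(candidate_genes_core(net$adj, net$nodes, ga, gb,
                                    exclude_seeds))
  support_a <- lapply(net$adj[cand], function(nb) sort(intersect(nb, a_in)))
  support_b <- lapply(net$adj[cand], function(nb) sort(intersect(nb, b_in)))
  out <- data.frame(gene = cand, stringsAsFactors = FALSE)
  out$support_a <- unname(support_a)
  out$support_b <- unname(support_b)
  rownames(out) <- NULL
  attr(out, "label_a") <- if (inherits(set_a, "nicd_gene_set")) set_a$label else "a"
  attr(out, "label_b") <- if (inherits(set_b, "nicd_gene_set")) set_b$label else "b"
  attr(out, "exclude_seeds") <- exclude_seeds
  attr(out, "n_seeds_a") <- length(a_in)
  attr(out, "n_seeds_b") <- length(b_in)
  class(out) <- c("nicd_candidates", class(out))
  nicd_msg(nrow(out), " primary candidate(s) found")
  out
}

#' Write primary candidates to TSV
#'
#' Columns: `gene`, `support_a`, `support_b`; support sets are comma-joined
#' and sorted.
#'
#' @param candidates A [find_primary_candidates()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  df <- data.frame(
    gene = candidates$gene,
    support_a = vapply(candidates$support_a, paste, "", collapse = ","),
    support_b = vapply(candidates$support_b, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
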