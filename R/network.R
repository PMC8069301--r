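#' Gene-gene interaction networks
#'
#' A `nicd_network` is an undirected, unweighted, simple graph over gene
#' identifiers: no self-loops, no duplicate edges, symmetric adjacency.
#' It is the container for composite interactomes such as PCNet. Internally
#' the graph is simplified with \pkg{igraph} and a named adjacency list is
#' cached so that neighbor queries inside the permutation loop are cheap.
#'
#' @param edges Two-column character matrix or data frame of edge endpoints.
#' @param nodes Optional additional node identifiers (e.g. isolated nodes).
#' @param provenance Free-text source label stored on the object.
#' @return An object of class `nicd_network` with elements `nodes` (sorted
#'   character vector), `edges` (two-column character matrix, each edge once
#'   with endpoints sorted), `adj` (named list: gene -> neighbor vector) and
#'   `provenance`.
#' @examples
#' net <- gene_network(data.frame(a = c("A", "B"), b = c("B", "C")))
#' gene_neighbors(net, "B")
#' @export
gene_network <- function(edges, nodes = NULL, provenance = "") {
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2])
  if (is.null(edges) || length(edges) == 0) {
    edges <- matrix(character(), ncol = 2)
  }
  storage.mode(edges) <- "character"
  edges[] <- norm_gene_id(edges)
  nodes <- unique(c(norm_gene_id(nodes %||% character()), as.vector(edges)))
  nodes <- sort(nodes[nzchar(nodes)])

  loops <- edges[, 1] == edges[, 2]
  if (any(loops)) {
    warning(sum(loops), " self-loop edge(s) dropped", call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)

  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) > 0) {
    el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  }
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), function(v) v$name)
  names(adj) <- nodes
  colnames(el) <- c("gene1", "gene2")
  structure(list(nodes = nodes, edges = el, adj = adj,
                 provenance = as.character(provenance)),
            class = "nicd_network")
}

#' @export
print.nicd_network <- function(x, ...) {
  cat(sprintf("<gene network: %d nodes, %d edges%s>\n",
              length(x$nodes), nrow(x$edges),
              if (nzchar(x$provenance)) paste0("; ", x$provenance) else ""))
  invisible(x)
}

#' Load a gene-gene interaction network from an edge list
#'
#' Reads a tab-separated 2+-column edge list (extra columns, e.g. weights or
#' interaction types, are ignored) or a SIF file (`node1 relation node2
#' [node2b ...]`). Gzipped files are read transparently. Duplicate lines,
#' reversed duplicates and self-loops are collapsed/dropped; self-loop
#' endpoints are retained as isolated nodes.
#'
#' @param path Path to the edge-list file (plain or gzipped).
#' @param format `"tsv"` (two or more tab-separated columns, first two are
#'   the endpoints) or `"sif"` (whitespace-separated, second token is the
#'   relation type).
#' @param mapping Optional path to a two-column TSV mapping file applied to
#'   every identifier at load time (e.g. Entrez -> symbol); identifiers not
#'   in the mapping are kept as-is.
#' @param provenance Source label; defaults to the file name.
#' @return A [gene_network()] object.
#' @export
load_edge_list <- function(path, format = c("tsv", "sif"), mapping = NULL,
                           provenance = basename(path)) {
  format <- match.arg(format)
  lines <- read_text_lines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0) {
    warning("edge-list file is empty: ", path, call. = FALSE)
    return(gene_network(NULL, provenance = provenance))
  }

  ends <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tok <- if (format == "tsv") {
      strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    } else {
      strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    }
    tok <- tok[nzchar(tok)]
    if (format == "tsv") {
      if (length(tok) < 2) {
        stop(sprintf("malformed edge line %d (need >= 2 columns): '%s'",
                     line_no[i], lines[[i]]), call. = FALSE)
      }
      ends[[i]] <- cbind(tok[1], tok[2])
    } else {
      if (length(tok) < 3) {
        stop(sprintf("malformed SIF line %d (need node relation node): '%s'",
                     line_no[i], lines[[i]]), call. = FALSE)
      }
      ends[[i]] <- cbind(tok[1], tok[-(1:2)])
    }
  }
  edges <- do.call(rbind, ends)

  if (!is.null(mapping)) {
    map <- utils::read.delim(gzfile(mapping), header = FALSE,
                             colClasses = "character")
    lut <- stats::setNames(norm_gene_id(map[[2]]), norm_gene_id(map[[1]]))
    remap <- function(v) {
      v <- norm_gene_id(v)
      hit <- v %in% names(lut)
      v[hit] <- unname(lut[v[hit]])
      v
    }
    edges[] <- remap(edges)
  }

  net <- gene_network(edges, provenance = provenance)
  nicd_msg(sprintf("loaded network '%s': %d nodes, %d edges",
                   provenance, length(net$nodes), nrow(net$edges)))
  net
}

#' Write a network as a canonical two-column TSV edge list
#'
#' Each edge is written once with lexicographically sorted endpoints, rows
#' sorted, no header. Reloading with [load_edge_list()] yields the identical
#' node and edge set (isolated nodes excepted).
#'
#' @param net A [gene_network()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "nicd_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Remove genes (and their incident edges) from a network
#'
#' Used to drop promiscuous hubs before analysis; the reference profile
#' removes Ubiquitin C (UBC), which connects to nearly every gene in
#' composite interactomes and would make almost everything a candidate.
#' Idempotent; excluding genes absent from the network is a logged no-op.
#'
#' @param net A [gene_network()] object.
#' @param excluded A [gene_set()] or character vector of genes to remove.
#' @return A new [gene_network()] without the excluded genes.
#' @export
exclude_genes <- function(net, excluded = "UBC") {
  stopifnot(inherits(net, "nicd_network"))
  ex <- as_gene_vector(excluded)
  absent <- setdiff(ex, net$nodes)
  if (length(absent) > 0) {
    nicd_msg(length(absent), " excluded gene(s) not present in network: ",
             paste(absent, collapse = ", "))
  }
  keep_nodes <- setdiff(net$nodes, ex)
  keep_edge <- !(net$edges[, 1] %in% ex | net$edges[, 2] %in% ex)
  gene_network(net$edges[keep_edge, , drop = FALSE], nodes = keep_nodes,
               provenance = net$provenance)
}

#' Direct neighbors of a gene
#'
#' @param net A [gene_network()] object.
#' @param gene A single gene identifier present in the network.
#' @return A [gene_set()] of all genes sharing an edge with `gene`
#'   (never includes `gene` itself).
#' @export
gene_neighbors <- function(net, gene) {
  stopifnot(inherits(net, "nicd_network"))
  gene <- norm_gene_id(gene)
  if (length(gene) != 1 || !(gene %in% net$nodes)) {
    stop("gene not in network: ", gene, call. = FALSE)
  }
  gene_set(net$adj[[gene]], label = paste0("neighbors(", gene, ")"))
}

#' Union of neighbors over a seed gene set
#'
#' Computes the genes with a direct physical link to *any* seed gene. Seeds
#' absent from the network are skipped with a logged count. The result may
#' overlap the seeds themselves; filtering seeds out is the candidate
#' finder's job.
#'
#' @param net A [gene_network()] object.
#' @param seeds A [gene_set()] or character vector of seed genes.
#' @return A [gene_set()] of neighbor genes.
#' @export
neighborhood_of_set <- function(net, seeds) {
  stopifnot(inherits(net, "nicd_network"))
  sv <- as_gene_vector(seeds)
  in_net <- intersect(sv, net$nodes)
  n_skip <- length(sv) - length(in_net)
  if (n_skip > 0) {
    nicd_msg(n_skip, " seed gene(s) not in network, skipped")
  }
  lab <- if (inherits(seeds, "nicd_gene_set")) seeds$label else "seeds"
  gene_set(unlist(net$adj[in_net], use.names = FALSE),
           label = paste0("neighborhood(", lab, ")"))
}
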