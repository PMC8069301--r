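# Shared fixtures and independent oracles. Every oracle here is written
# naively (double loops, explicit enumeration, direct combinatorics) so it
# stays independent of the implementation paths it checks.

triangle_net <- function() {
  gene_network(rbind(c("A", "B"), c("B", "C"), c("A", "C")))
}

# small Erdos-Renyi edge table over n named genes (implementation-free:
# enumerates all pairs and flips coins)
random_edge_table <- function(n, p) {
  genes <- sprintf("N%03d", seq_len(n))
  pairs <- t(utils::combn(genes, 2))
  pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
}

random_network <- function(n, p) {
  genes <- sprintf("N%03d", seq_len(n))
  gene_network(random_edge_table(n, p), nodes = genes)
}

# brute-force candidate oracle: explicit double loop over all nodes and
# all seed genes, testing both neighbor intersections
brute_force_candidates <- function(net, set_a, set_b, exclude_seeds = TRUE) {
  ga <- intersect(set_a, net$nodes)
  gb <- intersect(set_b, net$nodes)
  has_edge <- function(x, y) {
    any((net$edges[, 1] == x & net$edges[, 2] == y) |
        (net$edges[, 1] == y & net$edges[, 2] == x))
  }
  out <- character()
  for (g in net$nodes) {
    hit_a <- FALSE
    for (s in ga) if (has_edge(g, s)) { hit_a <- TRUE; break }
    if (!hit_a) next
    hit_b <- FALSE
    for (s in gb) if (has_edge(g, s)) { hit_b <- TRUE; break }
    if (!hit_b) next
    if (exclude_seeds && g %in% c(set_a, set_b)) next
    out <- c(out, g)
  }
  sort(out)
}

# hand-coded Benjamini-Hochberg step-up: sort, cumulative minimum from the
# largest rank down, restore input order
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(ranked)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# exact null probability that `gene` is a candidate when one gene is drawn
# for each side uniformly from `universe` (sizes 1,1): enumerate all
# ordered pairs
exact_single_draw_prob <- function(net, universe, gene, exclude_seeds = TRUE) {
  hits <- 0
  for (a in universe) for (b in universe) {
    cand <- brute_force_candidates(net, a, b, exclude_seeds)
    if (gene %in% cand) hits <- hits + 1
  }
  hits / length(universe)^2
}

# upper-tail hypergeometric by direct combinatorial enumeration
hyper_tail_oracle <- function(k, K, n, N) {
  js <- seq(from = k, to = min(K, n))
  js <- js[js >= max(0, K + n - N)]
  if (length(js) == 0) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# 5-gene toy universe whose null is exactly enumerable
toy_universe_net <- function() {
  gene_network(rbind(c("D1", "C1"), c("O1", "C1"), c("D1", "C2")),
               nodes = c("D1", "O1", "C1", "C2", "X5"))
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
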