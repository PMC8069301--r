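#' Permutation-test configuration
#'
#' Controls the empirical null used to score primary candidates. Two
#' sampling universes are supported. In `disease_id` mode (the default),
#' each replicate draws two CUI sets of the observed query sizes from the
#' distinct CUIs of the disease-variant table and expands them to gene sets
#' through the variant-gene mapping; this emulates querying the database
#' with random diseases. In `gene` mode each replicate draws two gene sets
#' of the observed disease-set sizes directly from the network nodes.
#' Within a replicate both sets are drawn uniformly without replacement,
#' independently of each other (they may overlap each other).
#'
#' @param mode `"disease_id"` or `"gene"`.
#' @param iterations Number of replicates; default (`NULL`) is
#'   `100 * n` where `n` is the number of primary candidates.
#' @param seed Integer RNG seed; required for reproducibility.
#' @param alpha FDR threshold in (0, 1] used downstream by
#'   [significant_drivers()]; default 0.05.
#' @param plus_one If `TRUE`, p-values are the conservative
#'   `(x + 1) / (iterations + 1)` instead of the exact `x / iterations`.
#' @param progress_every Log progress every this many replicates
#'   (0 = silent).
#' @return An object of class `nicd_perm_config`.
#' @export
permutation_config <- function(mode = c("disease_id", "gene"),
                               iterations = NULL, seed = 1L, alpha = 0.05,
                               plus_one = FALSE, progress_every = 0L) {
  mode <- match.arg(mode)
  if (!is.null(iterations)) {
    iterations <- as.integer(iterations)
    if (is.na(iterations) || iterations < 1) {
      stop("iterations must be >= 1", call. = FALSE)
    }
  }
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]", call. = FALSE)
  structure(list(mode = mode, iterations = iterations,
                 seed = as.integer(seed), alpha = alpha,
                 plus_one = isTRUE(plus_one),
                 progress_every = as.integer(progress_every)),
            class = "nicd_perm_config")
}

#' Draw one null replicate of the two input sets
#'
#' Samples two identifier sets of the requested sizes uniformly without
#' replacement from `universe`, independently of each other. Uses the
#' current RNG state; seed control belongs to the caller.
#'
#' @param universe Character vector to sample from (network nodes in `gene`
#'   mode; distinct CUIs in `disease_id` mode).
#' @param size_a,size_b Sample sizes (the observed input-set sizes).
#' @return List with elements `a` and `b` (character vectors).
#' @export
sample_null_replicate <- function(universe, size_a, size_b) {
  if (size_a > length(universe) || size_b > length(universe)) {
    stop(sprintf("requested sample size (%d, %d) exceeds universe size %d",
                 size_a, size_b, length(universe)), call. = FALSE)
  }
  list(a = if (size_a > 0) sample(universe, size_a) else character(),
       b = if (size_b > 0) sample(universe, size_b) else character())
}

#' Empirical permutation p-value
#'
#' The exact rational `x / iterations` (possibly 0), matching the
#' occurrence-count definition of the permutation test; the opt-in
#' `plus_one` mode returns `(x + 1) / (iterations + 1)`, which cannot be 0.
#'
#' @param x Occurrence count(s), `0 <= x <= iterations`.
#' @param iterations Number of replicates run (>= 1).
#' @param plus_one Use the conservative add-one estimator.
#' @return Numeric vector of p-values.
#' @export
empirical_pvalue <- function(x, iterations, plus_one = FALSE) {
  iterations <- as.numeric(iterations)
  if (any(iterations < 1)) stop("iterations must be >= 1", call. = FALSE)
  if (any(x < 0) || any(x > iterations)) {
    stop("x must satisfy 0 <= x <= iterations", call. = FALSE)
  }
  if (plus_one) (x + 1) / (iterations + 1) else x / iterations
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment `q_(i) = min_(j >= i) p_(j) * m / j`, clipped to
#' 1 and returned in the original input order (delegates to
#' [stats::p.adjust()] with `method = "BH"` after domain validation).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same order as `p`; `q >= p`
#'   elementwise.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Score primary candidates against a permutation null
#'
#' Re-runs the candidate identification on randomly sampled input sets and
#' counts, for every observed candidate `g`, the number of replicates `x(g)`
#' whose null candidate set contains `g`. Empirical p-values are
#' `x / iterations`, corrected across candidates by Benjamini-Hochberg.
#' Each replicate applies [find_primary_candidates()]'s rule with the same
#' `exclude_seeds` flag as the observed run (sampled sets acting as seeds).
#'
#' @param net A [gene_network()] object.
#' @param set_a,set_b The observed disease gene sets ([gene_set()]).
#' @param candidates The observed [find_primary_candidates()] result.
#' @param cfg A [permutation_config()].
#' @param dvt,vgt Required in `disease_id` mode: the mapping tables used to
#'   expand sampled CUI sets to gene sets.
#' @param query_a,query_b Required in `disease_id` mode: the observed
#'   [disease_query()] objects (their CUI-list sizes are the sample sizes).
#' @return An object of class `nicd_permutation`: a list with `table` (data
#'   frame `gene`, `x`, `p`, `q`), `iterations`, `seed`, `mode`, `alpha`,
#'   `exclude_seeds` and `replicate_overlap_sizes` (per-replicate count of
#'   null candidates that are observed candidates; `sum(table$x)` equals
#'   `sum(replicate_overlap_sizes)` by construction, which the tests check).
#' @export
run_permutation <- function(net, set_a, set_b, candidates, cfg,
                            dvt = NULL, vgt = NULL,
                            query_a = NULL, query_b = NULL) {
  stopifnot(inherits(net, "nicd_network"),
            inherits(cfg, "nicd_perm_config"),
            inherits(candidates, "nicd_candidates"))
  if (nrow(candidates) == 0) stop("no candidates to test", call. = FALSE)
  exclude_seeds <- attr(candidates, "exclude_seeds") %||% TRUE
  obs <- candidates$gene
  n_cand <- length(obs)
  iterations <- cfg$iterations %||% (100L * n_cand)

  if (cfg$mode == "disease_id") {
    if (is.null(dvt) || is.null(vgt) || is.null(query_a) || is.null(query_b)) {
      stop("disease_id mode requires dvt, vgt, query_a and query_b",
           call. = FALSE)
    }
    universe <- unique(dvt$cui)
    size_a <- length(query_a$cuis)
    size_b <- length(query_b$cuis)
    # precompute CUI -> gene set once; replicates only union cached vectors
    merged <- merge(dvt, vgt, by = "variant")
    cui2genes <- lapply(split(merged$gene, merged$cui), unique)
    expand <- function(cuis) {
      unique(unlist(cui2genes[intersect(cuis, names(cui2genes))],
                    use.names = FALSE))
    }
  } else {
    universe <- net$nodes
    size_a <- length(as_gene_vector(set_a))
    size_b <- length(as_gene_vector(set_b))
    expand <- identity
  }

  set.seed(cfg$seed)
  x <- stats::setNames(integer(n_cand), obs)
  overlap_sizes <- integer(iterations)
  for (r in seq_len(iterations)) {
    smp <- sample_null_replicate(universe, size_a, size_b)
    ga <- expand(smp$a)
    gb <- expand(smp$b)
    cand <- candidate_genes_core(net$adj, net$nodes, ga, gb, exclude_seeds)
    hits <- intersect(cand, obs)
    x[hits] <- x[hits] + 1L
    overlap_sizes[r] <- length(hits)
    if (cfg$progress_every > 0 && r %% cfg$progress_every == 0) {
      nicd_msg(sprintf("permutation %d/%d", r, iterations))
    }
  }

  p <- empirical_pvalue(unname(x), iterations, plus_one = cfg$plus_one)
  structure(list(
    table = data.frame(gene = obs, x = unname(x), p = p, q = bh_adjust(p),
                       stringsAsFactors = FALSE),
    iterations = iterations, seed = cfg$seed, mode = cfg$mode,
    alpha = cfg$alpha, plus_one = cfg$plus_one,
    exclude_seeds = exclude_seeds,
    replicate_overlap_sizes = overlap_sizes
  ), class = "nicd_permutation")
}

#' @export
print.nicd_permutation <- function(x, ...) {
  cat(sprintf(
    "<permutation result: %d candidates, %d iterations, mode=%s, seed=%d>\n",
    nrow(x$table), x$iterations, x$mode, x$seed))
  cat(sprintf("  significant at q <= %g: %d\n", x$alpha,
              sum(x$table$q <= x$alpha)))
  invisible(x)
}

#' Select significant common drivers
#'
#' Candidates whose BH-adjusted q-value passes the FDR threshold, ordered
#' by ascending p then gene identifier, with `x`, `p` and `q` carried into
#' the output.
#'
#' @param res A [run_permutation()] result covering every candidate.
#' @param candidates The observed [find_primary_candidates()] result.
#' @param alpha FDR threshold; defaults to the one in the permutation run.
#' @return A data frame like `candidates` with extra columns `x`, `p`, `q`,
#'   restricted to drivers with `q <= alpha`.
#' @export
significant_drivers <- function(res, candidates, alpha = res$alpha) {
  stopifnot(inherits(res, "nicd_permutation"),
            inherits(candidates, "nicd_candidates"))
  if (!all(candidates$gene %in% res$table$gene)) {
    stop("permutation result does not cover every candidate", call. = FALSE)
  }
  idx <- match(candidates$gene, res$table$gene)
  out <- candidates
  out$x <- res$table$x[idx]
  out$p <- res$table$p[idx]
  out$q <- res$table$q[idx]
  out <- out[out$q <= alpha, , drop = FALSE]
  out <- out[order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  nicd_msg(nrow(out), " significant driver(s) at q <= ", alpha)
  out
}

#' Write a permutation-scored driver table to TSV (plus a JSON sidecar)
#'
#' Columns: `gene`, comma-joined `support_a`/`support_b`, `x`, `p`, `q`,
#' `significant`. The sidecar `<path>.json` echoes the run configuration
#' for provenance.
#'
#' @param res A [run_permutation()] result.
#' @param candidates The matching [find_primary_candidates()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_permutation_result <- function(res, candidates, path) {
  idx <- match(candidates$gene, res$table$gene)
  df <- data.frame(
    gene = candidates$gene,
    support_a = vapply(candidates$support_a, paste, "", collapse = ","),
    support_b = vapply(candidates$support_b, paste, "", collapse = ","),
    x = res$table$x[idx], p = res$table$p[idx], q = res$table$q[idx],
    significant = res$table$q[idx] <= res$alpha,
    stringsAsFactors = FALSE
  )
  df <- df[order(df$p, df$gene), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(iterations = res$iterations, seed = res$seed, mode = res$mode,
         alpha = res$alpha, plus_one = res$plus_one,
         exclude_seeds = res$exclude_seeds),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
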