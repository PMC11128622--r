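#' Upper-tail (one-sided) hypergeometric probability
#'
#' Probability of observing an overlap of at least `k` between a gene set
#' of size `m` and a selection of size `n` drawn from a universe of size
#' `N`: `P(X >= k)` with `X ~ Hypergeometric(N, m, n)`. Computed as an
#' exact tail sum (no normal approximation).
#'
#' @param k observed overlap.
#' @param m gene-set size (within the universe).
#' @param n number of selected genes.
#' @param N universe size.
#' @return the upper-tail probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, m, n, N) {
  stopifnot(length(k) == 1, length(m) == 1, length(n) == 1, length(N) == 1)
  if (any(c(k, m, n, N) < 0) || m > N || n > N || k > min(m, n))
    stop("inconsistent counts: need 0 <= k <= min(m, n) <= N")
  phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate adjustment: `q_(i) = min_{j >= i}
#' p_(j) * m / j`, capped at 1, returned in input order.
#'
#' @param p p-values, each in (0, 1].
#' @return adjusted q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

normalize_gene_sets <- function(gene_sets) {
  if (is.data.frame(gene_sets)) stop("gene_sets must be a list of sets")
  lapply(seq_along(gene_sets), function(i) {
    s <- gene_sets[[i]]
    if (is.character(s)) {
      id <- if (!is.null(names(gene_sets))) names(gene_sets)[i] else paste0("set", i)
      list(set_id = id, name = id, genes = unique(s))
    } else list(set_id = s$set_id, name = s$name, genes = unique(s$genes))
  })
}

#' Gene-set over-representation analysis
#'
#' One-sided hypergeometric test of each gene set's overlap with the
#' selected genes against a gene universe, with Benjamini-Hochberg
#' correction across the tested sets. Every set is intersected with the
#' universe before testing; sets with an empty intersection are skipped
#' with a warning.
#'
#' @param selected_genes character vector of selected gene symbols (must
#'   be a subset of `universe`).
#' @param gene_sets list of gene sets ([read_gene_sets()] output, or a
#'   named list of character vectors).
#' @param universe character vector of gene symbols defining the sampling
#'   frame (typically all genes harbouring at least one QC-passing variant
#'   in the cohort).
#' @param fdr_level significance level on the adjusted q-value
#'   (default 0.05).
#' @return data frame with one row per tested set: `set_id`, `name`,
#'   `k_overlap`, `m_set`, `n_selected`, `N_universe`, `p_value`, `fdr_q`,
#'   `significant`; ordered as the input sets.
#' @export
run_ora <- function(selected_genes, gene_sets, universe, fdr_level = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  selected_genes <- unique(selected_genes)
  if (!all(selected_genes %in% universe))
    stop("selected genes outside the universe: ",
         paste(head(setdiff(selected_genes, universe), 5), collapse = ", "))
  sets <- normalize_gene_sets(gene_sets)
  rows <- lapply(sets, function(s) {
    g <- intersect(s$genes, universe)
    if (length(g) == 0) return(NULL)
    k <- length(intersect(g, selected_genes))
    data.frame(set_id = s$set_id, name = s$name,
               k_overlap = k, m_set = length(g),
               n_selected = length(selected_genes),
               N_universe = length(universe),
               p_value = hypergeom_upper_tail(k, length(g),
                                              length(selected_genes),
                                              length(universe)),
               stringsAsFactors = FALSE)
  })
  skipped <- vapply(rows, is.null, logical(1))
  if (any(skipped))
    warning("gene sets with no universe overlap skipped: ",
            paste(vapply(sets[skipped], `[[`, character(1), "set_id"),
                  collapse = ", "))
  rows <- rows[!skipped]
  if (length(rows) == 0)
    return(data.frame(set_id = character(0), name = character(0),
                      k_overlap = integer(0), m_set = integer(0),
                      n_selected = integer(0), N_universe = integer(0),
                      p_value = numeric(0), fdr_q = numeric(0),
                      significant = logical(0)))
  res <- do.call(rbind, rows)
  res$fdr_q <- bh_adjust(res$p_value)
  res$significant <- res$fdr_q < fdr_level
  rownames(res) <- NULL
  res
}

#' Resampled background null for over-representation
#'
#' Draws `n_draws` random sets of `set_size` variants (without
#' replacement) from a background pool, maps each draw to its genes, runs
#' [run_ora()] and records, per gene set, how many draws reach
#' `fdr_q < fdr_level`. A small count certifies that an observed
#' enrichment is unlikely to arise from the background's gene-level
#' tolerance to qualifying variants alone.
#'
#' @param background data frame with columns `variant_id` and `gene`
#'   (one row per variant-gene assignment) describing the background pool.
#' @param gene_sets gene sets, as in [run_ora()].
#' @param universe gene universe; defaults to all genes in `background`.
#' @param n_draws number of random draws (default 100).
#' @param set_size number of variants per draw (default 403).
#' @param fdr_level significance level (default 0.05).
#' @param seed optional integer seed; the same seed yields an identical
#'   summary.
#' @return an object of class `"null_enrichment"`: list with `n_draws`,
#'   `set_size`, `counts` (named integer vector: draws significant per
#'   set) and `n_draws_any_significant`.
#' @export
resampled_null <- function(background, gene_sets, universe = NULL,
                           n_draws = 100, set_size = 403,
                           fdr_level = 0.05, seed = NULL) {
  stopifnot(is.data.frame(background),
            all(c("variant_id", "gene") %in% names(background)))
  pool <- unique(background$variant_id)
  if (length(pool) < set_size)
    stop("background pool (", length(pool), ") smaller than set_size (",
         set_size, ")")
  if (is.null(universe)) universe <- unique(background$gene)
  if (!is.null(seed)) set.seed(seed)
  sets <- normalize_gene_sets(gene_sets)
  ids <- vapply(sets, `[[`, character(1), "set_id")
  counts <- setNames(integer(length(ids)), ids)
  any_sig <- 0L
  for (d in seq_len(n_draws)) {
    draw <- sample(pool, set_size)
    genes <- unique(background$gene[background$variant_id %in% draw])
    res <- suppressWarnings(run_ora(intersect(genes, universe), sets,
                                    universe, fdr_level))
    sig <- res$set_id[res$significant]
    counts[sig] <- counts[sig] + 1L
    if (length(sig)) any_sig <- any_sig + 1L
  }
  structure(list(n_draws = n_draws, set_size = set_size, counts = counts,
                 n_draws_any_significant = any_sig),
            class = "null_enrichment")
}

#' @export
print.null_enrichment <- function(x, ...) {
  cat(sprintf("<null_enrichment> %d draws of %d variants; %d draws with any significant set\n",
              x$n_draws, x$set_size, x$n_draws_any_significant))
  hits <- x$counts[x$counts > 0]
  if (length(hits))
    for (s in names(hits)) cat(sprintf("  %s: %d/%d\n", s, hits[[s]], x$n_draws))
  invisible(x)
}
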