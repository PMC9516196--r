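#' Specification for simulated ontology-term annotations
#'
#' @param n_terms total number of terms (planted terms included).
#' @param size_range inclusive range of genes per term for unplanted
#'   terms.
#' @param planted optional data.frame with columns `term`, `size`, `fold`:
#'   terms whose expected overlap with a designated DEG-like subset is
#'   `fold` times the null expectation. A fold of exactly 1 means no
#'   planting (the term is drawn uniformly); for any other fold the
#'   expected overlap `round(fold * size * |D| / N)` is realized exactly,
#'   so power analyses are reproducible.
#' @param seed integer seed.
#' @return An object of class `annotation_sim_spec`.
#' @export
annotation_sim_spec <- function(n_terms, size_range = c(10, 200),
                                planted = NULL, seed = NULL) {
  if (!is_count(n_terms) || n_terms < 1) stop_param("n_terms must be >= 1")
  if (length(size_range) != 2 || size_range[1] < 1 ||
      size_range[2] < size_range[1]) {
    stop_param("size_range must be an increasing pair with minimum >= 1")
  }
  if (!is.null(planted) && nrow(planted)) {
    if (!all(c("term", "size", "fold") %in% names(planted))) {
      stop_param("planted needs columns term, size, fold")
    }
    if (any(planted$fold < 0)) stop_constraint("fold-enrichment must be >= 0")
    if (any(planted$size < 1)) stop_constraint("term sizes must be >= 1")
    if (nrow(planted) > n_terms) {
      stop_constraint("more planted terms than n_terms")
    }
  }
  structure(list(n_terms = as.integer(n_terms), size_range = size_range,
                 planted = planted, seed = seed),
            class = "annotation_sim_spec")
}

#' Simulate a gene-term annotation map
#'
#' Unplanted terms are uniform random gene subsets with sizes drawn from
#' `size_range`. Planted terms (fold != 1) oversample the designated
#' DEG-like subset so that the realized overlap equals
#' `round(fold * size * |deg_like| / |universe|)` (clamped to the feasible
#' range), with the remaining members drawn uniformly outside the subset.
#'
#' @param spec an [annotation_sim_spec()].
#' @param gene_universe character vector of gene ids (nonempty).
#' @param deg_like genes the planted terms are enriched for (required when
#'   `spec$planted` has folds != 1).
#' @return Named list mapping term id to a character vector of gene ids.
#' @export
simulate_annotations <- function(spec, gene_universe, deg_like = NULL) {
  stopifnot(inherits(spec, "annotation_sim_spec"))
  if (!length(gene_universe)) stop_param("gene_universe must be nonempty")
  N <- length(gene_universe)
  if (spec$size_range[2] > N ||
      (!is.null(spec$planted) && any(spec$planted$size > N))) {
    stop_constraint("term size exceeds the gene universe")
  }
  planted <- spec$planted
  n_plain <- spec$n_terms - if (is.null(planted)) 0L else nrow(planted)
  with_seed_opt(spec$seed, {
    terms <- list()
    if (n_plain > 0) {
      sizes <- sample(seq(spec$size_range[1], spec$size_range[2]),
                      n_plain, replace = TRUE)
      for (i in seq_len(n_plain)) {
        terms[[sprintf("term%03d", i)]] <- sample(gene_universe, sizes[i])
      }
    }
    if (!is.null(planted) && nrow(planted)) {
      for (i in seq_len(nrow(planted))) {
        size <- planted$size[i]
        fold <- planted$fold[i]
        if (fold == 1) {
          terms[[planted$term[i]]] <- sample(gene_universe, size)
          next
        }
        if (is.null(deg_like) || !length(deg_like)) {
          stop_param("planted folds != 1 require a deg_like subset")
        }
        deg_like <- intersect(deg_like, gene_universe)
        k <- round(fold * size * length(deg_like) / N)
        k <- min(max(k, 0), size, length(deg_like))
        rest <- setdiff(gene_universe, deg_like)
        if (size - k > length(rest)) {
          stop_constraint("term too large for the non-DEG remainder")
        }
        terms[[planted$term[i]]] <- c(sample(deg_like, k),
                                      sample(rest, size - k))
      }
    }
    terms
  })
}
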