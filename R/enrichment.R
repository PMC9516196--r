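# Vectorised smaller-tail hypergeometric p for overlap counts k, term sizes
# K (within background), DEG size n, background size N. Direction is the
# tail that is smaller; ties go to "enriched". K = 0 is degenerate: p = 1,
# direction NA.
fisher_tail <- function(k, K, n, N) {
  upper <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  lower <- phyper(k, K, N - K, n)
  p <- pmin(upper, lower)
  direction <- ifelse(upper <= lower, "enriched", "depleted")
  degenerate <- K == 0
  p[degenerate] <- 1
  direction[degenerate] <- NA_character_
  list(p = p, direction = direction)
}

#' Fisher's exact enrichment/depletion test for one term
#'
#' Builds the 2x2 table of DEG membership against term membership over the
#' background, computes the one-sided hypergeometric tail probability in
#' each direction, and reports the smaller tail with its direction. The
#' term is intersected with the background before testing; a term with no
#' background genes is degenerate and returns p = 1 with no direction.
#'
#' @param deg_set character vector of DEG gene ids (must be a subset of
#'   the background).
#' @param term_genes character vector of the term's gene ids.
#' @param background character vector of detectable gene ids.
#' @return list with `fisher_p`, `direction` ("enriched"/"depleted"/NA),
#'   `degenerate`, and the table counts `deg_in_term`, `deg_not_term`,
#'   `term_not_deg`, `neither` (summing to `|background|`).
#' @export
fisher_term_test <- function(deg_set, term_genes, background) {
  if (!length(background)) stop_param("background must be nonempty")
  if (!all(deg_set %in% background)) {
    stop_param("deg_set must be a subset of the background")
  }
  deg_set <- unique(deg_set)
  term <- intersect(unique(term_genes), background)
  N <- length(unique(background))
  n <- length(deg_set)
  K <- length(term)
  k <- length(intersect(deg_set, term))
  tail <- fisher_tail(k, K, n, N)
  list(fisher_p = tail$p, direction = tail$direction, degenerate = K == 0,
       deg_in_term = k, deg_not_term = n - k, term_not_deg = K - k,
       neither = N - K - n + k)
}

# Sparse background-genes x terms membership matrix.
term_membership <- function(annotations, background) {
  term_ids <- names(annotations)
  i <- unlist(lapply(annotations, function(g)
    match(intersect(unique(g), background), background)))
  j <- rep(seq_along(annotations),
           vapply(annotations, function(g)
             length(intersect(unique(g), background)), integer(1)))
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(background), length(annotations)),
                       dimnames = list(NULL, term_ids))
}

#' Test every annotation term against a DEG set
#'
#' @param deg_set character vector of DEG ids (subset of background).
#' @param annotations named list term -> gene ids.
#' @param background character vector of detectable genes (e.g. from
#'   [background_from_counts()]).
#' @return data.frame with one row per term: 2x2 counts, `fisher_p`,
#'   `direction`, `degenerate`.
#' @export
enrich_terms <- function(deg_set, annotations, background) {
  if (!length(background)) stop_param("background must be nonempty")
  background <- unique(background)
  deg_set <- unique(deg_set)
  if (!all(deg_set %in% background)) {
    stop_param("deg_set must be a subset of the background")
  }
  M <- term_membership(annotations, background)
  K <- Matrix::colSums(M)
  ind <- background %in% deg_set
  k <- as.numeric(Matrix::crossprod(M, ind))
  n <- length(deg_set)
  N <- length(background)
  tail <- fisher_tail(k, K, n, N)
  data.frame(term_id = colnames(M), deg_in_term = k, deg_not_term = n - k,
             term_not_deg = K - k, neither = N - K - n + k,
             fisher_p = tail$p, direction = tail$direction,
             degenerate = K == 0, row.names = NULL)
}

#' Empirical permutation correction for multiple testing
#'
#' For each of `n_perm` permutations a gene set of the observed DEG size
#' is drawn uniformly without replacement from the background and every
#' term's Fisher p is recomputed. The corrected p of a term is the
#' add-one-smoothed fraction of permutations at least as extreme as the
#' observation: `(1 + #\{perm p <= observed p\}) / (1 + n_perm)`, so it
#' always lies in `[1/(n_perm+1), 1]` and never returns zero.
#'
#' @param observed result of [enrich_terms()] for the real DEG set.
#' @param deg_size size of the DEG set (drawn per permutation).
#' @param background,annotations as in [enrich_terms()].
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed; corrected p-values are deterministic under a
#'   fixed seed.
#' @return `observed` with a `corrected_p` column appended.
#' @export
permutation_correct <- function(observed, deg_size, background, annotations,
                                n_perm = 1000, seed = NULL) {
  if (!is_count(n_perm) || n_perm < 1) stop_param("n_perm must be >= 1")
  background <- unique(background)
  N <- length(background)
  if (deg_size > N) stop_param("deg_size exceeds the background")
  M <- term_membership(annotations, background)
  M <- M[, observed$term_id, drop = FALSE]
  K <- Matrix::colSums(M)
  with_seed_opt(seed, {
    draws <- Matrix::sparseMatrix(
      i = as.vector(vapply(seq_len(n_perm),
                           function(p) sample.int(N, deg_size),
                           integer(deg_size))),
      j = rep(seq_len(n_perm), each = deg_size), x = 1,
      dims = c(N, n_perm))
    kmat <- as.matrix(Matrix::crossprod(M, draws))  # terms x perms
    perm_p <- fisher_tail(as.vector(kmat), rep(K, n_perm), deg_size, N)$p
    perm_p <- matrix(perm_p, nrow = nrow(kmat))
    observed$corrected_p <-
      (1 + rowSums(perm_p <= observed$fisher_p)) / (1 + n_perm)
    observed
  })
}

#' Significant terms at an empirical alpha
#'
#' Keeps terms with `corrected_p < alpha` (strict inequality), sorted by
#' corrected p ascending with ties broken by term id.
#'
#' @param results data.frame carrying `corrected_p` (from
#'   [permutation_correct()]).
#' @param alpha significance level (default 0.05).
#' @return The significant rows, sorted.
#' @export
significant_terms <- function(results, alpha = 0.05) {
  if (!"corrected_p" %in% names(results)) {
    stop_param("results must carry corrected_p (run permutation_correct)")
  }
  out <- results[results$corrected_p < alpha, , drop = FALSE]
  out <- out[order(out$corrected_p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive the expressed-gene background from a counts table
#'
#' The background contains the genes detectable in the expression data:
#' those with at least `min_count` summed read counts.
#'
#' @param counts data.frame with a `gene_id` column and one or more
#'   numeric count columns.
#' @param min_count detection floor (default 2).
#' @return character vector of background gene ids.
#' @export
background_from_counts <- function(counts, min_count = 2) {
  if (!"gene_id" %in% names(counts)) {
    stop_param("counts needs a gene_id column")
  }
  num <- counts[setdiff(names(counts), "gene_id")]
  total <- rowSums(as.matrix(num))
  unique(counts$gene_id[total >= min_count])
}
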