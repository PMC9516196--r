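# Independent brute-force oracles and small fixture builders shared by the
# tests. These deliberately avoid the package's own code paths.

# Upper / lower hypergeometric tail by direct combinatorial summation.
oracle_hyper_upper <- function(k, K, n, N) {
  js <- max(0, n + K - N):min(K, n)
  js <- js[js >= k]
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

oracle_hyper_lower <- function(k, K, n, N) {
  js <- max(0, n + K - N):min(K, n)
  js <- js[js <= k]
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# O(n^3) complete-linkage agglomeration over Euclidean distances,
# returning the merge heights in order.
oracle_complete_linkage <- function(mat) {
  d <- as.matrix(dist(mat, method = "euclidean"))
  clusters <- as.list(seq_len(nrow(mat)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- max(d[clusters[[i]], clusters[[j]], drop = FALSE])
        if (h < best_h) {
          best_h <- h
          best <- c(j, i)
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Random variant records for filter oracles.
random_records <- function(n, seed) {
  withr::with_seed(seed, {
    dp <- sample(1:60, n, replace = TRUE)
    variant_records(
      chrom = sample(c("chr01", "chr02"), n, replace = TRUE),
      pos = sample.int(1e6, n),
      ref = sample(c("A", "C", "G"), n, replace = TRUE),
      alt = "T",
      alt_depth = vapply(dp, function(d) sample(0:d, 1), integer(1)),
      total_depth = dp,
      mapping_quality = sample(10:60, n, replace = TRUE),
      base_quality = sample(5:45, n, replace = TRUE)
    )
  })
}

# A single-codon gene fixture: the codon sits at positions 5-7 of a padded
# chromosome, optionally on the minus strand (in which case the stored
# sequence is the reverse complement so the coding sequence still reads
# `codon`).
codon_fixture <- function(codon, strand = "+", pad = "AAAA") {
  if (strand == "+") {
    seq <- paste0(pad, codon, pad)
  } else {
    rc <- function(s) {
      paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
    }
    seq <- paste0(pad, rc(codon), pad)
  }
  ref <- Biostrings::DNAStringSet(seq)
  names(ref) <- "chrT"
  model <- gene_model("toy", "chrT", strand,
                      data.frame(start = 5, end = 7))
  list(reference = ref, model = model,
       codon_pos = if (strand == "+") 5:7 else 7:5)
}
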