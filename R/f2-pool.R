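#' Specification of a sequenced F2 pool
#'
#' @param n_individuals number of pooled plants (>= 1).
#' @param depth mean sequencing coverage per site (x, > 0); read depths are
#'   Poisson with this mean.
#' @param error_rate per-base probability that a read reports the specific
#'   other allele (0 <= e < 0.5).
#' @param selection `"mutant_phenotype"` keeps only individuals homozygous
#'   for the causal alt allele (a fully penetrant recessive);
#'   `"unselected"` keeps every F2.
#' @param seed integer seed; identical seeds give byte-identical pools.
#' @return An object of class `f2_pool_spec`.
#' @export
f2_pool_spec <- function(n_individuals, depth = 20, error_rate = 0.001,
                         selection = c("mutant_phenotype", "unselected"),
                         seed = NULL) {
  selection <- match.arg(selection)
  if (!is_count(n_individuals) || n_individuals < 1) {
    stop_param("n_individuals must be >= 1")
  }
  if (!is.numeric(depth) || depth <= 0) stop_param("depth must be > 0")
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 0.5) {
    stop_param("error_rate must satisfy 0 <= e < 0.5")
  }
  structure(list(n_individuals = as.integer(n_individuals), depth = depth,
                 error_rate = error_rate, selection = selection, seed = seed),
            class = "f2_pool_spec")
}

# One gamete from the (mutant x wild-type) F1: a recombinant mosaic of the
# two parental haplotypes under the Haldane model (Poisson crossovers, no
# interference). `gpos` are site positions in Morgans, `L` the chromosome's
# genetic length in Morgans. TRUE = site inherited from the mutant haplotype.
gamete_origin <- function(gpos, L) {
  start <- sample.int(2L, 1L) - 1L
  nx <- rpois(1L, L)
  if (nx == 0L) return(rep(start == 1L, length(gpos)))
  x <- sort(runif(nx, 0, L))
  ((start + findInterval(gpos, x)) %% 2L) == 1L
}

#' Simulate pooled sequencing of a selected F2 population
#'
#' Simulates F2 individuals from a mutant x wild-type cross by
#' per-chromosome recombination (Haldane map function on the genome's
#' genetic map), genotypes each individual at every variant site of the
#' line, applies phenotype selection, and then draws per-site read counts:
#' total depth Poisson(`depth`) and alt reads Binomial with success
#' probability `f(1-e) + (1-f)e`, where `f` is the pooled alt-allele
#' frequency and `e` the error rate. Variants fixed in both parents
#' (`shared_variants`, e.g. cultivar-vs-reference polymorphisms) are
#' homozygous in every F2 and appear with true frequency 1.
#'
#' The true pooled frequency of every site is retained in the `true_freq`
#' column as hidden ground truth; mapping functions ignore it.
#'
#' @param line a `mutant_line` from [simulate_mutagenesis()].
#' @param genome the [genome_spec()] the line was simulated on.
#' @param spec an [f2_pool_spec()].
#' @param shared_variants optional data.frame (chrom, pos, ref, alt) of
#'   variants carried by both parents.
#' @param pool_id sample label written to the records.
#' @return data.frame of variant records with columns chrom, pos, ref, alt,
#'   alt_depth, total_depth, mapping_quality, base_quality, pool_id, and
#'   hidden-truth columns true_freq and source
#'   ("causal"/"background"/"shared").
#' @export
simulate_f2_pool <- function(line, genome, spec, shared_variants = NULL,
                             pool_id = line$line_id) {
  stopifnot(inherits(line, "mutant_line"), inherits(spec, "f2_pool_spec"))
  vars <- line_variants(line)
  chrom_length(genome, unique(vars$chrom))  # bounds/consistency check
  n <- spec$n_individuals

  with_seed_opt(spec$seed, {
    by_chrom <- split(seq_len(nrow(vars)), vars$chrom)
    cchrom <- line$causal$chrom
    cidx_local <- match(1L, by_chrom[[cchrom]])  # causal row is first in vars
    gpos <- lapply(names(by_chrom), function(ch)
      genetic_pos(genome, ch, vars$pos[by_chrom[[ch]]]))
    names(gpos) <- names(by_chrom)
    L <- setNames(chrom_morgans(genome, names(by_chrom)), names(by_chrom))
    other_chroms <- setdiff(names(by_chrom), cchrom)

    alt_sum <- numeric(nrow(vars))
    kept <- 0L
    attempts <- 0L
    max_attempts <- 100L * n
    select <- spec$selection == "mutant_phenotype"
    while (kept < n) {
      if (attempts >= max_attempts) {
        stop_simulation(sprintf(
          "only %d of %d individuals passed selection after %d attempts; the pool spec is implausible",
          kept, n, attempts))
      }
      attempts <- attempts + 1L
      g1 <- gamete_origin(gpos[[cchrom]], L[[cchrom]])
      g2 <- gamete_origin(gpos[[cchrom]], L[[cchrom]])
      if (select && !(g1[cidx_local] && g2[cidx_local])) next
      kept <- kept + 1L
      alt_sum[by_chrom[[cchrom]]] <- alt_sum[by_chrom[[cchrom]]] + g1 + g2
      for (ch in other_chroms) {
        alt_sum[by_chrom[[ch]]] <- alt_sum[by_chrom[[ch]]] +
          gamete_origin(gpos[[ch]], L[[ch]]) +
          gamete_origin(gpos[[ch]], L[[ch]])
      }
    }

    freq <- alt_sum / (2 * n)
    out <- vars
    out$true_freq <- freq
    if (!is.null(shared_variants) && nrow(shared_variants)) {
      sh <- shared_variants[, c("chrom", "pos", "ref", "alt")]
      sh$source <- "shared"
      sh$true_freq <- 1
      dup <- variant_key(sh$chrom, sh$pos, sh$ref, sh$alt) %in%
        variant_key(out$chrom, out$pos, out$ref, out$alt)
      out <- rbind(out, sh[!dup, names(out)])
    }
    m <- nrow(out)
    dp <- rpois(m, spec$depth)
    p_read <- out$true_freq * (1 - spec$error_rate) +
      (1 - out$true_freq) * spec$error_rate
    ad <- rbinom(m, dp, p_read)
    rec <- data.frame(chrom = out$chrom, pos = out$pos, ref = out$ref,
                      alt = out$alt, alt_depth = ad, total_depth = dp,
                      mapping_quality = sample(45:60, m, replace = TRUE),
                      base_quality = sample(30:40, m, replace = TRUE),
                      pool_id = pool_id, true_freq = out$true_freq,
                      source = out$source)
    rec <- rec[order(rec$chrom, rec$pos), , drop = FALSE]
    rownames(rec) <- NULL
    rec
  })
}

#' Simulate the wild-type (parental) sequencing pool
#'
#' The wild-type carries only the variants fixed relative to the mapping
#' reference (cultivar polymorphisms); a variant caller emits records only
#' where there is variant evidence, so the returned records cover exactly
#' those sites, with true alt frequency 1.
#'
#' @param shared_variants data.frame (chrom, pos, ref, alt) of
#'   cultivar-vs-reference variants; may have zero rows.
#' @param depth mean coverage (Poisson).
#' @param error_rate per-base miscall probability towards the reference.
#' @param seed integer seed.
#' @param pool_id sample label.
#' @return data.frame of variant records (same schema as
#'   [simulate_f2_pool()]).
#' @export
simulate_wildtype_pool <- function(shared_variants, depth = 20,
                                   error_rate = 0.001, seed = NULL,
                                   pool_id = "wild_type") {
  m <- if (is.null(shared_variants)) 0L else nrow(shared_variants)
  with_seed_opt(seed, {
    if (m == 0L) {
      return(data.frame(chrom = character(0), pos = numeric(0),
                        ref = character(0), alt = character(0),
                        alt_depth = integer(0), total_depth = integer(0),
                        mapping_quality = integer(0),
                        base_quality = integer(0),
                        pool_id = character(0), true_freq = numeric(0),
                        source = character(0)))
    }
    dp <- rpois(m, depth)
    ad <- rbinom(m, dp, 1 - error_rate)
    rec <- data.frame(chrom = shared_variants$chrom,
                      pos = shared_variants$pos,
                      ref = shared_variants$ref, alt = shared_variants$alt,
                      alt_depth = ad, total_depth = dp,
                      mapping_quality = sample(45:60, m, replace = TRUE),
                      base_quality = sample(30:40, m, replace = TRUE),
                      pool_id = pool_id, true_freq = 1, source = "shared")
    rec <- rec[order(rec$chrom, rec$pos), , drop = FALSE]
    rownames(rec) <- NULL
    rec
  })
}
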