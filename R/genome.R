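#' Describe a genome for forward simulation
#'
#' A genome specification carries the chromosome lengths and a uniform
#' per-chromosome genetic-map rate (centimorgan per megabase). It is the
#' coordinate frame for mutagenesis and F2-pool simulation. Sequence is
#' optional: mapping-scale simulations work from coordinates alone, while
#' codon-effect fixtures attach an explicit sequence per chromosome.
#'
#' @param chromosomes data.frame with columns `name` (unique chromosome
#'   names) and `length` (bp, > 0).
#' @param cm_per_mb genetic-map rate(s) in cM/Mb, length 1 (recycled) or one
#'   per chromosome; must be >= 0.
#' @param sequence optional named [Biostrings::DNAStringSet] (names matching
#'   chromosome names, widths matching lengths) giving the reference
#'   sequence.
#' @return An object of class `genome_spec`.
#' @examples
#' toy <- genome_spec(data.frame(name = "chr1", length = 3e6), cm_per_mb = 4)
#' @export
genome_spec <- function(chromosomes, cm_per_mb = 4, sequence = NULL) {
  if (!is.data.frame(chromosomes) ||
      !all(c("name", "length") %in% names(chromosomes))) {
    stop_param("`chromosomes` must be a data.frame with columns name, length")
  }
  name <- as.character(chromosomes$name)
  len <- as.numeric(chromosomes$length)
  if (anyDuplicated(name)) stop_param("chromosome names must be unique")
  if (any(!is.finite(len)) || any(len <= 0)) {
    stop_param("chromosome lengths must be positive")
  }
  rate <- rep_len(as.numeric(cm_per_mb), length(name))
  if (any(!is.finite(rate)) || any(rate < 0)) {
    stop_param("cm_per_mb must be >= 0")
  }
  if (!is.null(sequence)) {
    if (!methods::is(sequence, "DNAStringSet")) {
      stop_param("`sequence` must be a DNAStringSet")
    }
    if (!setequal(names(sequence), name)) {
      stop_param("sequence names must match chromosome names")
    }
    widths <- Biostrings::width(sequence)[match(name, names(sequence))]
    if (!all(widths == len)) {
      stop_param("sequence widths must match chromosome lengths")
    }
  }
  structure(
    list(chromosomes = data.frame(name = name, length = len,
                                  cm_per_mb = rate),
         sequence = sequence),
    class = "genome_spec"
  )
}

#' Rice-like default genome for mapping simulations
#'
#' Twelve chromosomes with approximately the sizes of the rice (Oryza
#' sativa) reference assembly (~373 Mb in total) and a uniform genetic map
#' of 4 cM/Mb, close to the genome-wide average for rice. This is the
#' coordinate frame on which pooled-F2 mapping simulations run.
#'
#' @param cm_per_mb genetic-map rate in cM/Mb (default 4).
#' @return A [genome_spec()].
#' @export
default_genome <- function(cm_per_mb = 4) {
  lengths_mb <- c(43.3, 35.9, 36.4, 35.5, 29.9, 31.2,
                  29.7, 28.4, 23.0, 23.2, 29.0, 27.5)
  genome_spec(
    data.frame(name = sprintf("chr%02d", seq_along(lengths_mb)),
               length = round(lengths_mb * 1e6)),
    cm_per_mb = cm_per_mb
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  chr <- x$chromosomes
  cat(sprintf("genome_spec: %d chromosome(s), %.1f Mb total, %s cM/Mb\n",
              nrow(chr), sum(chr$length) / 1e6,
              paste(unique(chr$cm_per_mb), collapse = "/")))
  cat(sprintf("  sequence: %s\n",
              if (is.null(x$sequence)) "none attached" else "attached"))
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$name)
  if (anyNA(i)) stop_param(paste0("unknown chromosome: ",
                                  paste(chrom[is.na(i)], collapse = ", ")))
  genome$chromosomes$length[i]
}

chrom_rate <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$name)
  genome$chromosomes$cm_per_mb[i]
}

# Genetic length of a chromosome in Morgans.
chrom_morgans <- function(genome, chrom) {
  chrom_length(genome, chrom) / 1e6 * chrom_rate(genome, chrom) / 100
}

# Genetic position (Morgans) of physical positions on one chromosome.
genetic_pos <- function(genome, chrom, pos) {
  pos / 1e6 * chrom_rate(genome, chrom) / 100
}

ref_base_at <- function(genome, chrom, pos) {
  if (is.null(genome$sequence)) return(NULL)
  as.character(Biostrings::subseq(genome$sequence[[chrom]], pos, pos))
}

#' Attach a random reference sequence to a genome
#'
#' Generates an i.i.d. uniform A/C/G/T sequence per chromosome. Intended
#' for small (kb-to-Mb) fixtures used by codon-effect annotation; mapping
#' simulations do not need sequence.
#'
#' @param genome a [genome_spec()].
#' @param seed integer seed for reproducibility.
#' @return The genome with `$sequence` populated.
#' @export
random_genome_sequence <- function(genome, seed = NULL) {
  seqs <- with_seed_opt(seed, {
    lapply(seq_len(nrow(genome$chromosomes)), function(i) {
      n <- genome$chromosomes$length[i]
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    })
  })
  dss <- Biostrings::DNAStringSet(unlist(seqs))
  names(dss) <- genome$chromosomes$name
  genome$sequence <- dss
  genome
}
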