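#' Default mutagen substitution spectrum
#'
#' Probability per strand-collapsed substitution class. Sodium-azide (and
#' EMS) mutagenesis in plants is dominated by G:C -> A:T transitions, so
#' the default puts 0.85 on that class and spreads the remainder evenly
#' over the other five classes.
#'
#' @param gc_to_at probability mass on the G:C -> A:T class.
#' @return Named numeric vector over the six substitution classes, summing
#'   to 1.
#' @export
default_spectrum <- function(gc_to_at = 0.85) {
  if (gc_to_at < 0 || gc_to_at > 1) stop_param("gc_to_at must be in [0,1]")
  other <- (1 - gc_to_at) / 5
  c("GC>AT" = gc_to_at, "AT>GC" = other, "GC>TA" = other,
    "GC>CG" = other, "AT>CG" = other, "AT>TA" = other)
}

# ref/alt pairs for each class; each class has two strand orientations.
.class_pairs <- list(
  "GC>AT" = rbind(c("G", "A"), c("C", "T")),
  "AT>GC" = rbind(c("A", "G"), c("T", "C")),
  "GC>TA" = rbind(c("G", "T"), c("C", "A")),
  "GC>CG" = rbind(c("G", "C"), c("C", "G")),
  "AT>CG" = rbind(c("A", "C"), c("T", "G")),
  "AT>TA" = rbind(c("A", "T"), c("T", "A"))
)

substitution_class <- function(ref, alt) {
  pur <- paste0(ref, alt)
  switch(pur,
         GA = , CT = "GC>AT", AG = , TC = "AT>GC",
         GT = , CA = "GC>TA", GC = , CG = "GC>CG",
         AC = , TG = "AT>CG", AT = , TA = "AT>TA",
         stop_param(paste0("not a point substitution: ", ref, ">", alt)))
}

#' Simulate a mutagenized line
#'
#' Draws `n_background` induced background SNPs uniformly over the genome,
#' with substitution classes drawn from `spectrum` (heavily weighted to
#' G:C -> A:T transitions by default), plus one designated causal SNP.
#' Position collisions (with the causal SNP or among background SNPs) are
#' resolved by redrawing, never by dropping, so the realized background
#' count is exact. If the genome carries sequence, reference bases are read
#' from it and the substitution class is drawn conditional on the actual
#' base; otherwise the reference base is implied by the drawn class (strand
#' orientation uniform).
#'
#' @param genome a [genome_spec()].
#' @param n_background number of background SNPs (>= 0).
#' @param causal list or one-row data.frame with `chrom`, `pos`, `ref`,
#'   `alt` for the causal SNP.
#' @param spectrum named class-probability vector as from
#'   [default_spectrum()].
#' @param line_id identifier for the line.
#' @param seed integer seed; identical seeds give identical lines.
#' @param avoid optional `mutant_line` (or data.frame with chrom, pos)
#'   whose positions are redrawn if hit. Lines mutagenized independently
#'   on one reference can never disagree about the base at a shared
#'   position; when no explicit sequence is attached this option keeps a
#'   panel of simulated lines mutually consistent by making their variant
#'   positions disjoint (same-position hits across two real lines are
#'   vanishingly rare at genome scale).
#' @return An object of class `mutant_line` with elements `line_id`,
#'   `causal` (one-row data.frame), `background` (data.frame with columns
#'   chrom, pos, ref, alt) and `spectrum`.
#' @examples
#' line <- simulate_mutagenesis(default_genome(), n_background = 10,
#'   causal = list(chrom = "chr07", pos = 1600000, ref = "G", alt = "A"),
#'   seed = 1)
#' @export
simulate_mutagenesis <- function(genome, n_background, causal,
                                 spectrum = default_spectrum(),
                                 line_id = "line", seed = NULL,
                                 avoid = NULL) {
  if (!is_count(n_background)) stop_param("n_background must be a count >= 0")
  causal <- as.list(causal)
  causal_df <- data.frame(chrom = as.character(causal$chrom),
                          pos = as.numeric(causal$pos),
                          ref = as.character(causal$ref),
                          alt = as.character(causal$alt))
  clen <- chrom_length(genome, causal_df$chrom)
  if (causal_df$pos < 1 || causal_df$pos > clen) {
    stop_param("causal position outside chromosome bounds")
  }
  if (causal_df$ref == causal_df$alt) stop_param("causal ref must differ from alt")
  sref <- ref_base_at(genome, causal_df$chrom, causal_df$pos)
  if (!is.null(sref) && sref != causal_df$ref) {
    stop_integrity("causal ref base does not match the reference sequence")
  }
  if (abs(sum(spectrum) - 1) > 1e-8 || any(spectrum < 0)) {
    stop_param("spectrum must be a probability vector over substitution classes")
  }

  taken <- paste(causal_df$chrom, causal_df$pos, sep = ":")
  if (!is.null(avoid)) {
    av <- if (inherits(avoid, "mutant_line")) line_variants(avoid) else avoid
    taken <- c(taken, paste(av$chrom, av$pos, sep = ":"))
  }
  background <- with_seed_opt(seed, {
    draw_background(genome, n_background, spectrum, taken_pos = taken)
  })

  structure(list(line_id = line_id, causal = causal_df,
                 background = background, spectrum = spectrum),
            class = "mutant_line")
}

draw_background <- function(genome, n, spectrum, taken_pos) {
  chr <- genome$chromosomes
  out <- data.frame(chrom = character(0), pos = numeric(0),
                    ref = character(0), alt = character(0))
  while (nrow(out) < n) {
    m <- n - nrow(out)
    ci <- sample.int(nrow(chr), m, replace = TRUE, prob = chr$length)
    pos <- floor(runif(m, 0, chr$length[ci])) + 1
    chrom <- chr$name[ci]
    if (is.null(genome$sequence)) {
      cls <- sample(names(spectrum), m, replace = TRUE, prob = spectrum)
      strand <- sample.int(2L, m, replace = TRUE)
      pair <- t(vapply(seq_len(m),
                       function(i) .class_pairs[[cls[i]]][strand[i], ],
                       character(2)))
      ref <- pair[, 1]; alt <- pair[, 2]
    } else {
      ref <- vapply(seq_len(m),
                    function(i) ref_base_at(genome, chrom[i], pos[i]),
                    character(1))
      alt <- vapply(seq_len(m),
                    function(i) draw_alt_for_ref(ref[i], spectrum),
                    character(1))
    }
    key <- paste(chrom, pos, sep = ":")
    keep <- !(key %in% taken_pos) & !duplicated(key)
    out <- rbind(out, data.frame(chrom = chrom[keep], pos = pos[keep],
                                 ref = ref[keep], alt = alt[keep]))
    taken_pos <- c(taken_pos, key[keep])
  }
  ord <- order(out$chrom, out$pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Alt-base distribution conditional on a fixed reference base: restrict the
# spectrum to classes whose orientation matches ref, renormalize.
draw_alt_for_ref <- function(ref, spectrum) {
  alts <- character(0); w <- numeric(0)
  for (cls in names(spectrum)) {
    pairs <- .class_pairs[[cls]]
    hit <- pairs[, 1] == ref
    if (any(hit)) {
      alts <- c(alts, pairs[hit, 2])
      w <- c(w, spectrum[[cls]])
    }
  }
  sample(alts, 1, prob = w)
}

#' All variants of a mutant line (causal first)
#'
#' @param line a `mutant_line`.
#' @return data.frame with columns chrom, pos, ref, alt, source
#'   ("causal"/"background").
#' @export
line_variants <- function(line) {
  rbind(cbind(line$causal, source = "causal"),
        if (nrow(line$background))
          cbind(line$background, source = "background"))
}

#' @export
print.mutant_line <- function(x, ...) {
  cat(sprintf("mutant_line '%s': causal %s:%d %s>%s, %d background SNP(s)\n",
              x$line_id, x$causal$chrom, x$causal$pos, x$causal$ref,
              x$causal$alt, nrow(x$background)))
  invisible(x)
}
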