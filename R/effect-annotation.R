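#' Construct a gene model for codon-effect annotation
#'
#' A gene model is a strand-aware set of CDS segments plus optional
#' protein-domain intervals in amino-acid space. Segment coordinates are
#' genomic, 1-based inclusive; the total CDS length must be divisible by 3
#' and segments must be non-overlapping.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds data.frame with columns `start`, `end` (genomic, 1-based
#'   inclusive).
#' @param domains optional data.frame with columns `name`, `aa_start`,
#'   `aa_end` (1-based inclusive amino-acid coordinates).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, cds, domains = NULL) {
  if (!strand %in% c("+", "-")) stop_param("strand must be '+' or '-'")
  cds <- cds[order(cds$start), c("start", "end"), drop = FALSE]
  if (any(cds$end < cds$start)) stop_param("CDS segment end < start")
  if (nrow(cds) > 1 && any(cds$start[-1] <= cds$end[-nrow(cds)])) {
    stop_param("CDS segments overlap")
  }
  total <- sum(cds$end - cds$start + 1)
  if (total %% 3 != 0) {
    abort(sprintf("CDS length %d of %s is not divisible by 3", total, gene_id),
          "mutmapr_model_error")
  }
  if (!is.null(domains) && nrow(domains)) {
    if (any(domains$aa_start < 1 | domains$aa_end < domains$aa_start)) {
      stop_param("domain coordinates must satisfy 1 <= aa_start <= aa_end")
    }
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 cds = cds, domains = domains, aa_length = total / 3),
            class = "gene_model")
}

# Map a genomic position to its 1-based position along the coding sequence
# (5' -> 3' on the coding strand), or NA when the position is intronic or
# outside the gene.
genomic_to_cds <- function(model, pos) {
  cds <- model$cds
  seg <- which(pos >= cds$start & pos <= cds$end)
  if (!length(seg)) return(NA_integer_)
  if (model$strand == "+") {
    before <- if (seg > 1) sum(cds$end[seq_len(seg - 1)] -
                                 cds$start[seq_len(seg - 1)] + 1) else 0
    before + (pos - cds$start[seg] + 1)
  } else {
    n <- nrow(cds)
    after <- if (seg < n) sum(cds$end[(seg + 1):n] -
                                cds$start[(seg + 1):n] + 1) else 0
    after + (cds$end[seg] - pos + 1)
  }
}

# Inverse of genomic_to_cds: genomic position of the k-th coding base.
cds_to_genomic <- function(model, cds_pos) {
  cds <- model$cds
  lens <- cds$end - cds$start + 1
  if (cds_pos < 1 || cds_pos > sum(lens)) stop_param("cds_pos out of range")
  if (model$strand == "+") {
    cum <- cumsum(lens)
    seg <- which(cds_pos <= cum)[1]
    offset <- cds_pos - (if (seg > 1) cum[seg - 1] else 0)
    cds$start[seg] + offset - 1
  } else {
    cum <- cumsum(rev(lens))
    seg_rev <- which(cds_pos <= cum)[1]
    seg <- nrow(cds) - seg_rev + 1
    offset <- cds_pos - (if (seg_rev > 1) cum[seg_rev - 1] else 0)
    cds$end[seg] - offset + 1
  }
}

complement_base <- function(b) {
  chartr("ACGT", "TGCA", b)
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# Positions within `dist` bases of a CDS boundary on the intron side of an
# internal junction (splice-adjacent by convention).
is_splice_adjacent <- function(model, pos, dist = 2) {
  cds <- model$cds
  n <- nrow(cds)
  if (n < 2) return(FALSE)
  donors <- cds$end[-n]        # intron starts at donors + 1
  acceptors <- cds$start[-1]   # intron ends at acceptors - 1
  any(pos > donors & pos <= donors + dist) ||
    any(pos < acceptors & pos >= acceptors - dist)
}

#' Annotate a point substitution against gene models
#'
#' For each gene model overlapping the variant, locates the affected codon
#' (strand-aware: on minus-strand genes the alleles are complemented and
#' the codon is read 5' to 3' on the coding strand), translates reference
#' and alternate codons with the standard genetic code, and categorises the
#' effect as synonymous, missense, nonsense (a gained stop), or
#' splice-adjacent (within 2 bp of an internal CDS boundary on the intron
#' side). Loss of the annotated stop codon is reported as missense with
#' `stop_loss = TRUE`. A variant outside every CDS (and no splice
#' neighbourhood) yields a single noncoding call.
#'
#' @param record one-row variant-record data.frame (chrom, pos, ref, alt).
#' @param models list of [gene_model()]s.
#' @param reference named [Biostrings::DNAStringSet] with the chromosome
#'   sequences.
#' @return data.frame of effect calls: gene_id, category, codon_number,
#'   ref_codon, alt_codon, ref_aa, alt_aa, stop_loss, domain_hit.
#' @export
annotate_variant <- function(record, models, reference) {
  chrom <- record$chrom[1]; pos <- record$pos[1]
  ref <- record$ref[1]; alt <- record$alt[1]
  if (!chrom %in% names(reference)) {
    stop_param(paste0("no reference sequence for ", chrom))
  }
  genome_base <- as.character(Biostrings::subseq(reference[[chrom]], pos, pos))
  if (genome_base != ref) {
    stop_integrity(sprintf(
      "record ref '%s' does not match reference base '%s' at %s:%d",
      ref, genome_base, chrom, pos))
  }
  calls <- list()
  for (model in models) {
    if (model$chrom != chrom) next
    cds_pos <- genomic_to_cds(model, pos)
    if (is.na(cds_pos)) {
      if (is_splice_adjacent(model, pos)) {
        calls[[length(calls) + 1]] <- effect_call_row(
          model$gene_id, "splice-adjacent")
      }
      next
    }
    codon_number <- (cds_pos - 1) %/% 3 + 1
    offset <- (cds_pos - 1) %% 3 + 1
    codon_gpos <- vapply((codon_number - 1) * 3 + 1:3,
                         function(k) cds_to_genomic(model, k), numeric(1))
    bases <- vapply(codon_gpos, function(p)
      as.character(Biostrings::subseq(reference[[chrom]], p, p)), character(1))
    if (model$strand == "-") bases <- complement_base(bases)
    ref_codon <- paste(bases, collapse = "")
    coding_alt <- if (model$strand == "-") complement_base(alt) else alt
    alt_bases <- bases
    alt_bases[offset] <- coding_alt
    alt_codon <- paste(alt_bases, collapse = "")
    ref_aa <- translate_codon(ref_codon)
    alt_aa <- translate_codon(alt_codon)
    stop_loss <- ref_aa == "*" && alt_aa != "*"
    category <- if (ref_aa == alt_aa) {
      "synonymous"
    } else if (alt_aa == "*") {
      "nonsense"
    } else {
      "missense"   # includes stop loss, flagged separately
    }
    call <- effect_call_row(model$gene_id, category, codon_number,
                            ref_codon, alt_codon, ref_aa, alt_aa, stop_loss)
    calls[[length(calls) + 1]] <- domain_overlap(call, model)
  }
  if (!length(calls)) {
    return(effect_call_row(NA_character_, "noncoding"))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

effect_call_row <- function(gene_id, category, codon_number = NA_integer_,
                            ref_codon = NA_character_,
                            alt_codon = NA_character_,
                            ref_aa = NA_character_, alt_aa = NA_character_,
                            stop_loss = FALSE, domain_hit = NA_character_) {
  data.frame(gene_id = gene_id, category = category,
             codon_number = codon_number, ref_codon = ref_codon,
             alt_codon = alt_codon, ref_aa = ref_aa, alt_aa = alt_aa,
             stop_loss = stop_loss, domain_hit = domain_hit)
}

#' Fill the protein-domain hit of an effect call
#'
#' Sets `domain_hit` to the name of the first model domain whose inclusive
#' amino-acid interval contains the call's codon number, or leaves it
#' missing.
#'
#' @param call one-row effect-call data.frame (from [annotate_variant()]).
#' @param model the [gene_model()] supplying the domain intervals.
#' @return The call with `domain_hit` filled where a domain contains the
#'   codon.
#' @export
domain_overlap <- function(call, model) {
  if (is.na(call$codon_number) || is.null(model$domains) ||
      !nrow(model$domains)) {
    return(call)
  }
  hit <- which(model$domains$aa_start <= call$codon_number &
                 model$domains$aa_end >= call$codon_number)
  if (length(hit)) call$domain_hit <- model$domains$name[hit[1]]
  call
}

#' Annotate many candidate variants
#'
#' @param records variant records.
#' @param models list of [gene_model()]s.
#' @param reference named DNAStringSet.
#' @return data.frame of effect calls with the variant coordinates
#'   prepended.
#' @export
annotate_candidates <- function(records, models, reference) {
  out <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    calls <- annotate_variant(rec, models, reference)
    cbind(chrom = rec$chrom, pos = rec$pos, ref = rec$ref, alt = rec$alt,
          calls, row.names = NULL)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
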