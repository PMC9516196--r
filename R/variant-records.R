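#' Construct a table of candidate variant records
#'
#' A variant record is one candidate SNP with its per-pool read support:
#' the unit on which SNP indices are computed. This constructor validates
#' the record invariants (0 <= alt_depth <= total_depth, pos >= 1,
#' ref != alt).
#'
#' @param chrom,pos,ref,alt variant coordinates and alleles (1-based).
#' @param alt_depth,total_depth read counts supporting the alt allele and
#'   in total at the site.
#' @param mapping_quality,base_quality phred-scaled qualities.
#' @param pool_id sample label.
#' @return data.frame of variant records.
#' @export
variant_records <- function(chrom, pos, ref, alt, alt_depth, total_depth,
                            mapping_quality = 60, base_quality = 37,
                            pool_id = "pool") {
  rec <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                    ref = as.character(ref), alt = as.character(alt),
                    alt_depth = as.numeric(alt_depth),
                    total_depth = as.numeric(total_depth),
                    mapping_quality = as.numeric(mapping_quality),
                    base_quality = as.numeric(base_quality),
                    pool_id = as.character(pool_id))
  validate_records(rec)
  rec
}

validate_records <- function(rec) {
  needed <- c("chrom", "pos", "ref", "alt", "alt_depth", "total_depth",
              "mapping_quality", "base_quality")
  missing <- setdiff(needed, names(rec))
  if (length(missing)) {
    stop_param(paste0("variant records lack column(s): ",
                      paste(missing, collapse = ", ")))
  }
  if (any(rec$pos < 1)) stop_param("positions must be >= 1")
  if (any(rec$ref == rec$alt)) stop_param("ref and alt must differ")
  if (any(rec$alt_depth < 0 | rec$alt_depth > rec$total_depth)) {
    stop_param("alt_depth must satisfy 0 <= alt_depth <= total_depth")
  }
  invisible(rec)
}
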