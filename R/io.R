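#' Write variant records as VCF v4.2
#'
#' One sample column per pool, with `AD` (ref,alt depths) and `DP` FORMAT
#' fields and `MQ`/`BQ` INFO fields. Hidden-truth columns (`true_freq`,
#' `source`), when present, are preserved in INFO as `TF`/`SRC` so a
#' simulated pool round-trips with its ground truth.
#'
#' @param records variant-record data.frame (one pool).
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(records, path) {
  validate_records(records)
  rec <- records[order(records$chrom, records$pos), , drop = FALSE]
  info <- sprintf("MQ=%g;BQ=%g", rec$mapping_quality, rec$base_quality)
  if ("true_freq" %in% names(rec)) {
    info <- paste0(info, sprintf(";TF=%.6g", rec$true_freq))
  }
  if ("source" %in% names(rec)) {
    info <- paste0(info, sprintf(";SRC=%s", rec$source))
  }
  sample_id <- if ("pool_id" %in% names(rec) && nrow(rec)) {
    rec$pool_id[1]
  } else {
    "pool"
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mutmapr",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=BQ,Number=1,Type=Float,Description=\"Mean base quality\">",
    "##INFO=<ID=TF,Number=1,Type=Float,Description=\"True pooled alt frequency (simulation truth)\">",
    "##INFO=<ID=SRC,Number=1,Type=String,Description=\"Simulated variant source\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id)
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tAD:DP\t%d,%d:%d",
                  rec$chrom, as.integer(rec$pos), rec$ref, rec$alt, info,
                  as.integer(rec$total_depth - rec$alt_depth),
                  as.integer(rec$alt_depth), as.integer(rec$total_depth))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read variant records from a VCF
#'
#' Expects single-sample VCFs with `AD`/`DP` FORMAT fields and `MQ`/`BQ`
#' INFO fields, as written by [write_variant_vcf()]; truth fields
#' (`TF`/`SRC`) are restored when present.
#'
#' @param path VCF path.
#' @return variant-record data.frame.
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v))
  ad <- vcfR::extract.gt(v, "AD")[, 1]
  dp <- as.numeric(vcfR::extract.gt(v, "DP")[, 1])
  ad2 <- as.numeric(vapply(strsplit(ad, ","), `[`, character(1), 2))
  info_field <- function(key) {
    vcfR::extract.info(v, key)
  }
  rec <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                    ref = fix$REF, alt = fix$ALT,
                    alt_depth = ad2, total_depth = dp,
                    mapping_quality = as.numeric(info_field("MQ")),
                    base_quality = as.numeric(info_field("BQ")),
                    pool_id = colnames(v@gt)[2])
  tf <- suppressWarnings(as.numeric(info_field("TF")))
  if (!all(is.na(tf))) rec$true_freq <- tf
  src <- info_field("SRC")
  if (!all(is.na(src))) rec$source <- src
  validate_records(rec)
  rec
}

#' Write a reference genome as FASTA
#'
#' @param genome a [genome_spec()] with sequence attached.
#' @param path output path.
#' @export
write_reference_fasta <- function(genome, path) {
  if (is.null(genome$sequence)) stop_param("genome has no sequence attached")
  Biostrings::writeXStringSet(genome$sequence, path)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits one `gene` feature and its `CDS` features per model.
#'
#' @param models list of [gene_model()]s.
#' @param path output path.
#' @export
write_gene_models_gff3 <- function(models, path) {
  grl <- lapply(models, function(m) {
    gene <- GenomicRanges::GRanges(
      m$chrom, IRanges::IRanges(min(m$cds$start), max(m$cds$end)),
      strand = m$strand, type = "gene", ID = m$gene_id)
    lens <- m$cds$end - m$cds$start + 1
    tx_order <- if (m$strand == "+") {
      seq_len(nrow(m$cds))
    } else {
      rev(seq_len(nrow(m$cds)))
    }
    phase <- integer(nrow(m$cds))
    phase[tx_order] <- (3 - c(0, cumsum(lens[tx_order])[-nrow(m$cds)]) %% 3) %% 3
    cds <- GenomicRanges::GRanges(
      m$chrom, IRanges::IRanges(m$cds$start, m$cds$end),
      strand = m$strand, type = "CDS", phase = phase,
      ID = paste0(m$gene_id, ".cds", seq_len(nrow(m$cds))),
      Parent = m$gene_id)
    c(gene, cds)
  })
  gr <- suppressWarnings(do.call(c, grl))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3 (plus a domain side-car table)
#'
#' Reconstructs [gene_model()]s from `CDS` features grouped by their
#' `Parent` (falling back to `ID` prefix), with optional protein domains
#' supplied as a TSV with columns gene_id, domain, aa_start, aa_end.
#'
#' @param gff3_path GFF3 path.
#' @param domains_path optional domain TSV path.
#' @return list of [gene_model()]s.
#' @export
read_gene_models <- function(gff3_path, domains_path = NULL) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  parent <- as.character(S4Vectors::mcols(cds)$Parent)
  domains <- if (!is.null(domains_path)) {
    read.table(domains_path, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE)
  }
  models <- lapply(unique(parent), function(g) {
    seg <- cds[parent == g]
    dom <- if (!is.null(domains)) {
      d <- domains[domains$gene_id == g, , drop = FALSE]
      if (nrow(d)) data.frame(name = d$domain, aa_start = d$aa_start,
                              aa_end = d$aa_end)
    }
    gene_model(g, as.character(GenomicRanges::seqnames(seg))[1],
               as.character(GenomicRanges::strand(seg))[1],
               data.frame(start = GenomicRanges::start(seg),
                          end = GenomicRanges::end(seg)),
               domains = dom)
  })
  names(models) <- unique(parent)
  models
}

#' Read/write DEG tables and annotation maps as TSV
#'
#' DEG tables are tab-separated with columns gene_id, log2fc, p_value;
#' annotation maps are two-column TSVs (term_id, gene_id), one row per
#' gene-term link.
#'
#' @param table,path,annotations objects and file paths.
#' @name deg_io
NULL

#' @rdname deg_io
#' @export
write_deg_table <- function(table, path) {
  write.table(table[c("gene_id", "log2fc", "p_value")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname deg_io
#' @export
read_deg_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname deg_io
#' @export
write_annotation_map <- function(annotations, path) {
  df <- data.frame(
    term_id = rep(names(annotations), lengths(annotations)),
    gene_id = unlist(annotations, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname deg_io
#' @export
read_annotation_map <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  split(df$gene_id, df$term_id)
}

#' Write a SNP-index track or peak regions as BED-compatible text
#'
#' Tracks are written as (chrom, start0, end, index); regions as
#' (chrom, start0, end, mean_index). Coordinates are converted to BED's
#' 0-based half-open convention.
#'
#' @param track per-site track from [snp_index_track()].
#' @param regions peak regions from [call_peak_regions()].
#' @param path output path.
#' @name bed_io
NULL

#' @rdname bed_io
#' @export
write_track_bed <- function(track, path) {
  bed <- data.frame(track$chrom, as.integer(track$pos - 1),
                    as.integer(track$pos), track$snp_index)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname bed_io
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(regions$chrom, as.integer(regions$start - 1),
                    as.integer(regions$end), regions$mean_index)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
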