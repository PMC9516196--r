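#' Quality thresholds for candidate SNPs
#'
#' Defaults follow standard MutMap practice: mapping quality >= 30 and
#' base quality >= 20 (both inclusive). The depth floor (default 5) guards
#' the SNP index against instability at very low coverage; it applies when
#' indices are computed, not at this filter.
#'
#' @param min_mapping_quality,min_base_quality,min_total_depth thresholds,
#'   all >= 0.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_mapping_quality = 30, min_base_quality = 20,
                          min_total_depth = 5) {
  vals <- c(min_mapping_quality, min_base_quality, min_total_depth)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop_param("all thresholds must be >= 0")
  }
  structure(list(min_mapping_quality = min_mapping_quality,
                 min_base_quality = min_base_quality,
                 min_total_depth = min_total_depth),
            class = "filter_config")
}

#' Keep records meeting all quality thresholds
#'
#' Thresholds are inclusive (a record at exactly MQ 30 / BQ 20 is kept);
#' record order is preserved. The depth floor of the config is *not*
#' applied here (it belongs to index computation); this filter uses mapping
#' and base quality only.
#'
#' @param records variant-record data.frame.
#' @param config a [filter_config()].
#' @return The surviving records, order preserved.
#' @export
quality_filter <- function(records, config = filter_config()) {
  validate_records(records)
  keep <- records$mapping_quality >= config$min_mapping_quality &
    records$base_quality >= config$min_base_quality
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove SNPs shared with the wild type or other mutant pools
#'
#' Implements the cross-exclusion step of MutMap-style mapping: SNPs that
#' are also present in the wild-type parent or in another mutant's pool
#' cannot be the unique induced causal mutation and are removed. Presence
#' is keyed on (chrom, pos, ref, alt) with read support
#' `alt_depth >= presence_min_alt_reads` in the comparison set; a matching
#' position with a *different* alt allele does not exclude.
#'
#' @param target variant records of the pool being mapped.
#' @param wild_type variant records of the wild-type parent (may be empty).
#' @param other_pools list of variant-record data.frames from other mutant
#'   pools.
#' @param presence_min_alt_reads minimum alt reads for a comparison-set
#'   variant to count as present (default 2).
#' @return The target records whose keys are absent from every comparison
#'   set.
#' @export
exclude_shared <- function(target, wild_type = NULL, other_pools = list(),
                           presence_min_alt_reads = 2) {
  validate_records(target)
  comparison <- c(list(wild_type), other_pools)
  present <- character(0)
  for (set in comparison) {
    if (is.null(set) || nrow(set) == 0) next
    validate_records(set)
    hit <- set$alt_depth >= presence_min_alt_reads
    present <- c(present, variant_key(set$chrom[hit], set$pos[hit],
                                      set$ref[hit], set$alt[hit]))
    # conflicting reference alleles at one coordinate signal mixed
    # coordinate systems
    both <- merge(unique(target[c("chrom", "pos", "ref")]),
                  unique(set[c("chrom", "pos", "ref")]),
                  by = c("chrom", "pos"))
    if (any(both$ref.x != both$ref.y)) {
      stop_integrity("conflicting ref alleles between record sets at the same coordinate")
    }
  }
  keys <- variant_key(target$chrom, target$pos, target$ref, target$alt)
  out <- target[!(keys %in% present), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' SNP index of a single record
#'
#' The SNP index is the fraction of reads carrying the mutant allele:
#' `alt_depth / total_depth`.
#'
#' @param record one-row variant-record data.frame (or a vectorised table).
#' @return Numeric in \[0, 1\] (vectorised over rows).
#' @export
compute_snp_index <- function(record) {
  record$alt_depth / record$total_depth
}

#' Per-site SNP-index track
#'
#' Computes the SNP index for every record with `total_depth >=
#' min_total_depth`; shallower records are flagged and excluded from the
#' track (not an error). Sites are sorted by (chrom, pos).
#'
#' @param records variant records.
#' @param config a [filter_config()]; only its depth floor is used here.
#' @return data.frame (chrom, pos, snp_index, total_depth).
#' @export
snp_index_track <- function(records, config = filter_config()) {
  validate_records(records)
  deep <- records$total_depth >= config$min_total_depth
  rec <- records[deep, , drop = FALSE]
  track <- data.frame(chrom = rec$chrom, pos = rec$pos,
                      snp_index = compute_snp_index(rec),
                      total_depth = rec$total_depth)
  track <- track[order(track$chrom, track$pos), , drop = FALSE]
  rownames(track) <- NULL
  attr(track, "n_low_depth") <- sum(!deep)
  track
}

#' Sliding-window SNP-index scan
#'
#' Smooths the per-site track with a sliding window per chromosome:
#' windows are half-open `[start, start + window_size)` internally,
#' advanced by `step`, and each reports the arithmetic mean of the site
#' indices it covers. Windows with fewer than `min_sites_per_window`
#' supporting sites are emitted with a missing mean.
#'
#' @param records filtered variant records (or a track from
#'   [snp_index_track()]).
#' @param window_size,step window width and stride in bp.
#' @param min_sites_per_window minimum sites for a window mean.
#' @param config depth floor for the per-site track.
#' @return list with `sites` (the per-site track) and `windows`
#'   (chrom, start, end, mean_index, n_sites; start/end 1-based inclusive).
#' @export
scan_genome <- function(records, window_size = 1e6, step = 1e5,
                        min_sites_per_window = 2,
                        config = filter_config()) {
  if (!is.numeric(window_size) || window_size <= 0) {
    stop_param("window_size must be > 0")
  }
  if (!is.numeric(step) || step <= 0) stop_param("step must be > 0")
  track <- if (all(c("snp_index", "total_depth") %in% names(records)) &&
               !("alt_depth" %in% names(records))) {
    records
  } else {
    snp_index_track(records, config)
  }
  win <- lapply(split(track, track$chrom), function(tr) {
    span <- max(tr$pos)
    starts <- seq(1, max(1, span), by = step)
    n <- length(starts)
    mean_index <- numeric(n)
    n_sites <- integer(n)
    for (i in seq_len(n)) {
      inw <- tr$pos >= starts[i] & tr$pos < starts[i] + window_size
      n_sites[i] <- sum(inw)
      mean_index[i] <- if (n_sites[i] >= min_sites_per_window) {
        mean(tr$snp_index[inw])
      } else {
        NA_real_
      }
    }
    data.frame(chrom = tr$chrom[1], start = starts,
               end = starts + window_size - 1, mean_index = mean_index,
               n_sites = n_sites)
  })
  windows <- do.call(rbind, win)
  rownames(windows) <- NULL
  list(sites = track, windows = windows)
}

#' Call candidate peak regions from a smoothed track
#'
#' A peak region is a maximal run of consecutive windows whose mean SNP
#' index is at least `index_threshold`; runs separated by at most
#' `merge_gap` windows scanning *below* the threshold are merged. Windows
#' with too few sites for a mean carry no evidence in either direction
#' and are neutral: they neither qualify nor break a run (sparse coverage
#' inside a selected region must not split its peak). Regions supported by
#' fewer than `min_sites` distinct sites are dropped. Each region reports
#' its bounds (1-based inclusive), the mean index over its sites, the
#' number of supporting sites and the top site (highest per-site index,
#' leftmost on ties). Regions are sorted by mean index descending, ties
#' broken by genomic order.
#'
#' @param scan result of [scan_genome()] (or a window data.frame plus
#'   `sites=`).
#' @param index_threshold window mean required to qualify (default 0.9,
#'   operationalising "SNP index close to 1").
#' @param min_sites minimum supporting sites per region (default 3).
#' @param merge_gap maximum run of sub-threshold windows bridged when
#'   merging (default 2).
#' @param sites per-site track; defaults to `scan$sites`.
#' @return data.frame of peak regions (chrom, start, end, mean_index,
#'   n_sites, top_pos, top_index).
#' @export
call_peak_regions <- function(scan, index_threshold = 0.9, min_sites = 3,
                              merge_gap = 2, sites = NULL) {
  windows <- if (is.data.frame(scan)) scan else scan$windows
  if (is.null(sites)) sites <- scan$sites
  if (is.null(windows) || nrow(windows) == 0) stop_param("empty track")
  regions <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    qual <- !is.na(w$mean_index) & w$mean_index >= index_threshold
    breaking <- !is.na(w$mean_index) & w$mean_index < index_threshold
    if (!any(qual)) next
    idx <- which(qual)
    # count only sub-threshold (non-missing) windows between consecutive
    # qualifying ones; merge when no more than merge_gap of them intervene
    n_breaking_between <- vapply(seq_len(length(idx) - 1), function(b) {
      lo <- idx[b] + 1
      hi <- idx[b + 1] - 1
      if (hi < lo) 0 else sum(breaking[lo:hi])
    }, numeric(1))
    brk <- c(0, which(n_breaking_between > merge_gap), length(idx))
    for (b in seq_len(length(brk) - 1)) {
      run <- idx[(brk[b] + 1):brk[b + 1]]
      start <- w$start[min(run)]
      end <- w$end[max(run)]
      ins <- sites$chrom == ch & sites$pos >= start & sites$pos <= end
      n_sites <- sum(ins)
      if (n_sites < min_sites) next
      s <- sites[ins, , drop = FALSE]
      top <- which.max(s$snp_index)  # leftmost maximum (sites are sorted)
      regions[[length(regions) + 1]] <- data.frame(
        chrom = ch, start = start, end = end,
        mean_index = mean(s$snp_index), n_sites = n_sites,
        top_pos = s$pos[top], top_index = s$snp_index[top])
    }
  }
  if (!length(regions)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), mean_index = numeric(0),
                      n_sites = integer(0), top_pos = numeric(0),
                      top_index = numeric(0)))
  }
  out <- do.call(rbind, regions)
  out <- out[order(-out$mean_index, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full mapping pipeline: filter, exclude, scan, call
#'
#' Convenience composition of [quality_filter()], [exclude_shared()],
#' [scan_genome()] and [call_peak_regions()]; deterministic in its inputs.
#'
#' @inheritParams quality_filter
#' @inheritParams exclude_shared
#' @inheritParams scan_genome
#' @inheritParams call_peak_regions
#' @return list with `records` (surviving records), `scan` and `regions`.
#' @export
map_mutant_pool <- function(target, wild_type = NULL, other_pools = list(),
                            config = filter_config(),
                            presence_min_alt_reads = 2,
                            window_size = 1e6, step = 1e5,
                            min_sites_per_window = 2,
                            index_threshold = 0.9, min_sites = 3,
                            merge_gap = 2) {
  kept <- quality_filter(target, config)
  kept <- exclude_shared(kept, wild_type, other_pools,
                         presence_min_alt_reads)
  scan <- scan_genome(kept, window_size, step, min_sites_per_window, config)
  regions <- call_peak_regions(scan, index_threshold, min_sites, merge_gap)
  list(records = kept, scan = scan, regions = regions)
}

#' Recover the genetic-map rate from SNP-index decay
#'
#' Under recessive-phenotype selection the expected SNP index at a locus a
#' recombination fraction `r` from the causal site is `1 - r`. Inverting
#' the Haldane map function on `r_hat = 1 - index` converts each site to an
#' estimated genetic distance, and a regression through the origin of that
#' distance on physical distance estimates the map rate in cM/Mb.
#'
#' @param track per-site track (chrom, pos, snp_index).
#' @param causal_chrom,causal_pos location of the selected causal locus.
#' @param max_r sites beyond this recombination fraction are dropped (the
#'   Haldane inverse degenerates near r = 0.5); default 0.35. The cut is
#'   applied in two stages: a first fit restricted on the *estimated* r,
#'   then a refit restricted on the r *predicted* from the first-stage
#'   rate and physical distance. The second cut does not depend on a
#'   site's own noise, which removes the selection bias that a single
#'   noisy-r cut introduces at the boundary.
#' @return list with `cm_per_mb` (estimate) and `n_sites` used in the
#'   final fit.
#' @export
estimate_map_rate <- function(track, causal_chrom, causal_pos,
                              max_r = 0.35) {
  tr <- track[track$chrom == causal_chrom & track$pos != causal_pos, ,
              drop = FALSE]
  r_hat <- pmin(pmax(1 - tr$snp_index, 0), 0.48)
  d_cm <- -50 * log(1 - 2 * r_hat)            # Haldane inverse, in cM
  dist_mb <- abs(tr$pos - causal_pos) / 1e6
  fit_rate <- function(keep) {
    if (sum(keep) < 3) {
      stop_param("too few linked sites to estimate a map rate")
    }
    unname(coef(lm(d_cm[keep] ~ 0 + dist_mb[keep]))[1])
  }
  rate1 <- fit_rate(r_hat <= max_r)
  pred_r <- (1 - exp(-2 * dist_mb * rate1 / 100)) / 2
  keep <- pred_r <= max_r
  list(cm_per_mb = fit_rate(keep), n_sites = sum(keep))
}
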