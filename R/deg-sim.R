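#' Specification for simulated differential-expression tables
#'
#' Tables are *constructed*, not sampled: each gene is assigned a joint
#' direction profile across the contrasts (up/down/none per contrast), and
#' the per-profile gene counts are realized exactly. This makes planted
#' intersection sizes and direction-concordance fractions deterministic,
#' so downstream overlap statistics are exactly reproducible. P-values and
#' log2 fold changes are then drawn consistently with the profile: DEGs
#' get `p <= 0.05` and `|log2FC| >= 1` with the profiled sign, non-DEGs
#' get uniform p on \[0, 1\] and `|log2FC| < 1`.
#'
#' @param n_genes size of the shared gene universe.
#' @param profile_counts data.frame with one column per contrast (values
#'   `"up"`, `"down"` or `"none"`) plus a `count` column; rows are joint
#'   direction profiles. The remaining genes are `none` everywhere.
#' @param lfc_min minimum absolute log2 fold change of a DEG (default 1).
#' @param seed integer seed.
#' @return An object of class `deg_sim_spec`.
#' @export
deg_sim_spec <- function(n_genes, profile_counts, lfc_min = 1, seed = NULL) {
  if (!is_count(n_genes) || n_genes < 1) stop_param("n_genes must be >= 1")
  if (!"count" %in% names(profile_counts)) {
    stop_param("profile_counts needs a `count` column")
  }
  contrasts <- setdiff(names(profile_counts), "count")
  if (!length(contrasts)) stop_param("profile_counts needs contrast columns")
  vals <- unlist(profile_counts[contrasts])
  if (!all(vals %in% c("up", "down", "none"))) {
    stop_param("profile entries must be 'up', 'down' or 'none'")
  }
  if (any(profile_counts$count < 0)) stop_param("profile counts must be >= 0")
  if (sum(profile_counts$count) > n_genes) {
    stop_constraint("planted profile counts exceed the gene universe")
  }
  structure(list(n_genes = as.integer(n_genes),
                 contrasts = contrasts,
                 profile_counts = profile_counts,
                 lfc_min = lfc_min, seed = seed),
            class = "deg_sim_spec")
}

#' Two-contrast planted overlap, expressed as joint profiles
#'
#' Convenience translation of pairwise targets (set sizes, intersection,
#' direction concordance and the down-down share of the concordant genes)
#' into an exact joint-profile table for [deg_sim_spec()]. Discordant
#' intersection genes are split evenly between down/up and up/down;
#' non-overlapping DEGs are split to honour the per-set totals with the
#' remainder down (mutant screens here are dominated by downregulation).
#'
#' @param contrasts length-2 character vector of contrast names.
#' @param sizes DEG counts of the two sets.
#' @param intersection number of shared genes.
#' @param concordance fraction of shared genes with equal direction.
#' @param down_down_frac fraction of the concordant genes that are
#'   down-down.
#' @param down per-set downregulated totals (defaults to all DEGs down).
#' @return profile-count data.frame for [deg_sim_spec()].
#' @export
pair_overlap_profiles <- function(contrasts, sizes, intersection,
                                  concordance = 1, down_down_frac = 1,
                                  down = sizes) {
  if (intersection > min(sizes)) {
    stop_constraint("intersection exceeds a set size")
  }
  if (concordance < 0 || concordance > 1 ||
      down_down_frac < 0 || down_down_frac > 1) {
    stop_constraint("fractions must lie in [0, 1]")
  }
  conc <- round(concordance * intersection)
  dd <- round(down_down_frac * conc)
  uu <- conc - dd
  disc <- intersection - conc
  du <- disc %/% 2
  ud <- disc - du
  a_only_down <- down[1] - dd - du
  a_only_up <- (sizes[1] - down[1]) - uu - ud
  b_only_down <- down[2] - dd - ud
  b_only_up <- (sizes[2] - down[2]) - uu - du
  if (min(a_only_down, a_only_up, b_only_down, b_only_up) < 0) {
    stop_constraint("pairwise targets are mutually inconsistent")
  }
  a <- c("down", "up", "down", "up", "down", "up", "none", "none")
  b <- c("down", "up", "up", "down", "none", "none", "down", "up")
  count <- c(dd, uu, du, ud, a_only_down, a_only_up, b_only_down, b_only_up)
  out <- data.frame(a, b, count)
  names(out)[1:2] <- contrasts
  out[out$count > 0, , drop = FALSE]
}

#' Canonical three-contrast co-regulation profile
#'
#' Joint direction profiles for two single mutants (`mut_a`, `mut_b`) and
#' their double mutant (`double`), emulating a pair of transcription-factor
#' mutants whose targets are predominantly co-downregulated and whose
#' double mutant extends the downregulated set. The cell counts realize,
#' exactly, a structure in which `mut_a` has 1,128 down- and 217
#' upregulated DEGs, `mut_b` 866 down and 348 up, the double 1,853 down
#' and 213 up, the singles share 757 DEGs of which 729 are
#' direction-concordant and 666 down-down, 654 of those 666 are also down
#' in the double, and 1,197 of the 1,328 genes down in either single are
#' regulated in the double.
#'
#' @return profile-count data.frame for [deg_sim_spec()].
#' @export
coregulation_profiles <- function() {
  data.frame(
    mut_a  = c("down", "down", "down", "down", "down",
               "up", "none", "none", "up", "up", "none", "none", "none"),
    mut_b  = c("down", "down", "up", "none", "none",
               "down", "down", "down", "up", "none", "up", "none", "none"),
    double = c("down", "none", "down", "down", "none",
               "down", "down", "none", "up", "none", "none", "down", "up"),
    count  = c(654, 12, 14, 382, 66,
               14, 133, 53, 63, 140, 271, 656, 150)
  )
}

#' Simulate differential-expression tables with planted structure
#'
#' Realizes a [deg_sim_spec()]: assigns joint direction profiles to a
#' random subset of the gene universe (counts exact by construction) and
#' draws p-values and log2 fold changes consistent with each profile.
#' Applying [filter_degs()] with the default thresholds recovers the
#' planted sets exactly.
#'
#' @param spec a [deg_sim_spec()].
#' @return named list of raw DEG tables (one per contrast), each a
#'   data.frame (gene_id, log2fc, p_value) over the shared gene universe,
#'   with the planted direction in a hidden `true_direction` column.
#' @export
simulate_deg_tables <- function(spec) {
  stopifnot(inherits(spec, "deg_sim_spec"))
  n <- spec$n_genes
  genes <- sprintf("gene%05d", seq_len(n))
  pc <- spec$profile_counts
  with_seed_opt(spec$seed, {
    assigned <- sample(genes, sum(pc$count))
    profile_of <- rep(seq_len(nrow(pc)), pc$count)
    tables <- lapply(spec$contrasts, function(ct) {
      dir <- setNames(rep("none", n), genes)
      dir[assigned] <- pc[[ct]][profile_of]
      is_deg <- dir != "none"
      p <- runif(n)
      p[is_deg] <- runif(sum(is_deg), 0, 0.05)
      lfc <- runif(n, -0.99, 0.99)
      sign <- ifelse(dir == "up", 1, -1)
      lfc[is_deg] <- sign[is_deg] *
        (spec$lfc_min + rexp(sum(is_deg), rate = 1.2))
      data.frame(gene_id = genes, log2fc = lfc, p_value = p,
                 true_direction = unname(dir))
    })
    names(tables) <- spec$contrasts
    tables
  })
}
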