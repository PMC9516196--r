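#' Apply DEG thresholds to a raw differential-expression table
#'
#' A gene is a differentially expressed gene (DEG) when `p_value <= p_max`
#' and `|log2fc| >= min_abs_log2fc`, both bounds inclusive. The fold-change
#' bound is two-sided: downregulated genes (negative log2FC) count as DEGs
#' with direction `"down"`, positive ones as `"up"`. The operation is
#' idempotent.
#'
#' @param table data.frame with columns gene_id, log2fc, p_value.
#' @param p_max p-value ceiling (default 0.05).
#' @param min_abs_log2fc absolute log2 fold-change floor (default 1).
#' @return The DEG rows with a `direction` column added.
#' @export
filter_degs <- function(table, p_max = 0.05, min_abs_log2fc = 1) {
  needed <- c("gene_id", "log2fc", "p_value")
  if (!all(needed %in% names(table))) {
    stop_param("DEG table needs columns gene_id, log2fc, p_value")
  }
  if (any(table$p_value < 0 | table$p_value > 1)) {
    stop_param("p_value must lie in [0, 1]")
  }
  keep <- table$p_value <= p_max & abs(table$log2fc) >= min_abs_log2fc
  out <- table[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Multi-set DEG overlap and direction concordance
#'
#' Computes, over two or three filtered DEG tables sharing one gene
#' universe: per-set DEG/up/down counts; all pairwise intersections with
#' their direction-concordant and down-down/up-up subsets; and, for three
#' tables, conditional statistics of each pair's overlap inside the third
#' set (how many down-down genes of a pair are also down in the third, and
#' how many of the pair's union of downregulated genes are regulated at
#' all in the third). Set algebra is exact; percentages are rounded half
#' up to one decimal, matching the conventional printed style.
#'
#' @param tables named list of 2-3 filtered DEG tables (from
#'   [filter_degs()]), each with gene_id and direction columns.
#' @return An object of class `overlap_summary`: list with `sets`,
#'   `pairs` and (for three tables) `conditional` data.frames.
#' @export
overlap_summary <- function(tables) {
  if (length(tables) < 2 || length(tables) > 3) {
    stop_param("overlap_summary takes 2 or 3 DEG tables")
  }
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- paste0("set", seq_along(tables))
  }
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if (!all(c("gene_id", "direction") %in% names(tb))) {
      stop_param("each table needs gene_id and direction columns (run filter_degs first)")
    }
    if (anyDuplicated(tb$gene_id)) {
      stop_integrity(paste0("duplicate gene ids within table ", nm))
    }
  }
  dirs <- lapply(tables, function(tb) setNames(tb$direction, tb$gene_id))
  sets <- data.frame(
    set = names(tables),
    n_deg = vapply(dirs, length, integer(1)),
    n_up = vapply(dirs, function(d) sum(d == "up"), integer(1)),
    n_down = vapply(dirs, function(d) sum(d == "down"), integer(1)),
    row.names = NULL
  )
  combos <- utils::combn(names(tables), 2, simplify = FALSE)
  pairs <- do.call(rbind, lapply(combos, function(ab) {
    a <- dirs[[ab[1]]]; b <- dirs[[ab[2]]]
    shared <- intersect(names(a), names(b))
    same <- shared[a[shared] == b[shared]]
    dd <- same[a[same] == "down"]
    uu <- same[a[same] == "up"]
    data.frame(
      set_a = ab[1], set_b = ab[2],
      intersection = length(shared),
      same_direction = length(same),
      down_down = length(dd), up_up = length(uu),
      pct_of_a = pct(length(shared), length(a)),
      pct_of_b = pct(length(shared), length(b)),
      pct_concordant = pct(length(same), length(shared)),
      pct_down_down = pct(length(dd), length(same))
    )
  }))
  out <- list(sets = sets, pairs = pairs)
  if (length(tables) == 3) {
    out$conditional <- do.call(rbind, lapply(combos, function(ab) {
      third <- setdiff(names(tables), ab)
      a <- dirs[[ab[1]]]; b <- dirs[[ab[2]]]; c3 <- dirs[[third]]
      shared <- intersect(names(a), names(b))
      dd <- shared[a[shared] == "down" & b[shared] == "down"]
      dd_third_down <- sum(c3[intersect(dd, names(c3))] == "down")
      union_down <- union(names(a)[a == "down"], names(b)[b == "down"])
      union_down_in_third <- length(intersect(union_down, names(c3)))
      data.frame(
        set_a = ab[1], set_b = ab[2], third = third,
        down_down = length(dd),
        down_down_also_down = dd_third_down,
        pct_down_down_also_down = pct(dd_third_down, length(dd)),
        union_down = length(union_down),
        union_down_regulated = union_down_in_third,
        pct_union_down_regulated = pct(union_down_in_third,
                                       length(union_down))
      )
    }))
  }
  class(out) <- "overlap_summary"
  out
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("DEG overlap summary\n\nPer set:\n")
  print(x$sets, row.names = FALSE)
  cat("\nPairwise:\n")
  print(x$pairs, row.names = FALSE)
  if (!is.null(x$conditional)) {
    cat("\nPair inside third set:\n")
    print(x$conditional, row.names = FALSE)
  }
  invisible(x)
}

#' Hierarchical clustering of a log2 fold-change matrix
#'
#' Agglomerative clustering with complete linkage on Euclidean distances
#' (the defaults of the standard heat-map workflow), applied to both rows
#' (genes) and columns (contrasts). Columns with zero variance are allowed;
#' missing values are an error unless zero-imputation is requested.
#'
#' @param mat numeric matrix, genes x contrasts (>= 2 columns).
#' @param impute_zero replace missing values by 0 before clustering.
#' @return list with `row_hclust`, `col_hclust` (stats::hclust objects)
#'   and `matrix`, the input reordered to the dendrogram leaf orders.
#' @export
cluster_log2fc <- function(mat, impute_zero = FALSE) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop_param("need at least 2 columns to cluster")
  if (anyNA(mat)) {
    if (!impute_zero) {
      stop_param("matrix contains missing values; set impute_zero = TRUE to zero-fill")
    }
    mat[is.na(mat)] <- 0
  }
  row_hclust <- if (nrow(mat) >= 2) {
    hclust(dist(mat, method = "euclidean"), method = "complete")
  }
  col_hclust <- hclust(dist(t(mat), method = "euclidean"),
                       method = "complete")
  ordered <- mat[if (is.null(row_hclust)) 1 else row_hclust$order,
                 col_hclust$order, drop = FALSE]
  list(row_hclust = row_hclust, col_hclust = col_hclust, matrix = ordered)
}
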