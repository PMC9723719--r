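#' Rarefy a count matrix to even depth
#'
#' Subsamples each sample's reads uniformly without replacement (multivariate
#' hypergeometric) to a common depth, the standard control for unequal
#' sequencing effort. Samples whose total is below `depth` are dropped and
#' reported. Deterministic given `seed`.
#'
#' @param cm a [count_matrix()].
#' @param depth target depth. Default: the minimum total among samples with
#'   at least `floor` reads.
#' @param seed integer RNG seed.
#' @param floor samples with fewer reads than this are dropped before the
#'   default depth is computed (default 1000).
#' @return a `count_matrix` whose retained samples all sum to `depth`, with
#'   attribute `"dropped"` listing removed sample ids.
#' @export
rarefy <- function(cm, depth = NULL, seed = 1, floor = 1000) {
  totals <- rowSums(cm$counts)
  if (is.null(depth)) {
    keep0 <- totals >= floor
    if (!any(keep0)) stop("no samples retained: all totals below floor ", floor)
    depth <- min(totals[keep0])
  }
  if (depth < 1) stop("depth must be >= 1")
  keep <- totals >= depth
  if (!any(keep)) stop("no samples retained at depth ", depth)
  dropped <- cm$sample_ids[!keep]
  if (length(dropped) > 0)
    message(length(dropped), " sample(s) below depth ", depth, " dropped: ",
            paste(dropped, collapse = ", "))
  sub <- cm$counts[keep, , drop = FALSE]
  # rrarefy's "smallest count" heuristic misfires on valid integer counts
  rar <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(sub, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  out <- count_matrix(rar, cm$dates[keep])
  attr(out, "dropped") <- dropped
  attr(out, "depth") <- depth
  out
}

#' Per-sample relative abundance
#'
#' @param cm a [count_matrix()].
#' @return list with `values` (samples x ASVs proportions, rows summing to 1),
#'   `dates`, and `zero_samples` flagging all-zero samples (left as zero rows).
#' @export
relative_abundance <- function(cm) {
  totals <- rowSums(cm$counts)
  zero <- totals == 0
  vals <- cm$counts / ifelse(totals == 0, 1, totals)
  structure(list(values = vals, dates = cm$dates,
                 sample_ids = cm$sample_ids, asv_ids = cm$asv_ids,
                 zero_samples = cm$sample_ids[zero]),
            class = "rel_abundance")
}

#' Collapse ASV counts to ecotype level
#'
#' Sums the counts of all ASVs sharing an ecotype label; per-sample totals
#' are conserved exactly.
#'
#' @param cm a [count_matrix()].
#' @param tax named character vector `asv_id -> ecotype` covering every ASV.
#' @return a `count_matrix` with one column per ecotype present.
#' @export
collapse_by_ecotype <- function(cm, tax) {
  missing <- setdiff(cm$asv_ids, names(tax))
  if (length(missing) > 0)
    stop("ASVs missing from taxonomy: ", paste(missing, collapse = ", "))
  labels <- tax[cm$asv_ids]
  groups <- factor(labels, levels = intersect(ECOTYPE_LEVELS, labels))
  collapsed <- t(rowsum(t(cm$counts), groups))
  count_matrix(collapsed, cm$dates)
}

#' Per-sample SAR11 fraction
#'
#' Fraction of reads assigned to any SAR11 ecotype (everything except
#' `"other"`), as plotted in ecotype-composition overviews.
#'
#' @param cm a [count_matrix()] at ASV or ecotype level.
#' @param tax taxonomy map covering `cm`'s columns.
#' @return named numeric vector in \[0,1\]; `NA` for zero-total samples.
#' @export
sar11_fraction <- function(cm, tax) {
  missing <- setdiff(cm$asv_ids, names(tax))
  if (length(missing) > 0)
    stop("ASVs missing from taxonomy: ", paste(missing, collapse = ", "))
  is_sar11 <- tax[cm$asv_ids] != "other"
  totals <- rowSums(cm$counts)
  frac <- rowSums(cm$counts[, is_sar11, drop = FALSE]) / totals
  frac[totals == 0] <- NA_real_
  stats::setNames(frac, cm$sample_ids)
}
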