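# Benchmarking machinery: replicate consensus peaks, standard
# preparation, count-ranked ROC/PR curves with trapezoidal areas, and
# per-peak characterization.

#' High-confidence consensus peaks across replicates
#'
#' Merges the union of all replicate peak sets into disjoint blocks
#' (chains of >= 1 bp overlaps) and keeps blocks supported by at least
#' `min_support` distinct replicates. This suppresses spurious peaks
#' that appear in a single replicate. With `min_support = 1` the result
#' is the plain union-merge.
#'
#' @param replicate_peaks A list of peak tibbles (or `peak_call`
#'   objects), one per biological replicate.
#' @param min_support Minimum number of distinct replicates that must
#'   contribute a peak to a block (default 2).
#' @return A tibble of disjoint consensus intervals with a `support`
#'   column.
#' @export
high_confidence <- function(replicate_peaks, min_support = 2) {
  if (!is.list(replicate_peaks) || is.data.frame(replicate_peaks)) {
    abort("`replicate_peaks` must be a list of peak sets")
  }
  replicate_peaks <- lapply(replicate_peaks, function(p) {
    if (inherits(p, "peak_call")) p$peaks else p
  })
  if (length(replicate_peaks) < min_support) {
    abort(sprintf(
      "%d replicate(s) supplied but min_support = %d",
      length(replicate_peaks), min_support
    ))
  }
  pooled <- dplyr::bind_rows(lapply(seq_along(replicate_peaks), function(i) {
    p <- replicate_peaks[[i]]
    if (!nrow(p)) {
      return(NULL)
    }
    check_intervals(p, sprintf("replicate %d", i))
    tibble::tibble(
      chrom = p$chrom, start = p$start, end = p$end, ..rep = i
    )
  }))
  empty <- tibble::tibble(
    chrom = character(), start = numeric(), end = numeric(),
    support = integer()
  )
  if (is.null(pooled) || !nrow(pooled)) {
    return(empty)
  }
  pooled$..block <- merge_block_ids(pooled, max_gap = -1)
  blocks <- dplyr::summarise(
    dplyr::group_by(pooled, .data$..block),
    chrom = .data$chrom[1],
    start = min(.data$start),
    end = max(.data$end),
    support = dplyr::n_distinct(.data$..rep),
    .groups = "drop"
  )
  blocks <- blocks[blocks$support >= min_support, , drop = FALSE]
  dplyr::arrange(
    dplyr::select(blocks, "chrom", "start", "end", "support"),
    .data$chrom, .data$start
  )
}

#' Prepare a scored standard for benchmarking
#'
#' Filters a scored peak set (scores on the -log10 p scale, e.g. from
#' [read_narrowpeak()]) to intervals with score strictly greater than
#' `min_neglog10p`, then merges survivors whose gap is at most
#' `merge_within` bp. Idempotent.
#'
#' @param scored Tibble with `chrom`, `start`, `end`, `score` (-log10 p).
#' @param min_neglog10p Score cutoff, strict (default 10).
#' @param merge_within Maximum gap for merging survivors (default 1000).
#' @return A tibble of disjoint standard intervals.
#' @export
prepare_standard <- function(scored, min_neglog10p = 10, merge_within = 1000) {
  if (!nrow(scored)) {
    return(tibble::tibble(
      chrom = character(), start = numeric(), end = numeric()
    ))
  }
  check_intervals(scored, "scored")
  if (is.null(scored[["score"]])) abort("`scored` must have a `score` column")
  keep <- scored[scored$score > min_neglog10p, , drop = FALSE]
  merge_intervals(keep, max_gap = merge_within)
}

#' Rank consensus intervals by fragment counts
#'
#' The ranking metric for ROC/PR evaluation: each consensus interval is
#' scored by the number of fragments overlapping it by >= 1 bp.
#'
#' @param consensus Consensus intervals ([high_confidence()]).
#' @param fragments Fragment tibble.
#' @return `consensus` with a `score` column of overlap counts.
#' @export
rank_counts <- function(consensus, fragments) {
  check_intervals(consensus, "consensus")
  check_intervals(fragments, "fragments")
  consensus$score <- overlap_counts(consensus, fragments)
  consensus
}

#' ROC and precision-recall curves for a ranked peak set
#'
#' Sweeps thresholds over the unique ranking scores (descending, with a
#' sentinel above the maximum so the sweep is anchored at the
#' all-negative end). At each threshold, predicted-positive intervals
#' are those with `score >= t`; actual-positive intervals are those
#' overlapping the standard by >= 1 bp. The confusion-matrix universe is
#' the ranked interval set itself: true negatives are intervals below
#' the threshold and absent from the standard. Areas use the trapezoid
#' rule; the ROC sweep spans (0,0) to (1,1). Precision at the empty
#' (sentinel) threshold is taken as 1 by convention.
#'
#' @param ranked Tibble with `chrom`, `start`, `end`, `score` (from
#'   [rank_counts()]).
#' @param standard Standard intervals ([prepare_standard()]).
#' @return A list with elements `roc` and `pr`, each an `eval_curve`
#'   tibble (threshold, tp, fp, fn, tn, tpr, fpr, precision, recall)
#'   carrying its trapezoidal `area` attribute. If the standard is empty
#'   (or no ranked interval overlaps it), recall is undefined and both
#'   curves are flagged degenerate with `NA` area.
#' @export
roc_pr <- function(ranked, standard) {
  check_intervals(ranked, "ranked")
  if (!nrow(ranked)) abort("`ranked` must contain at least one interval")
  if (is.null(ranked[["score"]])) abort("`ranked` must have a `score` column")
  label <- if (nrow(standard)) overlaps_any(ranked, standard) else
    rep(FALSE, nrow(ranked))
  pos <- sum(label)
  neg <- sum(!label)
  degenerate <- pos == 0 || neg == 0
  thresholds <- c(max(ranked$score) + 1, sort(unique(ranked$score),
    decreasing = TRUE
  ))
  rows <- lapply(thresholds, function(t) {
    pred <- ranked$score >= t
    tp <- sum(pred & label)
    fp <- sum(pred & !label)
    tibble::tibble(
      threshold = t, tp = tp, fp = fp,
      fn = pos - tp, tn = neg - fp,
      tpr = if (pos > 0) tp / pos else NA_real_,
      fpr = if (neg > 0) fp / neg else NA_real_,
      precision = if (tp + fp > 0) tp / (tp + fp) else 1,
      recall = if (pos > 0) tp / pos else NA_real_
    )
  })
  curve <- dplyr::bind_rows(rows)
  roc_area <- if (degenerate) NA_real_ else trapezoid_area(curve$fpr, curve$tpr)
  pr_area <- if (degenerate) NA_real_ else
    trapezoid_area(curve$recall, curve$precision)
  list(
    roc = new_eval_curve(curve, type = "roc", area = roc_area,
      degenerate = degenerate
    ),
    pr = new_eval_curve(curve, type = "pr", area = pr_area,
      degenerate = degenerate
    )
  )
}

trapezoid_area <- function(x, y) {
  ord <- order(x)
  x <- x[ord]
  y <- y[ord]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

new_eval_curve <- function(curve, type, area, degenerate) {
  structure(curve,
    class = c("eval_curve", class(curve)),
    type = type, area = area, degenerate = degenerate
  )
}

#' @export
print.eval_curve <- function(x, ...) {
  type <- toupper(attr(x, "type"))
  if (isTRUE(attr(x, "degenerate"))) {
    cat(sprintf("%s curve: degenerate (one class empty), area undefined\n",
      type
    ))
  } else {
    cat(sprintf("%s curve: %d thresholds, trapezoidal area %.4f\n",
      type, nrow(x), attr(x, "area")
    ))
  }
  NextMethod()
}

#' @rdname roc_pr
#' @param x An `eval_curve`.
#' @param ... Unused.
#' @export
tidy.eval_curve <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname roc_pr
#' @export
glance.eval_curve <- function(x, ...) {
  tibble::tibble(
    type = attr(x, "type"),
    area = attr(x, "area"),
    n_thresholds = nrow(x),
    degenerate = attr(x, "degenerate")
  )
}

#' @rdname roc_pr
#' @param object An `eval_curve`.
#' @export
autoplot.eval_curve <- function(object, ...) {
  type <- attr(object, "type")
  df <- tibble::as_tibble(unclass(object))
  if (type == "roc") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_abline(
        slope = 1, intercept = 0, linetype = "dashed", colour = "grey60"
      ) +
      ggplot2::geom_step(direction = "hv") +
      ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
      ggplot2::labs(
        x = "False positive rate", y = "Recall (TPR)",
        title = sprintf("ROC (AUROC = %.3f)", attr(object, "area"))
      )
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
      ggplot2::labs(
        x = "Recall", y = "Precision",
        title = sprintf("Precision-recall (AUPR = %.3f)", attr(object, "area"))
      )
  }
}

#' Per-peak characterization statistics
#'
#' For each peak: its width, the number of overlapping fragments, and
#' the distance to the nearest other peak on the same chromosome (the
#' gap in bp; 0 for touching peaks, `NA` for a chromosome singleton).
#'
#' @param peaks Peak tibble or `peak_call` object.
#' @param fragments Fragment tibble.
#' @return A tibble with `chrom`, `start`, `end`, `width`, `count`,
#'   `nearest_dist`.
#' @export
peak_stats <- function(peaks, fragments) {
  if (inherits(peaks, "peak_call")) peaks <- peaks$peaks
  check_intervals(peaks, "peaks")
  check_intervals(fragments, "fragments")
  out <- tibble::tibble(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    width = peaks$end - peaks$start,
    count = overlap_counts(peaks, fragments)
  )
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$chrom),
    nearest_dist = {
      gap_prev <- .data$start - dplyr::lag(.data$end)
      gap_next <- dplyr::lead(.data$start) - .data$end
      pmax(pmin(gap_prev, gap_next, na.rm = TRUE), 0)
    }
  )
  dplyr::ungroup(out)
}

#' Peak width versus fragment count plot
#'
#' Scatter of per-peak fragment counts against peak widths (log-log), a
#' standard way to visualize how a caller's peaks partition into narrow
#' high-density and broad low-density classes.
#'
#' @param stats Output of [peak_stats()].
#' @return A ggplot object.
#' @export
plot_peak_stats <- function(stats) {
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$width, y = .data$count)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Peak width (bp)", y = "Fragments in peak")
}
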