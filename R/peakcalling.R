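# Core caller: genome-wide binomial null over bin counts, BH correction,
# gap-merge of significant bins into peaks.

# Control-scaled counts are real-valued; the binomial test needs integer
# successes, so counts are rounded half-away-from-zero before testing and
# model estimation.
integerize <- function(x) {
  as.integer(floor(x + 0.5))
}

#' Estimate the genome-wide binomial null for bin counts
#'
#' The null models the count in a bin as Binomial(n, p) with `n` the
#' library fragment depth and `p` estimated as the mean count over
#' non-zero bins divided by `n`. Real-valued (control-scaled) counts are
#' rounded half-away-from-zero first.
#'
#' @param counts Numeric vector of per-bin counts, or a bin-count tibble
#'   from [count_fragments()]/[scale_to_control()] (the `scaled` column
#'   is used when present, else `count`).
#' @param n Library fragment depth (trials).
#' @return An object of class `binom_null` with elements `n` and `p`.
#' @examples
#' m <- estimate_binomial_model(c(0, 0, 2, 4, 6), n = 12)
#' m$p # (2+4+6)/3 / 12 = 1/3
#' @export
estimate_binomial_model <- function(counts, n) {
  counts <- extract_test_counts(counts)
  if (n < 1) abort("library depth `n` must be >= 1")
  nz <- counts[counts > 0]
  if (!length(nz)) {
    abort("no signal: all bin counts are zero")
  }
  p <- mean(nz) / n
  if (p >= 1) {
    abort("estimated success probability >= 1; check `n` against counts")
  }
  structure(list(n = as.numeric(n), p = p), class = "binom_null")
}

extract_test_counts <- function(counts) {
  if (is.data.frame(counts)) {
    col <- if (!is.null(counts[["scaled"]])) "scaled" else "count"
    counts <- counts[[col]]
    if (is.null(counts)) abort("no `scaled` or `count` column in counts")
  }
  integerize(counts)
}

#' @export
print.binom_null <- function(x, ...) {
  cat(sprintf(
    "Binomial null: n = %s trials, p = %.4g (expected bin count %.3f)\n",
    format(x$n, big.mark = ","), x$p, x$n * x$p
  ))
  invisible(x)
}

#' Upper-tail binomial p-value for a bin count
#'
#' Returns P(X >= x) for X ~ Binomial(n, p): the probability of drawing
#' at least `x` of the library's `n` fragments into one bin under the
#' genome-wide null. Exact to double precision; `x = 0` gives 1.
#'
#' @param x Non-negative integer count(s), each `<= n`.
#' @param model A `binom_null` from [estimate_binomial_model()], or a
#'   list with `n` and `p`.
#' @return Numeric vector of upper-tail probabilities in `[0, 1]`.
#' @export
binom_tail <- function(x, model) {
  if (any(x < 0)) abort("counts must be non-negative")
  if (any(x > model$n)) abort("count exceeds the number of trials `n`")
  pbinom(x - 1, size = model$n, prob = model$p, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment over one family of tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Test bins against the binomial null
#'
#' Only bins whose (integerized) count strictly exceeds `minreads` enter
#' testing; the BH family is exactly that tested set. A tested bin is
#' significant when its adjusted p-value is `<= pthresh`. Untested bins
#' carry `NA` p-values and are never significant.
#'
#' @param counts Bin-count tibble ([count_fragments()], optionally
#'   [scale_to_control()]); the `scaled` column is tested when present.
#' @param n Library fragment depth.
#' @param minreads Minimum count to enter testing (strict `>`; default
#'   15).
#' @param pthresh Adjusted-p significance cutoff (default 0.05).
#' @return The bin tibble with columns `test_count`, `tested`, `pvalue`,
#'   `padj`, `significant`.
#' @export
test_bins <- function(counts, n, minreads = 15, pthresh = 0.05) {
  check_intervals(counts, "counts")
  if (pthresh <= 0 || pthresh > 1) abort("`pthresh` must be in (0, 1]")
  out <- counts
  out$test_count <- extract_test_counts(counts)
  out$tested <- out$test_count > minreads
  out$pvalue <- NA_real_
  out$padj <- NA_real_
  out$significant <- FALSE
  if (any(out$tested)) {
    model <- estimate_binomial_model(out$test_count, n)
    out$pvalue[out$tested] <- binom_tail(out$test_count[out$tested], model)
    out$padj[out$tested] <- bh_adjust(out$pvalue[out$tested])
    out$significant[out$tested] <- out$padj[out$tested] <= pthresh
  }
  out
}

#' Merge significant bins into peaks
#'
#' Bins on the same chromosome merge into one peak when they overlap or
#' when the gap between them (next start minus previous end) is at most
#' `mdist` bp. Merged peaks narrower than `minwidth` are discarded.
#' Bins on different chromosomes never merge.
#'
#' @param bins Tibble of significant bins (`chrom`, `start`, `end`;
#'   `padj` and `test_count` aggregated into per-peak statistics when
#'   present).
#' @param mdist Maximum merge gap in bp (default 150).
#' @param minwidth Minimum emitted peak width in bp (default 150).
#' @return A tibble of disjoint, sorted peaks with `chrom`, `start`,
#'   `end`, `name`, `score` (-log10 min adjusted p, capped at 3100),
#'   `min_padj`, `n_bins`, `max_count`.
#' @export
merge_significant <- function(bins, mdist = 150, minwidth = 150) {
  empty <- tibble::tibble(
    chrom = character(), start = numeric(), end = numeric(),
    name = character(), score = numeric(), min_padj = numeric(),
    n_bins = integer(), max_count = numeric()
  )
  if (!nrow(bins)) {
    return(empty)
  }
  check_intervals(bins, "bins")
  bins$..block <- merge_block_ids(bins, max_gap = mdist)
  has_padj <- !is.null(bins[["padj"]])
  has_count <- !is.null(bins[["test_count"]])
  peaks <- dplyr::summarise(
    dplyr::group_by(bins, .data$..block),
    chrom = .data$chrom[1],
    start = min(.data$start),
    end = max(.data$end),
    min_padj = if (has_padj) min(.data$padj) else NA_real_,
    n_bins = dplyr::n(),
    max_count = if (has_count) max(.data$test_count) else NA_real_,
    .groups = "drop"
  )
  peaks <- peaks[peaks$end - peaks$start >= minwidth, , drop = FALSE]
  peaks <- dplyr::arrange(peaks, .data$chrom, .data$start)
  if (!nrow(peaks)) {
    return(empty)
  }
  peaks$name <- sprintf("peak_%d", seq_len(nrow(peaks)))
  peaks$score <- pmin(-log10(pmax(peaks$min_padj, 0)), 3100)
  peaks$score[is.na(peaks$score)] <- 0
  dplyr::select(
    peaks, "chrom", "start", "end", "name", "score",
    "min_padj", "n_bins", "max_count"
  )
}

#' Call peaks from paired-end fragments
#'
#' The full pipeline: bin the genome on a sliding grid, count fragments
#' per bin, CPM-normalize, optionally scale against a negative control,
#' test bins against the genome-wide binomial null, BH-correct over the
#' tested family, and merge significant bins into peaks. Deterministic:
#' identical inputs and parameters give identical output.
#'
#' `broad = TRUE` switches to the domain-scale parameterization (5000-bp
#' bins on a 1000-bp grid) for marks such as H3K27me3; `mdist` stays
#' under user control and is often raised (e.g. to 3000) alongside it.
#'
#' @param fragments Fragment tibble ([read_fragments()]).
#' @param chrom_sizes Tibble from [read_chrom_sizes()].
#' @param control Optional negative-control fragment tibble (IgG/input).
#' @param step,slide Bin width and start spacing in bp (defaults 100/50).
#' @param minreads Minimum bin count to enter testing (default 15).
#' @param pthresh Adjusted-p cutoff (default 0.05).
#' @param mdist Maximum gap for merging significant bins (default 150).
#' @param minwidth Minimum peak width (default 150).
#' @param broad Use the broad parameterization: overrides `step`/`slide`
#'   to 5000/1000.
#' @param blacklist Optional interval tibble; fragments overlapping it
#'   are removed (from sample and control) before counting.
#' @param sample_id Optional label carried into the result.
#' @return An object of class `peak_call`: `peaks` (tibble as from
#'   [merge_significant()]), `model` (`binom_null` or NULL when nothing
#'   was tested), `params`, `n_bins`, `n_tested`, `n_significant`,
#'   `bins` (per-bin test table), `chrom_sizes`. Use [tidy()] for the
#'   peak tibble and [glance()] for a one-row run summary.
#' @examples
#' sizes <- tibble::tibble(chrom = "chrI", size = 100000L)
#' cfg <- sim_config(sizes,
#'   truth = tibble::tibble(
#'     chrom = "chrI", start = 40000, end = 41000,
#'     shape = "narrow", fold = 30
#'   ),
#'   background_rate = 5, depth = 20000
#' )
#' sim <- simulate_fragments(cfg, seed = 1)
#' fit <- call_peaks(sim$sample, sizes)
#' tidy(fit)
#' @export
call_peaks <- function(fragments, chrom_sizes, control = NULL,
                       step = 100, slide = 50, minreads = 15,
                       pthresh = 0.05, mdist = 150, minwidth = 150,
                       broad = FALSE, blacklist = NULL,
                       sample_id = NULL) {
  check_intervals(fragments, "fragments")
  if (broad) {
    step <- 5000
    slide <- 1000
  }
  if (!is.null(blacklist) && nrow(blacklist)) {
    fragments <- exclude_blacklist(fragments, blacklist)
    if (!is.null(control)) control <- exclude_blacklist(control, blacklist)
  }
  bins <- make_bins(chrom_sizes, step = step, slide = slide)
  counts <- count_fragments(bins, fragments)
  if (!is.null(control)) {
    check_intervals(control, "control")
    ctrl_counts <- count_fragments(bins, control)
    counts <- scale_to_control(counts, ctrl_counts)
  }
  n <- nrow(fragments)
  tests <- test_bins(counts, n = n, minreads = minreads, pthresh = pthresh)
  model <- if (any(tests$tested)) {
    estimate_binomial_model(tests$test_count, n)
  } else {
    NULL
  }
  sig <- tests[tests$significant, , drop = FALSE]
  peaks <- merge_significant(sig, mdist = mdist, minwidth = minwidth)
  structure(
    list(
      peaks = peaks,
      model = model,
      params = list(
        step = step, slide = slide, minreads = minreads,
        pthresh = pthresh, mdist = mdist, minwidth = minwidth,
        broad = broad
      ),
      n_fragments = n,
      n_bins = nrow(tests),
      n_tested = sum(tests$tested),
      n_significant = sum(tests$significant),
      bins = tests,
      chrom_sizes = chrom_sizes,
      sample_id = sample_id
    ),
    class = "peak_call"
  )
}

#' @export
print.peak_call <- function(x, ...) {
  cat(sprintf(
    "Peak call%s: %d peak(s) from %s fragments\n",
    if (!is.null(x$sample_id)) paste0(" [", x$sample_id, "]") else "",
    nrow(x$peaks), format(x$n_fragments, big.mark = ",")
  ))
  cat(sprintf(
    "  bins: %d total, %d tested (> %d counts), %d significant (padj <= %g)\n",
    x$n_bins, x$n_tested, x$params$minreads, x$n_significant,
    x$params$pthresh
  ))
  if (!is.null(x$model)) {
    cat(sprintf("  null: Binomial(n = %s, p = %.3g)\n",
      format(x$model$n, big.mark = ","), x$model$p
    ))
  }
  if (nrow(x$peaks)) {
    cat(sprintf(
      "  widths: %d-%d bp (median %d)\n",
      min(x$peaks$end - x$peaks$start), max(x$peaks$end - x$peaks$start),
      as.integer(stats::median(x$peaks$end - x$peaks$start))
    ))
  }
  invisible(x)
}

#' @rdname call_peaks
#' @param x A `peak_call` object.
#' @export
tidy.peak_call <- function(x, ...) {
  x$peaks
}

#' @rdname call_peaks
#' @export
glance.peak_call <- function(x, ...) {
  tibble::tibble(
    n_fragments = x$n_fragments,
    n_bins = x$n_bins,
    n_tested = x$n_tested,
    n_significant = x$n_significant,
    n_peaks = nrow(x$peaks),
    null_n = if (!is.null(x$model)) x$model$n else NA_real_,
    null_p = if (!is.null(x$model)) x$model$p else NA_real_,
    step = x$params$step,
    slide = x$params$slide,
    minreads = x$params$minreads,
    pthresh = x$params$pthresh,
    mdist = x$params$mdist,
    minwidth = x$params$minwidth,
    broad = x$params$broad
  )
}

#' Write a peak call to BED
#'
#' @param x A `peak_call` object.
#' @param path Output BED path.
#' @return Invisibly, the path.
#' @export
write_peaks <- function(x, path) {
  if (!inherits(x, "peak_call")) abort("`x` must be a peak_call")
  write_bed(
    dplyr::select(x$peaks, "chrom", "start", "end", "name", "score"),
    path,
    chrom_order = x$chrom_sizes
  )
}

#' @rdname call_peaks
#' @param object A `peak_call` object.
#' @export
autoplot.peak_call <- function(object, ...) {
  pk <- object$peaks
  if (!nrow(pk)) {
    abort("no peaks to plot")
  }
  ggplot2::ggplot(pk) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$start, xend = .data$end,
        y = .data$score, yend = .data$score
      ),
      linewidth = 2
    ) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(
      x = "Genomic position (bp)",
      y = expression(-log[10] ~ "adjusted p"),
      title = sprintf("%d peak(s)", nrow(pk))
    )
}
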