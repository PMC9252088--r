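#' Build a sliding-bin grid over the genome
#'
#' Partitions each chromosome into bins of width `step` whose starts
#' fall on a grid spaced `slide` bp apart (0, slide, 2*slide, ...).
#' When `slide < step` consecutive bins overlap; `slide == step` gives a
#' plain non-overlapping tiling. Trailing bins are truncated at the
#' chromosome end, and a start at or beyond the chromosome end produces
#' no bin.
#'
#' @param chrom_sizes Tibble from [read_chrom_sizes()] (`chrom`, `size`).
#' @param step Bin width in bp (default 100).
#' @param slide Offset between consecutive bin starts in bp (default
#'   50); must satisfy `0 < slide <= step`.
#' @return A tibble of bins: `chrom`, `start`, `end` (0-based
#'   half-open), ordered by chromosome (input order) then start.
#' @examples
#' sizes <- tibble::tibble(chrom = "chr1", size = 250L)
#' make_bins(sizes, step = 100, slide = 50)
#' @export
make_bins <- function(chrom_sizes, step = 100, slide = 50) {
  if (!is.data.frame(chrom_sizes) ||
    !all(c("chrom", "size") %in% names(chrom_sizes))) {
    abort("`chrom_sizes` must have columns `chrom` and `size`")
  }
  if (step <= 0 || slide <= 0) {
    abort("`step` and `slide` must be positive")
  }
  if (slide > step) {
    abort("`slide` must not exceed `step`")
  }
  pieces <- lapply(seq_len(nrow(chrom_sizes)), function(i) {
    len <- chrom_sizes$size[i]
    starts <- seq(0, len - 1, by = slide)
    tibble::tibble(
      chrom = chrom_sizes$chrom[i],
      start = starts,
      end = pmin(starts + step, len)
    )
  })
  dplyr::bind_rows(pieces)
}

#' Count fragments per bin and CPM-normalize
#'
#' A fragment increments every bin it overlaps by at least 1 bp, so with
#' overlapping bins one fragment contributes to several. The CPM column
#' normalizes by library depth: `cpm = count * 1e6 / total`. The depth
#' is the number of fragments in the library, not the sum of bin counts
#' (overlapping bins double-count).
#'
#' @param bins Bin grid from [make_bins()].
#' @param fragments Fragment tibble (`chrom`, `start`, `end`).
#' @param total Library depth used for CPM (default `nrow(fragments)`).
#' @return `bins` with added columns `count` (integer) and `cpm`.
#' @export
count_fragments <- function(bins, fragments, total = nrow(fragments)) {
  check_intervals(bins, "bins")
  check_intervals(fragments, "fragments")
  unknown <- setdiff(unique(fragments$chrom), unique(bins$chrom))
  if (length(unknown)) {
    abort(sprintf(
      "fragments on chromosome(s) absent from the bin grid: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  if (total < 0) abort("`total` must be non-negative")
  out <- bins
  out$count <- overlap_counts(bins, fragments)
  out$cpm <- if (total > 0) out$count * 1e6 / total else 0
  out
}

#' Scale sample bin counts against a negative control
#'
#' Applies the piecewise control-scaling rule on the CPM scale: in bins
#' where the sample CPM exceeds the control CPM, the raw sample count is
#' multiplied by `1 - cpm_control / cpm_sample` (so an empty control bin
#' leaves the count unchanged); otherwise the bin is zeroed. Scaling a
#' sample against itself therefore zeroes every bin.
#'
#' @param sample Bin counts from [count_fragments()] for the sample.
#' @param control Bin counts on the identical grid for the negative
#'   control (IgG/input).
#' @return `sample` with an added `scaled` column (real-valued,
#'   element-wise `<= count`).
#' @export
scale_to_control <- function(sample, control) {
  for (col in c("count", "cpm")) {
    if (is.null(sample[[col]]) || is.null(control[[col]])) {
      abort("`sample` and `control` must come from count_fragments()")
    }
  }
  if (nrow(sample) != nrow(control) ||
    !all(sample$chrom == control$chrom) ||
    !all(sample$start == control$start) ||
    !all(sample$end == control$end)) {
    abort("`sample` and `control` must share an identical bin grid")
  }
  out <- sample
  enriched <- sample$cpm > control$cpm
  out$scaled <- ifelse(
    enriched,
    sample$count * (1 - control$cpm / sample$cpm),
    0
  )
  out
}
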