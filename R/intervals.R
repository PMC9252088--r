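# Interval primitives shared across modules. All coordinates are 0-based
# half-open ([start, end)), the BED convention; IRanges is 1-based closed,
# so conversion adds 1 to starts. Overlap always means >= 1 bp.

check_intervals <- function(x, arg = "x") {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame of intervals", arg))
  }
  missing <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing)) {
    abort(sprintf(
      "`%s` lacks required column(s): %s", arg,
      paste(missing, collapse = ", ")
    ))
  }
  if (nrow(x) && any(x$start < 0 | x$end <= x$start)) {
    bad <- which(x$start < 0 | x$end <= x$start)[1]
    abort(sprintf(
      "`%s` row %d is not a valid half-open interval (start %s, end %s)",
      arg, bad, x$start[bad], x$end[bad]
    ))
  }
  invisible(x)
}

as_iranges0 <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

# Per-query count of subject intervals overlapping by >= 1 bp,
# chromosome-aware.
overlap_counts <- function(query, subject) {
  out <- integer(nrow(query))
  if (!nrow(query) || !nrow(subject)) {
    return(out)
  }
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (!length(si)) next
    out[qi] <- IRanges::countOverlaps(
      as_iranges0(query[qi, , drop = FALSE]),
      as_iranges0(subject[si, , drop = FALSE])
    )
  }
  out
}

# TRUE for query rows overlapping any subject interval by >= 1 bp.
overlaps_any <- function(query, subject) {
  overlap_counts(query, subject) > 0L
}

# Total bp of each query interval covered by the subject set.
overlap_coverage <- function(query, subject) {
  out <- numeric(nrow(query))
  if (!nrow(query) || !nrow(subject)) {
    return(out)
  }
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (!length(si)) next
    q <- as_iranges0(query[qi, , drop = FALSE])
    s <- IRanges::reduce(as_iranges0(subject[si, , drop = FALSE]))
    hits <- IRanges::findOverlaps(q, s)
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      q[qh], s[S4Vectors::subjectHits(hits)]
    ))
    cov <- tapply(ov, qh, sum)
    out[qi[as.integer(names(cov))]] <- as.numeric(cov)
  }
  out
}

# Assign merge-block ids: two intervals belong to one block when the gap
# between them (next start - running max end) is <= max_gap. max_gap = -1
# merges strict overlaps only; max_gap = 0 also merges touching intervals.
merge_block_ids <- function(x, max_gap) {
  stopifnot(nrow(x) > 0)
  ord <- order(x$chrom, x$start, x$end)
  block <- integer(nrow(x))
  cur_chrom <- ""
  cur_end <- -Inf
  id <- 0L
  for (i in ord) {
    if (x$chrom[i] != cur_chrom || x$start[i] - cur_end > max_gap) {
      id <- id + 1L
      cur_chrom <- x$chrom[i]
      cur_end <- x$end[i]
    } else {
      cur_end <- max(cur_end, x$end[i])
    }
    block[i] <- id
  }
  block
}

# Union-merge a set of intervals under the gap rule; returns disjoint
# sorted intervals.
merge_intervals <- function(x, max_gap = -1) {
  check_intervals(x)
  if (!nrow(x)) {
    return(tibble::tibble(
      chrom = character(), start = numeric(), end = numeric()
    ))
  }
  x$..block <- merge_block_ids(x, max_gap)
  out <- dplyr::summarise(
    dplyr::group_by(x, .data$..block),
    chrom = .data$chrom[1],
    start = min(.data$start),
    end = max(.data$end),
    .groups = "drop"
  )
  dplyr::arrange(
    dplyr::select(out, "chrom", "start", "end"),
    .data$chrom, .data$start
  )
}
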