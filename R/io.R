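#' Read a chromosome-sizes file
#'
#' Parses a UCSC-style `chrom.sizes` file: one chromosome per line,
#' `name<TAB>length`. The file order is preserved and defines the
#' chromosome sort order used when peaks are written out.
#'
#' @param path Path to a two-column tab-separated file.
#' @return A tibble with columns `chrom` (character) and `size` (integer
#'   bp), one row per chromosome in file order.
#' @examples
#' tf <- tempfile()
#' writeLines(c("chr1\t100000", "chr2\t50000"), tf)
#' read_chrom_sizes(tf)
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    abort(sprintf("chrom.sizes file '%s' is empty", path))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 2 || !nzchar(f[1]) || is.na(suppressWarnings(as.numeric(f[2])))) {
      abort(sprintf("malformed chrom.sizes line %d: '%s'", i, lines[i]))
    }
    if (as.numeric(f[2]) <= 0) {
      abort(sprintf("non-positive chromosome length on line %d: '%s'", i, lines[i]))
    }
  }
  chrom <- vapply(fields, `[`, character(1), 1)
  size <- vapply(fields, function(f) as.numeric(f[2]), numeric(1))
  if (anyDuplicated(chrom)) {
    dup <- chrom[duplicated(chrom)][1]
    abort(sprintf(
      "duplicate chromosome '%s' (line %d)", dup,
      which(chrom == dup)[2]
    ))
  }
  tibble::tibble(chrom = chrom, size = as.integer(size))
}

#' Read paired-end fragments from a BAM, BED or BEDPE file
#'
#' For BAM input, one fragment is emitted per properly-paired read pair,
#' spanning the leftmost mate start to the rightmost mate end (the
#' template length), counted once per pair. Secondary, supplementary and
#' duplicate-flagged alignments are skipped; duplicate marking is
#' respected but no deduplication is performed here. For interval input
#' (BED3+ or BEDPE), one fragment is emitted per row.
#'
#' @param path Path to a BAM, BED or BEDPE file.
#' @param format One of `"auto"`, `"bam"`, `"bed"`, `"bedpe"`. With
#'   `"auto"`, `.bam` extensions select BAM and the column layout of the
#'   first data line distinguishes BED from BEDPE.
#' @param min_mapq Minimum mapping quality for BAM records (default 0,
#'   no filter).
#' @param tlen_bounds Length-2 numeric: fragments reconstructed from BAM
#'   are kept when their template length is within these bounds
#'   (default `c(10, 700)`, mirroring typical paired-end insert bounds).
#'   Ignored for interval input.
#' @return A tibble of fragments with columns `chrom`, `start`, `end`
#'   (0-based half-open). The library depth is the row count.
#' @export
read_fragments <- function(path, format = c("auto", "bam", "bed", "bedpe"),
                           min_mapq = 0, tlen_bounds = c(10, 700)) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("fragment file '%s' does not exist", path))
  }
  if (format == "auto") {
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) {
      "bam"
    } else {
      sniff_interval_format(path)
    }
  }
  switch(format,
    bam = read_fragments_bam(path, min_mapq, tlen_bounds),
    bed = read_fragments_bed(path),
    bedpe = read_fragments_bedpe(path)
  )
}

sniff_interval_format <- function(path) {
  first <- readLines(path, n = 50)
  first <- first[nzchar(first) & !grepl("^(#|track|browser)", first)]
  if (!length(first)) {
    return("bed")
  }
  f <- strsplit(first[1], "\t", fixed = TRUE)[[1]]
  # BEDPE: col 4 is a chromosome name and cols 5-6 are coordinates;
  # BED6 has a numeric score in col 5 but a strand in col 6.
  if (length(f) >= 6 &&
    !is.na(suppressWarnings(as.numeric(f[5]))) &&
    !is.na(suppressWarnings(as.numeric(f[6]))) &&
    is.na(suppressWarnings(as.numeric(f[4])))) {
    "bedpe"
  } else {
    "bed"
  }
}

read_fragments_bam <- function(path, min_mapq, tlen_bounds) {
  n_paired <- Rsamtools::countBam(
    path,
    param = Rsamtools::ScanBamParam(flag = Rsamtools::scanBamFlag(isPaired = TRUE))
  )$records
  if (n_paired == 0) {
    n_any <- Rsamtools::countBam(path)$records
    if (n_any > 0) {
      abort(paste(
        "BAM file contains no paired reads; fragments cannot be",
        "reconstructed from single-end data. Supply pre-extracted",
        "intervals (BED/BEDPE) instead."
      ))
    }
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(
      isPaired = TRUE, isProperPair = TRUE,
      isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
      isDuplicate = FALSE, isUnmappedQuery = FALSE
    ),
    what = c("rname", "pos", "isize", "mapq")
  )
  rec <- Rsamtools::scanBam(path, param = param)[[1]]
  # isize > 0 selects the leftmost mate, so each pair is counted once and
  # the fragment spans the full template.
  keep <- !is.na(rec$isize) & rec$isize > 0 &
    rec$isize >= tlen_bounds[1] & rec$isize <= tlen_bounds[2] &
    (is.na(rec$mapq) | rec$mapq >= min_mapq)
  tibble::tibble(
    chrom = as.character(rec$rname[keep]),
    start = rec$pos[keep] - 1L,
    end = rec$pos[keep] - 1L + rec$isize[keep]
  )
}

read_fragments_bed <- function(path) {
  x <- read_interval_table(path, min_cols = 3)
  out <- tibble::tibble(
    chrom = as.character(x[[1]]),
    start = as.integer(x[[2]]),
    end = as.integer(x[[3]])
  )
  check_intervals(out, "fragments")
  out
}

read_fragments_bedpe <- function(path) {
  x <- read_interval_table(path, min_cols = 6)
  if (any(x[[1]] != x[[4]])) {
    warn("dropping BEDPE rows with mates on different chromosomes")
    x <- x[x[[1]] == x[[4]], , drop = FALSE]
  }
  out <- tibble::tibble(
    chrom = as.character(x[[1]]),
    start = as.integer(pmin(x[[2]], x[[5]])),
    end = as.integer(pmax(x[[3]], x[[6]]))
  )
  check_intervals(out, "fragments")
  out
}

read_interval_table <- function(path, min_cols) {
  x <- utils::read.table(path,
    sep = "\t", header = FALSE, comment.char = "#",
    stringsAsFactors = FALSE, colClasses = NA
  )
  if (ncol(x) < min_cols) {
    abort(sprintf(
      "'%s' has %d column(s); at least %d required", path, ncol(x), min_cols
    ))
  }
  x
}

#' Read a BED file of intervals
#'
#' @param path Path to a BED3+ file.
#' @return A tibble with `chrom`, `start`, `end`, plus `name` and `score`
#'   when present.
#' @export
read_bed <- function(path) {
  x <- read_interval_table(path, min_cols = 3)
  out <- tibble::tibble(
    chrom = as.character(x[[1]]),
    start = as.integer(x[[2]]),
    end = as.integer(x[[3]])
  )
  if (ncol(x) >= 4) out$name <- as.character(x[[4]])
  if (ncol(x) >= 5) out$score <- as.numeric(x[[5]])
  check_intervals(out, "bed")
  out
}

#' Read a narrowPeak/broadPeak file as scored intervals
#'
#' Column 8 of the ENCODE narrowPeak/broadPeak format is the peak's
#' -log10 p-value; it is returned as the interval `score`, the scale
#' expected by [prepare_standard()].
#'
#' @param path Path to a narrowPeak or broadPeak file (>= 8 columns).
#' @return A tibble with `chrom`, `start`, `end`, `score` (-log10 p).
#' @export
read_narrowpeak <- function(path) {
  x <- read_interval_table(path, min_cols = 8)
  out <- tibble::tibble(
    chrom = as.character(x[[1]]),
    start = as.integer(x[[2]]),
    end = as.integer(x[[3]]),
    score = as.numeric(x[[8]])
  )
  check_intervals(out, "narrowpeak")
  out
}

#' Remove intervals overlapping a blacklist
#'
#' Drops every row of `x` that overlaps any blacklist interval by at
#' least 1 bp. Curated blacklists collect regions with anomalous,
#' artifact-prone signal; excluding fragments or peaks falling in them is
#' standard practice before peak calling or benchmarking. An empty
#' blacklist returns `x` unchanged.
#'
#' @param x A tibble of intervals (`chrom`, `start`, `end`, any extra
#'   columns preserved).
#' @param blacklist A tibble of intervals to exclude.
#' @return `x` restricted to rows with zero blacklist overlap.
#' @export
exclude_blacklist <- function(x, blacklist) {
  check_intervals(x)
  if (is.null(blacklist) || !nrow(blacklist)) {
    return(x)
  }
  check_intervals(blacklist, "blacklist")
  x[!overlaps_any(x, blacklist), , drop = FALSE]
}

#' Write intervals or peaks to a BED file
#'
#' Writes tab-separated BED (0-based half-open). Rows are sorted by
#' chromosome then start; when `chrom_order` is given (e.g. from
#' [read_chrom_sizes()]) chromosomes follow that order, otherwise they
#' sort lexicographically. For peak tables from [call_peaks()], the name
#' column is `peak_<i>` and the score is -log10 of the peak's minimum
#' adjusted p-value, capped at 3100 for narrowPeak-style compatibility.
#'
#' @param x A tibble of intervals; columns beyond `chrom`/`start`/`end`
#'   named `name` and `score` are written as BED columns 4-5.
#' @param path Output file path.
#' @param chrom_order Optional character vector (or tibble with a
#'   `chrom` column) giving the chromosome sort order.
#' @return Invisibly, the path.
#' @export
write_bed <- function(x, path, chrom_order = NULL) {
  check_intervals(x)
  if (is.data.frame(chrom_order)) chrom_order <- chrom_order$chrom
  if (!is.null(chrom_order)) {
    x <- x[order(match(x$chrom, chrom_order), x$start, x$end), , drop = FALSE]
  } else {
    x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  }
  cols <- list(x$chrom, format_bed_num(x$start), format_bed_num(x$end))
  if (!is.null(x[["name"]])) {
    cols <- c(cols, list(x$name))
    if (!is.null(x[["score"]])) cols <- c(cols, list(format_bed_num(x$score)))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

format_bed_num <- function(x) {
  ifelse(x == floor(x), sprintf("%d", as.integer(x)), sprintf("%.6g", x))
}

#' Export per-bin coverage as bedGraph
#'
#' @param counts A bin-count tibble from [count_fragments()].
#' @param path Output path.
#' @param value Name of the column to write as the bedGraph value
#'   (default `"count"`).
#' @return Invisibly, the path.
#' @export
write_bedgraph <- function(counts, path, value = "count") {
  check_intervals(counts, "counts")
  if (!value %in% names(counts)) {
    abort(sprintf("no column '%s' in counts", value))
  }
  lines <- paste(counts$chrom, format_bed_num(counts$start),
    format_bed_num(counts$end), format_bed_num(counts[[value]]),
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}
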