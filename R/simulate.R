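# Synthetic CUT&Tag-like fragment simulator. Fragment midpoints arise
# from a Poisson process: uniform background over the genome plus extra
# intensity inside ground-truth regions (uniform for broad domains,
# triangular peaked at the region center for narrow peaks, an equal
# superposition for mixed shapes). A matched control channel carries
# background plus a small leak of the enriched process, emulating faint
# IgG signal.

#' Configure a fragment simulation
#'
#' @param chrom_sizes Tibble (`chrom`, `size`) defining the genome.
#' @param truth Tibble of ground-truth regions: `chrom`, `start`, `end`,
#'   `shape` (one of `"narrow"`, `"broad"`, `"mixed"`), `fold`
#'   (enrichment over background, `>= 1`). `NULL` for background only.
#' @param background_rate Background density in fragments per kb
#'   (default 2, the sparse near-zero background typical of the assay).
#' @param frag_len_mean,frag_len_sd Fragment-length distribution
#'   (normal, bp; defaults 200 and 50).
#' @param frag_len_range Truncation bounds for fragment lengths
#'   (default `c(10, 700)`, the usual paired-end insert bounds).
#' @param depth Optional total expected fragment count; when given, all
#'   intensities are rescaled so the expected library size equals it.
#' @param control_depth Expected background fragment count of the
#'   control channel (default: half the sample's expected total).
#' @param control_leak Fraction of the sample's enriched (peak) process
#'   leaking into the control (default 0.02).
#' @return A `sim_config` object.
#' @export
sim_config <- function(chrom_sizes, truth = NULL, background_rate = 2,
                       frag_len_mean = 200, frag_len_sd = 50,
                       frag_len_range = c(10, 700), depth = NULL,
                       control_depth = NULL, control_leak = 0.02) {
  if (!is.data.frame(chrom_sizes) ||
    !all(c("chrom", "size") %in% names(chrom_sizes))) {
    abort("`chrom_sizes` must have columns `chrom` and `size`")
  }
  if (is.null(truth)) {
    truth <- tibble::tibble(
      chrom = character(), start = numeric(), end = numeric(),
      shape = character(), fold = numeric()
    )
  }
  if (nrow(truth)) {
    check_intervals(truth, "truth")
    if (is.null(truth[["shape"]]) || is.null(truth[["fold"]])) {
      abort("`truth` must have `shape` and `fold` columns")
    }
    if (!all(truth$shape %in% c("narrow", "broad", "mixed"))) {
      abort("truth shapes must be 'narrow', 'broad' or 'mixed'")
    }
    if (any(truth$fold < 1)) abort("truth folds must be >= 1")
    sizes <- chrom_sizes$size[match(truth$chrom, chrom_sizes$chrom)]
    if (any(is.na(sizes)) || any(truth$end > sizes)) {
      abort("truth regions must lie within the declared chromosomes")
    }
  }
  if (background_rate < 0) abort("`background_rate` must be >= 0")
  structure(
    list(
      chrom_sizes = chrom_sizes, truth = truth,
      background_rate = background_rate,
      frag_len_mean = frag_len_mean, frag_len_sd = frag_len_sd,
      frag_len_range = frag_len_range, depth = depth,
      control_depth = control_depth, control_leak = control_leak
    ),
    class = "sim_config"
  )
}

#' Simulate a CUT&Tag-like fragment library with ground truth
#'
#' Draws sample and control fragment sets from the Poisson-process model
#' described in [sim_config()]. Deterministic for a given seed; the
#' caller's RNG state is left untouched.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed (mandatory; reproducibility is part of the
#'   output contract).
#' @return A `sim_output` list: `sample` and `control` fragment tibbles,
#'   `truth` (the config's regions), `config`, `seed`.
#' @export
simulate_fragments <- function(config, seed) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory")
  with_local_seed(seed, {
    genome_kb <- sum(config$chrom_sizes$size) / 1000
    bg_expect <- config$background_rate * genome_kb
    extra_expect <- if (nrow(config$truth)) {
      (config$truth$fold - 1) * config$background_rate *
        (config$truth$end - config$truth$start) / 1000
    } else {
      numeric(0)
    }
    total_expect <- bg_expect + sum(extra_expect)
    if (!is.null(config$depth) && total_expect == 0) {
      # degenerate but useful case: no background process at all; spread
      # the requested depth over the regions in proportion to fold*width
      if (!nrow(config$truth)) {
        abort("depth requested but all intensities are zero")
      }
      w <- config$truth$fold * (config$truth$end - config$truth$start)
      extra_expect <- config$depth * w / sum(w)
      bg_expect <- 0
      total_expect <- config$depth
    }
    scale <- if (!is.null(config$depth)) config$depth / total_expect else 1
    sample <- draw_channel(config, bg_expect * scale, extra_expect * scale)
    ctrl_bg <- if (!is.null(config$control_depth)) {
      config$control_depth
    } else {
      (bg_expect + sum(extra_expect)) * scale / 2
    }
    control <- draw_channel(
      config, ctrl_bg, extra_expect * scale * config$control_leak
    )
    structure(
      list(
        sample = sample, control = control,
        truth = config$truth, config = config, seed = seed
      ),
      class = "sim_output"
    )
  })
}

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

draw_channel <- function(config, bg_expect, extra_expect) {
  sizes <- config$chrom_sizes
  mids <- list()
  chroms <- list()
  n_bg <- rpois(1, bg_expect)
  if (n_bg > 0) {
    ci <- sample.int(nrow(sizes), n_bg, replace = TRUE, prob = sizes$size)
    chroms[[1]] <- sizes$chrom[ci]
    mids[[1]] <- runif(n_bg, 0, sizes$size[ci])
  }
  if (length(extra_expect)) {
    for (i in seq_along(extra_expect)) {
      n_i <- rpois(1, extra_expect[i])
      if (n_i == 0) next
      reg <- config$truth[i, ]
      w <- reg$end - reg$start
      m <- switch(reg$shape,
        broad = runif(n_i, reg$start, reg$end),
        # mean of two uniforms: triangular density peaked at the center
        narrow = reg$start + w * (runif(n_i) + runif(n_i)) / 2,
        mixed = {
          tri <- runif(n_i) < 0.5
          ifelse(tri,
            reg$start + w * (runif(n_i) + runif(n_i)) / 2,
            runif(n_i, reg$start, reg$end)
          )
        }
      )
      chroms[[length(chroms) + 1]] <- rep(reg$chrom, n_i)
      mids[[length(mids) + 1]] <- m
    }
  }
  chrom <- unlist(chroms)
  mid <- unlist(mids)
  if (is.null(mid) || !length(mid)) {
    return(tibble::tibble(
      chrom = character(), start = integer(), end = integer()
    ))
  }
  len <- draw_lengths(length(mid), config)
  chrom_len <- sizes$size[match(chrom, sizes$chrom)]
  start <- round(mid - len / 2)
  start <- pmax(0, pmin(start, chrom_len - len))
  out <- tibble::tibble(
    chrom = chrom,
    start = as.integer(start),
    end = as.integer(start + len)
  )
  dplyr::arrange(out, .data$chrom, .data$start, .data$end)
}

draw_lengths <- function(n, config) {
  lo <- config$frag_len_range[1]
  hi <- config$frag_len_range[2]
  out <- numeric(0)
  while (length(out) < n) {
    cand <- round(rnorm(n - length(out), config$frag_len_mean,
      config$frag_len_sd
    ))
    out <- c(out, cand[cand >= lo & cand <= hi])
  }
  out[seq_len(n)]
}

#' Recovery metrics against ground-truth regions
#'
#' Recall is the fraction of truth regions of which a called peak set
#' covers at least `min_frac`; precision is the fraction of called
#' peaks with at least `min_frac` of their length inside truth. With
#' zero calls, precision is vacuously reported as 1 and flagged.
#'
#' @param called Peak tibble or `peak_call`.
#' @param truth Truth interval tibble.
#' @param min_frac Minimum covered fraction (default 0.5).
#' @return A one-row tibble: `recall`, `precision`, `n_called`,
#'   `n_truth`, `zero_calls`.
#' @export
truth_overlap_metrics <- function(called, truth, min_frac = 0.5) {
  if (inherits(called, "peak_call")) called <- called$peaks
  if (nrow(truth)) check_intervals(truth, "truth")
  if (nrow(called)) check_intervals(called, "called")
  recall <- if (nrow(truth)) {
    cov <- overlap_coverage(truth, called)
    mean(cov >= min_frac * (truth$end - truth$start))
  } else {
    NA_real_
  }
  if (!nrow(called)) {
    return(tibble::tibble(
      recall = recall, precision = 1, n_called = 0L,
      n_truth = nrow(truth), zero_calls = TRUE
    ))
  }
  cov <- overlap_coverage(called, truth)
  precision <- mean(cov >= min_frac * (called$end - called$start))
  tibble::tibble(
    recall = recall, precision = precision,
    n_called = nrow(called), n_truth = nrow(truth), zero_calls = FALSE
  )
}

#' Plot simulated coverage and called peaks
#'
#' Shows binned fragment coverage along one chromosome with truth
#' regions and (optionally) called peaks as shaded bands — a quick
#' visual check of a simulation scenario.
#'
#' @param sim A `sim_output`.
#' @param chrom Chromosome to plot (default: the first).
#' @param fit Optional `peak_call` to overlay.
#' @param step Bin width for the displayed coverage (default 200).
#' @return A ggplot object.
#' @export
plot_simulation <- function(sim, chrom = NULL, fit = NULL, step = 200) {
  if (!inherits(sim, "sim_output")) abort("`sim` must be a sim_output")
  sizes <- sim$config$chrom_sizes
  if (is.null(chrom)) chrom <- sizes$chrom[1]
  bins <- make_bins(sizes[sizes$chrom == chrom, ], step = step, slide = step)
  cov <- count_fragments(bins, sim$sample[sim$sample$chrom == chrom, ])
  p <- ggplot2::ggplot(cov, ggplot2::aes(x = .data$start, y = .data$count)) +
    ggplot2::geom_col(width = step, fill = "grey40") +
    ggplot2::labs(
      x = sprintf("%s position (bp)", chrom), y = "Fragments per bin"
    )
  truth <- sim$truth[sim$truth$chrom == chrom, , drop = FALSE]
  if (nrow(truth)) {
    p <- p + ggplot2::geom_rect(
      data = truth,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, fill = "steelblue", alpha = 0.2,
      inherit.aes = FALSE
    )
  }
  if (!is.null(fit)) {
    pk <- tidy(fit)
    pk <- pk[pk$chrom == chrom, , drop = FALSE]
    if (nrow(pk)) {
      p <- p + ggplot2::geom_segment(
        data = pk,
        ggplot2::aes(x = .data$start, xend = .data$end),
        y = -1, yend = -1, linewidth = 2, colour = "firebrick",
        inherit.aes = FALSE
      )
    }
  }
  p
}
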