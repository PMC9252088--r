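# Independent brute-force oracles. These deliberately avoid the code
# paths they check: tail sums use choose() directly, BH is a literal
# step-up, merging is graph connected components, overlap counting is a
# double loop.

brute_binom_tail <- function(x, n, p) {
  if (x == 0) {
    return(1)
  }
  k <- x:n
  sum(choose(n, k) * p^k * (1 - p)^(n - k))
}

brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  if (m > 1) {
    for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  }
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Connected-components merge: edge iff same chrom and gap <= max_gap.
brute_merge <- function(df, max_gap) {
  n <- nrow(df)
  comp <- seq_len(n)
  gap <- function(i, j) {
    max(df$start[j] - df$end[i], df$start[i] - df$end[j])
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && df$chrom[i] == df$chrom[j] &&
          gap(i, j) <= max_gap && comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(comp), function(cc) {
    rows <- df[comp == cc, ]
    data.frame(
      chrom = rows$chrom[1], start = min(rows$start), end = max(rows$end)
    )
  }))
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

brute_overlap_counts <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    sum(subject$chrom == query$chrom[i] &
      subject$start < query$end[i] &
      query$start[i] < subject$end)
  }, numeric(1))
}

iv <- function(chrom, start, end, ...) {
  tibble::tibble(chrom = chrom, start = start, end = end, ...)
}
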