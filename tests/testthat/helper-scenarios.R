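# Shared simulation scenarios: the narrow-peak recovery study (2 x 5 Mb
# genome, 20 narrow truth peaks, fold 16, background 2 fragments/kb,
# depth 1e5) and the broad-domain study (1 Mb genome, one 20-kb domain
# at fold 8, background 1 fragment/kb).

narrow_scenario <- function(fold = 16) {
  sizes <- tibble::tibble(
    chrom = c("chr1", "chr2"), size = c(5000000L, 5000000L)
  )
  widths <- rep(c(600, 700, 800, 900, 1000), 4)
  starts <- 300000 + (0:9) * 450000
  truth <- tibble::tibble(
    chrom = rep(sizes$chrom, each = 10),
    start = rep(starts, 2),
    end = rep(starts, 2) + widths,
    shape = "narrow",
    fold = fold
  )
  sim_config(sizes,
    truth = truth, background_rate = 2, depth = 1e5
  )
}

broad_scenario <- function() {
  sizes <- tibble::tibble(chrom = "chr1", size = 1000000L)
  truth <- tibble::tibble(
    chrom = "chr1", start = 400000, end = 420000,
    shape = "broad", fold = 8
  )
  sim_config(sizes, truth = truth, background_rate = 1)
}

# Tiny SAM files for BAM-path tests; converted with asBam at test time.
sam_header <- c(
  "@HD\tVN:1.6\tSO:coordinate",
  "@SQ\tSN:chr1\tLN:1000"
)

write_sam_as_bam <- function(records, env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  sam <- file.path(dir, "reads.sam")
  writeLines(c(sam_header, records), sam)
  Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE)
}
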