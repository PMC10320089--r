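# Shared in-code fixtures and independent oracles for the test suite.

# Minimal library builder: intervals on one contig, types given per record.
toy_library <- function(starts, ends, types, chrom = "chr1",
                        subset_flags = NULL, sequences = NULL) {
  rec <- tibble::tibble(
    chrom = chrom, start = as.integer(starts), end = as.integer(ends),
    nonb_type = types
  )
  if (!is.null(subset_flags)) rec$subset_flag <- subset_flags
  if (!is.null(sequences)) rec$sequence <- sequences
  nbburden::nonb_library(rec, genome_build = "toy")
}

toy_query <- function(starts, ends, name = "Q", chrom = "chr1",
                      level = "site") {
  tibble::tibble(name = name, level = level, chrom = chrom,
                 start = as.integer(starts), end = as.integer(ends))
}

# Brute-force overlap oracle: pairwise interval intersection with motif-id
# dedup.  Pure arithmetic, independent of the GenomicRanges machinery.
brute_count <- function(records, regions) {
  hit <- vapply(seq_len(nrow(records)), function(i) {
    any(regions$chrom == records$chrom[i] &
          regions$start < records$end[i] &
          records$start[i] < regions$end)
  }, logical(1))
  length(unique(records$motif_id[hit]))
}

# Boolean coverage-mask oracle for merged length on a toy contig.
bitmap_length <- function(starts, ends, contig_len = 10000) {
  mask <- logical(contig_len)
  for (i in seq_along(starts)) {
    mask[(starts[i] + 1):ends[i]] <- TRUE
  }
  sum(mask)
}

# Deterministic random query regions on chr1 of a toy contig.
random_regions <- function(n, contig_len, max_len = 200) {
  starts <- sample.int(contig_len - max_len, n) - 1L
  lens <- sample.int(max_len, n)
  tibble::tibble(chrom = "chr1", start = starts,
                 end = pmin(starts + lens, contig_len))
}
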