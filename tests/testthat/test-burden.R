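# Burden engine: overlap counting, merged length, normalization, matrices.

test_that("overlap counting follows the >= 1 bp half-open rule with dedup", {
  lib <- toy_library(starts = c(100, 100, 100),
                     ends = c(150, 300, 150),
                     types = c("G4", "MR", "STR"))
  # partial overlap counts
  q <- toy_query(140, 200)
  expect_equal(count_motif_overlaps(q, lib, "G4")$raw_count, 1L)
  # a motif spanning two regions of one unit counts once
  q2 <- toy_query(c(120, 250), c(130, 260))
  expect_equal(count_motif_overlaps(q2, lib, "MR")$raw_count, 1L)
  # half-open touch is not an overlap
  q3 <- toy_query(150, 200)
  expect_equal(count_motif_overlaps(q3, lib, "STR")$raw_count, 0L)
  # empty intersection is 0, not an error
  q4 <- toy_query(5000, 5100)
  expect_equal(sum(count_motif_overlaps(q4, lib)$raw_count), 0L)
})

test_that("count_motif_overlaps matches the brute-force oracle on random data", {
  set.seed(42)
  contig_len <- 10000
  starts <- sample.int(contig_len - 60, 1000, replace = TRUE) - 1L
  lens <- sample.int(60, 1000, replace = TRUE)
  types <- sample(nonb_types(), 1000, replace = TRUE)
  lib <- toy_library(starts, pmin(starts + lens, contig_len), types)
  regions <- random_regions(50, contig_len)
  q <- tibble::tibble(name = "R", level = "site", regions)
  got <- count_motif_overlaps(q, lib)
  for (t in nonb_types()) {
    rec <- lib$records[lib$records$nonb_type == t, ]
    expect_equal(got$raw_count[got$nonb_type == t], brute_count(rec, regions),
                 info = t)
  }
})

test_that("merged_length merges overlapping and book-ended regions", {
  expect_equal(merged_length(toy_query(c(100, 150), c(200, 300)))$merged_length_bp,
               200)
  expect_equal(merged_length(toy_query(c(0, 200), c(100, 300)))$merged_length_bp,
               200)
  expect_error(merged_length(toy_query(integer(), integer())), "empty")
})

test_that("merged_length equals the boolean coverage-mask oracle", {
  set.seed(7)
  for (rep in 1:5) {
    regions <- random_regions(50, 10000)
    q <- tibble::tibble(name = "R", level = "site", regions)
    expect_equal(merged_length(q)$merged_length_bp,
                 bitmap_length(regions$start, regions$end, 10000))
  }
})

test_that("burden_value implements all four normalization modes", {
  expect_identical(burden_value(5, 2000, 1e6, "cpkm"), 2.5)
  expect_identical(burden_value(5, merged_length_bp = 2000, mode = "per_kb"),
                   2.5)
  expect_identical(burden_value(5, library_size = 1e6, mode = "per_million"),
                   5)
  expect_identical(burden_value(5, mode = "raw"), 5)
  for (m in c("raw", "per_kb", "per_million", "cpkm")) {
    expect_equal(burden_value(0, 100, 100, m), 0)
  }
  expect_error(burden_value(1, 100, 0, "cpkm"), "library size")
  expect_error(burden_value(1, 100, 0, "per_million"), "library size")
})

test_that("cpkm agrees with direct formula evaluation on random triples", {
  set.seed(11)
  for (i in 1:200) {
    raw <- as.numeric(sample.int(1000, 1))
    len <- as.numeric(sample.int(1e6, 1))
    size <- as.numeric(sample.int(1e7, 1))
    expect_equal(burden_value(raw, len, size, "cpkm"),
                 raw * 1e3 * 1e6 / (size * len))
  }
})

test_that("empty-library types error under library-size normalization", {
  lib <- toy_library(100, 150, "G4")
  q <- toy_query(0, 1000)
  expect_error(nonb_burden(q, lib, types = c("G4", "Z"), mode = "cpkm"),
               "library size")
  expect_silent(nonb_burden(q, lib, types = c("G4", "Z"), mode = "raw"))
})

test_that("cpkm is invariant under library duplication", {
  set.seed(3)
  starts <- sample.int(900, 40) - 1L
  lib <- toy_library(starts, starts + 50, rep("G4", 40))
  q <- toy_query(c(100, 600), c(400, 800))
  b1 <- nonb_burden(q, lib, types = "G4", mode = "cpkm")
  dup <- lib$records
  dup$motif_id <- paste0(dup$motif_id, "_copy")
  lib2 <- nonb_library(rbind(lib$records, dup))
  b2 <- nonb_burden(q, lib2, types = "G4", mode = "cpkm")
  expect_equal(b2$raw_count, 2L * b1$raw_count)
  expect_equal(b2$library_size, 2L * b1$library_size)
  expect_equal(b2$burden, b1$burden)
})

test_that("doubling merged length at fixed raw count halves per_kb and cpkm", {
  raw <- 7
  for (m in c("per_kb", "cpkm")) {
    b1 <- burden_value(raw, 1000, 1e4, m)
    b2 <- burden_value(raw, 2000, 1e4, m)
    expect_equal(b2, b1 / 2)
  }
})

test_that("raw mode burden is exactly integer-valued", {
  set.seed(5)
  starts <- sample.int(5000, 100) - 1L
  lib <- toy_library(starts, starts + 20,
                     sample(nonb_types(), 100, replace = TRUE))
  q <- rbind(toy_query(c(0, 2000), c(1500, 3000), name = "a"),
             toy_query(3000, 5000, name = "b"))
  b <- nonb_burden(q, lib, mode = "raw")
  expect_true(all(b$burden == floor(b$burden)))
})

test_that("adding a region never decreases raw count or merged length", {
  set.seed(9)
  lib_starts <- sample.int(9000, 300) - 1L
  lib <- toy_library(lib_starts, lib_starts + 30,
                     sample(nonb_types(), 300, replace = TRUE))
  base_regions <- random_regions(5, 10000)
  for (i in 1:10) {
    extra <- random_regions(1, 10000)
    q0 <- tibble::tibble(name = "u", level = "site", base_regions)
    q1 <- tibble::tibble(name = "u", level = "site",
                         rbind(base_regions, extra))
    expect_true(all(count_motif_overlaps(q1, lib)$raw_count >=
                      count_motif_overlaps(q0, lib)$raw_count))
    expect_gte(merged_length(q1)$merged_length_bp,
               merged_length(q0)$merged_length_bp)
    base_regions <- rbind(base_regions, extra)
  }
})

test_that("burden matrix has units x types cells and types x units on disk", {
  set.seed(13)
  starts <- sample.int(900, 60) - 1L
  lib <- toy_library(starts, starts + 15,
                     sample(nonb_types()[1:6], 60, replace = TRUE))
  q <- purrr::list_rbind(lapply(1:3, function(i) {
    toy_query((i - 1) * 300, i * 300, name = paste0("u", i))
  }))
  bm <- burden_matrix(nonb_burden(q, lib, types = nonb_types()[1:6],
                                  mode = "raw"))
  expect_equal(dim(bm$values), c(3L, 6L))           # units x types in memory
  path <- withr::local_tempfile(fileext = ".tsv")
  write_burden_matrix(bm, path)
  body <- readLines(path)
  body <- body[!startsWith(body, "#")]
  expect_equal(length(body), 7L)                     # header + 6 type rows
  expect_equal(strsplit(body[1], "\t")[[1]], c("nonb_type", "u1", "u2", "u3"))
  back <- read_burden_matrix(path)
  expect_equal(back$values, bm$values)
  expect_equal(back$mode, "raw")
})

test_that("disjoint sub-units sum to at least the merged unit's count", {
  # spanning motif sits across the u1/u2 boundary and counts in both units
  lib <- toy_library(starts = c(50, 280, 500),
                     ends = c(80, 330, 540),
                     types = rep("G4", 3))
  parts <- rbind(toy_query(0, 300, name = "u1"),
                 toy_query(300, 600, name = "u2"))
  whole <- toy_query(0, 600, name = "all")
  per_part <- count_motif_overlaps(parts, lib, "G4")
  whole_n <- count_motif_overlaps(whole, lib, "G4")$raw_count
  expect_equal(sum(per_part$raw_count), 4L)  # spanning motif double-counted
  expect_equal(whole_n, 3L)
  expect_gte(sum(per_part$raw_count), whole_n)

  # without spanning motifs the counts add exactly
  lib2 <- toy_library(starts = c(50, 350, 500), ends = c(80, 380, 540),
                      types = rep("G4", 3))
  expect_equal(sum(count_motif_overlaps(parts, lib2, "G4")$raw_count),
               count_motif_overlaps(whole, lib2, "G4")$raw_count)
})

test_that("include_subsets adds flagged-only rows", {
  lib <- toy_library(
    starts = c(0, 100, 200, 300), ends = c(50, 150, 250, 350),
    types = c("MR", "MR", "IR", "G4"),
    subset_flags = c("Triplex-MR", NA, "Cruciform-IR", NA)
  )
  q <- toy_query(0, 400)
  b <- nonb_burden(q, lib, mode = "raw", include_subsets = TRUE)
  expect_setequal(unique(b$nonb_type), c(nonb_types(), nonb_subsets()))
  expect_equal(b$raw_count[b$nonb_type == "MR"], 2L)
  expect_equal(b$raw_count[b$nonb_type == "Triplex-MR"], 1L)
  expect_equal(b$raw_count[b$nonb_type == "Cruciform-IR"], 1L)
})

test_that("fully-contained-only counting is available as an option", {
  lib <- toy_library(starts = c(100, 190), ends = c(150, 260),
                     types = c("G4", "G4"))
  q <- toy_query(90, 200)
  expect_equal(count_motif_overlaps(q, lib, "G4")$raw_count, 2L)
  expect_equal(count_motif_overlaps(q, lib, "G4",
                                    contained_only = TRUE)$raw_count, 1L)
})
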