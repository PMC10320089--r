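# Motif screen: sequence features, k-means clustering, selection.

features_from_seqs <- function(seqs, types = "MR") {
  lens <- nchar(seqs)
  ends <- cumsum(lens + 10)
  toy_library(ends - lens, ends, rep_len(types, length(seqs)),
              sequences = seqs) |>
    motif_features()
}

test_that("length, %G and %A match direct counts on known sequences", {
  f <- features_from_seqs(c(
    "AAAGAGAGAGAGAGAGCAAGAGAGAGAGAGAGAAA",
    "TGTGTGTGCGCGTGTGCGTGTGTGT",
    "GGGG"
  ))
  expect_equal(f$length, c(35L, 25L, 4L))
  expect_equal(f$pct_g, c(40, 48, 100))
  expect_equal(f$pct_a[3], 0)
  # %A by direct count on the first sequence
  expect_equal(f$pct_a[1],
               100 * lengths(regmatches(
                 "AAAGAGAGAGAGAGAGCAAGAGAGAGAGAGAGAAA",
                 gregexpr("A", "AAAGAGAGAGAGAGAGCAAGAGAGAGAGAGAGAAA"))) / 35)
})

test_that("features are case-insensitive and count N in the denominator only", {
  f <- features_from_seqs(c("ggGgA", "GGNNN"))
  expect_equal(f$pct_g[1], 80)
  expect_equal(f$pct_g[2], 40)  # 2 G over length 5, N in denominator
  expect_equal(f$pct_a[2], 0)
})

test_that("sequences are fetched from a genome when records carry none", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AAAAGGGGCCCCTTTT"))
  lib <- toy_library(4, 8, "G4")
  f <- motif_features(lib, genome = genome)
  expect_equal(f$length, 4L)
  expect_equal(f$pct_g, 100)
  expect_error(motif_features(lib), "no genome")
})

test_that("gene labels attach the first overlapping query unit", {
  lib <- toy_library(c(100, 500, 900), c(150, 560, 950), rep("G4", 3),
                     sequences = c(strrep("G", 50), strrep("G", 60),
                                   strrep("G", 50)))
  q <- rbind(toy_query(0, 300, name = "GENE_A", level = "gene"),
             toy_query(400, 600, name = "GENE_B", level = "gene"))
  f <- motif_features(lib, query = q)
  expect_equal(f$gene_label, c("GENE_A", "GENE_B", NA))
})

test_that("pct_g is reverse-complement covariant", {
  set.seed(17)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
               collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    f <- features_from_seqs(c(s, rc))
    gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C"))
    expect_equal(f$pct_g[1] + f$pct_g[2], 100 * gc / 40)
  }
})

planted_blobs <- function(n_per = 20, seed = 19) {
  set.seed(seed)
  long_high <- tibble::tibble(
    motif_id = sprintf("hi%02d", 1:n_per), gene_label = NA_character_,
    nonb_type = "MR", subset_flag = NA_character_, chrom = "chr1",
    start = 0L, end = 0L,
    length = as.integer(round(rnorm(n_per, 30, 1))),
    pct_g = rnorm(n_per, 80, 1), pct_a = rnorm(n_per, 5, 1)
  )
  short_low <- tibble::tibble(
    motif_id = sprintf("lo%02d", 1:n_per), gene_label = NA_character_,
    nonb_type = "STR", subset_flag = NA_character_, chrom = "chr1",
    start = 0L, end = 0L,
    length = as.integer(round(rnorm(n_per, 12, 1))),
    pct_g = rnorm(n_per, 20, 1), pct_a = rnorm(n_per, 40, 1)
  )
  rbind(long_high, short_low)
}

test_that("k-means recovers two planted feature blobs exactly", {
  feats <- planted_blobs()
  cl <- cluster_motifs(feats, c("length", "pct_g"), k = 2, seed = 13)
  truth <- rep(1:2, each = 20)
  got <- cl$assignment$cluster
  agreement <- max(mean(got == truth), mean(got == 3 - truth))
  expect_equal(agreement, 1.0)
})

test_that("degenerate k values behave: k = 1 mean centroid, k = n zero WSS", {
  feats <- planted_blobs(n_per = 5)
  one <- cluster_motifs(feats, c("length", "pct_g"), k = 1, seed = 1)
  expect_true(all(one$assignment$cluster == 1L))
  expect_equal(unname(one$centers[1, "length"]), mean(feats$length))
  expect_equal(unname(one$centers[1, "pct_g"]), mean(feats$pct_g))

  sat <- cluster_motifs(feats, c("length", "pct_g"), k = 10, seed = 1)
  expect_equal(sort(sat$assignment$cluster), 1:10)
  expect_equal(sat$tot_withinss, 0)

  expect_error(cluster_motifs(feats, c("length", "pct_g"), k = 11), "exceeds")
})

test_that("identical seed gives bit-identical assignments; seeds restore RNG state", {
  feats <- planted_blobs()
  set.seed(999)
  before <- runif(1)
  a <- cluster_motifs(feats, c("length", "pct_g"), k = 3, seed = 7)
  b <- cluster_motifs(feats, c("length", "pct_g"), k = 3, seed = 7)
  expect_identical(a$assignment, b$assignment)
  expect_identical(a$centers, b$centers)
  set.seed(999)
  expect_identical(runif(1), before)
})

test_that("constant features are dropped with a warning under z-scoring", {
  feats <- planted_blobs(n_per = 6)
  feats$pct_a <- 50
  expect_warning(
    cl <- cluster_motifs(feats, c("length", "pct_a"), k = 2, seed = 1),
    "constant"
  )
  expect_equal(cl$feature_cols, "length")
  feats$length <- 10L
  expect_error(
    suppressWarnings(cluster_motifs(feats, c("length", "pct_a"), k = 2)),
    "constant"
  )
})

test_that("all-N motifs are excluded from clustering with a warning", {
  feats <- rbind(planted_blobs(n_per = 5),
                 features_from_seqs("NNNNN"))
  expect_warning(cl <- cluster_motifs(feats, c("length", "pct_g"), k = 2,
                                      seed = 2),
                 "excluded")
  expect_equal(nrow(cl$assignment), 10L)
})

test_that("elbow helper reports non-increasing WSS over the planted blobs", {
  feats <- planted_blobs()
  elbow <- kmeans_elbow(feats, c("length", "pct_g"), ks = c(1, 2, 4), seed = 5)
  expect_equal(nrow(elbow), 3L)
  expect_true(elbow$tot_withinss[2] <= elbow$tot_withinss[1])
  expect_true(elbow$tot_withinss[3] <= elbow$tot_withinss[2] + 1e-8)
})

test_that("select_motifs filters by predicates and by cluster label", {
  f <- features_from_seqs(c(
    "AAAGAGAGAGAGAGAGCAAGAGAGAGAGAGAGAAA",
    "TGTGTGTGCGCGTGTGCGTGTGTGT"
  ))
  kept <- select_motifs(f, pct_g >= 40, length >= 25)
  expect_equal(nrow(kept), 2L)
  expect_equal(nrow(select_motifs(f, pct_g > 100)), 0L)

  feats <- planted_blobs()
  cl <- cluster_motifs(feats, c("length", "pct_g"), k = 2, seed = 13)
  for (ci in 1:2) {
    by_select <- select_motifs(feats, cluster == ci, clusters = cl)
    expect_setequal(by_select$motif_id,
                    cl$assignment$motif_id[cl$assignment$cluster == ci])
  }
})

test_that("motif cluster plot and tidiers work", {
  feats <- planted_blobs()
  cl <- cluster_motifs(feats, c("length", "pct_g"), k = 2, seed = 13)
  expect_s3_class(ggplot2::autoplot(cl), "ggplot")
  td <- generics::tidy(cl)
  expect_true(all(c("motif_id", "cluster", "length", "pct_g") %in% names(td)))
  gl <- generics::glance(cl)
  expect_equal(gl$k, 2L)
})
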