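# Motif screen: per-motif sequence features (length, %G, %A), k-means
# clustering of motifs in feature space, and feature/cluster-based selection
# of high-quality candidates.

#' Load a reference genome
#'
#' Accepts a FASTA path or an existing [Biostrings::DNAStringSet];
#' sequence names are trimmed at the first whitespace.
#'
#' @param genome FASTA path or `DNAStringSet`.
#' @return A `DNAStringSet`.
#' @export
load_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) return(genome)
  if (!file.exists(genome)) abort(sprintf("no such file: %s", genome))
  g <- readDNAStringSet(genome)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

fetch_sequences <- function(records, genome) {
  g <- load_genome(genome)
  missing <- setdiff(unique(records$chrom), names(g))
  if (length(missing) > 0) {
    abort(paste0("contig(s) absent from genome: ",
                 paste(missing, collapse = ", ")))
  }
  vapply(seq_len(nrow(records)), function(i) {
    as.character(subseq(g[[records$chrom[i]]],
                        start = records$start[i] + 1L,
                        end = records$end[i]))
  }, character(1))
}

#' Per-motif sequence features for the motif screen
#'
#' Computes, for every motif record, its length (nt), guanine content
#' (`pct_g`, percent of bases that are G, case-insensitive, N counted in
#' the denominator only) and adenine content (`pct_a`), plus a
#' `gene_label`: the name of the first query unit the motif overlaps
#' (`NA` when no query is supplied or nothing overlaps).  Length and %G are
#' the two major features for judging non-B forming quality; all-N motifs
#' carry `NA` percentages and are dropped from clustering with a warning.
#'
#' @param library A [nonb_library()]; records must carry sequences or a
#'   `genome` must be supplied to fetch them.
#' @param genome Optional FASTA path / `DNAStringSet`.
#' @param query Optional query tibble used to attach `gene_label`s.
#' @param types Restrict to these type codes (subset codes allowed).
#' @return A tibble `motif_id`, `gene_label`, `nonb_type`, `subset_flag`,
#'   `chrom`, `start`, `end`, `length`, `pct_g`, `pct_a`.
#' @export
#' @examples
#' lib <- nonb_library(tibble::tibble(
#'   chrom = "chr1", start = 0L, end = 4L, nonb_type = "G4",
#'   sequence = "GGAG"
#' ))
#' motif_features(lib)
motif_features <- function(library, genome = NULL, query = NULL,
                           types = NULL) {
  stopifnot(inherits(library, "nonb_library"))
  rec <- library$records
  if (!is.null(types)) {
    keep <- rec$nonb_type %in% types |
      (!is.na(rec$subset_flag) & rec$subset_flag %in% types)
    rec <- rec[keep, ]
  }
  if (nrow(rec) == 0) {
    return(tibble(motif_id = character(), gene_label = character(),
                  nonb_type = character(), subset_flag = character(),
                  chrom = character(), start = integer(), end = integer(),
                  length = integer(), pct_g = double(), pct_a = double()))
  }
  seqs <- rec$sequence
  need <- is.na(seqs)
  if (any(need)) {
    if (is.null(genome)) {
      abort(paste0("motif(s) without stored sequence and no genome supplied: ",
                   paste(head(rec$motif_id[need], 5), collapse = ", ")))
    }
    seqs[need] <- fetch_sequences(rec[need, ], genome)
  }
  seqs <- str_to_upper(seqs)
  dna <- DNAStringSet(seqs)
  counts <- letterFrequency(dna, letters = c("A", "C", "G", "T", "N"))
  len <- rec$end - rec$start
  informative <- rowSums(counts[, c("A", "C", "G", "T"), drop = FALSE])
  all_n <- informative == 0
  gene_label <- rep(NA_character_, nrow(rec))
  if (!is.null(query)) {
    query <- validate_query(query)
    units <- query_unit_names(query)
    qgr <- as_granges(query)
    hits <- findOverlaps(as_granges(rec), qgr, ignore.strand = TRUE)
    if (length(hits) > 0) {
      h <- tibble(
        motif = S4Vectors::queryHits(hits),
        unit = match(query$name[S4Vectors::subjectHits(hits)], units)
      ) |>
        group_by(.data$motif) |>
        summarise(unit = min(.data$unit), .groups = "drop")
      gene_label[h$motif] <- units[h$unit]
    }
  }
  tibble(
    motif_id = rec$motif_id,
    gene_label = gene_label,
    nonb_type = rec$nonb_type,
    subset_flag = rec$subset_flag,
    chrom = rec$chrom,
    start = rec$start,
    end = rec$end,
    length = as.integer(len),
    pct_g = ifelse(all_n, NA_real_, 100 * counts[, "G"] / len),
    pct_a = ifelse(all_n, NA_real_, 100 * counts[, "A"] / len)
  )
}

# k-means++ seeding: first center uniform, then each next center drawn with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums((X - matrix(X[centers[1], ], n, ncol(X), byrow = TRUE))^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        centers[j] <- sample.int(n, 1)
      } else {
        centers[j] <- sample.int(n, 1, prob = d2)
      }
      dj <- rowSums((X - matrix(X[centers[j], ], n, ncol(X), byrow = TRUE))^2)
      d2 <- pmin(d2, dj)
    }
  }
  X[centers, , drop = FALSE]
}

#' K-means clustering of motif sequence features
#'
#' Partitions motifs in the space of selected sequence features
#' (`length`, `pct_g`, `pct_a`) with k-means, seeded by k-means++ from a
#' fixed seed so identical inputs give identical assignments.  Features are
#' z-scored by default: length is in nucleotides and the compositions in
#' percent, so unscaled Euclidean distance would be dominated by length.
#' A feature that is constant across motifs cannot be z-scored and is
#' dropped with a warning (error if none remain).
#'
#' @param features Output of [motif_features()].
#' @param feature_cols Subset of `c("length", "pct_g", "pct_a")` to cluster
#'   on (default length + %G, the two major quality factors).
#' @param k Number of clusters (default 4).
#' @param seed Integer RNG seed for the k-means++ initialization.
#' @param standardize Z-score features before clustering (default `TRUE`).
#' @param iter_max Lloyd iteration cap.
#' @return A `motif_clusters` object: `assignment` (tibble `motif_id`,
#'   `cluster` in `1..k`), `centers` (k x features, original feature
#'   units), `k`, `seed`, `tot_withinss`.
#' @export
cluster_motifs <- function(features, feature_cols = c("length", "pct_g"),
                           k = 4, seed = 1, standardize = TRUE,
                           iter_max = 100) {
  stopifnot(length(feature_cols) >= 1)
  bad <- setdiff(feature_cols, c("length", "pct_g", "pct_a"))
  if (length(bad) > 0) {
    abort(paste0("unknown feature(s): ", paste(bad, collapse = ", ")))
  }
  rows <- features
  drop_na <- !stats::complete.cases(rows[, feature_cols, drop = FALSE])
  if (any(drop_na)) {
    warn(sprintf("%d motif(s) with undefined features (e.g. all-N) excluded",
                 sum(drop_na)))
    rows <- rows[!drop_na, ]
  }
  n <- nrow(rows)
  if (k < 1) abort("k must be >= 1")
  if (k > n) abort(sprintf("k = %d exceeds the %d clusterable motifs", k, n))
  X <- as.matrix(rows[, feature_cols, drop = FALSE])
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  if (standardize) {
    const <- sdev == 0 | is.na(sdev)
    if (all(const)) abort("all selected features are constant; nothing to cluster")
    if (any(const)) {
      warn(paste0("constant feature(s) dropped before z-scoring: ",
                  paste(feature_cols[const], collapse = ", ")))
      feature_cols <- feature_cols[!const]
      X <- X[, !const, drop = FALSE]
      mu <- mu[!const]
      sdev <- sdev[!const]
    }
    Z <- scale(X)
  } else {
    Z <- X
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  init <- kmeanspp_centers(Z, k)
  fit <- if (k == n) {
    # saturation: every point its own cluster, WSS exactly 0
    list(cluster = seq_len(n), centers = Z, tot.withinss = 0)
  } else {
    tryCatch(
      suppressWarnings(
        kmeans(Z, centers = init, iter.max = iter_max, algorithm = "Lloyd")
      ),
      # Lloyd errors on an empty cluster (duplicated points); retry on a
      # deterministically perturbed copy with MacQueen updates.
      error = function(e) NULL
    ) %||% suppressWarnings(
      kmeans(jitter_ties(Z, seed), centers = init, iter.max = iter_max,
             algorithm = "MacQueen")
    )
  }
  centers_z <- fit$centers
  centers <- if (standardize) {
    sweep(sweep(centers_z, 2, sdev, "*"), 2, mu, "+")
  } else {
    centers_z
  }
  colnames(centers) <- feature_cols
  structure(
    list(
      assignment = tibble(motif_id = rows$motif_id,
                          cluster = as.integer(fit$cluster)),
      centers = centers,
      k = as.integer(k),
      seed = as.integer(seed),
      feature_cols = feature_cols,
      standardize = standardize,
      tot_withinss = fit$tot.withinss,
      features = rows
    ),
    class = "motif_clusters"
  )
}

# Deterministic tiny perturbation used only when Lloyd lands on an empty
# cluster (duplicated points); keeps reruns reproducible.
jitter_ties <- function(Z, seed) {
  set.seed(seed + 1L)
  Z + matrix(runif(length(Z), -1e-9, 1e-9), nrow(Z))
}

#' @export
print.motif_clusters <- function(x, ...) {
  cat(sprintf("<motif_clusters> %d motifs in k = %d clusters (seed %d)\n",
              nrow(x$assignment), x$k, x$seed))
  print(round(x$centers, 2))
  invisible(x)
}

#' @rdname cluster_motifs
#' @param x A `motif_clusters`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.motif_clusters <- function(x, ...) {
  x$features |>
    left_join(x$assignment, by = "motif_id")
}

#' @rdname cluster_motifs
#' @export
#' @exportS3Method generics::glance
glance.motif_clusters <- function(x, ...) {
  tibble(k = x$k, n_motifs = nrow(x$assignment), seed = x$seed,
         tot_withinss = x$tot_withinss,
         features = paste(x$feature_cols, collapse = "+"))
}

#' Elbow curve for choosing k
#'
#' Total within-cluster sum of squares as a function of k, for the same
#' features/seed/standardization as [cluster_motifs()].  No automatic k is
#' chosen; inspect the curve.
#'
#' @inheritParams cluster_motifs
#' @param ks Candidate k values.
#' @return A tibble `k`, `tot_withinss`.
#' @export
kmeans_elbow <- function(features, feature_cols = c("length", "pct_g"),
                         ks = 1:8, seed = 1, standardize = TRUE) {
  tibble(
    k = as.integer(ks),
    tot_withinss = map_dbl(ks, function(k) {
      cluster_motifs(features, feature_cols, k = k, seed = seed,
                     standardize = standardize)$tot_withinss
    })
  )
}

#' Select motifs by feature predicate or cluster membership
#'
#' Filters a motif feature table (optionally joined with a clustering) by
#' arbitrary predicates over the computed features and `cluster` label —
#' e.g. high %G and decent length to pick strong non-B forming candidates.
#' Row order is preserved; an unsatisfiable predicate yields an empty
#' table, not an error.
#'
#' @param features Output of [motif_features()].
#' @param ... Filter predicates (as in [dplyr::filter()]), referring to
#'   `length`, `pct_g`, `pct_a`, `nonb_type`, `gene_label`, `cluster`.
#' @param clusters Optional [cluster_motifs()] result; joins its `cluster`
#'   column before filtering.
#' @return The filtered feature tibble.
#' @export
#' @examples
#' feats <- tibble::tibble(motif_id = c("a", "b"), gene_label = NA,
#'                         nonb_type = "MR", length = c(35L, 12L),
#'                         pct_g = c(40, 10), pct_a = c(40, 50))
#' select_motifs(feats, pct_g >= 40, length >= 25)
select_motifs <- function(features, ..., clusters = NULL) {
  tbl <- features
  if (!is.null(clusters)) {
    stopifnot(inherits(clusters, "motif_clusters"))
    tbl <- tbl |> left_join(clusters$assignment, by = "motif_id")
  }
  tbl |> filter(...)
}

#' Scatter plot of clustered motif features
#'
#' 2D view of the first two clustering features, coloured by cluster and
#' labelled either by gene (`label = "gene"`, gene-informed) or by non-B
#' type (`label = "type"`, non-B informed).
#'
#' @param object A [cluster_motifs()] result.
#' @param label `"gene"` or `"type"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.motif_clusters <- function(object, label = c("type", "gene"), ...) {
  label <- match.arg(label)
  tbl <- tidy(object)
  fx <- object$feature_cols[1]
  fy <- if (length(object$feature_cols) >= 2) object$feature_cols[2] else fx
  lab <- if (label == "gene") "gene_label" else "nonb_type"
  ggplot(tbl, aes(x = .data[[fx]], y = .data[[fy]],
                  colour = factor(.data$cluster), shape = .data[[lab]])) +
    geom_point(size = 2) +
    labs(colour = "cluster", shape = if (label == "gene") "gene" else "non-B type",
         title = "Motif feature clustering") +
    theme_minimal()
}
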