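# Synthetic fixtures with exact ground truth: toy genomes, planted motif
# libraries, grouped site batches, and a bundled "case3-mini" preset.
# Every generator is a pure function of (seed, parameters): reruns are
# byte-identical.

with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a deterministic toy genome
#'
#' Uniform-random A/C/G/T contigs, a pure function of the seed.
#'
#' @param n_contigs Number of contigs (named `chr1`, `chr2`, ...).
#' @param contig_len Length of each contig in bp (>= 100).
#' @param seed Integer RNG seed.
#' @param path Optional FASTA path to also write the genome to.
#' @return A `DNAStringSet` (invisibly also written to `path` if given).
#' @export
make_toy_genome <- function(n_contigs = 1, contig_len = 10000, seed = 1,
                            path = NULL) {
  if (contig_len < 100) abort("contig_len must be >= 100")
  contig_len <- rep_len(contig_len, n_contigs)
  g <- with_seed(seed, {
    seqs <- vapply(seq_len(n_contigs), function(i) {
      paste(sample(c("A", "C", "G", "T"), contig_len[i], replace = TRUE),
            collapse = "")
    }, character(1))
    DNAStringSet(setNames(seqs, paste0("chr", seq_len(n_contigs))))
  })
  if (!is.null(path)) writeXStringSet(g, path, width = 80L)
  g
}

# Sample a nucleotide sequence of given length with an exact number of G's
# (target %G rounded to the nearest base); non-G positions are A/C/T.
planted_sequence <- function(len, pct_g) {
  n_g <- round(len * pct_g / 100)
  n_g <- max(0L, min(len, n_g))
  bases <- c(rep("G", n_g),
             sample(c("A", "C", "T"), len - n_g, replace = TRUE))
  paste(sample(bases), collapse = "")
}

#' Plant non-B motifs into a toy genome with exact ground truth
#'
#' Places non-overlapping motif records of requested types into a genome,
#' writing each motif's sequence (hitting its target %G to within one base)
#' into the genome itself, and returns both the resulting motif library and
#' a truth table from which the expected raw overlap count of any later
#' query can be computed exactly ([expected_counts()]).
#'
#' @param genome A `DNAStringSet` (e.g. [make_toy_genome()]).
#' @param plan A data frame with one row per type to plant: columns
#'   `nonb_type`, `n` (count), `min_len`, `max_len` (nt), `pct_g` (target
#'   percent), and optionally `subset_frac` (fraction of MR rows flagged
#'   `Triplex-MR` / IR rows flagged `Cruciform-IR`).
#' @param seed Integer RNG seed.
#' @param allow_overlap Permit planted motifs to overlap one another
#'   (stress testing); ground-truth counts remain exact but coverage-based
#'   reasoning no longer holds.
#' @param max_tries Placement attempts per motif before declaring the
#'   packing infeasible.
#' @return A list: `genome` (modified `DNAStringSet`), `library`
#'   ([nonb_library()] with sequences), `truth` (tibble `motif_id`,
#'   `chrom`, `start`, `end`, `nonb_type`, `subset_flag`).
#' @export
plant_motifs <- function(genome, plan, seed = 1, allow_overlap = FALSE,
                         max_tries = 200) {
  plan <- as_tibble(plan)
  stopifnot(all(c("nonb_type", "n", "min_len", "max_len", "pct_g") %in%
                  names(plan)))
  if (!"subset_frac" %in% names(plan)) plan$subset_frac <- 0
  bad <- setdiff(plan$nonb_type, nonb_types())
  if (length(bad) > 0) {
    abort(paste0("plan contains unknown type(s): ", paste(bad, collapse = ", ")))
  }
  contigs <- names(genome)
  clens <- setNames(Biostrings::width(genome), contigs)
  with_seed(seed, {
    occupied <- lapply(setNames(contigs, contigs),
                       function(.) IRanges())
    rows <- list()
    seq_strings <- as.character(genome)
    for (p in seq_len(nrow(plan))) {
      n <- plan$n[p]
      if (n == 0) next
      n_flag <- round(plan$subset_frac[p] * n)
      flag_code <- switch(plan$nonb_type[p], MR = "Triplex-MR",
                          IR = "Cruciform-IR", NA_character_)
      len_choices <- plan$min_len[p]:plan$max_len[p]
      for (i in seq_len(n)) {
        len <- len_choices[sample.int(length(len_choices), 1)]
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          chrom <- sample(contigs, 1)
          if (clens[[chrom]] < len) next
          s0 <- sample.int(clens[[chrom]] - len + 1L, 1) - 1L
          cand <- IRanges(start = s0 + 1L, end = s0 + len)
          if (!allow_overlap &&
              sum(countOverlaps(cand, occupied[[chrom]])) > 0) next
          occupied[[chrom]] <- c(occupied[[chrom]], cand)
          seq <- planted_sequence(len, plan$pct_g[p])
          substr(seq_strings[[chrom]], s0 + 1L, s0 + len) <- seq
          rows[[length(rows) + 1]] <- tibble(
            chrom = chrom, start = s0, end = s0 + len,
            nonb_type = plan$nonb_type[p],
            subset_flag = if (i <= n_flag && !is.na(flag_code)) {
              flag_code
            } else NA_character_,
            sequence = seq
          )
          placed <- TRUE
          break
        }
        if (!placed) {
          abort(paste0(
            "infeasible packing: could not place a ", plan$nonb_type[p],
            " motif of ", len, " bp after ", max_tries,
            " tries; use longer contigs or fewer/shorter motifs"
          ))
        }
      }
    }
    rec <- list_rbind(rows)
    rec$motif_id <- sprintf("%s_%04d", tolower(rec$nonb_type), seq_len(nrow(rec)))
    new_genome <- DNAStringSet(setNames(seq_strings, contigs))
    lib <- nonb_library(rec, genome_build = "toy")
    list(
      genome = new_genome,
      library = lib,
      truth = lib$records[, c("motif_id", "chrom", "start", "end",
                              "nonb_type", "subset_flag")]
    )
  })
}

#' Expected raw overlap counts from a truth table
#'
#' Brute-force O(motifs x regions) oracle: for each query unit and type,
#' counts distinct truth motifs with >= 1 bp overlap with any of the unit's
#' regions, using nothing but pairwise interval arithmetic.  Independent of
#' the interval-tree machinery of the burden engine, so the two routes
#' cross-check each other.
#'
#' @param truth Truth table from [plant_motifs()] (or any tibble with
#'   `motif_id`, `chrom`, `start`, `end`, `nonb_type`, `subset_flag`).
#' @param query A query tibble.
#' @param types Type codes to count (subset codes use the flag column).
#' @return A tibble `name`, `nonb_type`, `expected_count`.
#' @export
expected_counts <- function(truth, query, types = nonb_types()) {
  query <- validate_query(query)
  units <- query_unit_names(query)
  grid <- expand.grid(name = units, nonb_type = types,
                      stringsAsFactors = FALSE)
  grid$expected_count <- vapply(seq_len(nrow(grid)), function(g) {
    u <- grid$name[g]
    t <- grid$nonb_type[g]
    mot <- if (t %in% nonb_subsets()) {
      truth[!is.na(truth$subset_flag) & truth$subset_flag == t, ]
    } else {
      truth[truth$nonb_type == t, ]
    }
    regs <- query[query$name == u, ]
    hit <- vapply(seq_len(nrow(mot)), function(i) {
      any(regs$chrom == mot$chrom[i] &
            regs$start < mot$end[i] &
            mot$start[i] < regs$end)
    }, logical(1))
    length(unique(mot$motif_id[hit]))
  }, integer(1))
  as_tibble(grid)
}

#' Generate a grouped site batch
#'
#' Random site-level regions assigned to `n_groups` named groups (samples),
#' emulating per-sample mutation-site input for burden-in-batch runs.
#'
#' @param contig_lens Named integer vector of contig lengths the sites must
#'   fall in (e.g. `c(chr1 = 10000)`).
#' @param n_groups Number of groups (>= 1), labelled `s001`, `s002`, ...
#' @param sites_per_group Regions per group.
#' @param site_len Length of each site in bp.
#' @param seed Integer RNG seed.
#' @return A query tibble (`level = "site"`, units in group order).
#' @export
make_site_batch <- function(contig_lens, n_groups, sites_per_group = 10,
                            site_len = 20, seed = 1) {
  if (n_groups < 1) abort("n_groups must be >= 1")
  contigs <- names(contig_lens)
  with_seed(seed, {
    rows <- lapply(seq_len(n_groups), function(gi) {
      chrom <- sample(contigs, sites_per_group, replace = TRUE)
      s0 <- vapply(chrom, function(ch) {
        sample.int(contig_lens[[ch]] - site_len, 1) - 1L
      }, integer(1))
      tibble(
        name = sprintf("s%03d", gi), level = "site",
        chrom = chrom, start = as.integer(s0),
        end = as.integer(s0 + site_len)
      )
    })
    list_rbind(rows)
  })
}

#' Write a complete fixture preset to a directory
#'
#' Emits a self-consistent set of inputs (genome.fa, motifs.bed, motifs.tsv,
#' genes.bed, signatures.gmt, sites.bed, truth.tsv) generated from one
#' seed.  The `"case3-mini"` preset emulates the shape of a burden-in-batch
#' study — 104 sample groups of mutation sites over a 2-contig toy genome
#' with all 7 motif types planted (MR/IR subsets flagged) — at desk scale.
#' `"tiny"` is a minimal 1-contig variant for quick runs.
#'
#' @param dir Output directory (created if needed).
#' @param preset `"case3-mini"` or `"tiny"`.
#' @param seed Integer RNG seed.
#' @return Invisibly, a list with the in-memory objects (`genome`,
#'   `library`, `truth`, `annotation`, `sites`) and `paths` of the files
#'   written.
#' @export
write_fixture_preset <- function(dir, preset = c("case3-mini", "tiny"),
                                 seed = 1) {
  preset <- match.arg(preset)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- switch(preset,
    "case3-mini" = list(n_contigs = 2, contig_len = 60000, n_groups = 104,
                        sites_per_group = 10,
                        plan = tibble(
                          nonb_type = nonb_types(),
                          n = c(6, 60, 60, 120, 90, 80, 100),
                          min_len = c(12, 15, 10, 14, 12, 12, 8),
                          max_len = c(30, 40, 30, 40, 40, 40, 30),
                          pct_g = c(10, 80, 45, 30, 35, 30, 25),
                          subset_frac = c(0, 0, 0, 0.3, 0.3, 0, 0)
                        )),
    "tiny" = list(n_contigs = 1, contig_len = 10000, n_groups = 3,
                  sites_per_group = 4,
                  plan = tibble(
                    nonb_type = nonb_types(),
                    n = c(1, 4, 2, 3, 5, 2, 4),
                    min_len = c(12, 15, 10, 14, 12, 12, 8),
                    max_len = c(25, 30, 25, 30, 30, 30, 20),
                    pct_g = c(10, 80, 45, 30, 35, 30, 25),
                    subset_frac = c(0, 0, 0, 0.4, 0.4, 0, 0)
                  ))
  )
  genome0 <- make_toy_genome(cfg$n_contigs, cfg$contig_len, seed = seed)
  planted <- plant_motifs(genome0, cfg$plan, seed = seed + 1L)
  clens <- setNames(Biostrings::width(planted$genome), names(planted$genome))
  sites <- make_site_batch(clens, cfg$n_groups, cfg$sites_per_group,
                           seed = seed + 2L)
  # simple tiling gene annotation: consecutive windows named GENE001...
  n_genes <- 12
  gene_len <- floor(cfg$contig_len / n_genes)
  ann <- tibble(
    symbol = sprintf("GENE%03d", seq_len(n_genes)),
    chrom = names(clens)[1],
    start = as.integer((seq_len(n_genes) - 1) * gene_len),
    end = as.integer(seq_len(n_genes) * gene_len)
  )
  sig <- tibble(
    signature = c("SIG_EVEN", "SIG_ODD"),
    description = c("even-indexed toy genes", "odd-indexed toy genes"),
    symbols = list(ann$symbol[seq(2, n_genes, 2)],
                   ann$symbol[seq(1, n_genes, 2)])
  )
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    motifs_bed = file.path(dir, "motifs.bed"),
    motifs_tsv = file.path(dir, "motifs.tsv"),
    genes = file.path(dir, "genes.bed"),
    signatures = file.path(dir, "signatures.gmt"),
    sites = file.path(dir, "sites.bed"),
    truth = file.path(dir, "truth.tsv")
  )
  writeXStringSet(planted$genome, paths$genome, width = 80L)
  write_motif_library(planted$library, paths$motifs_bed, dialect = "bed6+type")
  write_motif_library(planted$library, paths$motifs_tsv, dialect = "nonbdb-tsv")
  writeLines(sprintf("%s\t%d\t%d\t%s", ann$chrom, ann$start, ann$end,
                     ann$symbol), paths$genes)
  writeLines(vapply(seq_len(nrow(sig)), function(i) {
    paste(c(sig$signature[i], sig$description[i], sig$symbols[[i]]),
          collapse = "\t")
  }, character(1)), paths$signatures)
  writeLines(sprintf("%s\t%d\t%d\t%s", sites$chrom, sites$start, sites$end,
                     sites$name), paths$sites)
  write_tsv(planted$truth, paths$truth)
  invisible(list(genome = planted$genome, library = planted$library,
                 truth = planted$truth, annotation = ann, sites = sites,
                 signatures = sig, paths = paths))
}
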