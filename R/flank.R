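# Flank extraction: motif sequences padded with fixed-length flanks sliced
# from a reference genome, for downstream wet-lab use.

#' Extract motifs with flanking sequence from a reference genome
#'
#' For each selected motif, slices `flank_len` nucleotides of genomic
#' context on both sides of the motif.  Flanks are clipped at contig
#' boundaries (the `clipped` flag records when a flank came back shorter
#' than requested); output is uppercase and the concatenation
#' `left_flank + motif_seq + right_flank` always equals the direct genome
#' substring of the padded interval.  Flanks are taken from the plus strand
#' regardless of motif strand unless `orient_by_strand` is set, in which
#' case minus-strand motifs are reverse-complemented after slicing.
#'
#' @param library A [nonb_library()].
#' @param genome FASTA path or `DNAStringSet` containing every motif contig.
#' @param flank_len Requested flank length (nt, >= 0).
#' @param ids Optional motif ids to restrict to (default: all records).
#' @param orient_by_strand Reverse-complement minus-strand motifs+flanks.
#' @return A tibble `motif_id`, `chrom`, `start`, `end`, `nonb_type`,
#'   `left_flank`, `motif_seq`, `right_flank`, `flank_len_requested`,
#'   `clipped`.
#' @export
extract_flanked <- function(library, genome, flank_len, ids = NULL,
                            orient_by_strand = FALSE) {
  stopifnot(inherits(library, "nonb_library"))
  if (flank_len < 0) abort("flank_len must be >= 0")
  rec <- library$records
  if (!is.null(ids)) {
    missing <- setdiff(ids, rec$motif_id)
    if (length(missing) > 0) {
      abort(paste0("unknown motif id(s): ", paste(missing, collapse = ", ")))
    }
    rec <- rec[match(ids, rec$motif_id), ]
  }
  g <- load_genome(genome)
  missing_chrom <- setdiff(unique(rec$chrom), names(g))
  if (length(missing_chrom) > 0) {
    abort(paste0("contig(s) absent from genome: ",
                 paste(missing_chrom, collapse = ", ")))
  }
  rows <- lapply(seq_len(nrow(rec)), function(i) {
    contig <- g[[rec$chrom[i]]]
    clen <- length(contig)
    s0 <- rec$start[i]            # 0-based half-open motif coordinates
    e0 <- rec$end[i]
    if (e0 > clen) {
      abort(sprintf("motif %s extends past the end of contig %s",
                    rec$motif_id[i], rec$chrom[i]))
    }
    ls <- max(0L, s0 - flank_len)
    re <- min(clen, e0 + flank_len)
    left <- if (s0 > ls) as.character(subseq(contig, ls + 1L, s0)) else ""
    mot <- as.character(subseq(contig, s0 + 1L, e0))
    right <- if (re > e0) as.character(subseq(contig, e0 + 1L, re)) else ""
    if (orient_by_strand && identical(rec$strand[i], "-")) {
      rc <- function(s) {
        if (nchar(s) == 0) "" else as.character(reverseComplement(DNAStringSet(s)))
      }
      tmp <- rc(left)
      left <- rc(right)
      right <- tmp
      mot <- rc(mot)
    }
    tibble(
      motif_id = rec$motif_id[i],
      chrom = rec$chrom[i],
      start = s0, end = e0,
      nonb_type = rec$nonb_type[i],
      left_flank = toupper(left),
      motif_seq = toupper(mot),
      right_flank = toupper(right),
      flank_len_requested = as.integer(flank_len),
      clipped = nchar(left) < flank_len || nchar(right) < flank_len
    )
  })
  list_rbind(rows)
}

#' Format flanked sequences for display
#'
#' Joins left flank, motif and right flank with a visible separator
#' (an em dash, "\u2014", by default), the display convention for flanked motif
#' output.
#'
#' @param flanked Output of [extract_flanked()].
#' @param sep Separator string.
#' @return Character vector, one formatted string per motif.
#' @export
format_flanked <- function(flanked, sep = "\u2014") {
  paste0(flanked$left_flank, sep, flanked$motif_seq, sep, flanked$right_flank)
}

#' Write flanked sequences to FASTA or TSV
#'
#' FASTA output soft-masks the flanks (lowercase) and uppercases the motif,
#' encoding the flank/motif boundary exactly without a separator character;
#' TSV output keeps the three parts in separate columns.
#'
#' @param flanked Output of [extract_flanked()].
#' @param path Output path.
#' @param format `"fasta"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_flanked <- function(flanked, path, format = c("fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "fasta") {
    recs <- paste0(
      ">", flanked$motif_id,
      " ", flanked$chrom, ":", flanked$start, "-", flanked$end,
      " flank=", flanked$flank_len_requested,
      ifelse(flanked$clipped, " clipped", ""),
      "\n",
      tolower(flanked$left_flank), flanked$motif_seq,
      tolower(flanked$right_flank)
    )
    writeLines(recs, path)
  } else {
    write_tsv(flanked, path)
  }
  invisible(path)
}
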