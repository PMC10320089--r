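# Canonical non-B structure type vocabulary and coordinate helpers.
# All coordinates inside the package are 0-based half-open (BED convention);
# 1-based inclusive dialects are converted at the file boundary.

#' The seven non-B DNA structure types
#'
#' Canonical order used everywhere a type axis appears: A-phased repeats
#' (APR), G-quadruplex motifs (G4), Z-DNA motifs (Z), inverted repeats (IR),
#' mirror repeats (MR), direct repeats (DR) and short tandem repeats (STR).
#'
#' @return Character vector of the seven type codes, in canonical order.
#' @export
#' @examples
#' nonb_types()
nonb_types <- function() {
  c("APR", "G4", "Z", "IR", "MR", "DR", "STR")
}

#' The two delineated non-B subsets
#'
#' Triplex-forming mirror repeats (`Triplex-MR`, a subset of MR) and
#' cruciform-forming inverted repeats (`Cruciform-IR`, a subset of IR).
#' Subset motifs are flagged rows of their parent type; parent library
#' sizes include them.
#'
#' @return Character vector of the two subset codes.
#' @export
nonb_subsets <- function() {
  c("Triplex-MR", "Cruciform-IR")
}

subset_parent <- function(subset) {
  c("Triplex-MR" = "MR", "Cruciform-IR" = "IR")[[subset]]
}

#' Default aliases mapping file type tokens to the canonical vocabulary
#'
#' Non-B motif databases spell structure types in several dialects
#' (`Z_DNA_Motif`, `Short_Tandem_Repeat`, ...).  This table maps
#' case-insensitively from known tokens to the canonical codes of
#' [nonb_types()] and [nonb_subsets()].  Pass a modified copy to
#' [read_motif_library()] to accept further dialects; unknown tokens are
#' hard errors, never silent drops.
#'
#' @return Named character vector: `names` are lower-cased input tokens,
#'   values are canonical codes.
#' @export
nonb_type_aliases <- function() {
  canon <- c(nonb_types(), nonb_subsets())
  auto <- setNames(canon, tolower(canon))
  extra <- c(
    "a_phased_repeat"      = "APR",
    "a-phased_repeat"      = "APR",
    "g_quadruplex_motif"   = "G4",
    "g-quadruplex"         = "G4",
    "gq"                   = "G4",
    "z_dna_motif"          = "Z",
    "z-dna"                = "Z",
    "z_dna"                = "Z",
    "inverted_repeat"      = "IR",
    "mirror_repeat"        = "MR",
    "direct_repeat"        = "DR",
    "short_tandem_repeat"  = "STR",
    "triplex"              = "Triplex-MR",
    "triplex_mr"           = "Triplex-MR",
    "triplex-mr"           = "Triplex-MR",
    "cruciform"            = "Cruciform-IR",
    "cruciform_ir"         = "Cruciform-IR",
    "cruciform-ir"         = "Cruciform-IR"
  )
  c(auto, extra)
}

# Map raw type tokens to canonical codes; error names the first offending
# line (1-based line number in the source file when provided).
canonicalize_types <- function(tokens, aliases = nonb_type_aliases(),
                               lines = seq_along(tokens), file = "<input>") {
  hit <- aliases[tolower(str_trim(tokens))]
  bad <- which(is.na(hit))
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown non-B type token '%s' at %s line %d (known tokens: %s)",
      tokens[bad[1]], file, lines[bad[1]],
      paste(sort(unique(names(aliases))), collapse = ", ")
    ))
  }
  unname(hit)
}

# tibble(chrom, start, end[, strand]) with 0-based half-open coordinates
# -> GRanges (1-based inclusive).
as_granges <- function(tbl) {
  strand <- if ("strand" %in% names(tbl)) {
    ifelse(tbl$strand %in% c("+", "-"), tbl$strand, "*")
  } else "*"
  GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges(start = tbl$start + 1L, end = tbl$end),
    strand = strand
  )
}

# GRanges -> tibble with 0-based half-open coordinates.
granges_to_tbl <- function(gr) {
  tibble(
    chrom = as.character(seqnames(gr)),
    start = start(gr) - 1L,
    end = end(gr)
  )
}

check_coords <- function(tbl, file = "<input>", lines = seq_len(nrow(tbl))) {
  bad <- which(!(tbl$start >= 0 & tbl$start < tbl$end))
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid interval [%s, %s) at %s line %d: need 0 <= start < end",
      format(tbl$start[bad[1]], scientific = FALSE),
      format(tbl$end[bad[1]], scientific = FALSE),
      file, lines[bad[1]]
    ))
  }
  invisible(tbl)
}

# Merge overlapping or book-ended intervals per chromosome; returns a tibble
# of disjoint intervals in 0-based half-open coordinates.
merge_intervals <- function(tbl) {
  if (nrow(tbl) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  granges_to_tbl(reduce(as_granges(tbl), ignore.strand = TRUE)) |>
    arrange(.data$chrom, .data$start)
}
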