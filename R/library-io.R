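# Motif library container and readers/writers for its two on-disk dialects.

#' Construct a non-B motif library
#'
#' A motif library is the universe of non-B forming motifs against which
#' burdens are computed.  It wraps a record table (one row per motif) plus a
#' genome-build label, and exposes per-type library sizes — the "total non-B
#' library size" denominator of the CPKM normalization.
#'
#' @param records A data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `nonb_type` (codes from [nonb_types()]), and
#'   optionally `subset_flag` (`Triplex-MR` on MR rows, `Cruciform-IR` on IR
#'   rows, else `NA`), `motif_id` (unique; generated when absent),
#'   `sequence` (A/C/G/T/N, length `end - start`), `strand` (`+`/`-`/`.`).
#' @param genome_build Free-text label of the assembly the coordinates
#'   refer to (e.g. `"hg19"`, `"toy"`).
#'
#' @return An object of class `nonb_library`.
#' @export
#' @examples
#' lib <- nonb_library(
#'   tibble::tibble(
#'     chrom = "chr1", start = c(0L, 50L), end = c(20L, 80L),
#'     nonb_type = c("G4", "MR")
#'   ),
#'   genome_build = "toy"
#' )
#' library_size(lib)
nonb_library <- function(records, genome_build = "custom") {
  records <- as_tibble(records)
  required <- c("chrom", "start", "end", "nonb_type")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    abort(paste0("records lack required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(records) > 0) check_coords(records)
  bad_type <- setdiff(unique(records$nonb_type), nonb_types())
  if (length(bad_type) > 0) {
    abort(paste0("unknown nonb_type value(s): ",
                 paste(bad_type, collapse = ", ")))
  }
  if (!"subset_flag" %in% names(records)) {
    records$subset_flag <- NA_character_
  }
  if (!"motif_id" %in% names(records)) {
    records$motif_id <- sprintf("m%06d", seq_len(nrow(records)))
  }
  if (!"sequence" %in% names(records)) records$sequence <- NA_character_
  if (!"strand" %in% names(records)) records$strand <- "."
  if (anyDuplicated(records$motif_id)) {
    abort("motif_id values must be unique")
  }
  flagged <- !is.na(records$subset_flag)
  if (any(flagged)) {
    parent <- vapply(records$subset_flag[flagged], subset_parent, character(1))
    ok <- parent == records$nonb_type[flagged]
    if (!all(ok)) {
      abort(sprintf(
        "subset_flag '%s' is invalid on a record of type %s",
        records$subset_flag[flagged][!ok][1],
        records$nonb_type[flagged][!ok][1]
      ))
    }
  }
  has_seq <- !is.na(records$sequence)
  if (any(has_seq)) {
    len_ok <- nchar(records$sequence[has_seq]) ==
      (records$end[has_seq] - records$start[has_seq])
    if (!all(len_ok)) {
      abort(sprintf("sequence length does not match end - start for motif %s",
                    records$motif_id[has_seq][!len_ok][1]))
    }
  }
  records <- records[, union(
    c("chrom", "start", "end", "nonb_type", "subset_flag", "motif_id",
      "sequence", "strand"),
    names(records)
  )]
  structure(
    list(records = records, genome_build = genome_build),
    class = "nonb_library"
  )
}

#' @export
print.nonb_library <- function(x, ...) {
  cat(sprintf("<nonb_library> %d motifs, genome build '%s'\n",
              nrow(x$records), x$genome_build))
  sizes <- library_size(x)
  sizes <- sizes[sizes > 0]
  if (length(sizes) > 0) {
    cat(paste(sprintf("  %-12s %d", names(sizes), sizes), collapse = "\n"),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
#' @exportS3Method generics::tidy
tidy.nonb_library <- function(x, ...) x$records

#' Per-type library sizes of a motif library
#'
#' The number of motifs of each type genome-wide — the denominator factor of
#' per-million and CPKM burden normalization.  Subset types (`Triplex-MR`,
#' `Cruciform-IR`) count their flagged records; parent types include them.
#'
#' @param library A [nonb_library()].
#' @param type Optional single type code (one of [nonb_types()] or
#'   [nonb_subsets()]).  When omitted, sizes for all nine are returned.
#'
#' @return A named integer vector, or a single integer when `type` is given.
#' @export
library_size <- function(library, type = NULL) {
  stopifnot(inherits(library, "nonb_library"))
  rec <- library$records
  sizes <- vapply(nonb_types(), function(t) sum(rec$nonb_type == t), integer(1))
  sub <- vapply(nonb_subsets(), function(s) {
    sum(!is.na(rec$subset_flag) & rec$subset_flag == s)
  }, integer(1))
  all_sizes <- c(sizes, sub)
  if (is.null(type)) return(all_sizes)
  if (!type %in% names(all_sizes)) {
    abort(sprintf("unknown non-B type '%s'", type))
  }
  all_sizes[[type]]
}

# Records of a given type; subset codes select flagged rows only.
records_of_type <- function(library, type) {
  rec <- library$records
  if (type %in% nonb_subsets()) {
    rec[!is.na(rec$subset_flag) & rec$subset_flag == type, ]
  } else {
    rec[rec$nonb_type == type, ]
  }
}

#' Read a non-B motif library from disk
#'
#' Two dialects are supported.  `bed6+type`: BED6 columns
#' (chrom, start, end, name, score, strand; 0-based half-open) plus a 7th
#' column carrying the non-B type token and an optional 8th carrying a
#' subset flag (`Triplex-MR` / `Cruciform-IR`, or `.`).  `nonbdb-tsv`: a
#' headered TSV with columns `chrom`, `start` (1-based inclusive), `end`,
#' `type`, `sequence`, and optionally `motif_id`, `subset_flag`, `strand`;
#' coordinates are converted to 0-based half-open on read.
#'
#' Type tokens are matched case-insensitively against `aliases`; an unknown
#' token is an error naming the offending line, never a silent drop.  A type
#' token that names a subset (`Triplex-MR`, `Cruciform-IR`) yields a record
#' of the parent type with the subset flag set.
#'
#' @param path Path to the library file.
#' @param dialect `"bed6+type"` (default) or `"nonbdb-tsv"`.
#' @param aliases Token alias table, see [nonb_type_aliases()].
#' @param genome_build Label stored on the returned library.
#'
#' @return A [nonb_library()].
#' @export
read_motif_library <- function(path, dialect = c("bed6+type", "nonbdb-tsv"),
                               aliases = nonb_type_aliases(),
                               genome_build = "custom") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (dialect == "bed6+type") {
    lines <- readLines(path)
    keep <- !grepl("^\\s*(#|$)", lines)
    line_no <- which(keep)
    lines <- lines[keep]
    if (length(lines) == 0) {
      return(nonb_library(
        tibble(chrom = character(), start = integer(), end = integer(),
               nonb_type = character()),
        genome_build = genome_build
      ))
    }
    fields <- str_split(lines, "\t")
    nf <- lengths(fields)
    if (any(nf < 7)) {
      abort(sprintf("%s line %d: expected >= 7 tab-separated fields, got %d",
                    path, line_no[which(nf < 7)[1]], min(nf)))
    }
    rec <- tibble(
      chrom = map_chr(fields, 1),
      start = suppressWarnings(as.integer(map_chr(fields, 2))),
      end = suppressWarnings(as.integer(map_chr(fields, 3))),
      motif_id = map_chr(fields, 4),
      strand = map_chr(fields, 6),
      type_token = map_chr(fields, 7),
      flag_token = map_chr(fields, function(f) if (length(f) >= 8) f[8] else ".")
    )
    bad <- which(is.na(rec$start) | is.na(rec$end))
    if (length(bad) > 0) {
      abort(sprintf("%s line %d: non-numeric coordinate", path, line_no[bad[1]]))
    }
    check_coords(rec, file = path, lines = line_no)
    canon <- canonicalize_types(rec$type_token, aliases, line_no, path)
    flag <- rep(NA_character_, nrow(rec))
    has_flag <- !rec$flag_token %in% c(".", "", "NA")
    if (any(has_flag)) {
      flag[has_flag] <- canonicalize_types(rec$flag_token[has_flag], aliases,
                                           line_no[has_flag], path)
    }
    # A subset code in the type column implies parent type + flag.
    is_sub <- canon %in% nonb_subsets()
    flag[is_sub] <- canon[is_sub]
    canon[is_sub] <- vapply(canon[is_sub], subset_parent, character(1))
    rec$nonb_type <- canon
    rec$subset_flag <- flag
    rec <- rec[, c("chrom", "start", "end", "nonb_type", "subset_flag",
                   "motif_id", "strand")]
  } else {
    df <- suppressMessages(read_tsv(path, comment = "#", show_col_types = FALSE))
    needed <- c("chrom", "start", "end", "type")
    missing <- setdiff(needed, names(df))
    if (length(missing) > 0) {
      abort(paste0(path, ": nonbdb-tsv dialect needs column(s): ",
                   paste(missing, collapse = ", ")))
    }
    if (nrow(df) == 0) {
      return(nonb_library(
        tibble(chrom = character(), start = integer(), end = integer(),
               nonb_type = character()),
        genome_build = genome_build
      ))
    }
    rec <- tibble(
      chrom = as.character(df$chrom),
      start = as.integer(df$start) - 1L,  # 1-based inclusive -> 0-based
      end = as.integer(df$end),
      type_token = as.character(df$type),
      sequence = if ("sequence" %in% names(df)) {
        str_to_upper(as.character(df$sequence))
      } else NA_character_,
      motif_id = if ("motif_id" %in% names(df)) as.character(df$motif_id)
      else sprintf("m%06d", seq_len(nrow(df))),
      strand = if ("strand" %in% names(df)) as.character(df$strand) else ".",
      flag_token = if ("subset_flag" %in% names(df)) {
        as.character(df$subset_flag)
      } else NA_character_
    )
    line_no <- seq_len(nrow(rec)) + 1L  # +1 for the header line
    check_coords(rec, file = path, lines = line_no)
    canon <- canonicalize_types(rec$type_token, aliases, line_no, path)
    flag <- rec$flag_token
    has_flag <- !is.na(flag) & !flag %in% c(".", "")
    flag[!has_flag] <- NA_character_
    if (any(has_flag)) {
      flag[has_flag] <- canonicalize_types(flag[has_flag], aliases,
                                           line_no[has_flag], path)
    }
    is_sub <- canon %in% nonb_subsets()
    flag[is_sub] <- canon[is_sub]
    canon[is_sub] <- vapply(canon[is_sub], subset_parent, character(1))
    rec$nonb_type <- canon
    rec$subset_flag <- flag
    rec <- rec[, c("chrom", "start", "end", "nonb_type", "subset_flag",
                   "motif_id", "sequence", "strand")]
  }
  nonb_library(rec, genome_build = genome_build)
}

#' Write a non-B motif library to disk
#'
#' Inverse of [read_motif_library()]: writes the BED6+type dialect
#' (0-based half-open, col 7 = type, col 8 = subset flag or `.`) or the
#' headered TSV dialect (1-based inclusive start, with `motif_id`,
#' `subset_flag` and `strand` columns so a round-trip preserves records).
#'
#' @param library A [nonb_library()].
#' @param path Output path.
#' @param dialect `"bed6+type"` or `"nonbdb-tsv"`.
#' @return `path`, invisibly.
#' @export
write_motif_library <- function(library, path,
                                dialect = c("bed6+type", "nonbdb-tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(library, "nonb_library"))
  rec <- library$records
  if (dialect == "bed6+type") {
    out <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%s\t%s",
                   rec$chrom, rec$start, rec$end, rec$motif_id,
                   ifelse(rec$strand %in% c("+", "-"), rec$strand, "."),
                   rec$nonb_type,
                   ifelse(is.na(rec$subset_flag), ".", rec$subset_flag))
    writeLines(out, path)
  } else {
    df <- tibble(
      chrom = rec$chrom,
      start = rec$start + 1L,  # back to 1-based inclusive
      end = rec$end,
      type = rec$nonb_type,
      sequence = ifelse(is.na(rec$sequence), ".", rec$sequence),
      motif_id = rec$motif_id,
      subset_flag = ifelse(is.na(rec$subset_flag), ".", rec$subset_flag),
      strand = rec$strand
    )
    write_tsv(df, path)
  }
  invisible(path)
}
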