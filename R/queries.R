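# Query construction: gene annotations, signatures (GMT), site-level BED.
#
# A *query* is a tibble with one row per region and columns
#   name  - query unit label (gene symbol, signature name, sample id)
#   level - "gene", "signature" or "site"
#   chrom / start / end - 0-based half-open coordinates
# A batch is simply a query tibble with several distinct names; unit order
# is first-appearance order and is preserved by every downstream verb.

validate_query <- function(query) {
  query <- as_tibble(query)
  needed <- c("name", "chrom", "start", "end")
  missing <- setdiff(needed, names(query))
  if (length(missing) > 0) {
    abort(paste0("query lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"level" %in% names(query)) query$level <- "site"
  if (nrow(query) > 0) check_coords(query)
  query
}

query_unit_names <- function(query) unique(query$name)

#' Read a gene annotation mapping symbols to genomic intervals
#'
#' Accepts either BED (>= 4 columns; the name column carries the gene
#' symbol; 0-based half-open) or GFF3/GTF (any feature carrying a
#' `gene_name`, `Name` or `gene_id` attribute; 1-based inclusive, converted
#' on read).  A symbol maps to the union of all its intervals, merged per
#' chromosome.  A symbol annotated on two chromosomes is kept on both with
#' a warning (its burden uses the union).
#'
#' @param path Annotation file; `.gff`/`.gff3`/`.gtf` extensions select the
#'   GFF reader, anything else the BED reader.
#' @return A tibble with columns `symbol`, `chrom`, `start`, `end`
#'   (merged, 0-based half-open).
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (grepl("\\.(gff3?|gtf)$", path, ignore.case = TRUE)) {
    gr <- tryCatch(rtracklayer::import(path),
                   error = function(e) {
                     abort(sprintf("cannot parse annotation %s: %s",
                                   path, conditionMessage(e)))
                   })
    meta <- as.data.frame(gr@elementMetadata)
    sym_col <- intersect(c("gene_name", "Name", "gene_id"), names(meta))
    if (length(sym_col) == 0) {
      abort(sprintf("%s: no gene_name/Name/gene_id attribute found", path))
    }
    symbol <- as.character(meta[[sym_col[1]]])
    ann <- tibble(
      symbol = symbol,
      chrom = as.character(seqnames(gr)),
      start = start(gr) - 1L,
      end = end(gr)
    ) |> filter(!is.na(.data$symbol))
  } else {
    lines <- readLines(path)
    keep <- !grepl("^\\s*(#|track|browser|$)", lines)
    line_no <- which(keep)
    fields <- str_split(lines[keep], "\t")
    if (any(lengths(fields) < 4)) {
      abort(sprintf("%s line %d: BED annotation needs >= 4 columns",
                    path, line_no[which(lengths(fields) < 4)[1]]))
    }
    ann <- tibble(
      chrom = map_chr(fields, 1),
      start = suppressWarnings(as.integer(map_chr(fields, 2))),
      end = suppressWarnings(as.integer(map_chr(fields, 3))),
      symbol = map_chr(fields, 4)
    )
    bad <- which(is.na(ann$start) | is.na(ann$end))
    if (length(bad) > 0) {
      abort(sprintf("%s line %d: non-numeric coordinate", path, line_no[bad[1]]))
    }
    check_coords(ann, file = path, lines = line_no)
  }
  multi <- ann |>
    distinct(.data$symbol, .data$chrom) |>
    count(.data$symbol) |>
    filter(.data$n > 1)
  if (nrow(multi) > 0) {
    warn(paste0("symbol(s) annotated on multiple chromosomes (union kept): ",
                paste(multi$symbol, collapse = ", ")))
  }
  ann |>
    group_by(.data$symbol) |>
    group_modify(~ merge_intervals(.x)) |>
    ungroup() |>
    select("symbol", "chrom", "start", "end")
}

#' Build a gene-level query from symbols
#'
#' Resolves gene symbols against an annotation and returns one query unit
#' per symbol, its regions being the merged union of all intervals carrying
#' that symbol.  Resolution is idempotent: all requested symbols must be
#' present, otherwise the error lists every unresolved symbol.
#'
#' @param annotation Output of [read_gene_annotation()].
#' @param symbols Character vector of gene symbols (unit order follows it).
#' @return A query tibble (`name`, `level = "gene"`, `chrom`, `start`, `end`).
#' @export
query_genes <- function(annotation, symbols) {
  symbols <- unique(symbols)
  unresolved <- setdiff(symbols, annotation$symbol)
  if (length(unresolved) > 0) {
    abort(paste0("unresolved gene symbol(s): ",
                 paste(unresolved, collapse = ", ")))
  }
  annotation |>
    filter(.data$symbol %in% symbols) |>
    mutate(name = factor(.data$symbol, levels = symbols)) |>
    arrange(.data$name) |>
    transmute(name = as.character(.data$name), level = "gene",
              .data$chrom, .data$start, .data$end)
}

#' Read gene signatures from a GMT file
#'
#' Standard GMT: one signature per line — name, description, then
#' tab-separated member gene symbols.  Duplicate symbols within one
#' signature are deduplicated.
#'
#' @param path GMT file path.
#' @return A tibble with columns `signature`, `description` and a list
#'   column `symbols`.
#' @export
read_signatures_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  fields <- str_split(lines[keep], "\t")
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    abort(sprintf("%s line %d: GMT line needs >= 3 tab-separated fields",
                  path, keep[short[1]]))
  }
  tibble(
    signature = map_chr(fields, 1),
    description = map_chr(fields, 2),
    symbols = map(fields, ~ unique(.x[-(1:2)][.x[-(1:2)] != ""]))
  )
}

#' Build a signature-level query batch
#'
#' One query unit per signature; a unit's regions are the merged union of
#' its member genes' regions.  A signature none of whose symbols resolve is
#' an error naming the signature; partially resolvable signatures drop the
#' missing symbols with a warning.
#'
#' @param annotation Output of [read_gene_annotation()].
#' @param signatures Output of [read_signatures_gmt()] (or a tibble with
#'   `signature` and list column `symbols`).
#' @return A query tibble with `level = "signature"`.
#' @export
query_signatures <- function(annotation, signatures) {
  units <- pmap(
    list(signatures$signature, signatures$symbols),
    function(sig, syms) {
      syms <- unique(syms)
      found <- intersect(syms, annotation$symbol)
      if (length(found) == 0) {
        abort(sprintf("signature '%s': no member symbol resolves (%s)",
                      sig, paste(syms, collapse = ", ")))
      }
      lost <- setdiff(syms, found)
      if (length(lost) > 0) {
        warn(sprintf("signature '%s': unresolved symbol(s) dropped: %s",
                     sig, paste(lost, collapse = ", ")))
      }
      regions <- annotation |>
        filter(.data$symbol %in% found) |>
        select("chrom", "start", "end") |>
        merge_intervals()
      tibble(name = sig, level = "signature", regions)
    }
  )
  list_rbind(units)
}

#' Read site-level query regions from a BED file
#'
#' BED3 or more; with `group_column` set (a 1-based column index or a
#' header-less positional name like `4`), rows are grouped into one query
#' unit per distinct group value, preserving first-appearance order — the
#' "burden in batch" input of per-sample mutation-site sets.  Without a
#' group column all rows form a single unit.  Zero-length rows
#' (`start == end`, e.g. point mutations) are rejected; pre-expand them to
#' at least 1 bp before querying.
#'
#' @param path BED path.
#' @param group_column Optional integer column index holding the group /
#'   sample id (conventionally 4).
#' @param name Unit name used when `group_column` is `NULL`.
#' @return A query tibble with `level = "site"`.
#' @export
read_site_regions <- function(path, group_column = NULL, name = "sites") {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|track|browser|$)", lines)
  line_no <- which(keep)
  fields <- str_split(lines[keep], "\t")
  min_cols <- max(3L, group_column %||% 0L)
  short <- which(lengths(fields) < min_cols)
  if (length(short) > 0) {
    abort(sprintf("%s line %d: expected >= %d columns",
                  path, line_no[short[1]], min_cols))
  }
  tbl <- tibble(
    chrom = map_chr(fields, 1),
    start = suppressWarnings(as.integer(map_chr(fields, 2))),
    end = suppressWarnings(as.integer(map_chr(fields, 3)))
  )
  bad <- which(is.na(tbl$start) | is.na(tbl$end))
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: malformed coordinate", path, line_no[bad[1]]))
  }
  zero <- which(tbl$start == tbl$end)
  if (length(zero) > 0) {
    abort(sprintf(
      "%s line %d: zero-length site (start == end); expand point sites to >= 1 bp before querying",
      path, line_no[zero[1]]
    ))
  }
  check_coords(tbl, file = path, lines = line_no)
  if (is.null(group_column)) {
    tbl$name <- name
  } else {
    tbl$name <- map_chr(fields, group_column)
  }
  tbl |>
    mutate(name = factor(.data$name, levels = unique(.data$name))) |>
    arrange(.data$name) |>
    transmute(name = as.character(.data$name), level = "site",
              .data$chrom, .data$start, .data$end)
}

#' Merged query length per unit
#'
#' The "total query region length" denominator of length-normalized burden:
#' per unit, overlapping or book-ended regions are merged per chromosome and
#' the disjoint interval lengths summed.
#'
#' @param query A query tibble (see [query_genes()]).
#' @return A tibble `name`, `merged_length_bp`, in unit order.
#' @export
#' @examples
#' q <- tibble::tibble(name = "X", level = "gene", chrom = "chr1",
#'                     start = c(100L, 150L), end = c(200L, 300L))
#' merged_length(q)  # 200 bp
merged_length <- function(query) {
  query <- validate_query(query)
  if (nrow(query) == 0) abort("empty query: merged length is undefined")
  units <- query_unit_names(query)
  len <- vapply(units, function(u) {
    m <- merge_intervals(query[query$name == u, c("chrom", "start", "end")])
    sum(m$end - m$start)
  }, numeric(1))
  tibble(name = units, merged_length_bp = unname(len))
}
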