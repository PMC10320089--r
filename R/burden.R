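# Non-B burden engine: overlap counting, normalization, batch matrices.

burden_modes <- function() c("raw", "per_kb", "per_million", "cpkm")

#' Normalize a raw overlap count into a burden value
#'
#' The burden of a query unit for one non-B type is its raw motif overlap
#' count, optionally normalized by the merged query length (per kilobase,
#' factor 10^3) and/or by the genome-wide motif library size of the type
#' (per million, factor 10^6).  The doubly-normalized unit is CPKM:
#'
#' \deqn{\mathrm{CPKM} = \frac{\mathrm{count} \times 10^3 \times 10^6}
#'       {\mathrm{library\ size} \times \mathrm{query\ length}}}
#'
#' @param raw Nonnegative integer overlap count(s).
#' @param merged_length_bp Merged query length in bp (used by `per_kb`,
#'   `cpkm`).
#' @param library_size Genome-wide motif count of the type (used by
#'   `per_million`, `cpkm`).
#' @param mode One of `"raw"`, `"per_kb"`, `"per_million"`, `"cpkm"`.
#' @return Numeric burden value(s) in the requested unit.
#' @export
#' @examples
#' burden_value(5, merged_length_bp = 2000, library_size = 1e6, mode = "cpkm")
#' # 2.5
burden_value <- function(raw, merged_length_bp = NULL, library_size = NULL,
                         mode = c("cpkm", "raw", "per_kb", "per_million")) {
  mode <- match.arg(mode)
  if (any(raw < 0)) abort("raw counts must be nonnegative")
  needs_len <- mode %in% c("per_kb", "cpkm")
  needs_lib <- mode %in% c("per_million", "cpkm")
  if (needs_len) {
    if (is.null(merged_length_bp) || any(merged_length_bp <= 0)) {
      abort("merged_length_bp must be > 0 for length-normalized modes")
    }
  }
  if (needs_lib) {
    if (is.null(library_size) || any(library_size <= 0)) {
      abort(paste0("library size is 0: ", mode,
                   " burden is undefined for a type with an empty library"))
    }
  }
  raw <- as.numeric(raw)
  switch(mode,
    raw = raw,
    per_kb = raw * 1e3 / as.numeric(merged_length_bp),
    per_million = raw * 1e6 / as.numeric(library_size),
    cpkm = raw * 1e3 * 1e6 /
      (as.numeric(library_size) * as.numeric(merged_length_bp))
  )
}

#' Count motif overlaps per query unit and non-B type
#'
#' For each query unit and each requested type, counts the number of
#' *distinct* motifs of that type having at least 1 bp overlap with the
#' union of the unit's regions (a motif touching two regions of the same
#' unit counts once; half-open intervals that merely touch do not overlap).
#' The same motif may count in several units of a batch — each unit is an
#' independent query.
#'
#' @param query A query tibble (see [query_genes()], [read_site_regions()]).
#' @param library A [nonb_library()].
#' @param types Type codes to count (defaults to the 7 parent types; subset
#'   codes `Triplex-MR` / `Cruciform-IR` count flagged records only).
#' @param contained_only Count only motifs fully contained in the query
#'   union, instead of the default any-overlap (>= 1 bp) rule.
#' @return A tibble `name`, `nonb_type`, `raw_count`, in unit then
#'   canonical type order.
#' @export
count_motif_overlaps <- function(query, library, types = nonb_types(),
                                 contained_only = FALSE) {
  query <- validate_query(query)
  if (nrow(query) == 0) abort("empty query")
  stopifnot(inherits(library, "nonb_library"))
  bad <- setdiff(types, c(nonb_types(), nonb_subsets()))
  if (length(bad) > 0) {
    abort(paste0("unknown non-B type(s): ", paste(bad, collapse = ", ")))
  }
  units <- query_unit_names(query)
  type_gr <- lapply(setNames(types, types), function(t) {
    as_granges(records_of_type(library, t))
  })
  unit_gr <- lapply(setNames(units, units), function(u) {
    reduce(as_granges(query[query$name == u, ]), ignore.strand = TRUE)
  })
  grid <- expand.grid(name = units, nonb_type = types,
                      stringsAsFactors = FALSE)
  grid$raw_count <- pmap(
    list(grid$name, grid$nonb_type),
    function(u, t) {
      hits <- countOverlaps(
        type_gr[[t]], unit_gr[[u]],
        type = if (contained_only) "within" else "any",
        ignore.strand = TRUE
      )
      sum(hits > 0)
    }
  ) |> unlist() |> as.integer()
  grid |>
    as_tibble() |>
    mutate(name = factor(.data$name, levels = units),
           nonb_type = factor(.data$nonb_type, levels = types)) |>
    arrange(.data$name, .data$nonb_type) |>
    mutate(name = as.character(.data$name),
           nonb_type = as.character(.data$nonb_type))
}

#' Compute non-B burden for a query
#'
#' The main burden verb: counts motif overlaps per unit and type
#' ([count_motif_overlaps()]), derives the normalization denominators
#' (merged query length, per-type library size) and returns a tidy table of
#' burden values in the requested unit.
#'
#' @inheritParams count_motif_overlaps
#' @param mode Burden unit: `"cpkm"` (default), `"raw"`, `"per_kb"` or
#'   `"per_million"`.
#' @param include_subsets Also compute the `Triplex-MR` and `Cruciform-IR`
#'   subset rows (flagged records only).
#' @return A tibble `name`, `nonb_type`, `raw_count`, `merged_length_bp`,
#'   `library_size`, `burden`, `mode`.
#' @export
#' @examples
#' lib <- nonb_library(tibble::tibble(
#'   chrom = "chr1", start = c(100L, 400L), end = c(150L, 450L),
#'   nonb_type = c("G4", "STR")
#' ))
#' q <- tibble::tibble(name = "X", level = "gene", chrom = "chr1",
#'                     start = 0L, end = 500L)
#' nonb_burden(q, lib, mode = "raw")
nonb_burden <- function(query, library, types = nonb_types(),
                        mode = c("cpkm", "raw", "per_kb", "per_million"),
                        include_subsets = FALSE, contained_only = FALSE) {
  mode <- match.arg(mode)
  if (include_subsets) types <- union(types, nonb_subsets())
  counts <- count_motif_overlaps(query, library, types, contained_only)
  lens <- merged_length(query)
  sizes <- library_size(library)
  counts |>
    left_join(lens, by = "name") |>
    mutate(
      library_size = as.integer(sizes[.data$nonb_type]),
      burden = burden_value(
        .data$raw_count,
        merged_length_bp = if (mode %in% c("per_kb", "cpkm")) {
          .data$merged_length_bp
        } else NULL,
        library_size = if (mode %in% c("per_million", "cpkm")) {
          .data$library_size
        } else NULL,
        mode = mode
      ),
      mode = mode
    )
}

#' Assemble a burden matrix from a tidy burden table
#'
#' Pivots the output of [nonb_burden()] into a units-by-types matrix object
#' carrying its normalization metadata.  Unit order is query input order;
#' type order is canonical.  On disk ([write_burden_matrix()]) the
#' orientation is types as rows, units as columns — the layout of a
#' batch run over many samples.
#'
#' @param burden_tbl Output of [nonb_burden()] (single mode).
#' @return A `burden_matrix` object: list with `values` (numeric matrix,
#'   rows = units, cols = types), `mode`, `merged_length_bp` and
#'   `library_size` (named vectors).
#' @export
burden_matrix <- function(burden_tbl) {
  stopifnot(all(c("name", "nonb_type", "burden", "mode") %in%
                  names(burden_tbl)))
  mode <- unique(burden_tbl$mode)
  if (length(mode) != 1) abort("burden table mixes normalization modes")
  units <- unique(burden_tbl$name)
  types <- intersect(c(nonb_types(), nonb_subsets()),
                     unique(burden_tbl$nonb_type))
  values <- matrix(NA_real_, nrow = length(units), ncol = length(types),
                   dimnames = list(units, types))
  values[cbind(burden_tbl$name, burden_tbl$nonb_type)] <- burden_tbl$burden
  if (anyNA(values)) abort("burden table is not a complete unit x type grid")
  lens <- burden_tbl |> distinct(.data$name, .data$merged_length_bp)
  sizes <- burden_tbl |> distinct(.data$nonb_type, .data$library_size)
  structure(
    list(
      values = values,
      mode = mode,
      merged_length_bp = setNames(lens$merged_length_bp, lens$name)[units],
      library_size = setNames(sizes$library_size, sizes$nonb_type)[types]
    ),
    class = "burden_matrix"
  )
}

#' @export
print.burden_matrix <- function(x, ...) {
  cat(sprintf("<burden_matrix> %d units x %d types, mode = %s\n",
              nrow(x$values), ncol(x$values), x$mode))
  print(round(t(x$values), 3))
  invisible(x)
}

#' @rdname burden_matrix
#' @param x A `burden_matrix`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.burden_matrix <- function(x, ...) {
  as_tibble(x$values, rownames = "name") |>
    pivot_longer(-"name", names_to = "nonb_type", values_to = "burden") |>
    mutate(mode = x$mode)
}

#' @rdname burden_matrix
#' @export
#' @exportS3Method generics::glance
glance.burden_matrix <- function(x, ...) {
  tibble(
    n_units = nrow(x$values),
    n_types = ncol(x$values),
    mode = x$mode,
    total_burden = sum(x$values),
    max_burden = max(x$values)
  )
}

#' Write / read a burden matrix as TSV
#'
#' On-disk orientation is types as rows and units as columns, with the
#' first column named `nonb_type`; `#`-prefixed header lines carry the
#' normalization mode and denominators so the matrix is self-describing.
#'
#' @param x A `burden_matrix`.
#' @param path Output (input) TSV path.
#' @param header_lines Extra `#` comment lines to prepend (provenance).
#' @return `path` invisibly; `read_burden_matrix()` returns the
#'   `burden_matrix`.
#' @export
write_burden_matrix <- function(x, path, header_lines = character()) {
  stopifnot(inherits(x, "burden_matrix"))
  hdr <- c(
    header_lines,
    paste0("# mode: ", x$mode),
    paste0("# merged_length_bp: ",
           paste(sprintf("%s=%s", names(x$merged_length_bp),
                         x$merged_length_bp), collapse = ",")),
    paste0("# library_size: ",
           paste(sprintf("%s=%s", names(x$library_size), x$library_size),
                 collapse = ","))
  )
  tab <- t(x$values)  # types x units
  body <- c(
    paste(c("nonb_type", colnames(tab)), collapse = "\t"),
    vapply(seq_len(nrow(tab)), function(i) {
      paste(c(rownames(tab)[i],
              format(tab[i, ], scientific = FALSE, trim = TRUE, digits = 15)),
            collapse = "\t")
    }, character(1))
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_burden_matrix
#' @export
read_burden_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  body <- body[body != ""]
  fields <- str_split(body, "\t")
  units <- fields[[1]][-1]
  types <- map_chr(fields[-1], 1)
  values <- t(vapply(fields[-1], function(f) as.numeric(f[-1]),
                     numeric(length(units))))  # types x units
  dimnames(values) <- list(types, units)
  parse_kv <- function(key) {
    line <- hdr[str_detect(hdr, paste0("^# ", key, ": "))]
    if (length(line) == 0) return(NULL)
    kv <- str_split(sub(paste0("^# ", key, ": "), "", line[1]), ",")[[1]]
    parts <- str_split(kv, "=")
    setNames(as.numeric(map_chr(parts, 2)), map_chr(parts, 1))
  }
  mode_line <- hdr[str_detect(hdr, "^# mode: ")]
  structure(
    list(
      values = t(values),
      mode = if (length(mode_line) > 0) sub("^# mode: ", "", mode_line[1])
      else "unknown",
      merged_length_bp = parse_kv("merged_length_bp")[units],
      library_size = parse_kv("library_size")[types]
    ),
    class = "burden_matrix"
  )
}
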