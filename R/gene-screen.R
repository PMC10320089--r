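# Gene screen: descriptive analytics over a burden matrix — totals,
# composition, distribution-based banding, hierarchical burden clustering —
# plus the matching static plots (stacked bar, bubble, distribution,
# heatmap).

as_burden_tbl <- function(x) {
  if (inherits(x, "burden_matrix")) return(tidy(x))
  stopifnot(all(c("name", "nonb_type", "burden") %in% names(x)))
  as_tibble(x)
}

#' Total (cumulative) non-B burden per query unit
#'
#' Sums burden across types for each unit — the quantity behind the stacked
#' total-burden bar plot.  Returned sorted descending by total.
#'
#' @param x A tidy burden table ([nonb_burden()]) or a [burden_matrix()].
#' @return A tibble `name`, `total_burden`, sorted descending.
#' @export
total_burden <- function(x) {
  as_burden_tbl(x) |>
    group_by(.data$name) |>
    summarise(total_burden = sum(.data$burden), .groups = "drop") |>
    arrange(desc(.data$total_burden))
}

#' Per-type composition of a unit's non-B burden
#'
#' Fractions of each unit's total burden contributed by each type (the
#' bubble-plot quantity).  Fractions sum to 1 per unit; a unit with zero
#' total burden is an error — inspect [total_burden()] first.
#'
#' @inheritParams total_burden
#' @param unit Optional unit name(s) to restrict to.
#' @return A tibble `name`, `nonb_type`, `burden`, `fraction`.
#' @export
composition <- function(x, unit = NULL) {
  tbl <- as_burden_tbl(x)
  if (!is.null(unit)) {
    missing <- setdiff(unit, tbl$name)
    if (length(missing) > 0) {
      abort(paste0("unknown unit(s): ", paste(missing, collapse = ", ")))
    }
    tbl <- tbl |> filter(.data$name %in% unit)
  }
  tot <- tbl |> group_by(.data$name) |>
    summarise(total = sum(.data$burden), .groups = "drop")
  zero <- tot$name[tot$total == 0]
  if (length(zero) > 0) {
    abort(paste0(
      "zero total burden for unit(s) ", paste(zero, collapse = ", "),
      ": composition is undefined; check total_burden() first"
    ))
  }
  tbl |>
    left_join(tot, by = "name") |>
    mutate(fraction = .data$burden / .data$total) |>
    select("name", "nonb_type", "burden", "fraction")
}

#' Band units into low / mid / high burden from the burden distribution
#'
#' Labels every unit by where its burden for one type falls in the
#' across-unit distribution.  `method = "sd"` uses mean +/- k standard
#' deviations; `method = "quantile"` uses the (q_low, q_high) quantiles.
#' Thresholds are returned alongside the labels so the banding rule is
#' explicit in the output.
#'
#' @inheritParams total_burden
#' @param type One type code; or `"total"` to band on total burden.
#' @param method `"sd"` (default, mean +/- `k` SD) or `"quantile"`.
#' @param k SD multiplier for `method = "sd"`.
#' @param q Length-2 probabilities for `method = "quantile"`.
#' @return A tibble `name`, `value`, `band` (`low`/`mid`/`high`), `lower`,
#'   `upper`, `method`.
#' @export
burden_intervals <- function(x, type, method = c("sd", "quantile"),
                             k = 1, q = c(0.25, 0.75)) {
  method <- match.arg(method)
  tbl <- as_burden_tbl(x)
  vals <- if (identical(type, "total")) {
    total_burden(tbl) |> rename(value = "total_burden")
  } else {
    if (!type %in% tbl$nonb_type) abort(sprintf("type '%s' not in table", type))
    tbl |> filter(.data$nonb_type == type) |>
      select("name", value = "burden")
  }
  if (nrow(vals) < 3) abort("need >= 3 units to band a distribution")
  if (method == "sd") {
    s <- sd(vals$value)
    if (s == 0 || is.na(s)) {
      warn("constant burden values: all units labeled 'mid'")
      lower <- upper <- mean(vals$value)
      band <- rep("mid", nrow(vals))
    } else {
      lower <- mean(vals$value) - k * s
      upper <- mean(vals$value) + k * s
      band <- ifelse(vals$value > upper, "high",
                     ifelse(vals$value < lower, "low", "mid"))
    }
  } else {
    stopifnot(length(q) == 2, q[1] < q[2])
    qs <- quantile(vals$value, probs = q, names = FALSE)
    lower <- qs[1]
    upper <- qs[2]
    band <- ifelse(vals$value > upper, "high",
                   ifelse(vals$value < lower, "low", "mid"))
  }
  vals |>
    mutate(band = band, lower = lower, upper = upper,
           method = paste0(method, ":",
                           if (method == "sd") k else paste(q, collapse = "-")))
}

#' Hierarchically cluster a burden matrix (heatmap ordering)
#'
#' Agglomerative clustering of both axes of a burden matrix — the ordering
#' behind the burden heatmap.  Deterministic: `hclust` leaf order with ties
#' broken by input order.
#'
#' @param x A [burden_matrix()] (or tidy burden table, pivoted internally).
#' @param distance Distance measure passed to [stats::dist()]
#'   (default `"euclidean"`).
#' @param linkage Agglomeration method for [stats::hclust()]
#'   (default `"complete"`).
#' @return A `burden_clustering` object: `unit_order` and `type_order`
#'   (label character vectors), `unit_hclust` / `type_hclust` dendrograms,
#'   and the clustered `values` matrix.
#' @export
cluster_burden <- function(x, distance = "euclidean", linkage = "complete") {
  bm <- if (inherits(x, "burden_matrix")) x else burden_matrix(as_burden_tbl(x))
  values <- bm$values
  if (nrow(values) < 2 || ncol(values) < 2) {
    abort("need >= 2 units and >= 2 types to cluster")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort("burden matrix contains NA/NaN cells; clean before clustering")
  }
  hc_units <- hclust(dist(values, method = distance), method = linkage)
  hc_types <- hclust(dist(t(values), method = distance), method = linkage)
  structure(
    list(
      unit_order = rownames(values)[hc_units$order],
      type_order = colnames(values)[hc_types$order],
      unit_hclust = hc_units,
      type_hclust = hc_types,
      values = values[hc_units$order, hc_types$order, drop = FALSE],
      distance = distance,
      linkage = linkage,
      mode = bm$mode
    ),
    class = "burden_clustering"
  )
}

#' @export
print.burden_clustering <- function(x, ...) {
  cat(sprintf("<burden_clustering> %s/%s\n", x$distance, x$linkage))
  cat("unit order:", paste(x$unit_order, collapse = ", "), "\n")
  cat("type order:", paste(x$type_order, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname cluster_burden
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.burden_clustering <- function(x, ...) {
  as_tibble(x$values, rownames = "name") |>
    pivot_longer(-"name", names_to = "nonb_type", values_to = "burden") |>
    mutate(name = factor(.data$name, levels = x$unit_order),
           nonb_type = factor(.data$nonb_type, levels = x$type_order))
}

# ---- plots -----------------------------------------------------------------

#' Gene-screen plots
#'
#' Static ggplot2 renderings of the gene-screen views: stacked total-burden
#' bars, per-type burden distributions, the gene-by-type bubble plot, and
#' the clustered burden heatmap.
#'
#' @param x A tidy burden table or [burden_matrix()]
#'   (for `autoplot.burden_clustering`, a [cluster_burden()] result).
#' @param type For `plot_burden_distribution`, optional subset of types.
#' @param object,... `autoplot` arguments (`...` unused).
#' @return A ggplot object.
#' @name gene-screen-plots
NULL

#' @rdname gene-screen-plots
#' @export
plot_total_burden <- function(x) {
  tbl <- as_burden_tbl(x)
  order <- total_burden(tbl)$name
  ggplot(tbl, aes(x = factor(.data$name, levels = order), y = .data$burden,
                  fill = .data$nonb_type)) +
    geom_col() +
    labs(x = NULL, y = "non-B burden", fill = "non-B type",
         title = "Total non-B burden") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' @rdname gene-screen-plots
#' @export
plot_burden_distribution <- function(x, type = NULL) {
  tbl <- as_burden_tbl(x)
  if (!is.null(type)) tbl <- tbl |> filter(.data$nonb_type %in% type)
  ggplot(tbl, aes(x = .data$nonb_type, y = .data$burden)) +
    geom_boxplot(outlier.shape = NA, fill = "grey90") +
    geom_jitter(width = 0.15, height = 0, alpha = 0.7, size = 1) +
    labs(x = "non-B type", y = "non-B burden",
         title = "Burden distribution by non-B type") +
    theme_minimal()
}

#' @rdname gene-screen-plots
#' @export
plot_burden_composition <- function(x) {
  comp <- composition(x)
  ggplot(comp, aes(x = .data$nonb_type, y = .data$name,
                   size = .data$burden, colour = .data$fraction)) +
    geom_point() +
    scale_size_area(max_size = 10) +
    labs(x = "non-B type", y = NULL, size = "burden", colour = "fraction",
         title = "Non-B burden by unit and type") +
    theme_minimal()
}

#' @rdname gene-screen-plots
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.burden_matrix <- function(object, ...) {
  autoplot(cluster_burden(object))
}

#' @rdname gene-screen-plots
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.burden_clustering <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$name, y = .data$nonb_type,
                           fill = .data$burden)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = NULL, y = NULL, fill = object$mode %||% "burden",
         title = "Clustered non-B burden") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
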