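#' Probability-density histogram whose bars sum to one
#'
#' Bar height = count / total, so the heights always sum to exactly one —
#' the presentation used for locus-position distributions: a probability mass
#' per bin rather than a density per unit length.
#'
#' @param values numeric vector, nonempty.
#' @param bin_edges increasing vector of bin edges covering the data range;
#'   alternatively `bins` uniform bins over \[0, 1\] are used (the natural
#'   axis for normalized radial positions).
#' @param bins number of uniform bins when `bin_edges` is `NULL`. For
#'   micrometre distances pass explicit `bin_edges` (e.g. Freedman-Diaconis
#'   via [fd_bin_edges()]).
#' @param condition optional condition label.
#' @return A `pdf_histogram` object: tibble with `bin_lo`, `bin_hi`, `count`,
#'   `height`, plus attributes `n` and `condition`.
#' @export
pdf_histogram <- function(values, bin_edges = NULL, bins = 20L,
                          condition = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values))
    abort("`values` must be nonempty and finite")
  if (is.null(bin_edges)) bin_edges <- seq(0, 1, length.out = bins + 1L)
  if (is.unsorted(bin_edges, strictly = TRUE) || length(bin_edges) < 2)
    abort("`bin_edges` must be strictly increasing")
  if (min(values) < bin_edges[1] || max(values) > bin_edges[length(bin_edges)])
    abort("bins must cover the data range")
  nb <- length(bin_edges) - 1L
  bin <- pmin(pmax(findInterval(values, bin_edges, rightmost.closed = TRUE),
                   1L), nb)
  counts <- tabulate(bin, nb)
  out <- tibble(bin_lo = bin_edges[-length(bin_edges)],
                bin_hi = bin_edges[-1],
                count = counts,
                height = counts / length(values))
  structure(out, class = c("pdf_histogram", class(out)),
            n = length(values), condition = condition)
}

#' Freedman-Diaconis bin edges
#'
#' Standard data-driven bin width `2 * IQR / n^(1/3)` for micrometre distance
#' histograms, snapped to cover the data range.
#'
#' @param values numeric vector.
#' @return Vector of bin edges.
#' @export
fd_bin_edges <- function(values) {
  n <- length(values)
  iqr <- stats::IQR(values)
  width <- if (iqr > 0) 2 * iqr / n^(1 / 3) else diff(range(values)) / max(1, ceiling(sqrt(n)))
  if (width <= 0) width <- 1
  lo <- min(values); hi <- max(values)
  nb <- max(1L, ceiling((hi - lo) / width))
  seq(lo, lo + nb * width, length.out = nb + 1L)
}

#' @export
print.pdf_histogram <- function(x, ...) {
  cat(sprintf("<pdf_histogram> %d observations, %d bins, sum of heights = %.15g\n",
              attr(x, "n"), nrow(x), sum(x$height)))
  NextMethod()
}

#' @importFrom ggplot2 autoplot ggplot aes geom_col labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a probability-density histogram
#'
#' @param object a [pdf_histogram()].
#' @param ... unused.
#' @return A ggplot: one bar per bin, heights summing to one, with n in the
#'   subtitle.
#' @method autoplot pdf_histogram
#' @export
autoplot.pdf_histogram <- function(object, ...) {
  df <- tibble(mid = (object$bin_lo + object$bin_hi) / 2,
               width = object$bin_hi - object$bin_lo,
               height = object$height)
  ggplot(df, aes(x = .data$mid, y = .data$height)) +
    geom_col(width = df$width, fill = "steelblue", colour = "grey30") +
    labs(x = "value", y = "probability",
         title = attr(object, "condition") %||% "probability density",
         subtitle = sprintf("n = %d", attr(object, "n"))) +
    theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare the locus-position distributions of two conditions
#'
#' Builds per-condition probability-density histograms on shared bins and
#' summary statistics (n, median, mean, sd) of the chosen readout, and
#' reports the difference of medians (A minus B). No hypothesis test is
#' attached: the comparison is descriptive, distributions side by side.
#'
#' @param records_a,records_b distance-record tibbles (from
#'   [spot_lamin_distances()] or [radial_positions()]).
#' @param value_col readout column, present in both: `"normalized_position"`
#'   or `"distance_3d_um"`.
#' @param labels length-2 condition labels.
#' @param bin_edges shared bin edges; default 20 uniform bins over \[0, 1\]
#'   for normalized positions, Freedman-Diaconis over the pooled values for
#'   micrometre distances.
#' @return A `condition_comparison` object with `summary` (tibble),
#'   `histograms` (list of two [pdf_histogram()]s) and `diff_of_medians`.
#' @export
compare_conditions <- function(records_a, records_b,
                               value_col = "normalized_position",
                               labels = c("A", "B"), bin_edges = NULL) {
  if (nrow(records_a) == 0 || nrow(records_b) == 0)
    abort("both conditions must be nonempty")
  if (!value_col %in% names(records_a) || !value_col %in% names(records_b))
    abort(paste0("both conditions must carry the `", value_col, "` readout"))
  va <- records_a[[value_col]]; vb <- records_b[[value_col]]
  if (is.null(bin_edges)) {
    bin_edges <- if (value_col == "normalized_position") {
      seq(0, 1, length.out = 21L)
    } else {
      fd_bin_edges(c(va, vb))
    }
  }
  hists <- list(pdf_histogram(va, bin_edges, condition = labels[1]),
                pdf_histogram(vb, bin_edges, condition = labels[2]))
  summ <- tibble(condition = labels,
                 n = c(length(va), length(vb)),
                 median = c(median(va), median(vb)),
                 mean = c(mean(va), mean(vb)),
                 sd = c(sd(va), sd(vb)))
  structure(list(summary = summ, histograms = hists,
                 value_col = value_col, bin_edges = bin_edges,
                 diff_of_medians = median(va) - median(vb)),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> readout: %s\n", x$value_col))
  print(x$summary)
  cat(sprintf("difference of medians (%s - %s): %.4g\n",
              x$summary$condition[1], x$summary$condition[2],
              x$diff_of_medians))
  invisible(x)
}

#' @rdname compare_conditions
#' @param x a `condition_comparison`.
#' @param ... unused.
#' @method tidy condition_comparison
#' @export
tidy.condition_comparison <- function(x, ...) x$summary

#' @rdname compare_conditions
#' @method glance condition_comparison
#' @export
glance.condition_comparison <- function(x, ...) {
  tibble(value_col = x$value_col,
         n_a = x$summary$n[1], n_b = x$summary$n[2],
         median_a = x$summary$median[1], median_b = x$summary$median[2],
         diff_of_medians = x$diff_of_medians)
}

#' @rdname compare_conditions
#' @param object a `condition_comparison`.
#' @method autoplot condition_comparison
#' @export
autoplot.condition_comparison <- function(object, ...) {
  df <- purrr::map_dfr(object$histograms, function(h) {
    tibble(condition = attr(h, "condition"),
           mid = (h$bin_lo + h$bin_hi) / 2,
           width = h$bin_hi - h$bin_lo, height = h$height)
  })
  ggplot(df, aes(x = .data$mid, y = .data$height, fill = .data$condition)) +
    geom_col(width = df$width, position = "identity", alpha = 0.55,
             colour = "grey30") +
    labs(x = object$value_col, y = "probability") +
    theme_minimal()
}
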