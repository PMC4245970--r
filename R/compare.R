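# Comparison machinery: fragment distributions, Pearson correlations,
# normalization of external reactivity scales to theta.

#' Convert stop counts to fragment frequency distributions
#'
#' Divides the fragment count at each position by the total number of
#' fragments in the channel, so the distribution sums to 1.
#'
#' @param counts A count table with columns `index`, `plus_count`,
#'   `minus_count` (extra columns such as `target` are carried through
#'   grouping by target).
#' @param drop_full_length Drop the `k = 0` full-length bin before
#'   normalizing (default `FALSE`).
#' @return A long tibble with columns `index`, `channel`, `frequency`; the
#'   frequencies sum to 1 within each channel (and target).
#' @export
to_distribution <- function(counts, drop_full_length = FALSE) {
  stopifnot(is.data.frame(counts),
            all(c("index", "plus_count", "minus_count") %in% names(counts)))
  if (drop_full_length) counts <- filter(counts, .data$index > 0)
  long <- tidyr::pivot_longer(counts, c("plus_count", "minus_count"),
                              names_to = "channel", values_to = "count")
  long$channel <- sub("_count$", "", long$channel)
  grp <- intersect("target", names(long))
  long <- group_by(long, across(all_of(c(grp, "channel"))))
  totals <- summarise(long, total = sum(.data$count), .groups = "drop")
  if (any(totals$total <= 0)) {
    stop("distribution undefined: zero total count in channel ",
         paste(totals$channel[totals$total <= 0], collapse = ", "),
         call. = FALSE)
  }
  out <- ungroup(mutate(long, frequency = .data$count / sum(.data$count)))
  select(out, all_of(c(grp, "index", "channel", "frequency")))
}

#' Pearson product-moment correlation with explicit degenerate handling
#'
#' Positions where either vector is `NA` (no data) are dropped pairwise. A
#' constant vector makes the correlation undefined; `NA` is returned with a
#' warning rather than an arbitrary value.
#'
#' @param x,y Equal-length numeric vectors (length >= 2 after `NA` removal).
#' @return The correlation coefficient in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) {
    stop("need at least 2 paired observations", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined for a constant vector; returning NA")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Normalize an external reactivity scale to theta
#'
#' Converts reactivities from an arbitrary scale (e.g. capillary-
#' electrophoresis SHAPE reactivities) to the theta scale by dividing by a
#' normalization factor so they sum to 1 over the positions with data.
#' Negative inputs are clamped to 0 first (and flagged); `NA` no-data
#' positions propagate as `NA`.
#'
#' @param reactivities Numeric vector, `NA` = no data.
#' @return A numeric vector summing to 1 over non-`NA` positions, with a
#'   logical attribute `"clamped"` marking clamped positions.
#' @export
normalize_to_theta <- function(reactivities) {
  x <- as.numeric(reactivities)
  clamped <- !is.na(x) & x < 0
  x[clamped] <- 0
  tot <- sum(x, na.rm = TRUE)
  if (!any(!is.na(x)) || tot <= 0) {
    stop("cannot normalize: no positive reactivity values", call. = FALSE)
  }
  structure(x / tot, clamped = clamped)
}

#' Correlate two reactivity profiles over their common scored positions
#'
#' Replicate/variant comparisons align on the shared scored-position range
#' and drop no-data positions pairwise.
#'
#' @param a,b `reactivity_profile` objects (or tibbles with `index` and
#'   `theta` columns).
#' @return A one-row tibble: `n` positions compared and Pearson `r`.
#' @export
compare_profiles <- function(a, b) {
  grab <- function(p) {
    if (inherits(p, "reactivity_profile")) {
      filter(p$data, .data$scored)[, c("index", "theta")]
    } else {
      p[, c("index", "theta")]
    }
  }
  m <- dplyr::inner_join(grab(a), grab(b), by = "index",
                         suffix = c("_a", "_b"))
  tibble(n = nrow(m), r = pearson_cor(m$theta_a, m$theta_b))
}

#' Correlate fragment distributions between two count tables
#'
#' By default the full-length `k = 0` bin is excluded so the comparison is
#' over reactivity-bearing positions only.
#'
#' @param counts_a,counts_b Count tables (same target/length).
#' @param drop_full_length Exclude the `k = 0` bin (default `TRUE`).
#' @return A tibble with one row per channel: `channel`, `n`, `r`.
#' @export
compare_distributions <- function(counts_a, counts_b,
                                  drop_full_length = TRUE) {
  da <- to_distribution(counts_a, drop_full_length = drop_full_length)
  db <- to_distribution(counts_b, drop_full_length = drop_full_length)
  m <- dplyr::inner_join(da, db, by = c("index", "channel"),
                         suffix = c("_a", "_b"))
  m |>
    group_by(.data$channel) |>
    summarise(n = n(), r = pearson_cor(.data$frequency_a, .data$frequency_b),
              .groups = "drop")
}

#' Plot per-channel fragment distributions
#'
#' @param counts A count table with columns `index`, `plus_count`,
#'   `minus_count`.
#' @param drop_full_length Exclude the `k = 0` bin (default `FALSE`).
#' @return A ggplot object.
#' @export
plot_stop_counts <- function(counts, drop_full_length = FALSE) {
  d <- to_distribution(counts, drop_full_length = drop_full_length)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$frequency,
                                  fill = .data$channel)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "stop index (0 = full length)",
                  y = "fragment frequency") +
    ggplot2::theme_minimal()
}
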