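# Patient-interest mining: thresholded topic ratios, containment fractions,
# Welch t tests and Cohen's d with the published effect-size bands.

#' Threshold topic ratios at a noise floor
#'
#' A review's topic ratio is its theta entry — the proportion of the message
#' attributed to a topic. To suppress noise, ratios below the floor (default
#' `1/9`, the uniform value for the nine-label taxonomy) are set to 0;
#' ratios at or above it are unchanged.
#'
#' @param theta documents x L matrix of topic ratios (rows sum to 1).
#' @param floor noise floor in \[0, 1\]; default `1/9`.
#' @return The thresholded matrix, same shape and dimnames.
#' @export
topic_ratios <- function(theta, floor = 1 / 9) {
  if (floor < 0 || floor > 1) abort("floor must lie in [0, 1]")
  theta <- as.matrix(theta)
  theta[theta < floor] <- 0
  theta
}

#' Containment fraction per topic
#'
#' The fraction of reviews whose thresholded ratio for a topic is positive —
#' the share of messages that "contain" the topic, the bar heights of
#' group-comparison figures.
#'
#' @param ratios thresholded ratio matrix from [topic_ratios()].
#' @param group optional logical/integer index selecting a subset of rows.
#' @return Named numeric vector of per-topic fractions in \[0, 1\].
#' @export
containment_fraction <- function(ratios, group = NULL) {
  ratios <- as.matrix(ratios)
  if (!is.null(group)) ratios <- ratios[group, , drop = FALSE]
  if (nrow(ratios) == 0) abort("empty group")
  colMeans(ratios > 0)
}

#' Cohen's d from group summary statistics
#'
#' Standardized mean difference `(mean1 - mean2) / s_pooled` with the pooled
#' standard deviation
#' `s_pooled = sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2))`.
#' Zero pooled variance yields `NA` (undefined marker).
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return Numeric vector of d values.
#' @examples
#' cohens_d(1, 1, 50, 0, 1, 50)
#' @export
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (any(n1 < 2 | n2 < 2)) abort("cohens_d needs n >= 2 per group")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  ifelse(sp2 <= 0, NA_real_, (mean1 - mean2) / sqrt(sp2))
}

#' Two-sample t test from summary statistics
#'
#' Welch's test by default: `t = (mean1 - mean2) / sqrt(sd1^2/n1 + sd2^2/n2)`
#' with Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#' `var_equal = TRUE` gives the pooled-variance test with `n1 + n2 - 2`
#' degrees of freedom. Both variances zero yields `NA` markers.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summary statistics (vectorized).
#' @param var_equal use the pooled-variance test instead of Welch.
#' @return A tibble with columns `t`, `df`, `p_value`.
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2, var_equal = FALSE) {
  if (any(n1 < 2 | n2 < 2)) abort("welch_t needs n >= 2 per group")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- ifelse(se > 0, (mean1 - mean2) / se, NA_real_)
  p <- ifelse(is.na(t), NA_real_, 2 * pt(-abs(t), df))
  tibble::tibble(t = t, df = ifelse(is.na(t), NA_real_, df), p_value = p)
}

#' Recover t from a printed (delta-u, Cohen d) pair
#'
#' Consistency check for published summary triples: with
#' `s_pooled = delta_u / d`, the pooled-SE t statistic is
#' `t = delta_u / (s_pooled sqrt(1/n1 + 1/n2))`. Feeding a published delta-u
#' and d together with the group sizes should reproduce the published t
#' within the rounding of two-decimal inputs (about 1%).
#'
#' @param delta_u printed mean difference.
#' @param cohen_d printed effect size (nonzero).
#' @param n1,n2 group sizes.
#' @return The implied t statistic.
#' @examples
#' t_from_printed_summary(0.216, 1.58, 27374, 92610)
#' @export
t_from_printed_summary <- function(delta_u, cohen_d, n1, n2) {
  if (any(cohen_d == 0)) abort("cohen_d must be nonzero")
  s_pooled <- delta_u / cohen_d
  delta_u / (s_pooled * sqrt(1 / n1 + 1 / n2))
}

effect_band_levels <- c("small", "medium", "large", "very large", "huge")

#' Effect-size band for Cohen's d
#'
#' Buckets `|d|` on the published cut-points: small (< 0.01), medium
#' (0.01-0.20), large (0.20-0.50), very large (0.50-0.80), huge (>= 0.80,
#' including values above 2). Interval boundaries belong to the upper band.
#' Note these cut-points are the ones printed for this analysis framework;
#' they differ from the conventional Cohen/Sawilowsky thresholds.
#'
#' @param cohen_d numeric vector of effect sizes (sign ignored).
#' @return Factor with levels small < medium < large < very large < huge.
#' @examples
#' effect_band(c(0.005, 0.25, -1.55))
#' @export
effect_band <- function(cohen_d) {
  cut(abs(cohen_d), breaks = c(-Inf, 0.01, 0.20, 0.50, 0.80, Inf),
      labels = effect_band_levels, right = FALSE, ordered_result = TRUE)
}

#' Compare patient groups topic by topic
#'
#' The group-contrast engine: on thresholded topic ratios, computes per topic
#' the group means, SDs and sizes, the mean difference delta-u, pooled-SD
#' Cohen's d with its band, a Welch t test (the default inference), and the
#' per-group containment fractions for figure-style reporting. The t tests
#' operate on the continuous thresholded ratios, not on binary containment
#' indicators. A topic with zero variance in both groups gets `NA` statistics
#' without affecting the others. No multiplicity correction is applied by
#' default; set `p_adjust` to a [stats::p.adjust()] method to add one.
#'
#' @param ratios documents x L thresholded ratio matrix (see
#'   [topic_ratios()]).
#' @param group character/factor vector of group tags, parallel to the rows;
#'   `NA` rows (unmapped reviews) are dropped. Exactly two distinct groups
#'   must remain; `group1` is the first level (or `groups[1]`).
#' @param groups optional length-2 character vector fixing group order.
#' @param var_equal use the pooled-variance t test instead of Welch.
#' @param p_adjust optional multiple-testing correction method; default none.
#' @return A `"topic_comparison"` tibble with one row per topic: `label`,
#'   `group1`, `group2`, `n1`, `n2`, `mean1`, `mean2`, `sd1`, `sd2`,
#'   `delta_u`, `s_pooled`, `cohen_d`, `t`, `df`, `p_value`, `band`,
#'   `containment1`, `containment2`.
#' @seealso [mine_interests()] for the corpus-to-comparison pipeline.
#' @export
compare_groups <- function(ratios, group, groups = NULL, var_equal = FALSE,
                           p_adjust = NULL) {
  ratios <- as.matrix(ratios)
  if (length(group) != nrow(ratios)) {
    abort("group must have one tag per row of ratios")
  }
  keep <- !is.na(group)
  ratios <- ratios[keep, , drop = FALSE]
  group <- as.character(group[keep])
  groups <- groups %||% unique(group)
  if (length(setdiff(group, groups)) > 0) {
    abort("group tags outside the specified groups")
  }
  if (length(groups) != 2) abort("exactly two groups are required")
  i1 <- group == groups[1]
  i2 <- group == groups[2]
  if (!any(i1) || !any(i2)) abort("both groups must be non-empty")
  labels <- colnames(ratios) %||% as.character(seq_len(ncol(ratios)))

  m1 <- colMeans(ratios[i1, , drop = FALSE])
  m2 <- colMeans(ratios[i2, , drop = FALSE])
  s1 <- apply(ratios[i1, , drop = FALSE], 2, sd)
  s2 <- apply(ratios[i2, , drop = FALSE], 2, sd)
  n1 <- sum(i1)
  n2 <- sum(i2)
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  d <- cohens_d(m1, s1, n1, m2, s2, n2)
  tt <- welch_t(m1, s1, n1, m2, s2, n2, var_equal = var_equal)
  p <- tt$p_value
  if (!is.null(p_adjust)) p <- stats::p.adjust(p, method = p_adjust)

  out <- tibble::tibble(
    label = labels, group1 = groups[1], group2 = groups[2],
    n1 = n1, n2 = n2, mean1 = m1, mean2 = m2, sd1 = s1, sd2 = s2,
    delta_u = m1 - m2, s_pooled = sqrt(sp2), cohen_d = d,
    t = tt$t, df = tt$df, p_value = p, band = effect_band(d),
    containment1 = containment_fraction(ratios, i1),
    containment2 = containment_fraction(ratios, i2)
  )
  class(out) <- c("topic_comparison", class(out))
  out
}

#' Mine patient interests from a fitted topic model
#'
#' Pipeline convenience: takes labeled-LDA document-topic distributions,
#' applies the `1/L` noise floor, assigns patient groups under a grouping
#' scheme, and runs [compare_groups()].
#'
#' @param corpus the review corpus the theta rows belong to (row-aligned).
#' @param fit an `"lda_fit"`, or a theta matrix.
#' @param scheme a grouping scheme or packaged scheme name (see
#'   [load_grouping_scheme()]).
#' @param floor noise floor; default `1/9`.
#' @param ... passed to [compare_groups()].
#' @return A `"topic_comparison"` tibble.
#' @export
mine_interests <- function(corpus, fit, scheme, floor = 1 / 9, ...) {
  theta <- if (inherits(fit, "lda_fit")) fit$theta else as.matrix(fit)
  if (nrow(theta) != nrow(corpus)) {
    abort("theta rows must align with corpus rows")
  }
  if (is.character(scheme)) scheme <- load_grouping_scheme(scheme)
  corpus <- assign_group(corpus, scheme)
  ratios <- topic_ratios(theta, floor = floor)
  compare_groups(ratios, corpus$group, groups = scheme$groups, ...)
}

#' Format p-values for reports
#'
#' Truncated display style: values below the cutoff print as e.g. `"<.001"`;
#' exact values are kept everywhere else in the package.
#'
#' @param p numeric p-values.
#' @param cutoff truncation point; default 0.001.
#' @return Character vector.
#' @export
format_p <- function(p, cutoff = 0.001) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < cutoff, paste0("<", sub("^0", "", format(cutoff))),
                sub("^0", "", sprintf("%.3f", p))))
}

#' Plot a group comparison
#'
#' Containment-fraction bars per topic and group, annotated with the
#' effect-size band — the shape of the published group-comparison figures.
#'
#' @param object a `"topic_comparison"` from [compare_groups()].
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.topic_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("label", "group1", "group2",
                                "containment1", "containment2", "band")],
    cols = c("containment1", "containment2"),
    names_to = "side", values_to = "containment")
  long$group <- ifelse(long$side == "containment1", long$group1, long$group2)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$containment,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(
      data = tibble::as_tibble(object),
      ggplot2::aes(x = .data$label,
                   y = pmax(.data$containment1, .data$containment2) + 0.03,
                   label = as.character(.data$band)),
      inherit.aes = FALSE, size = 3) +
    ggplot2::labs(x = NULL, y = "share of messages containing the topic",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
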