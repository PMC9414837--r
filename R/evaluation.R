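# Agreement analysis between the computed index and the reference stream:
# Pearson correlation and Bland-Altman limits of agreement.

#' Pearson correlation coefficient
#'
#' Computed from its defining sum form,
#' \eqn{\sum (x_i-\bar x)(y_i-\bar y) / \sqrt{\sum (x_i-\bar x)^2 \sum (y_i-\bar y)^2}}.
#'
#' @param x,y Numeric vectors of equal length >= 3; both non-constant.
#' @return The correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  cx <- x - mean(x)
  cy <- y - mean(y)
  den <- sqrt(sum(cx^2) * sum(cy^2))
  if (den == 0) stop("constant input: correlation undefined", call. = FALSE)
  sum(cx * cy) / den
}

#' Bland-Altman agreement between index and reference
#'
#' Differences `d = index - reference` are computed on valid pairs only.
#' Reported are the bias `mean(d)`, the spread `sd(d)`, the limits of
#' agreement `bias +/- sd_mult * sd`, and the percentage of differences
#' falling inside the limits. The spread uses the sample standard deviation
#' (divisor `n - 1`) by default; `sd_type = "population"` switches to
#' divisor `n`.
#'
#' @param index Index values (e.g. the `tuned` column of a trace).
#' @param ref Reference values, same length.
#' @param valid Logical mask of usable pairs (default: pairs where both
#'   values are present). Pairs with `NA` in either series are always
#'   dropped.
#' @param sd_mult Limit multiplier (default 2).
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return A one-row tibble of class `ndoa_agreement`: `pearson_r`, `bias`,
#'   `sd`, `loa_lower`, `loa_upper`, `agreement_pct`, `n`.
#' @export
bland_altman <- function(index, ref, valid = NULL, sd_mult = 2,
                         sd_type = c("sample", "population")) {
  stopifnot(length(index) == length(ref))
  sd_type <- match.arg(sd_type)
  keep <- !is.na(index) & !is.na(ref)
  if (!is.null(valid)) keep <- keep & valid
  if (sum(keep) < 3) stop("fewer than 3 valid pairs", call. = FALSE)
  xi <- index[keep]
  yr <- ref[keep]
  d <- xi - yr
  n <- length(d)
  s <- stats::sd(d)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  bias <- mean(d)
  lo <- bias - sd_mult * s
  hi <- bias + sd_mult * s
  out <- tibble::tibble(
    pearson_r = if (stats::sd(xi) > 0 && stats::sd(yr) > 0) pearson_r(xi, yr) else NA_real_,
    bias = bias, sd = s, loa_lower = lo, loa_upper = hi,
    agreement_pct = 100 * mean(d >= lo & d <= hi), n = n
  )
  attr(out, "pairs") <- tibble::tibble(mean = (xi + yr) / 2, diff = d)
  class(out) <- c("ndoa_agreement", class(out))
  out
}

#' Plot a Bland-Altman agreement report
#'
#' Scatter of per-pair differences against per-pair means with the bias and
#' limits of agreement.
#'
#' @param object An `ndoa_agreement` from [bland_altman()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ndoa_agreement <- function(object, ...) {
  pairs <- attr(object, "pairs")
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "red", linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper)) +
    ggplot2::labs(x = "mean of index and reference", y = "difference (index - reference)")
}

#' Per-subject agreement report
#'
#' One row per subject with the Pearson correlation between the trace and
#' the valid reference seconds, plus a final `average` row holding the
#' arithmetic mean of the per-subject correlations (the pooled-summary row
#' convention of multi-subject monitor studies). Subjects are ordered by id.
#'
#' @param traces List of `ndoa_trace` objects (from [run_record()]).
#' @param logs List of matching `ndoa_datalog` objects (same subjects, any
#'   order).
#' @return A tibble with `subject_id`, `pearson_r`, `n`.
#' @export
per_subject_report <- function(traces, logs) {
  t_ids <- vapply(traces, function(tr) attr(tr, "subject_id"), character(1))
  l_ids <- vapply(logs, function(l) l$subject_id, character(1))
  if (!setequal(t_ids, l_ids) || anyDuplicated(t_ids) || anyDuplicated(l_ids)) {
    stop("traces and logs must carry the same (unique) subject ids", call. = FALSE)
  }
  ord <- order(t_ids)
  rows <- lapply(ord, function(i) {
    tr <- traces[[i]]
    log <- logs[[match(t_ids[i], l_ids)]]
    ann <- log$annotations
    keep <- valid_bis_mask(ann) & tr$valid & !is.na(tr$tuned)
    tibble::tibble(
      subject_id = t_ids[i],
      pearson_r = pearson_r(tr$tuned[keep], ann$bis[keep]),
      n = sum(keep)
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::bind_rows(out, tibble::tibble(
    subject_id = "average", pearson_r = mean(out$pearson_r), n = sum(out$n)
  ))
}
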