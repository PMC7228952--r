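#' One image's manual and automated counts
#'
#' @param image_id Identifier.
#' @param manual_counts Numeric vector of per-counter manual counts (MC).
#' @param ac Automated count (AC), nonnegative.
#' @param ac_corrected Optional bias-corrected automated count.
#' @return An object of class `count_record`.
#' @export
count_record <- function(image_id, manual_counts, ac, ac_corrected = NULL) {
  stop_if_not(length(manual_counts) >= 1, "manual_counts must be nonempty")
  stop_if_not(is.numeric(ac) && length(ac) == 1 && ac >= 0,
              "ac must be a single nonnegative number")
  structure(list(image_id = image_id,
                 manual_counts = as.numeric(manual_counts),
                 ac = ac, ac_corrected = ac_corrected),
            class = "count_record")
}

#' Automated counts for a set of annotated images
#'
#' Applies the trained model to every record's image (resized to
#' multiple-of-16 dimensions) and pairs the automated count with the
#' per-counter manual counts, yielding the [count_record()]s that the
#' correction and agreement statistics operate on.
#'
#' @param model A trained `unet_model`.
#' @param records Dataset records (see [generate_dataset()]).
#' @return List of `count_record`s.
#' @export
count_dataset <- function(model, records) {
  lapply(records, function(r) {
    rs <- resize_with_points(r$image$pixels, r$annotations)
    count_record(
      image_id = r$id,
      manual_counts = vapply(rs$points, function(a) nrow(a$points),
                             numeric(1)),
      ac = count_axons(model, rs$image))
  })
}

record_mc <- function(records) {
  vapply(records, function(r) mean(r$manual_counts), numeric(1))
}
record_ac <- function(records) {
  vapply(records, function(r) r$ac, numeric(1))
}
record_ac_best <- function(records) {
  vapply(records, function(r) {
    if (is.null(r$ac_corrected)) r$ac else r$ac_corrected
  }, numeric(1))
}

#' Fit the linear bias-correction equation on a validation subset
#'
#' Automated counting tools show a systematic, approximately linear bias
#' against manual counts. On a validation subset the automated count is
#' regressed on the mean manual count by ordinary least squares,
#' `AC = a * MC + b`; the fitted coefficients are later inverted by
#' [apply_correction()] to recalibrate counts on new images.
#'
#' @param records List of [count_record()]s (>= 3, with non-constant MC).
#' @return An object of class `correction_model` with `a`, `b`, `fit_n`,
#'   `fit_r2`.
#' @export
fit_correction <- function(records) {
  stop_if_not(length(records) >= 3, "need at least 3 records")
  mc <- record_mc(records)
  ac <- record_ac(records)
  stop_if_not(sd(mc) > 0, "manual counts must not all be identical")
  fit <- lm(ac ~ mc)
  a <- unname(coef(fit)[2])
  stop_if_not(a != 0, "degenerate fit: zero slope")
  r2 <- 1 - sum(residuals(fit)^2) / sum((ac - mean(ac))^2)
  structure(list(a = a, b = unname(coef(fit)[1]),
                 fit_n = length(records),
                 fit_r2 = r2),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf("correction: AC = %.4g * MC + %.4g (n = %d, R^2 = %.3f)\n",
              x$a, x$b, x$fit_n, x$fit_r2))
  invisible(x)
}

#' Invert the linear bias of an automated count
#'
#' `AC_corrected = (AC - b) / a`, the algebraic inverse of the fitted bias
#' relation, applied to counts from images outside the fitting subset.
#'
#' @param model A [fit_correction()] result (or any list with `a != 0` and
#'   `b`).
#' @param ac Automated count(s).
#' @return Corrected count(s).
#' @export
apply_correction <- function(model, ac) {
  stop_if_not(model$a != 0, "correction undefined for zero slope")
  (ac - model$b) / model$a
}

#' Apply a correction model to a list of count records
#'
#' @param model A `correction_model`.
#' @param records List of `count_record`s.
#' @return The records with `ac_corrected` filled in.
#' @export
correct_records <- function(model, records) {
  lapply(records, function(r) {
    r$ac_corrected <- apply_correction(model, r$ac)
    r
  })
}

#' Bland-Altman limits of agreement between automated and manual counts
#'
#' The count error is `AC_corrected - mean(MC)` per image; the limits of
#' agreement are the mean error plus/minus 1.96 sample standard deviations
#' of the error. Automated counts whose limits fall within the
#' inter-counter limits (individual MC against mean MC) agree with manual
#' counting as well as the human counters agree with each other.
#'
#' @param records List of `count_record`s (>= 2). Records without a
#'   corrected count fall back to the raw `ac`.
#' @return List with `bias_mean` and `loa = c(lower, upper)`.
#' @export
bland_altman <- function(records) {
  stop_if_not(length(records) >= 2, "need at least 2 records")
  err <- record_ac_best(records) - record_mc(records)
  m <- mean(err)
  s <- sd(err)
  list(bias_mean = m, loa = c(lower = m - 1.96 * s, upper = m + 1.96 * s))
}

#' Inter-counter limits of agreement
#'
#' The benchmark band for [bland_altman()]: limits of agreement of
#' individual counters' counts relative to the per-image mean manual count,
#' pooled over images and counters.
#'
#' @param records List of `count_record`s with >= 2 manual counts each.
#' @return List with `bias_mean` and `loa`.
#' @export
inter_counter_loa <- function(records) {
  err <- unlist(lapply(records, function(r) {
    r$manual_counts - mean(r$manual_counts)
  }))
  m <- mean(err)
  s <- sd(err)
  list(bias_mean = m, loa = c(lower = m - 1.96 * s, upper = m + 1.96 * s))
}

#' Success rate of corrected counts against the counters' 95% CI
#'
#' For images annotated by exactly four counters, the corrected automated
#' count is compared to the t-based 95% confidence interval of the mean
#' manual count (`mean +/- t(0.975, df = 3) * SD / 2`); the success rate is
#' the fraction of images whose corrected count falls inside its interval.
#' Records with a different number of counters are excluded with a warning.
#'
#' @param records List of `count_record`s.
#' @return Fraction in `[0, 1]`.
#' @export
success_rate <- function(records) {
  four <- Filter(function(r) length(r$manual_counts) == 4, records)
  if (length(four) < length(records)) {
    warning(sprintf("%d record(s) without exactly 4 counters excluded",
                    length(records) - length(four)))
  }
  stop_if_not(length(four) >= 1, "no records with 4 manual counts")
  hits <- vapply(four, function(r) {
    m <- mean(r$manual_counts)
    half <- qt(0.975, df = 3) * sd(r$manual_counts) / 2
    ac <- if (is.null(r$ac_corrected)) r$ac else r$ac_corrected
    ac >= m - half && ac <= m + half
  }, logical(1))
  mean(hits)
}

#' Inter-counter coefficient of variation
#'
#' Per image, the sample standard deviation of the counters' counts divided
#' by their mean; summarized by the median across images. Images whose mean
#' manual count is zero are excluded.
#'
#' @param records List of `count_record`s with >= 2 manual counts each.
#' @return List with `cov` (per-image values) and `median_cov`.
#' @export
cov_stats <- function(records) {
  cv <- vapply(records, function(r) {
    stop_if_not(length(r$manual_counts) >= 2,
                "coefficient of variation needs >= 2 counters")
    m <- mean(r$manual_counts)
    if (m == 0) NA_real_ else sd(r$manual_counts) / m
  }, numeric(1))
  cv <- cv[!is.na(cv)]
  list(cov = cv, median_cov = median(cv))
}

#' Full agreement report between automated and manual counts
#'
#' Combines the evaluation statistics: mean absolute error of the
#' (corrected) automated counts, R-squared of the corrected-count vs
#' manual-count regression, Bland-Altman bias and limits of agreement,
#' success rate against the four-counter 95% CI (when available), and the
#' median inter-counter coefficient of variation.
#'
#' @param records List of `count_record`s (corrected via
#'   [correct_records()]).
#' @return An object of class `agreement_report`.
#' @export
agreement_report <- function(records) {
  ac <- record_ac_best(records)
  mc <- record_mc(records)
  ba <- bland_altman(records)
  n4 <- sum(vapply(records, function(r) length(r$manual_counts) == 4,
                   logical(1)))
  sr <- if (n4 > 0) {
    suppressWarnings(success_rate(records))
  } else {
    NA_real_
  }
  multi <- Filter(function(r) length(r$manual_counts) >= 2, records)
  med_cov <- if (length(multi) >= 1) cov_stats(multi)$median_cov else NA_real_
  structure(list(mae = mean(abs(ac - mc)),
                 r2 = summary(lm(ac ~ mc))$r.squared,
                 bias_mean = ba$bias_mean,
                 loa = ba$loa,
                 success_rate = sr,
                 median_cov = med_cov,
                 n = length(records)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    paste0("agreement over %d images:\n",
           "  MAE            %.2f axons\n",
           "  R^2            %.3f\n",
           "  bias (mean)    %.2f axons\n",
           "  LoA            [%.2f, %.2f] axons\n",
           "  success rate   %s\n",
           "  median CoV     %s\n"),
    x$n, x$mae, x$r2, x$bias_mean, x$loa[1], x$loa[2],
    if (is.na(x$success_rate)) "-" else sprintf("%.0f%%",
                                                100 * x$success_rate),
    if (is.na(x$median_cov)) "-" else sprintf("%.3f", x$median_cov)))
  invisible(x)
}
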