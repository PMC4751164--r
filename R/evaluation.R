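#' Paired landmark errors between two sets of annotations
#'
#' Computes, per landmark and overall (pooled over all landmark-case pairs),
#' the mean, sample SD (n - 1) and median of the Euclidean distances between
#' matching landmarks in two equal-length lists of [landmark_set()]s --
#' the accuracy statistic conventionally reported for landmark detection
#' against a manual reference. Pairs with a landmark missing on either side
#' are skipped and counted.
#'
#' @param a,b equal-length lists of [landmark_set()]s with matching case
#'   order (case ids, when present, must agree).
#' @return object of class `paired_landmark_errors`: `table` (data.frame with
#'   landmark, n, mean, sd, median), `distances` (long data.frame), and
#'   `n_skipped`.
#' @export
landmark_errors <- function(a, b) {
  if (inherits(a, "landmark_set")) a <- list(a)
  if (inherits(b, "landmark_set")) b <- list(b)
  if (length(a) != length(b))
    abort("landmark set lists must have equal length", "pairing_error",
          stage = "evaluation")
  rows <- list()
  n_skipped <- 0L
  for (i in seq_along(a)) {
    ca <- attr(a[[i]], "case_id"); cb <- attr(b[[i]], "case_id")
    if (!is.null(ca) && !is.null(cb) && !identical(ca, cb))
      abort(sprintf("case id mismatch at position %d: %s vs %s", i, ca, cb),
            "pairing_error", stage = "evaluation")
    nms <- union(names(a[[i]]), names(b[[i]]))
    for (nm in nms) {
      pa <- a[[i]][[nm]]; pb <- b[[i]][[nm]]
      if (is.null(pa) || is.null(pb)) { n_skipped <- n_skipped + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        case = if (is.null(ca)) i else ca, landmark = nm,
        distance_mm = norm3(pa - pb), stringsAsFactors = FALSE)
    }
  }
  long <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case = integer(0), landmark = character(0),
               distance_mm = numeric(0))
  summarize <- function(d) c(n = length(d), mean = mean(d),
                             sd = if (length(d) > 1L) sd(d) else NA_real_,
                             median = median(d))
  tabs <- lapply(split(long$distance_mm, long$landmark), summarize)
  tab <- data.frame(landmark = names(tabs),
                    do.call(rbind, tabs), row.names = NULL)
  if (nrow(long) > 0L)
    tab <- rbind(tab, data.frame(landmark = "overall",
                                 t(summarize(long$distance_mm))))
  structure(list(table = tab, distances = long, n_skipped = n_skipped),
            class = "paired_landmark_errors")
}

#' @export
print.paired_landmark_errors <- function(x, ...) {
  cat("<paired_landmark_errors> Euclidean distances (mm)\n")
  print(x$table, row.names = FALSE, digits = 4)
  if (x$n_skipped > 0L)
    cat(sprintf("  (%d pairs skipped for missing landmarks)\n", x$n_skipped))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = x - y`; returns the mean difference, the sample SD of
#' differences, and the limits of agreement `mean +/- 1.96 * SD`.
#'
#' @param x,y paired measurements (equal length, n >= 2).
#' @return list of class `bland_altman`: `mean_diff`, `sd_diff`, `loa_lower`,
#'   `loa_upper`, `n`.
#' @export
bland_altman <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 2L)
    abort("bland_altman needs at least 2 pairs of equal length",
          "pairing_error", stage = "evaluation")
  d <- x - y
  m <- mean(d)
  s <- sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
                 n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d, mean difference %.3f (SD %.3f), LoA [%.3f, %.3f]\n",
              x$n, x$mean_diff, x$sd_diff, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from the
#' standard mean-squares decomposition (Shrout-Fleiss):
#' `(MSR - MSE) / (MSR + (k - 1) MSE + k (MSC - MSE) / n)` with `k = 2`
#' raters. Absolute agreement penalizes systematic offsets, matching its use
#' for method-versus-observer comparison. The consistency form ICC(3,1) is
#' available via `type = "consistency"`. Note the sample estimate is not
#' bounded below by -1 at small n; it converges to `[-1, 1]` asymptotically.
#'
#' @param x,y paired measurements from the two raters (n >= 3,
#'   non-constant).
#' @param type `"agreement"` (default, ICC(2,1)) or `"consistency"`
#'   (ICC(3,1)).
#' @return the ICC estimate (unitless).
#' @export
icc <- function(x, y, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L)
    abort("icc needs at least 3 pairs of equal length", "pairing_error",
          stage = "evaluation")
  if (sd(c(x, y)) < 1e-12)
    abort("icc is undefined for constant data", "undefined_icc_error",
          stage = "evaluation")
  n <- length(x); k <- 2
  grand <- mean(c(x, y))
  rowm <- (x + y) / 2
  colm <- c(mean(x), mean(y))
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((c(x, y) - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (type == "agreement")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (k - 1) * mse)
}
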