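#' Growth-performance and organ metrics
#'
#' Computes the eight trial metrics from a growth record, each exactly per
#' its conventional printed formula:
#' \itemize{
#'   \item WG\% = 100 x (final weight - initial weight) / initial weight
#'   \item SGR (\%/day) = 100 x (final weight - initial weight) / days
#'     (the printed linear form; set `sgr_log = TRUE` for the usual
#'     logarithmic variant 100 x (ln final - ln initial) / days)
#'   \item FE (\%) = 100 x weight gain (g) / feed intake (g/fish)
#'   \item ADFI (g/day/fish) = feed consumed / fish number / days
#'   \item survival (\%) = 100 x live fish at the end / live fish at the start
#'   \item HI = 100 x hepatopancreas weight / body weight
#'   \item ILI = 100 x intestine length / body length
#'   \item ISI = 100 x intestine weight / body weight
#' }
#' Weights are g/fish; lengths cm. A partial record yields the metrics its
#' fields allow; per-fish feed intake uses the live fish count at the end.
#'
#' @param rec Named list or one-row data frame with any of the fields
#'   `initial_weight`, `final_weight`, `feed_consumed`, `fish_n_start`,
#'   `fish_n_end`, `days`, `body_weight`, `body_length`,
#'   `hepatopancreas_weight`, `intestine_weight`, `intestine_length`.
#' @param sgr_log Use the logarithmic SGR variant (default `FALSE`).
#' @return Named numeric vector with the computable subset of
#'   `WG`, `SGR`, `FE`, `ADFI`, `survival`, `HI`, `ILI`, `ISI`.
#' @export
growth_metrics <- function(rec, sgr_log = FALSE) {
  rec <- as.list(rec)
  get <- function(f) if (!is.null(rec[[f]]) && !is.na(rec[[f]])) as.numeric(rec[[f]]) else NULL
  posit <- function(val, f) {
    if (!is.null(val) && val <= 0) stop("field '", f, "' must be positive")
    val
  }
  iw <- posit(get("initial_weight"), "initial_weight")
  fw <- posit(get("final_weight"), "final_weight")
  feed <- get("feed_consumed")
  n0 <- get("fish_n_start"); n1 <- get("fish_n_end")
  days <- get("days")
  bw <- posit(get("body_weight"), "body_weight")
  bl <- posit(get("body_length"), "body_length")
  hw <- get("hepatopancreas_weight")
  igw <- get("intestine_weight"); igl <- get("intestine_length")
  if (!is.null(n0) && !is.null(n1) && n1 > n0) {
    stop("fish_n_end exceeds fish_n_start")
  }
  if (!is.null(days) && days < 1) stop("days must be >= 1")

  out <- c()
  if (!is.null(iw) && !is.null(fw)) {
    out["WG"] <- 100 * (fw - iw) / iw
    if (!is.null(days)) {
      out["SGR"] <- if (sgr_log) 100 * (log(fw) - log(iw)) / days
                    else 100 * (fw - iw) / days
    }
  }
  if (!is.null(iw) && !is.null(fw) && !is.null(feed) && !is.null(n1)) {
    if (feed <= 0) stop("field 'feed_consumed' must be positive")
    if (n1 <= 0) stop("field 'fish_n_end' must be positive")
    out["FE"] <- 100 * (fw - iw) / (feed / n1)
  }
  if (!is.null(feed) && !is.null(n1) && !is.null(days)) {
    if (n1 <= 0) stop("field 'fish_n_end' must be positive")
    out["ADFI"] <- feed / n1 / days
  }
  if (!is.null(n0) && !is.null(n1)) {
    if (n0 <= 0) stop("field 'fish_n_start' must be positive")
    out["survival"] <- 100 * n1 / n0
  }
  if (!is.null(hw) && !is.null(bw)) out["HI"] <- 100 * hw / bw
  if (!is.null(igl) && !is.null(bl)) out["ILI"] <- 100 * igl / bl
  if (!is.null(igw) && !is.null(bw)) out["ISI"] <- 100 * igw / bw
  out
}

#' Background-corrected mean fluorescence density
#'
#' Implements the immunohistochemistry quantification
#' `mean density = (sum IntDen - mean background density x signal area)
#'  / whole-picture area`,
#' where `sum IntDen` is the total intensity over the signal mask, the mean
#' background density is the average over the background regions of each
#' region's per-pixel mean intensity, the signal area is the signal-mask
#' pixel count and the whole-picture area is the total pixel count.
#'
#' @param intensity Non-negative numeric matrix (the image).
#' @param signal_mask Logical matrix, same shape; an empty mask yields 0
#'   (with a message).
#' @param background_rois List of >= 1 logical matrices, same shape; an
#'   empty region is an error. Overlap with the signal mask is allowed but
#'   reported.
#' @return The mean density (intensity per pixel).
#' @export
mean_density <- function(intensity, signal_mask, background_rois) {
  intensity <- as.matrix(intensity)
  signal_mask <- as.matrix(signal_mask)
  stopifnot(is.numeric(intensity), all(intensity >= 0))
  if (!identical(dim(intensity), dim(signal_mask))) {
    stop("signal mask shape does not match the image")
  }
  if (!is.list(background_rois) || length(background_rois) < 1) {
    stop("need >= 1 background region")
  }
  signal_mask <- signal_mask != 0
  bg_means <- vapply(seq_along(background_rois), function(i) {
    roi <- as.matrix(background_rois[[i]]) != 0
    if (!identical(dim(roi), dim(intensity))) {
      stop("background region ", i, " shape does not match the image")
    }
    if (!any(roi)) stop("background region ", i, " is empty")
    if (any(roi & signal_mask)) {
      message("background region ", i, " overlaps the signal mask")
    }
    sum(intensity[roi]) / sum(roi)
  }, numeric(1))
  if (!any(signal_mask)) {
    message("empty signal mask: mean density 0")
    return(0)
  }
  int_den <- sum(intensity[signal_mask])
  signal_area <- sum(signal_mask)
  (int_den - mean(bg_means) * signal_area) / length(intensity)
}

#' Percent stained area of a mask
#'
#' @param mask Logical (or 0/1) matrix; must be non-empty.
#' @return `100 x true pixels / total pixels`.
#' @export
percent_area <- function(mask) {
  mask <- as.matrix(mask)
  if (length(mask) == 0) stop("mask is empty")
  100 * sum(mask != 0) / length(mask)
}

#' Two-group comparison by Welch t-test
#'
#' Two-sided unequal-variance t-test with a caller-supplied significance
#' level: 0.05 for growth-performance comparisons, 0.01 for morphometry.
#' Two constant groups with equal means give p = 1.
#'
#' @param values_a,values_b Numeric vectors, >= 2 values each.
#' @param alpha Significance level for the flag.
#' @return List with `p`, `significant`, `alpha`.
#' @export
group_compare <- function(values_a, values_b, alpha = 0.05) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2,
            alpha > 0, alpha < 1)
  p <- welch_p(values_a, values_b)
  list(p = p, significant = p < alpha, alpha = alpha)
}
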