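#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(template copies), the standard
#' absolute-quantification calibration. The amplification efficiency is
#' `10^(-1/slope) - 1`; a slope of `-1/log10(2) = -3.3219` corresponds to
#' perfect doubling per cycle (efficiency 1).
#'
#' @param points data frame with columns `copies` (> 0) and `ct`, or a
#'   `qpcr_run` (its `curve` element is used). At least two distinct copy
#'   levels are required.
#' @return a list of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `n_points`.
#' @export
fit_standard_curve <- function(points) {
  if (inherits(points, "qpcr_run")) points <- points$curve
  points <- as_tibble(points)
  stopifnot(all(c("copies", "ct") %in% names(points)))
  if (any(points$copies <= 0)) stop("copies must be > 0", call. = FALSE)
  if (length(unique(points$copies)) < 2) {
    stop("need >= 2 distinct copy levels", call. = FALSE)
  }
  x <- log10(points$copies)
  fit <- lm(ct ~ x, data = data.frame(x = x, ct = points$ct))
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((points$ct - mean(points$ct))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1,
                 n_points = nrow(points)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> Ct = %.4f %+.4f * log10(copies); R^2 = %.4f; efficiency = %.3f\n",
              x$intercept, x$slope, x$r_squared, x$efficiency))
  invisible(x)
}

#' Absolute quantification from a Ct value
#'
#' Inverts the standard curve: `copies = 10^((ct - intercept)/slope)`,
#' then `load = copies * conversion`. Cts that fall outside the curve's
#' calibrated range (1 to 10^7 copies by default) are still converted but
#' flagged as extrapolated.
#'
#' @param curve a [fit_standard_curve()] result.
#' @param ct observed quantification cycle(s).
#' @param conversion multiplicative copies -> CFU/ml factor (assay volume,
#'   dilution, marker copy number); default 1 keeps the result in copies.
#' @param curve_range copy range regarded as calibrated, for flagging.
#' @return a tibble with `ct`, `copies`, `load`, `extrapolated`.
#' @export
quantify <- function(curve, ct, conversion = 1,
                     curve_range = c(1, 1e7)) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope >= 0) stop("slope must be negative", call. = FALSE)
  copies <- 10^((ct - curve$intercept) / curve$slope)
  # small relative slack so values at the exact curve limits are in range
  flagged <- copies < curve_range[1] * (1 - 1e-9) |
    copies > curve_range[2] * (1 + 1e-9)
  if (any(flagged)) {
    warning(sum(flagged), " Ct value(s) outside the calibrated curve range; ",
            "loads extrapolated", call. = FALSE)
  }
  tibble(ct = ct, copies = copies, load = copies * conversion,
         extrapolated = flagged)
}

#' SFB positivity call at the assay detection limit
#'
#' Samples at or above the threshold load are called positive; samples
#' below it are treated as SFB-negative. The default threshold is the
#' assay detection limit of 1e4 CFU/ml of SFB (in a typical total
#' microbiota of ~1e11 CFU/ml); the boundary is inclusive.
#'
#' @param sfb_load numeric load(s), CFU/ml; must be >= 0.
#' @param threshold detection limit, CFU/ml.
#' @return logical vector: `TRUE` = SFB-positive.
#' @export
call_positivity <- function(sfb_load, threshold = 1e4) {
  if (any(sfb_load < 0)) stop("negative load", call. = FALSE)
  sfb_load >= threshold
}

#' Relative expression by the 2^-dCt method
#'
#' `2^-(ct_target - ct_reference)`: expression of a target gene relative
#' to a reference (housekeeping) gene such as actin.
#'
#' @param ct_target,ct_reference finite Ct values (vectorized).
#' @return fold expression relative to the reference gene.
#' @export
relative_expression <- function(ct_target, ct_reference) {
  stopifnot(all(is.finite(ct_target)), all(is.finite(ct_reference)))
  2^(-(ct_target - ct_reference))
}

#' Minimum detectable relative abundance of a taxon in a metagenome
#'
#' Under the Lander-Waterman model, sequencing depth `D` bases spread over
#' a community in which the taxon has relative abundance `a` gives the
#' taxon's genome (length `L`) expected coverage fraction
#' `1 - exp(-a*D/L)`. Requiring at least `min_cov_fraction` of the genome
#' covered for a confident detection yields the minimum detectable
#' abundance `a* = -L * log(1 - min_cov_fraction) / D`. This formalizes
#' why multi-gigabase shotgun sequencing can still miss a taxon at ~1e-6
#' relative abundance, motivating the targeted qPCR assay.
#'
#' @param depth_bp total sequenced bases.
#' @param genome_length_bp taxon genome length, bases.
#' @param min_cov_fraction required covered fraction of the genome, in
#'   (0, 1).
#' @return minimum detectable relative abundance (dimensionless).
#' @export
metagenome_detectability <- function(depth_bp, genome_length_bp,
                                     min_cov_fraction) {
  if (any(depth_bp <= 0) || any(genome_length_bp <= 0) ||
      any(min_cov_fraction <= 0)) {
    stop("all inputs must be > 0", call. = FALSE)
  }
  if (any(min_cov_fraction >= 1)) {
    stop("min_cov_fraction must be < 1", call. = FALSE)
  }
  -genome_length_bp * log(1 - min_cov_fraction) / depth_bp
}

#' Quantify a qPCR run end to end
#'
#' Fits the standard curve, averages replicate Cts per sample (mean by
#' default, median optionally), converts to loads, and calls positivity.
#'
#' @param run a `qpcr_run` (see [generate_qpcr_run()]) or a list with
#'   `curve` and `samples` tibbles.
#' @param conversion copies -> CFU/ml factor.
#' @param threshold positivity threshold, CFU/ml.
#' @param replicate_summary `"mean"` (default) or `"median"` Ct per
#'   (sample, target).
#' @return a tibble with `sample_id`, `target`, `ct`, `copies`, `load`,
#'   `extrapolated`, `positive`.
#' @export
quantify_run <- function(run, conversion = NULL, threshold = 1e4,
                         replicate_summary = c("mean", "median")) {
  replicate_summary <- match.arg(replicate_summary)
  if (is.null(conversion)) {
    conversion <- if (!is.null(run$conversion)) run$conversion else 1
  }
  curve <- fit_standard_curve(run$curve)
  s <- as_tibble(run$samples)
  agg <- stats::aggregate(ct ~ sample_id + target, data = s,
                          FUN = if (replicate_summary == "mean") mean else median)
  q <- quantify(curve, agg$ct, conversion = conversion)
  tibble(sample_id = agg$sample_id, target = agg$target, ct = agg$ct,
         copies = q$copies, load = q$load, extrapolated = q$extrapolated,
         positive = call_positivity(pmax(q$load, 0), threshold))
}
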