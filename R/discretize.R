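# Quantile / equal-width banding of continuous variables into the ordered
# states ("lower to higher bands") the belief network operates on.

#' Canonical ordered band labels
#' @param n number of bands.
#' @return character vector of `n` ordered labels; the canonical
#'   five-band set is `Very low, Low, Medium, High, Very high`.
#' @export
band_labels <- function(n) {
  if (n == 1L) return("All")
  if (n == 2L) return(c("Low", "High"))
  if (n == 3L) return(c("Low", "Medium", "High"))
  if (n == 4L) return(c("Very low", "Low", "High", "Very high"))
  if (n == 5L) return(c("Very low", "Low", "Medium", "High", "Very high"))
  paste("Band", seq_len(n))
}

#' Fit a banding scheme to training values
#'
#' Chooses `n_bins - 1` cut points from the data: the `quantile` method
#' (the default, reflecting the empirical distribution of the variable)
#' places them at the k/n empirical quantiles using the linear-interpolation
#' quantile definition (R type 7); `equal_width` divides the observed range
#' evenly; `explicit` takes user-supplied `boundaries`. Duplicate cut
#' points (heavily tied data) are collapsed with a warning, yielding fewer
#' bands. Band midpoints are the within-band medians of the fitting data
#' and carry each band's real-valued interpretation.
#'
#' @param values numeric vector of training values (non-empty, NA-free).
#' @param n_bins number of bands (>= 1). Ignored for `explicit`.
#' @param method `"quantile"`, `"equal_width"` or `"explicit"`.
#' @param labels optional ordered band names (defaults to [band_labels()]).
#' @param variable variable name recorded in the scheme.
#' @param boundaries strictly increasing cut points, `explicit` method only.
#' @return object of class `"bin_scheme"`: list with `variable`, `method`,
#'   `boundaries`, `labels`, `midpoints`, `range` (observed min/max of the
#'   fitting data).
#' @examples
#' fit_bins(1:100, n_bins = 5)$boundaries   # 20.8 40.6 60.4 80.2
#' @export
fit_bins <- function(values, n_bins = 5L,
                     method = c("quantile", "equal_width", "explicit"),
                     labels = NULL, variable = "x", boundaries = NULL) {
  method <- match.arg(method)
  values <- as.numeric(values)
  if (!length(values) || anyNA(values))
    stop_bbn("'values' must be non-empty and NA-free", "bbn_data_error")
  if (method != "explicit") {
    n_bins <- as.integer(n_bins)
    if (is.na(n_bins) || n_bins < 1L)
      stop_bbn("'n_bins' must be >= 1", "bbn_validation_error")
    b <- if (n_bins == 1L) numeric(0)
    else if (method == "quantile")
      unname(stats::quantile(values, seq_len(n_bins - 1L) / n_bins, type = 7))
    else
      seq(min(values), max(values), length.out = n_bins + 1L)[-c(1L, n_bins + 1L)]
  } else {
    if (is.null(boundaries))
      stop_bbn("'boundaries' required for method = 'explicit'",
               "bbn_validation_error")
    b <- as.numeric(boundaries)
    if (any(diff(b) <= 0))
      stop_bbn("'boundaries' must be strictly increasing", "bbn_validation_error")
    n_bins <- length(b) + 1L
  }
  # duplicate cut points (heavily tied data) and cut points at or below the
  # data minimum / above the maximum would leave empty bands: collapse them
  bu <- unique(b)
  bu <- bu[bu > min(values) & bu <= max(values)]
  if (length(bu) < length(b)) {
    warning(sprintf("variable '%s': %d degenerate boundary(ies) collapsed; %d band(s) instead of %d",
                    variable, length(b) - length(bu), length(bu) + 1L, n_bins),
            call. = FALSE)
    b <- bu
    n_bins <- length(b) + 1L
  }
  if (is.null(labels)) labels <- band_labels(n_bins)
  if (length(labels) != n_bins) labels <- band_labels(n_bins)

  band <- findInterval(values, b) + 1L
  lo_edge <- c(min(values), b)
  hi_edge <- c(b, max(values))
  midpoints <- vapply(seq_len(n_bins), function(k) {
    inb <- values[band == k]
    # empty bands can only arise with explicit boundaries; fall back to the
    # band centre, with open ends replaced by the observed min/max
    if (length(inb)) stats::median(inb) else (lo_edge[k] + hi_edge[k]) / 2
  }, 0)
  # guarantee strict monotonicity of midpoints (ties can arise from heavy
  # rounding in the fitting data); nudge by a negligible epsilon
  if (n_bins > 1L) {
    eps <- max(1e-9, 1e-9 * diff(range(values)))
    for (k in 2:n_bins)
      if (midpoints[k] <= midpoints[k - 1L])
        midpoints[k] <- midpoints[k - 1L] + eps
  }
  structure(list(variable = variable, method = method,
                 boundaries = b, labels = labels, midpoints = midpoints,
                 range = range(values)),
            class = "bin_scheme")
}

#' Map values onto the bands of a fitted scheme
#'
#' Bands are half-open intervals `[b_{k-1}, b_k)` — a value equal to a
#' boundary falls in the higher band — with the last band closed above.
#' Values outside the fitted range clamp to the outermost bands (test
#' seasons may exceed the training range; this is the documented
#' out-of-range behaviour, not an error).
#'
#' @param values numeric vector.
#' @param scheme a `"bin_scheme"` from [fit_bins()].
#' @return factor with levels = the scheme's band labels.
#' @export
apply_bins <- function(values, scheme) {
  stopifnot(inherits(scheme, "bin_scheme"))
  values <- as.numeric(values)
  if (anyNA(values))
    stop_bbn(sprintf("variable '%s': NA values cannot be banded",
                     scheme$variable), "bbn_data_error")
  idx <- findInterval(values, scheme$boundaries) + 1L
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' Five-band quantile scheme with the canonical output labels
#'
#' Output nodes of the tillage network are validated on 5x5 confusion
#' matrices whose axes read `Very low ... Very high`; this convenience
#' wrapper fits the corresponding 5-band quantile scheme.
#'
#' @param values training values of the variable.
#' @param variable variable name.
#' @return a `"bin_scheme"` with the canonical five labels (fewer if the
#'   training data forces a collapse).
#' @export
scheme_for_output <- function(values, variable = "x") {
  fit_bins(values, n_bins = 5L, method = "quantile",
           labels = band_labels(5L), variable = variable)
}

#' @export
print.bin_scheme <- function(x, digits = 4, ...) {
  cat(sprintf("Banding scheme for '%s' (%s): %d band(s)\n",
              x$variable, x$method, length(x$labels)))
  lo <- c(-Inf, x$boundaries); hi <- c(x$boundaries, Inf)
  for (k in seq_along(x$labels))
    cat(sprintf("  %-10s [%s, %s)  midpoint %s\n", x$labels[k],
                format(lo[k], digits = digits), format(hi[k], digits = digits),
                format(x$midpoints[k], digits = digits)))
  invisible(x)
}

#' @keywords internal
scheme_to_list <- function(s) {
  list(variable = s$variable, method = s$method,
       boundaries = as.numeric(s$boundaries), labels = s$labels,
       midpoints = as.numeric(s$midpoints), range = as.numeric(s$range))
}

#' @keywords internal
scheme_from_list <- function(l) {
  structure(list(variable = l$variable, method = l$method,
                 boundaries = as.numeric(l$boundaries),
                 labels = as.character(l$labels),
                 midpoints = as.numeric(l$midpoints),
                 range = as.numeric(l$range)),
            class = "bin_scheme")
}
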