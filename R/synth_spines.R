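# Synthetic dendritic spine geometry: shape classes ordered by the
# length-to-width ratio, from stubby/mushroom (mature) through thin and
# long-thin to filopodia-like (immature), and seeded sampling of spine
# populations from a class mixture.

#' Ratio bins of the five spine shape classes
#'
#' The scale-free length-to-width ratio orders spine shapes from stubby
#' (compact, mature) to filopodia-like (elongated, immature). Only the
#' ratio-2 boundary between the mature (< 2) and immature (> 2)
#' compartments is biologically canonical; the unit-wide bins within each
#' compartment follow the qualitative class ordering.
#'
#' @return data.frame with columns `class`, `lo`, `hi` (ratio bin
#'   `[lo, hi)`).
#' @export
spine_class_bins <- function() {
  data.frame(
    class = c("stubby", "mushroom", "thin", "long_thin", "filopodia"),
    lo = c(0, 1, 2, 3, 4),
    hi = c(1, 2, 3, 4, Inf),
    stringsAsFactors = FALSE
  )
}

#' Classify a length-to-width ratio into a spine shape class
#'
#' @param ratio numeric vector of positive length-to-width ratios.
#' @return character vector of class labels.
#' @examples
#' classify_ratio(c(0.7, 1.5, 2.5, 4.5))
#' @export
classify_ratio <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop_invalid("classify_ratio(): ratios must be finite and positive")
  }
  bins <- spine_class_bins()
  bins$class[findInterval(ratio, bins$lo)]
}

# Per-class generator defaults: ratio range actually sampled (inside the
# bin; stubby avoids ratios < 0.5 where the head would engulf the whole
# spine, filopodia are capped at 6) and a realistic length range in um.
spine_class_defaults <- function() {
  data.frame(
    class = c("stubby", "mushroom", "thin", "long_thin", "filopodia"),
    ratio_lo = c(0.55, 1.05, 2.05, 3.05, 4.05),
    ratio_hi = c(0.95, 1.95, 2.95, 3.95, 5.80),
    len_lo = c(0.60, 0.80, 1.20, 1.60, 2.00),
    len_hi = c(1.00, 1.50, 2.00, 2.60, 3.20),
    stringsAsFactors = FALSE
  )
}

#' Construct a single spine shape specification
#'
#' @param class_label one of `stubby`, `mushroom`, `thin`, `long_thin`,
#'   `filopodia`; must agree with `length/head_width`.
#' @param length curvilinear spine length in um (> 0), measured from the
#'   dendrite surface to the tip.
#' @param head_width maximal head diameter in um (> 0).
#' @param neck_width neck diameter in um, at most `head_width`.
#' @param orientation direction of the spine in the image plane, radians.
#' @param attachment arc position of the spine base along the dendrite
#'   core, um (assigned by the scene builder; may be `NA` until placed).
#' @param curvature optional in-plane curvature of the spine skeleton in
#'   1/um (0 = straight; the skeleton is then a circular arc).
#' @return `spine_shape_spec` object.
#' @export
spine_shape_spec <- function(class_label, length, head_width,
                             neck_width = 0.7 * head_width,
                             orientation = pi / 2, attachment = NA_real_,
                             curvature = 0) {
  bins <- spine_class_bins()
  if (!class_label %in% bins$class) {
    stop_invalid("unknown spine class '%s'", class_label)
  }
  if (!is.finite(length) || length <= 0 || !is.finite(head_width) ||
      head_width <= 0 || neck_width <= 0) {
    stop_invalid("spine length and widths must be strictly positive")
  }
  if (neck_width > head_width + 1e-12) {
    stop_invalid("neck_width must not exceed head_width")
  }
  ratio <- length / head_width
  if (classify_ratio(ratio) != class_label) {
    stop_invalid(
      "ratio %.3f outside the '%s' class bin", ratio, class_label)
  }
  structure(
    list(class_label = class_label, length = length, head_width = head_width,
         neck_width = neck_width, orientation = orientation,
         attachment = attachment, curvature = curvature, ratio = ratio),
    class = "spine_shape_spec"
  )
}

#' @export
print.spine_shape_spec <- function(x, ...) {
  cat(sprintf("spine [%s]: L = %.2f um, W = %.2f um, ratio = %.2f\n",
              x$class_label, x$length, x$head_width, x$ratio))
  invisible(x)
}

#' Sample spine shape specifications from a class mixture
#'
#' Draws `n` spines with class labels distributed according to `mixture`
#' and, within each class, a length-to-width ratio inside the class bin and
#' a length from a realistic per-class range. Reproducible for a fixed
#' seed.
#'
#' @param mixture named non-negative weights over the five class labels;
#'   must not be all zero.
#' @param n number of spines (>= 0).
#' @param seed integer seed.
#' @return list of [spine_shape_spec()] objects (unplaced: `attachment`
#'   is `NA`).
#' @examples
#' sp <- sample_spine_shapes(c(mushroom = 1, filopodia = 1), n = 4, seed = 1)
#' vapply(sp, function(s) s$class_label, "")
#' @export
sample_spine_shapes <- function(mixture, n, seed = 1) {
  if (n < 0) stop_invalid("sample_spine_shapes(): n must be >= 0")
  bins <- spine_class_bins()
  if (is.null(names(mixture)) || !all(names(mixture) %in% bins$class)) {
    stop_invalid("mixture must be named with spine class labels")
  }
  if (any(mixture < 0) || sum(mixture) <= 0) {
    stop_invalid("mixture weights must be non-negative with positive sum")
  }
  if (n == 0L) return(list())
  defs <- spine_class_defaults()
  with_seed(seed, {
    classes <- sample(names(mixture), n, replace = TRUE,
                      prob = mixture / sum(mixture))
    lapply(classes, function(cl) {
      d <- defs[defs$class == cl, ]
      ratio <- stats::runif(1, d$ratio_lo, d$ratio_hi)
      len <- stats::runif(1, d$len_lo, d$len_hi)
      w <- len / ratio
      spine_shape_spec(cl, length = len, head_width = w,
                       neck_width = w * stats::runif(1, 0.55, 0.85),
                       orientation = pi / 2)
    })
  })
}

#' Mixture presets for young-like and aged-like spine populations
#'
#' Young hippocampal dendrites carry more thin/filopodia-like (immature,
#' high-ratio) spines; aged dendrites are enriched in stubby and mushroom
#' (mature, low-ratio) shapes.
#'
#' @param kind `"young"` or `"aged"`.
#' @return named weight vector usable as `mixture` in
#'   [sample_spine_shapes()].
#' @export
spine_mixture_preset <- function(kind = c("young", "aged")) {
  kind <- match.arg(kind)
  if (kind == "young") {
    c(stubby = 0.10, mushroom = 0.25, thin = 0.30, long_thin = 0.20,
      filopodia = 0.15)
  } else {
    c(stubby = 0.25, mushroom = 0.40, thin = 0.20, long_thin = 0.10,
      filopodia = 0.05)
  }
}
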