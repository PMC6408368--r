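#' Resample an open curve to k equidistant points
#'
#' Points are placed at equal arc-length spacing along the input polyline
#' (linear interpolation; no smoothing spline), mirroring what curve-tracing
#' digitizers do when converting a traced outline into a fixed number of
#' semilandmarks. The first and last output points coincide with the curve
#' endpoints, and consecutive duplicate input points are dropped first.
#'
#' @param points Numeric matrix (>= 2 rows, 2 columns), an ordered open curve.
#' @param k Number of output points (>= 2).
#' @return A `k` x 2 matrix of points lying on the input polyline.
#' @export
resample_open_curve <- function(points, k) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("`points` must have two columns")
  if (k < 2L) stop("`k` must be at least 2")
  # drop consecutive duplicates
  if (nrow(points) > 1L) {
    keep <- c(TRUE, rowSums(abs(diff(points))) > 0)
    points <- points[keep, , drop = FALSE]
  }
  if (nrow(points) < 2L) stop("degenerate input: zero-length curve")
  seg <- sqrt(rowSums(diff(points)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate input: zero-length curve")
  target <- seq(0, total, length.out = k)
  out <- cbind(
    stats::approx(s, points[, 1], xout = target, ties = "ordered")$y,
    stats::approx(s, points[, 2], xout = target, ties = "ordered")$y
  )
  # guarantee exact endpoints regardless of rounding in cumsum
  out[1L, ] <- points[1L, ]
  out[k, ] <- points[nrow(points), ]
  out
}

#' Mirror a right-side shape to left-side orientation
#'
#' Negates x about the configuration centroid and relabels the side,
#' standardizing right-side bones to the left-hand orientation used when a
#' left element was not available. Point order is preserved. Applying it to
#' a shape already recorded as left is an error, so accidental double
#' reflection cannot silently flip a dataset.
#'
#' @param shape A [specimen_shape()] with `side == "right"`.
#' @return The reflected [specimen_shape()], `side == "left"`.
#' @export
mirror_reflect <- function(shape) {
  stopifnot(inherits(shape, "specimen_shape"))
  if (shape$side != "right") stop("mirror_reflect() expects a right-side shape")
  cx <- mean(shape$points[, 1])
  shape$points[, 1] <- 2 * cx - shape$points[, 1]
  shape$side <- "left"
  shape
}

#' Define a landmark scheme for one anatomical view
#'
#' A scheme declares, per view, how the digitized input maps onto a fixed
#' landmark configuration: standalone fixed landmarks come first, then one
#' block per curve in order. An `"open"` curve contributes `n` resampled
#' semilandmarks (endpoints fixed, interior sliding when `slide` is `TRUE`);
#' a `"crest"` curve contributes three points — its two endpoints as fixed
#' homologous landmarks plus one apex semilandmark that slides between them.
#'
#' @param view View label.
#' @param fixed_landmarks Character vector of standalone fixed-landmark names
#'   (may be empty).
#' @param curves Data.frame with columns `name`, `type` (`"open"` or
#'   `"crest"`), `n` (target semilandmark count, >= 2; ignored for crests),
#'   and `slide` (logical).
#' @return An object of class `landmark_scheme`.
#' @seealso [builtin_scheme()] for the astragalus and ungual schemes.
#' @export
landmark_scheme <- function(view, fixed_landmarks = character(), curves) {
  stopifnot(is.data.frame(curves),
            all(c("name", "type", "n", "slide") %in% names(curves)))
  curves$type <- match.arg(curves$type, c("open", "crest"), several.ok = TRUE)
  if (any(curves$type == "open" & curves$n < 2L)) {
    stop("open-curve target counts must be >= 2")
  }
  structure(
    list(view = view, fixed_landmarks = as.character(fixed_landmarks),
         curves = curves),
    class = "landmark_scheme"
  )
}

#' Total landmark count of a scheme
#' @param scheme A [landmark_scheme()].
#' @return Integer: standalone fixed landmarks plus per-curve contributions
#'   (`n` for open curves, 3 for crest curves).
#' @export
scheme_total <- function(scheme) {
  stopifnot(inherits(scheme, "landmark_scheme"))
  per_curve <- ifelse(scheme$curves$type == "crest", 3L, scheme$curves$n)
  length(scheme$fixed_landmarks) + sum(per_curve)
}

#' Built-in landmark schemes
#'
#' Two scheme families cover the eight canonical views. All six astragalar
#' views share one layout: a 25-semilandmark outline curve, the medial and
#' lateral trochlear crests each captured as two fixed endpoint landmarks
#' plus a sliding apex semilandmark, and a 10-semilandmark navicular-facet
#' curve (41 landmarks, 33 sliders). The two ungual views use a
#' 20-semilandmark outline of the ungual process plus two fixed landmarks
#' demarcating the process base (22 landmarks, 18 sliders). A
#' `"synthetic_outline"` scheme (single 25-point open curve) is used by the
#' synthetic-data module.
#'
#' @param view One of the eight canonical views or `"synthetic_outline"`.
#' @return A [landmark_scheme()].
#' @export
builtin_scheme <- function(view) {
  astragalar <- c("trochlear", "medial", "anterior", "plantar", "lateral", "posterior")
  if (view %in% astragalar) {
    landmark_scheme(
      view = view,
      curves = data.frame(
        name = c("outline", "medial_crest", "lateral_crest", "navicular_facet"),
        type = c("open", "crest", "crest", "open"),
        n = c(25L, NA_integer_, NA_integer_, 10L),
        slide = c(TRUE, TRUE, TRUE, TRUE)
      )
    )
  } else if (view %in% c("ungual_dorsal", "ungual_lateral")) {
    landmark_scheme(
      view = view,
      fixed_landmarks = c("process_base_dorsal", "process_base_plantar"),
      curves = data.frame(
        name = "outline", type = "open", n = 20L, slide = TRUE
      )
    )
  } else if (view == "synthetic_outline") {
    landmark_scheme(
      view = view,
      curves = data.frame(name = "outline", type = "open", n = 25L, slide = TRUE)
    )
  } else {
    stop("no built-in scheme for view: ", view)
  }
}

# apex landmark: point of maximum perpendicular distance from the endpoint
# chord; falls back to the midpoint index for a straight segment
curve_apex <- function(points) {
  a <- points[1L, ]; b <- points[nrow(points), ]
  ab <- b - a
  len <- sqrt(sum(ab^2))
  if (len < .Machine$double.eps) {
    return(points[ceiling(nrow(points) / 2), ])
  }
  nvec <- c(-ab[2], ab[1]) / len
  d <- abs(sweep(points, 2L, a) %*% nvec)
  points[which.max(d), ]
}

#' Assemble a specimen configuration from raw curves and fixed landmarks
#'
#' Applies a [landmark_scheme()] to one specimen's digitized raw data:
#' resamples each open curve to its target semilandmark count, extracts
#' endpoint landmarks and the apex semilandmark from crest curves, places
#' standalone fixed landmarks first, and generates the slider rows (interior
#' open-curve semilandmarks slide between their curve neighbours; crest
#' apices slide between their fixed endpoints; curve endpoints and fixed
#' landmarks never slide).
#'
#' @param curves Named list of raw polylines (2-column matrices), one per
#'   scheme curve, in any order but with names matching `scheme$curves$name`.
#' @param fixed_landmarks Named list (or `k` x 2 matrix with rownames) of
#'   standalone fixed-landmark coordinates; names must match
#'   `scheme$fixed_landmarks`.
#' @param scheme A [landmark_scheme()].
#' @param specimen_id,view,side,scale_mm_per_unit Passed to [specimen_shape()].
#' @return List with elements `shape` ([specimen_shape()], point count equal
#'   to [scheme_total()]) and `sliders` ([slider_table()]).
#' @export
assemble_configuration <- function(curves, fixed_landmarks = list(), scheme,
                                   specimen_id = "specimen", view = scheme$view,
                                   side = "left", scale_mm_per_unit = 1) {
  stopifnot(inherits(scheme, "landmark_scheme"))
  want_fixed <- scheme$fixed_landmarks
  if (length(want_fixed)) {
    if (is.matrix(fixed_landmarks)) {
      fixed_landmarks <- stats::setNames(
        lapply(seq_len(nrow(fixed_landmarks)), function(i) fixed_landmarks[i, ]),
        rownames(fixed_landmarks)
      )
    }
    missing <- setdiff(want_fixed, names(fixed_landmarks))
    if (length(missing)) {
      stop("missing fixed landmark(s): ", paste(missing, collapse = ", "))
    }
  }
  missing_curves <- setdiff(scheme$curves$name, names(curves))
  if (length(missing_curves)) {
    stop("missing curve(s): ", paste(missing_curves, collapse = ", "))
  }

  pts <- NULL
  before <- integer(); slider <- integer(); after <- integer()
  for (nm in want_fixed) pts <- rbind(pts, fixed_landmarks[[nm]])
  offset <- length(want_fixed)

  for (ci in seq_len(nrow(scheme$curves))) {
    cv <- scheme$curves[ci, ]
    raw <- as.matrix(curves[[cv$name]])
    if (cv$type == "open") {
      rs <- resample_open_curve(raw, cv$n)
      if (cv$slide && cv$n > 2L) {
        idx <- offset + seq(2L, cv$n - 1L)
        before <- c(before, idx - 1L)
        slider <- c(slider, idx)
        after <- c(after, idx + 1L)
      }
      pts <- rbind(pts, rs)
      offset <- offset + cv$n
    } else { # crest: endpoint, apex, endpoint
      if (nrow(raw) < 3L) stop("crest curve '", cv$name, "' needs >= 3 points")
      block <- rbind(raw[1L, ], curve_apex(raw), raw[nrow(raw), ])
      if (cv$slide) {
        before <- c(before, offset + 1L)
        slider <- c(slider, offset + 2L)
        after <- c(after, offset + 3L)
      }
      pts <- rbind(pts, block)
      offset <- offset + 3L
    }
  }

  shape <- specimen_shape(specimen_id, view, pts, side = side,
                          scale_mm_per_unit = scale_mm_per_unit)
  sliders <- slider_table(before, slider, after, n_landmarks = nrow(pts))
  list(shape = shape, sliders = sliders)
}
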