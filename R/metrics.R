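#' Structured 3D velocity field
#'
#' A structured-grid velocity field (components `u`, `v`, `w`, optional
#' pressure `p`) with uniform spacing, used by the helicity diagnostic and
#' the VTK/CSV exporters.
#'
#' @param u,v,w 3D numeric arrays of identical dimensions (m/s).
#' @param spacing Grid spacing `(dx, dy, dz)` in metres (positive; a single
#'   value is recycled).
#' @param p Optional pressure array (Pa) of the same dimensions.
#' @param periodic Logical; `TRUE` marks the field as periodic in all axes
#'   (finite differences then wrap around), as for the ABC flow.
#' @return An object of class `gridded_field`.
#' @seealso [abc_field()], [helicity_field()].
#' @export
gridded_field <- function(u, v, w, spacing, p = NULL, periodic = FALSE) {
  if (!is.array(u) || length(dim(u)) != 3) {
    abort_invalid("`u`, `v`, `w` must be 3D arrays.")
  }
  d <- dim(u)
  if (!identical(dim(v), d) || !identical(dim(w), d)) {
    abort_invalid("velocity components must share the same dimensions.")
  }
  if (!is.null(p) && !identical(dim(p), d)) {
    abort_invalid("`p` must match the velocity dimensions.")
  }
  spacing <- rep(as.double(spacing), length.out = 3)
  check_positive(spacing, "spacing")
  structure(list(u = u, v = v, w = w, p = p, spacing = spacing,
                 dim = d, periodic = isTRUE(periodic)),
            class = "gridded_field")
}

#' @export
print.gridded_field <- function(x, ...) {
  cat(sprintf("<gridded_field %d x %d x %d, spacing (%g, %g, %g) m%s%s>\n",
              x$dim[1], x$dim[2], x$dim[3], x$spacing[1], x$spacing[2],
              x$spacing[3], if (x$periodic) ", periodic" else "",
              if (is.null(x$p)) "" else ", with pressure"))
  invisible(x)
}

#' @method as_tibble gridded_field
#' @export
as_tibble.gridded_field <- function(x, ...) {
  d <- x$dim
  out <- tibble::tibble(
    x = rep((seq_len(d[1]) - 1) * x$spacing[1], times = d[2] * d[3]),
    y = rep(rep((seq_len(d[2]) - 1) * x$spacing[2], each = d[1]), times = d[3]),
    z = rep((seq_len(d[3]) - 1) * x$spacing[3], each = d[1] * d[2]),
    u = as.double(x$u), v = as.double(x$v), w = as.double(x$w)
  )
  if (!is.null(x$p)) out$p <- as.double(x$p)
  out
}

# second-order first derivative of a 3D array along one axis:
# central inside, one-sided second order at the ends (or periodic wrap)
fd_axis <- function(a, h, axis, periodic = FALSE) {
  d <- dim(a)
  n <- d[axis]
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(a, perm)
  dim(m) <- c(n, prod(d) / n)
  if (periodic) {
    out <- (m[c(2:n, 1), , drop = FALSE] -
              m[c(n, 1:(n - 1)), , drop = FALSE]) / (2 * h)
  } else {
    out <- matrix(0, n, ncol(m))
    out[2:(n - 1), ] <- (m[3:n, , drop = FALSE] -
                           m[1:(n - 2), , drop = FALSE]) / (2 * h)
    out[1, ] <- (-3 * m[1, ] + 4 * m[2, ] - m[3, ]) / (2 * h)
    out[n, ] <- (3 * m[n, ] - 4 * m[n - 1, ] + m[n - 2, ]) / (2 * h)
  }
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

#' Pointwise helicity density of a gridded field
#'
#' Helicity density \eqn{H = \mathbf{u} \cdot (\nabla \times \mathbf{u})},
#' expanded componentwise as
#' \eqn{u(\partial w/\partial y - \partial v/\partial z) +
#'      v(\partial u/\partial z - \partial w/\partial x) +
#'      w(\partial v/\partial x - \partial u/\partial y)}.
#' Derivatives are second-order central differences inside the domain and
#' one-sided second-order at boundaries (periodic wrapping when the field
#' is marked periodic). H scales quadratically with the velocity and is
#' invariant under `u -> -u`; it vanishes for uniform flow and for
#' solid-body rotation, and equals the squared speed for a Beltrami field.
#'
#' @param field A [gridded_field()] with at least 3 points per axis.
#' @return A 3D array of helicity density (m/s^2 scale, as the pointwise
#'   product of velocity and vorticity).
#' @examples
#' f <- abc_field(16)
#' h <- helicity_field(f)
#' max(abs(h - (f$u^2 + f$v^2 + f$w^2)))  # O(h^2) small
#' @export
helicity_field <- function(field) {
  if (!inherits(field, "gridded_field")) {
    abort_invalid("`field` must be a gridded_field.")
  }
  if (any(field$dim < 3)) {
    abort_invalid("helicity needs at least 3 grid points per axis.")
  }
  s <- field$spacing; per <- field$periodic
  curl_x <- fd_axis(field$w, s[2], 2, per) - fd_axis(field$v, s[3], 3, per)
  curl_y <- fd_axis(field$u, s[3], 3, per) - fd_axis(field$w, s[1], 1, per)
  curl_z <- fd_axis(field$v, s[1], 1, per) - fd_axis(field$u, s[2], 2, per)
  field$u * curl_x + field$v * curl_y + field$w * curl_z
}

#' Min / average / max summary of a quantity
#'
#' @param values Non-empty finite numeric vector.
#' @param quantity Label for the summarized quantity.
#' @return A one-row tibble `quantity`, `min`, `avg`, `max`
#'   (with `min <= avg <= max`).
#' @examples
#' summarize_metric(c(1, 2, 3), "wss")
#' @export
summarize_metric <- function(values, quantity = "value") {
  check_finite(values, "values")
  tibble::tibble(quantity = quantity, min = min(values),
                 avg = mean(values), max = max(values))
}

#' Default severity bands for WSS and pressure
#'
#' Ordered thresholds mapping a metric value to a `green` / `yellow` /
#' `red` severity category. For wall shear stress only the 0.4–1.5 Pa
#' physiological band for the average is an established reference value;
#' the remaining cutpoints (max: yellow above 1.5 Pa, red above 4.5 Pa;
#' min: yellow below 0.05 Pa) are illustrative configuration defaults.
#' Pressure bands map the min/avg/max to diastolic / mean / systolic norms
#' (60–90, 70–105, 90–140 mmHg, converted to Pa) and are entirely
#' illustrative defaults. Band edges belong to the lower-severity side
#' (conservative convention).
#'
#' @param quantity `"wss"` or `"pressure"`.
#' @return A named list (one entry per metric `min`, `avg`, `max`), each
#'   with increasing `breaks` and `categories` (length `breaks + 1`), plus
#'   attributes `quantity` and `illustrative`.
#' @export
severity_bands <- function(quantity = c("wss", "pressure")) {
  quantity <- match.arg(quantity)
  bands <- if (quantity == "wss") {
    list(
      min = list(breaks = 0.05, categories = c("yellow", "green")),
      avg = list(breaks = c(0.4, 1.5), categories = c("yellow", "green", "red")),
      max = list(breaks = c(1.5, 4.5), categories = c("green", "yellow", "red"))
    )
  } else {
    list(
      min = list(breaks = mmHg_to_Pa(c(50, 60, 90, 100)),
                 categories = c("red", "yellow", "green", "yellow", "red")),
      avg = list(breaks = mmHg_to_Pa(c(60, 70, 105, 115)),
                 categories = c("red", "yellow", "green", "yellow", "red")),
      max = list(breaks = mmHg_to_Pa(c(80, 90, 140, 160)),
                 categories = c("red", "yellow", "green", "yellow", "red"))
    )
  }
  attr(bands, "quantity") <- quantity
  attr(bands, "illustrative") <- TRUE
  bands
}

.severity_rank <- c(green = 1L, yellow = 2L, red = 3L)

classify_value <- function(value, breaks, categories) {
  if (length(categories) != length(breaks) + 1 || is.unsorted(breaks, strictly = TRUE)) {
    abort_invalid("invalid severity band: need strictly increasing breaks and breaks + 1 categories.")
  }
  i <- findInterval(value, breaks)    # value >= breaks[i]
  cat_here <- categories[i + 1]
  # a value sitting exactly on a break takes the lower-severity side
  if (i >= 1 && value == breaks[i]) {
    below <- categories[i]
    if (.severity_rank[below] < .severity_rank[cat_here]) cat_here <- below
  }
  cat_here
}

#' Classify a metric summary into severity categories
#'
#' Maps each of min / avg / max of a [summarize_metric()] row to a
#' green / yellow / red category using [severity_bands()]. The mapping is
#' deterministic, monotone (raising a value never lowers its severity
#' within the same side of the band), and assigns band edges to the
#' lower-severity category.
#'
#' @param summary A one-row tibble from [summarize_metric()].
#' @param bands A band set from [severity_bands()] (or the same structure).
#' @return A tibble of class `severity_report` with columns `metric`,
#'   `value`, `category`, and the bands attached as an attribute.
#' @examples
#' classify_severity(summarize_metric(c(0.03, 0.041, 0.07), "wss"),
#'                   severity_bands("wss"))
#' @export
classify_severity <- function(summary, bands) {
  if (!is.data.frame(summary) || !all(c("min", "avg", "max") %in% names(summary))) {
    abort_invalid("`summary` must have columns min, avg, max.")
  }
  if (!all(c("min", "avg", "max") %in% names(bands))) {
    abort_invalid("`bands` must provide entries for min, avg and max.")
  }
  out <- purrr::map_dfr(c("min", "avg", "max"), function(m) {
    v <- summary[[m]][1]
    check_scalar(v, paste0("summary$", m))
    tibble::tibble(metric = m, value = v,
                   category = classify_value(v, bands[[m]]$breaks,
                                             bands[[m]]$categories))
  })
  if (!is.null(summary$quantity)) out$quantity <- summary$quantity[1]
  attr(out, "bands") <- bands
  class(out) <- c("severity_report", class(out))
  out
}
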