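# Plot extraction: generate plot polygons from a field layout, project them
# into georeferenced images, pick the image where each plot is most central,
# and produce a rectified, upright plot crop.
#
# The per-image world->pixel homography is a supplied input (pose estimation
# and mosaicking are delegated to photogrammetry software); this module only
# consumes it.

#' Describe a field layout
#'
#' A trial laid out as `n_columns` x `n_rows` two-row plots.  Plot
#' rectangles are `plot_length` long; their width is `row_spacing` plus a
#' margin split evenly on both sides.  Field coordinates put columns along
#' x and plot rows along y; `field_bearing` rotates the whole field
#' (degrees, counter-clockwise) and `origin` translates it into world
#' coordinates.
#'
#' @param n_columns,n_rows grid dimensions.
#' @param plot_length plot length in meters (default 5).
#' @param row_spacing spacing between a plot's two rows in meters
#'   (default 0.76).
#' @param inter_plot_gap gap between consecutive plots along a column in
#'   meters (default 1).
#' @param margin extra plot width beyond the two rows in meters
#'   (default 0.76, split evenly).
#' @param origin world (x, y) of the corner of plot (1, 1)'s cell.
#' @param field_bearing rotation of the field in degrees.
#' @return Object of class `field_layout`.
#' @export
field_layout <- function(n_columns, n_rows, plot_length = 5,
                         row_spacing = 0.76, inter_plot_gap = 1,
                         margin = 0.76, origin = c(0, 0),
                         field_bearing = 0) {
  stopifnot(is_count(n_columns), is_count(n_rows), plot_length > 0,
            row_spacing > 0, inter_plot_gap > 0, margin >= 0)
  structure(list(n_columns = as.integer(n_columns),
                 n_rows = as.integer(n_rows),
                 plot_length = plot_length, row_spacing = row_spacing,
                 inter_plot_gap = inter_plot_gap, margin = margin,
                 origin = as.numeric(origin),
                 field_bearing = field_bearing),
            class = "field_layout")
}

#' Read a field layout from YAML
#'
#' @param path YAML file with the [field_layout()] fields.
#' @return A `field_layout`.
#' @export
read_field_layout <- function(path) {
  if (!file.exists(path)) stopf("layout file not found: %s", path)
  do.call(field_layout, yaml::read_yaml(path))
}

#' Generate world-coordinate plot rectangles
#'
#' One rectangle per plot, corners ordered counter-clockwise starting at
#' the plot's (low-x, low-y) corner, rotated by the field bearing and
#' translated by the layout origin.
#'
#' @param layout a [field_layout()].
#' @return List of entries with `plot_id` (`c(column, row)`) and `corners`
#'   (4 x 2 matrix of world (x, y)).
#' @export
plot_polygons <- function(layout) {
  stopifnot(inherits(layout, "field_layout"))
  w <- layout$row_spacing + layout$margin
  pitch_y <- layout$plot_length + layout$inter_plot_gap
  th <- layout$field_bearing * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  out <- vector("list", layout$n_columns * layout$n_rows)
  k <- 0L
  for (col in seq_len(layout$n_columns)) {
    for (row in seq_len(layout$n_rows)) {
      x0 <- (col - 1L) * w
      y0 <- (row - 1L) * pitch_y
      corners <- rbind(c(x0, y0), c(x0 + w, y0),
                       c(x0 + w, y0 + layout$plot_length),
                       c(x0, y0 + layout$plot_length))
      corners <- sweep(corners %*% t(rot), 2L, layout$origin, `+`)
      k <- k + 1L
      out[[k]] <- list(plot_id = c(column = col, row = row),
                       corners = corners)
    }
  }
  out
}

#' Read per-image georeference transforms
#'
#' @param path JSON list of objects with fields `image_id`, `homography`
#'   (3x3 world->pixel matrix, row-major), `height`, `width`.
#' @return Named list of georef objects (`image_id`, `H`, `size`).
#' @export
read_georefs <- function(path) {
  if (!file.exists(path)) stopf("georef file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  geos <- lapply(seq_len(nrow(raw)), function(i) {
    H <- matrix(unlist(raw$homography[i]), 3L, 3L, byrow = TRUE)
    if (abs(det(H)) < 1e-12)
      stopf("georef for image '%s' is singular", raw$image_id[i])
    list(image_id = raw$image_id[i], H = H,
         size = c(raw$height[i], raw$width[i]))
  })
  names(geos) <- raw$image_id
  geos
}

# Apply a 3x3 homography to world (x, y) points, with perspective division.
# Pixel output is (col = x, row = y), 1-based.
apply_homography <- function(H, xy) {
  p <- cbind(xy, 1) %*% t(H)
  w <- p[, 3]
  bad <- abs(w) < 1e-9
  cbind(col = p[, 1] / w, row = p[, 2] / w, valid = !bad)
}

#' Project a world plot rectangle into an image
#'
#' @param rect 4 x 2 matrix of world (x, y) corners.
#' @param georef one element of [read_georefs()].
#' @return List (class `plot_instance`): `image_id`, `quad` (4 x 2 matrix of
#'   pixel (row, col)), `valid` (all vertices finite and inside the image),
#'   `center_distance` (centroid to image center, pixels).
#' @export
project_plot <- function(rect, georef) {
  p <- apply_homography(georef$H, rect)
  quad <- cbind(row = p[, "row"], col = p[, "col"])
  sz <- georef$size
  valid <- all(p[, "valid"] == 1) &&
    all(quad[, "row"] >= 1 & quad[, "row"] <= sz[1] &
          quad[, "col"] >= 1 & quad[, "col"] <= sz[2])
  center <- c((sz[1] + 1) / 2, (sz[2] + 1) / 2)
  centroid <- colMeans(quad)
  structure(list(image_id = georef$image_id, quad = quad,
                 valid = isTRUE(valid),
                 center_distance = sqrt(sum((centroid - center)^2))),
            class = "plot_instance")
}

#' Select the most central instance of a plot
#'
#' Among the images a plot projects into, picks the valid instance whose
#' quadrilateral centroid has the shortest Euclidean distance to the image
#' center; ties go to the lexicographically smallest image id.
#'
#' @param instances list of `plot_instance` objects.
#' @return The selected `plot_instance`.
#' @export
select_best_instance <- function(instances) {
  ok <- Filter(function(x) isTRUE(x$valid), instances)
  if (!length(ok)) stopf("no valid instance of this plot in any image")
  d <- vapply(ok, `[[`, numeric(1), "center_distance")
  ids <- vapply(ok, `[[`, character(1), "image_id")
  ok[[order(d, ids)[1]]]
}

# Homography mapping output-rectangle pixel coords (row, col) to source
# quad pixel coords, by direct linear transform on the 4 corners.
solve_quad_homography <- function(quad, out_h, out_w) {
  dst <- rbind(c(1, 1), c(1, out_w), c(out_h, out_w), c(out_h, 1))
  src <- quad
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- dst[i, 2]; y <- dst[i, 1]       # (col, row) of output
    u <- src[i, 2]; v <- src[i, 1]       # (col, row) of source
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -x * u, -y * u)
    A[2 * i, ] <- c(0, 0, 0, x, y, 1, -x * v, -y * v)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  h <- solve(A, b)
  matrix(c(h, 1), 3L, 3L, byrow = TRUE)
}

#' Crop and rectify a plot quadrilateral
#'
#' Maps the quadrilateral to an upright rectangle with the plot's world
#' aspect ratio at the stated ground sampling distance (long axis vertical)
#' using the full perspective transform and bilinear resampling.  Source
#' pixels falling outside the image are filled black and flagged via the
#' `"clipped"` attribute.
#'
#' @param img the source [rgb_image()].
#' @param quad 4 x 2 matrix of pixel (row, col) corners, ordered around the
#'   quadrilateral and starting at the corner that maps to the rectified
#'   plot's top-left.
#' @param plot_size world (length, width) of the plot in meters.
#' @param gsd ground sampling distance in cm/pixel (default 0.45).
#' @return Rectified [rgb_image()] of size
#'   `round(100 * plot_size / gsd)` pixels.
#' @export
crop_and_rotate <- function(img, quad, plot_size = c(5, 1.52),
                            gsd = 0.45) {
  img <- rgb_image(img)
  if (!is.matrix(quad) || !identical(dim(quad), c(4L, 2L)))
    stopf("`quad` must be a 4 x 2 matrix of (row, col) corners")
  # shoelace area in pixel coords; degenerate quads cannot be rectified
  x <- quad[, 2]; y <- quad[, 1]
  area <- abs(sum(x * y[c(2:4, 1)] - x[c(2:4, 1)] * y)) / 2
  if (area < 1) stopf("degenerate (zero-area) quadrilateral")
  dims <- sort(round(100 * plot_size / gsd), decreasing = TRUE)
  out_h <- dims[1]; out_w <- dims[2]    # long axis vertical
  H <- solve_quad_homography(quad, out_h, out_w)
  grid <- cbind(rep(seq_len(out_w), each = out_h),
                rep(seq_len(out_h), times = out_w))  # (x=col, y=row)
  src <- apply_homography(H, grid)
  sc <- src[, "col"]; sr <- src[, "row"]
  d <- dim(img)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  inb <- sr >= 1 & sc >= 1 & sr <= d[1] & sc <= d[2] & src[, "valid"] == 1
  r1 <- pmin(r0 + 1, d[1]); c1 <- pmin(c0 + 1, d[2])  # clamp exact edges
  out <- array(0, dim = c(out_h, out_w, 3L))
  if (any(inb)) {
    lin <- function(r, c) (c - 1L) * d[1] + r
    i00 <- lin(r0[inb], c0[inb]); i10 <- lin(r1[inb], c0[inb])
    i01 <- lin(r0[inb], c1[inb]); i11 <- lin(r1[inb], c1[inb])
    wfr <- fr[inb]; wfc <- fc[inb]
    for (ch in 1:3) {
      plane <- img[, , ch]
      val <- plane[i00] * (1 - wfr) * (1 - wfc) +
        plane[i10] * wfr * (1 - wfc) +
        plane[i01] * (1 - wfr) * wfc +
        plane[i11] * wfr * wfc
      page <- matrix(0, out_h, out_w)
      page[inb] <- val
      out[, , ch] <- page
    }
  }
  res <- rgb_image(round(out))
  attr(res, "clipped") <- any(!inb)
  res
}

#' Extract the best rectified image of every plot
#'
#' Convenience driver: projects each plot rectangle into all georeferenced
#' images, selects the most central valid instance, and rectifies it.
#'
#' @param layout a [field_layout()].
#' @param georefs named list from [read_georefs()].
#' @param read_fn function mapping an image id to an [rgb_image()] (e.g. a
#'   closure around [read_image()]).
#' @param gsd ground sampling distance in cm/pixel.
#' @return Named list `plot_<col>_<row>` of entries with `instance` and
#'   `image` (the rectified crop); plots visible in no image are skipped
#'   with a message.
#' @export
extract_plots <- function(layout, georefs, read_fn, gsd = 0.45) {
  polys <- plot_polygons(layout)
  plot_w <- layout$row_spacing + layout$margin
  out <- list()
  for (p in polys) {
    inst <- lapply(georefs, function(g) project_plot(p$corners, g))
    best <- tryCatch(select_best_instance(inst), error = function(e) NULL)
    nm <- sprintf("plot_%d_%d", p$plot_id[["column"]], p$plot_id[["row"]])
    if (is.null(best)) {
      message(sprintf("%s: visible in no image, skipped", nm))
      next
    }
    img <- read_fn(best$image_id)
    out[[nm]] <- list(
      instance = best,
      image = crop_and_rotate(img, best$quad,
                              plot_size = c(layout$plot_length, plot_w),
                              gsd = gsd))
  }
  out
}
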