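#' Build the periodic-disturbance channel footprint
#'
#' Planar mid-depth footprint of the mixing channel: a straight rectangular
#' channel of the given width carrying semicircular wall obstacles whose
#' centre of curvature alternates between the bottom and top wall, so the
#' centripetal force vector flips by 180 degrees obstacle to obstacle. The
#' narrowest passage is `width - obstacle_radius` at each obstacle apex. With
#' the default dimensions (width 300 um, radius 260 um, 90 obstacles) the
#' straight-line path is 47.5 mm and the narrowest gap 40 um. Zero obstacles
#' gives a straight rectangular channel.
#'
#' @param width channel width (m); the depth is carried along for converting
#'   flow rates to the planar model.
#' @param depth channel depth (m).
#' @param obstacle_radius semicircle radius (m), must be positive and smaller
#'   than `width`.
#' @param obstacle_count number of semicircular obstacles (>= 0).
#' @param total_length straight-line channel length (m). If `NULL` it is
#'   derived as `2 * lead + obstacle_count * pitch`.
#' @param lead obstacle-free entry/exit length (m) at each end.
#' @param pitch centre-to-centre obstacle spacing (m); by default spread
#'   evenly over `total_length - 2 * lead`. Exposed because the published
#'   drawing fixes only radius and count.
#' @return An object of class `channel_geometry`.
#' @examples
#' g <- build_geometry()
#' g$total_length # 0.0475
#' g$gap          # 4e-05
#' @export
build_geometry <- function(width = 300e-6, depth = 300e-6,
                           obstacle_radius = 260e-6, obstacle_count = 90,
                           total_length = if (obstacle_count > 0) 47.5e-3 else 2e-3,
                           lead = 0.75e-3, pitch = NULL) {
  for (v in c(width, depth, lead)) {
    if (!is.numeric(v) || length(v) != 1 || v <= 0) {
      stop_invalid("dimensions must be positive numbers")
    }
  }
  if (!is.numeric(obstacle_count) || obstacle_count < 0 ||
      obstacle_count != round(obstacle_count)) {
    stop_invalid("'obstacle_count' must be a non-negative integer")
  }
  obstacle_count <- as.integer(obstacle_count)
  if (obstacle_count > 0) {
    if (!is.numeric(obstacle_radius) || obstacle_radius <= 0) {
      stop_invalid("'obstacle_radius' must be positive")
    }
    if (obstacle_radius >= width) {
      stop_invalid("'obstacle_radius' must be smaller than the channel width ",
                   "(the obstacle would seal the channel)")
    }
  }
  if (is.null(pitch)) {
    if (is.null(total_length)) {
      stop_invalid("give either 'total_length' or 'pitch'")
    }
    pitch <- if (obstacle_count > 0) {
      (total_length - 2 * lead) / obstacle_count
    } else {
      0
    }
  } else if (is.null(total_length)) {
    total_length <- 2 * lead + obstacle_count * pitch
  }
  if (obstacle_count > 0 && pitch <= 0) {
    stop_invalid("channel too short for the requested obstacles")
  }
  centers <- if (obstacle_count > 0) {
    lead + (seq_len(obstacle_count) - 0.5) * pitch
  } else {
    numeric(0)
  }
  sides <- rep(c("bottom", "top"), length.out = obstacle_count)
  structure(
    list(
      width = width, depth = depth, obstacle_radius = obstacle_radius,
      obstacle_count = obstacle_count, total_length = total_length,
      lead = lead, pitch = pitch, centers = centers, sides = sides,
      gap = if (obstacle_count > 0) width - obstacle_radius else width
    ),
    class = "channel_geometry"
  )
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf(
    "Channel footprint: %.0f um wide, %.1f mm long, %d obstacle(s) (r = %.0f um, gap = %.0f um)\n",
    x$width * 1e6, x$total_length * 1e3, x$obstacle_count,
    x$obstacle_radius * 1e6, x$gap * 1e6
  ))
  invisible(x)
}

# Is the point (x, y) inside an obstacle? Vectorised over x, y.
point_in_obstacle <- function(geom, x, y) {
  inside <- rep(FALSE, length(x))
  side_bottom <- rep(NA, length(x))
  r2 <- geom$obstacle_radius^2
  for (k in seq_along(geom$centers)) {
    yc <- if (geom$sides[k] == "bottom") 0 else geom$width
    hit <- (x - geom$centers[k])^2 + (y - yc)^2 < r2
    side_bottom[hit & !inside] <- geom$sides[k] == "bottom"
    inside <- inside | hit
  }
  list(inside = inside, bottom = side_bottom)
}

#' Discretise a channel geometry on a structured grid
#'
#' Cell-centred structured grid for the finite-volume transport solve, with
#' the co-located node grid used by the streamfunction flow solve. The
#' transverse resolution `ny` must resolve the narrowest gap with at least 4
#' cells. Cells are marked solid when their centre falls inside an obstacle;
#' nodes are solid when all four surrounding cells are solid, and wall nodes
#' (carrying streamfunction boundary values) are the fluid nodes touching a
#' solid cell or a channel wall.
#'
#' @param geom a [build_geometry()] object.
#' @param ny number of cells across the channel width.
#' @param dx_factor streamwise cell size as a multiple of the transverse cell
#'   size (default 1, i.e. square cells).
#' @return A list of class `channel_grid` describing cells, nodes and masks.
#' @export
discretize_geometry <- function(geom, ny = 30, dx_factor = 1) {
  stopifnot(inherits(geom, "channel_geometry"))
  if (!is_count(ny)) stop_invalid("'ny' must be a positive integer")
  ny <- as.integer(ny)
  dy <- geom$width / ny
  if (geom$obstacle_count > 0 && geom$gap / dy < 4 - 1e-9) {
    stop_invalid("transverse resolution too coarse: the narrowest gap must ",
                 "span at least 4 cells (need ny >= ",
                 ceiling(4 * geom$width / geom$gap), ")")
  }
  dx <- dy * dx_factor
  nx <- max(3L, as.integer(round(geom$total_length / dx)))
  dx <- geom$total_length / nx
  xc <- (seq_len(nx) - 0.5) * dx
  yc <- (seq_len(ny) - 0.5) * dy
  xn <- (seq_len(nx + 1) - 1) * dx
  yn <- (seq_len(ny + 1) - 1) * dy

  cellxy <- expand.grid(x = xc, y = yc)
  hit <- point_in_obstacle(geom, cellxy$x, cellxy$y)
  cell_solid <- matrix(hit$inside, nx, ny)
  cell_bottom <- matrix(hit$bottom, nx, ny) # NA for fluid cells

  # node (i, j) touches cells (i-1, j-1), (i, j-1), (i-1, j), (i, j);
  # pad the cell mask so off-domain "cells" read as solid walls
  pad <- matrix(TRUE, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- cell_solid
  pad[1, 2:(ny + 1)] <- cell_solid[1, ]    # upstream of inlet: open
  pad[nx + 2, 2:(ny + 1)] <- cell_solid[nx, ] # downstream of outlet: open
  padb <- matrix(NA, nx + 2, ny + 2)
  padb[2:(nx + 1), 2:(ny + 1)] <- cell_bottom
  padb[, 1] <- TRUE   # below bottom wall
  padb[, ny + 2] <- FALSE # above top wall
  padb[1, 2:(ny + 1)] <- cell_bottom[1, ]
  padb[nx + 2, 2:(ny + 1)] <- cell_bottom[nx, ]

  touch <- function(i, j) { # the 4 padded cells around node (i, j)
    cbind(pad[cbind(i, j)], pad[cbind(i + 1, j)],
          pad[cbind(i, j + 1)], pad[cbind(i + 1, j + 1)])
  }
  nodexy <- expand.grid(i = seq_len(nx + 1), j = seq_len(ny + 1))
  tc <- touch(nodexy$i, nodexy$j)
  node_solid <- matrix(rowSums(tc) == 4, nx + 1, ny + 1)
  node_wall <- matrix(rowSums(tc) > 0 & rowSums(tc) < 4, nx + 1, ny + 1)
  # wall side: bottom if any adjacent solid cell belongs to the bottom wall
  tb <- cbind(padb[cbind(nodexy$i, nodexy$j)], padb[cbind(nodexy$i + 1, nodexy$j)],
              padb[cbind(nodexy$i, nodexy$j + 1)],
              padb[cbind(nodexy$i + 1, nodexy$j + 1)])
  tb[!tc] <- NA
  node_bottom <- matrix(apply(tb, 1, function(z) {
    z <- z[!is.na(z)]
    if (!length(z)) NA else any(z)
  }), nx + 1, ny + 1)

  structure(
    list(
      geom = geom, nx = nx, ny = ny, dx = dx, dy = dy,
      xc = xc, yc = yc, xn = xn, yn = yn,
      cell_solid = cell_solid,
      node_solid = node_solid, node_wall = node_wall, node_bottom = node_bottom
    ),
    class = "channel_grid"
  )
}
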