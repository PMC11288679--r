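#' Hexagonal tessellation of a rectangular arena
#'
#' Pointy-top hexagonal grid anchored with the centre of hexagon (0, 0)
#' at the arena's lower-left corner. The hexagon size follows the
#' body-length calibration used for ant home ranges: circumradius =
#' `hex_size_bl` body lengths (default 2, i.e. "hexagons of two ant body
#' lengths"). Which hexagon dimension the calibration refers to is a
#' configuration choice; circumradius is the default and `hex_size_bl`
#' can be set to anything.
#'
#' @param width,height arena dimensions (body-length units).
#' @param body_length body length in the coordinate unit (default 1, i.e.
#'   coordinates already in body lengths).
#' @param hex_size_bl hexagon circumradius in body lengths (default 2).
#' @return a `hex_grid`: list with `R` (circumradius), bounds, a data.frame
#'   `hexes` of axial coordinates (q, r) and centres (cx, cy) of every
#'   hexagon intersecting the arena, and `N_hex` (their count).
#' @export
hex_grid <- function(width, height, body_length = 1, hex_size_bl = 2) {
  if (width <= 0 || height <= 0) stop_invalid("arena dimensions must be positive")
  R <- hex_size_bl * body_length
  # candidate rows/columns generously covering the rectangle
  r_range <- seq(floor((-R) / (1.5 * R)) - 1, ceiling((height + R) / (1.5 * R)) + 1)
  hexes <- do.call(rbind, lapply(r_range, function(r) {
    cy <- 1.5 * R * r
    q_lo <- floor((-sqrt(3) * R) / (sqrt(3) * R) - r / 2) - 1
    q_hi <- ceiling((width + sqrt(3) * R) / (sqrt(3) * R) - r / 2) + 1
    q <- seq(q_lo, q_hi)
    data.frame(q = q, r = r, cx = sqrt(3) * R * (q + r / 2), cy = cy)
  }))
  # a hexagon belongs to the grid iff the rectangle point nearest its
  # centre falls inside it (convexity makes this the intersection test)
  px <- pmin(pmax(hexes$cx, 0), width)
  py <- pmin(pmax(hexes$cy, 0), height)
  ax <- axial_round((sqrt(3) / 3 * px - py / 3) / R, (2 / 3 * py) / R)
  keep <- ax$q == hexes$q & ax$r == hexes$r
  hexes <- hexes[keep, , drop = FALSE]
  hexes <- hexes[order(hexes$q, hexes$r), , drop = FALSE]
  rownames(hexes) <- NULL
  structure(list(R = R, width = width, height = height,
                 hexes = hexes, N_hex = nrow(hexes)),
            class = "hex_grid")
}

# cube rounding of fractional axial coordinates (vectorised)
axial_round <- function(qf, rf) {
  xf <- qf
  zf <- rf
  yf <- -xf - zf
  rx <- round(xf); ry <- round(yf); rz <- round(zf)
  dx <- abs(rx - xf); dy <- abs(ry - yf); dz <- abs(rz - zf)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  data.frame(q = as.integer(rx), r = as.integer(rz))
}

#' Map points to hexagon axial indices
#'
#' Out-of-bounds points (tracking jitter) are clamped to the arena with a
#' warning rather than rejected.
#'
#' @param x,y numeric coordinate vectors.
#' @param grid a [hex_grid()].
#' @return data.frame with integer axial columns `q`, `r`.
#' @export
hex_index <- function(x, y, grid) {
  oob <- x < 0 | x > grid$width | y < 0 | y > grid$height
  if (any(oob)) {
    warning(sum(oob), " point(s) outside arena bounds were clamped")
    x <- pmin(pmax(x, 0), grid$width)
    y <- pmin(pmax(y, 0), grid$height)
  }
  axial_round((sqrt(3) / 3 * x - y / 3) / grid$R, (2 / 3 * y) / grid$R)
}

#' 90% home range on the hexagonal grid
#'
#' Ranks hexagons from most to least visited and accumulates them, most
#' visited first, until they cover at least `coverage` (default 90%) of
#' the ant's detections. Ties are broken by stable (q, r) hexagon order.
#'
#' @param detections data.frame with columns `x`, `y` for one ant.
#' @param grid a [hex_grid()].
#' @param coverage required fraction of detections covered (default 0.9).
#' @return a `home_range`: list with data.frame `hexes` (q, r, count),
#'   `n_hexes`, `covered` (detections covered), `total` and
#'   `proportion_of_arena` = n_hexes / N_hex.
#' @export
home_range_90 <- function(detections, grid, coverage = 0.9) {
  if (nrow(detections) < 1) stop_data("home range requires >= 1 detection")
  ax <- hex_index(detections$x, detections$y, grid)
  key <- paste(ax$q, ax$r, sep = ",")
  tab <- aggregate(list(count = rep(1L, nrow(ax))),
                   by = list(q = ax$q, r = ax$r), FUN = sum)
  tab <- tab[order(-tab$count, tab$q, tab$r), , drop = FALSE]
  total <- nrow(detections)
  cum <- cumsum(tab$count)
  n_needed <- which(cum >= coverage * total)[1]
  sel <- tab[seq_len(n_needed), , drop = FALSE]
  rownames(sel) <- NULL
  structure(list(hexes = sel, n_hexes = n_needed, covered = cum[n_needed],
                 total = total,
                 proportion_of_arena = n_needed / grid$N_hex),
            class = "home_range")
}
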