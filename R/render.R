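# Raster rendering of grid states: pointy-top hexagons, odd-r offset layout.
# Every pixel is assigned to the hexagon containing it by the standard
# fractional axial conversion + cube rounding, so the image is an exact
# hexagonal tiling and the output bytes are deterministic for a given state.

#' Render a grid state as a PNG image
#'
#' Colours each hexagonal cell by the level of one component. Level `k` of a
#' component with maximum level `m` takes the `k+1`-th colour of the palette
#' (default: a white-to-firebrick ramp with `m + 1` steps); cells whose model
#' lacks the component are drawn in light grey.
#'
#' @param state A `grid_state` (any state produced by this package).
#' @param component Component name to colour by.
#' @param path Output PNG path.
#' @param cell_size Hexagon size (centre-to-corner) in pixels.
#' @param palette Optional character vector of colours, one per level
#'   (length `max_level + 1`).
#' @return `path`, invisibly.
#' @export
render_state <- function(state, component, path, cell_size = 8,
                         palette = NULL) {
  topo <- attr(state, "topology")
  if (is.null(topo))
    stop("'state' carries no topology; use a state produced by this package",
         call. = FALSE)
  if (!component %in% colnames(state))
    stop("unknown component: ", component, call. = FALSE)
  v <- unclass(state)[, component]
  maxlev <- max(1L, max(v, na.rm = TRUE))
  if (is.null(palette))
    palette <- grDevices::colorRampPalette(c("#FFFFFF", "#B22222"))(maxlev + 1L)
  if (length(palette) < maxlev + 1L)
    stop(sprintf("palette needs %d colours for levels 0..%d", maxlev + 1L, maxlev),
         call. = FALSE)

  s <- cell_size
  margin <- 2
  ox <- s * sqrt(3) / 2 + margin
  oy <- s + margin
  wpx <- ceiling(sqrt(3) * s * (topo$width + 0.5) + 2 * margin)
  hpx <- ceiling(1.5 * s * (topo$height - 1) + 2 * s + 2 * margin)

  px <- matrix(rep(seq_len(wpx) - 0.5, each = hpx), hpx, wpx)
  py <- matrix(rep(seq_len(hpx) - 0.5, times = wpx), hpx, wpx)
  xf <- (px - ox) / s
  yf <- (py - oy) / s
  q <- sqrt(3) / 3 * xf - 1 / 3 * yf
  r <- 2 / 3 * yf
  # cube rounding of fractional axial coordinates
  cx <- q; cz <- r; cy <- -cx - cz
  rx <- round(cx); ry <- round(cy); rz <- round(cz)
  dx <- abs(rx - cx); dy <- abs(ry - cy); dz <- abs(rz - cz)
  fix_x <- dx > dy & dx > dz
  fix_y <- !fix_x & dy > dz
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  ry[fix_y] <- -rx[fix_y] - rz[fix_y]
  rz[!fix_x & !fix_y] <- -rx[!fix_x & !fix_y] - ry[!fix_x & !fix_y]
  col <- rx + (rz - rz %% 2L) / 2  # axial -> odd-r offset
  row <- rz

  inside <- col >= 0 & col < topo$width & row >= 0 & row < topo$height
  idx <- matrix(NA_integer_, hpx, wpx)
  idx[inside] <- .cell_index(topo, as.integer(col[inside]), as.integer(row[inside]))

  cols <- rep("#FFFFFF", hpx * wpx)
  lev <- ifelse(is.na(idx), NA_integer_, v[idx])
  cols[!is.na(idx) & is.na(lev)] <- "#DDDDDD"
  ok <- !is.na(lev)
  cols[ok] <- palette[lev[ok] + 1L]

  rgb <- grDevices::col2rgb(cols) / 255
  img <- array(0, dim = c(hpx, wpx, 3L))
  img[, , 1L] <- matrix(rgb[1L, ], hpx, wpx)
  img[, , 2L] <- matrix(rgb[2L, ], hpx, wpx)
  img[, , 3L] <- matrix(rgb[3L, ], hpx, wpx)
  png::writePNG(img, path)
  invisible(path)
}

#' Plot a grid state with base graphics
#'
#' Draws the hexagonal grid with [graphics::polygon()], coloured like
#' [render_state()].
#'
#' @param x A `grid_state`.
#' @param component Component to colour by (default: last column).
#' @param palette Optional colour vector, one per level.
#' @param ... Ignored.
#' @export
plot.grid_state <- function(x, component = NULL, palette = NULL, ...) {
  topo <- attr(x, "topology")
  if (is.null(component)) component <- colnames(x)[ncol(x)]
  v <- unclass(x)[, component]
  maxlev <- max(1L, max(v, na.rm = TRUE))
  if (is.null(palette))
    palette <- grDevices::colorRampPalette(c("#FFFFFF", "#B22222"))(maxlev + 1L)
  cr <- .cell_coords(topo)
  cx <- sqrt(3) * (cr[, "col"] + 0.5 * (cr[, "row"] %% 2))
  cy <- 1.5 * cr[, "row"]
  graphics::plot(NA, xlim = range(cx) + c(-1, 1), ylim = rev(range(cy)) + c(1.2, -1.2),
                 asp = 1, axes = FALSE, xlab = "", ylab = "",
                 main = component)
  ang <- pi / 180 * (60 * 0:5 + 30)
  for (i in seq_along(cx)) {
    fill <- if (is.na(v[i])) "#DDDDDD" else palette[v[i] + 1L]
    graphics::polygon(cx[i] + cos(ang), cy[i] + sin(ang), col = fill,
                      border = "grey40", lwd = 0.3)
  }
  invisible(x)
}
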