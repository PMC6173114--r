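# Hexagonal lattice topology.
#
# Cells live on a pointy-top hexagonal grid addressed by 0-based "odd-r"
# offset coordinates (col, row): odd rows are shifted half a cell to the
# right. Cells are enumerated row-major: index = row * width + col + 1.
# Borders may be wrapped per axis (rectangle / cylinder / torus). Distances
# are shortest paths in the wrapped adjacency graph, computed by breadth-first
# search, so every wrap mode shares one definition.

#' Hexagonal grid topology
#'
#' @param width,height Grid dimensions (columns, rows), both >= 1.
#' @param wrap_horizontal,wrap_vertical Connect the vertical (left/right) and
#'   horizontal (top/bottom) border pairs. Neither: rectangle; one: cylinder;
#'   both: torus. Vertical wrapping requires an even number of rows - odd-r
#'   adjacency depends on row parity, and wrapping an odd height would glue
#'   rows of equal parity inconsistently.
#' @return An object of class `hex_topology`.
#' @examples
#' hex_topology(50, 50)
#' hex_topology(10, 10, wrap_horizontal = TRUE, wrap_vertical = TRUE)
#' @export
hex_topology <- function(width, height, wrap_horizontal = FALSE,
                         wrap_vertical = FALSE) {
  width <- as.integer(width)
  height <- as.integer(height)
  if (is.na(width) || width < 1L)
    stop("'width' must be an integer >= 1", call. = FALSE)
  if (is.na(height) || height < 1L)
    stop("'height' must be an integer >= 1", call. = FALSE)
  if (isTRUE(wrap_vertical) && height %% 2L != 0L)
    stop("'wrap_vertical' requires an even 'height' (odd-r row-parity constraint)",
         call. = FALSE)
  structure(list(width = width, height = height,
                 wrap_horizontal = isTRUE(wrap_horizontal),
                 wrap_vertical = isTRUE(wrap_vertical)),
            class = "hex_topology")
}

#' @export
print.hex_topology <- function(x, ...) {
  shape <- if (x$wrap_horizontal && x$wrap_vertical) "torus"
  else if (x$wrap_horizontal || x$wrap_vertical) "cylinder"
  else "rectangle"
  cat(sprintf("Hexagonal grid %dx%d (%s), odd-r offset coordinates\n",
              x$width, x$height, shape))
  invisible(x)
}

.n_cells <- function(topo) topo$width * topo$height

# (col, row) [0-based] <-> 1-based row-major index
.cell_index <- function(topo, col, row) row * topo$width + col + 1L
.cell_coords <- function(topo, idx = seq_len(.n_cells(topo))) {
  cbind(col = (idx - 1L) %% topo$width, row = (idx - 1L) %/% topo$width)
}

.check_coord <- function(topo, col, row) {
  if (any(col < 0L | col >= topo$width | row < 0L | row >= topo$height))
    stop(sprintf("coordinate (%d,%d) outside %dx%d grid",
                 col[1L], row[1L], topo$width, topo$height), call. = FALSE)
  invisible(NULL)
}

# odd-r neighbour offsets (pointy-top): (dc_even, dc_odd, dr) per direction
.HEX_DIRS <- cbind(
  dc_even = c(1L, -1L, 0L, -1L, 0L, -1L),
  dc_odd  = c(1L, -1L, 1L, 0L, 1L, 0L),
  dr      = c(0L, 0L, -1L, -1L, 1L, 1L))

# Adjacency of every cell: n x 6 matrix of neighbour indices, NA where a
# candidate falls off a non-wrapped border.
.neighbor_index_matrix <- function(topo) {
  n <- .n_cells(topo)
  cr <- .cell_coords(topo)
  col <- cr[, "col"]
  row <- cr[, "row"]
  odd <- row %% 2L == 1L
  out <- matrix(NA_integer_, n, 6L)
  for (k in seq_len(6L)) {
    dc <- ifelse(odd, .HEX_DIRS[k, "dc_odd"], .HEX_DIRS[k, "dc_even"])
    nc <- col + dc
    nr <- row + .HEX_DIRS[k, "dr"]
    if (topo$wrap_horizontal) nc <- nc %% topo$width
    if (topo$wrap_vertical) nr <- nr %% topo$height
    ok <- nc >= 0L & nc < topo$width & nr >= 0L & nr < topo$height
    out[ok, k] <- .cell_index(topo, nc[ok], nr[ok])
  }
  out
}

# Adjacency list (unique neighbour indices per cell; wrapping a 1- or 2-wide
# axis can make two directions land on the same cell).
.adjacency_list <- function(topo, nbm = .neighbor_index_matrix(topo)) {
  lapply(seq_len(nrow(nbm)), function(i) {
    v <- nbm[i, ]
    sort(unique(v[!is.na(v) & v != i]))
  })
}

#' Neighbours of a cell
#'
#' The up-to-six cells adjacent to `cell`. Candidates beyond a non-wrapped
#' border are dropped; wrapped borders use modular arithmetic on that axis.
#'
#' @param topology A [hex_topology()].
#' @param cell Length-2 integer vector `c(col, row)`, 0-based.
#' @return Integer matrix with columns `col`, `row`, one row per neighbour,
#'   ordered by (row, col).
#' @examples
#' nrow(hex_neighbors(hex_topology(5, 5), c(2, 2)))  # interior cell: 6
#' nrow(hex_neighbors(hex_topology(5, 5), c(0, 0)))  # corner: fewer
#' @export
hex_neighbors <- function(topology, cell) {
  stopifnot(inherits(topology, "hex_topology"), length(cell) == 2L)
  col <- as.integer(cell[1L]); row <- as.integer(cell[2L])
  .check_coord(topology, col, row)
  nbm <- .neighbor_index_matrix(topology)
  idx <- nbm[.cell_index(topology, col, row), ]
  idx <- sort(unique(idx[!is.na(idx)]))
  .cell_coords(topology, idx)
}

# BFS distances from one source cell; Inf where unreachable (cannot happen on
# a connected grid, kept for safety). `adj` = adjacency list.
.bfs_distances <- function(adj, from, dmax = Inf) {
  dist <- rep(NA_integer_, length(adj))
  dist[from] <- 0L
  frontier <- from
  d <- 0L
  while (length(frontier) && d < dmax) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    d <- d + 1L
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Hexagonal graph distance
#'
#' Length of the shortest path between two cells in the adjacency graph
#' induced by [hex_neighbors()]; border wrapping is respected.
#'
#' @param topology A [hex_topology()].
#' @param a,b Cells as `c(col, row)`, 0-based.
#' @return Integer distance; 0 iff `a` equals `b`.
#' @export
hex_distance <- function(topology, a, b) {
  stopifnot(inherits(topology, "hex_topology"))
  a <- as.integer(a); b <- as.integer(b)
  .check_coord(topology, a[1L], a[2L])
  .check_coord(topology, b[1L], b[2L])
  ia <- .cell_index(topology, a[1L], a[2L])
  ib <- .cell_index(topology, b[1L], b[2L])
  if (ia == ib) return(0L)
  adj <- .adjacency_list(topology)
  d <- .bfs_distances(adj, ia)[ib]
  if (is.na(d)) stop("cells are not connected", call. = FALSE)
  d
}

#' Cells within a distance band
#'
#' All cells whose hexagonal graph distance from `cell` lies in
#' `[dmin, dmax]`. With `dmin >= 1` the cell itself is excluded. On an
#' unbounded lattice the band `[1, d]` holds `3 d (d + 1)` cells
#' (rings of 6, 12, 18, ...); borders truncate it.
#'
#' @param topology A [hex_topology()].
#' @param cell `c(col, row)`, 0-based.
#' @param dmin,dmax Distance bounds, `0 <= dmin <= dmax`.
#' @return Integer matrix with columns `col`, `row`, ordered by (row, col).
#' @examples
#' nrow(cells_at_distance(hex_topology(20, 20), c(10, 10), 1, 3))  # 36
#' @export
cells_at_distance <- function(topology, cell, dmin, dmax) {
  stopifnot(inherits(topology, "hex_topology"), length(cell) == 2L)
  dmin <- as.integer(dmin); dmax <- as.integer(dmax)
  if (is.na(dmin) || is.na(dmax) || dmin < 0L || dmin > dmax)
    stop("need 0 <= dmin <= dmax", call. = FALSE)
  col <- as.integer(cell[1L]); row <- as.integer(cell[2L])
  .check_coord(topology, col, row)
  adj <- .adjacency_list(topology)
  d <- .bfs_distances(adj, .cell_index(topology, col, row), dmax = dmax)
  idx <- which(!is.na(d) & d >= dmin & d <= dmax)
  .cell_coords(topology, idx)
}

# Sparse band matrix M (n x n): M[i, j] = 1 iff dmin <= dist(i, j) <= dmax.
# Used to count satisfying neighbours of every cell in one product.
.band_matrix <- function(topo, dmin, dmax, adj = .adjacency_list(topo)) {
  n <- length(adj)
  is <- vector("list", n)
  js <- vector("list", n)
  for (i in seq_len(n)) {
    d <- .bfs_distances(adj, i, dmax = dmax)
    j <- which(!is.na(d) & d >= dmin & d <= dmax)
    is[[i]] <- rep.int(i, length(j))
    js[[i]] <- j
  }
  M <- Matrix::sparseMatrix(i = unlist(is), j = unlist(js), x = 1,
                            dims = c(n, n))
  list(M = M, size = as.numeric(Matrix::rowSums(M)))
}
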