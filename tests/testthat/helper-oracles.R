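# Shared fixtures and independent oracles used across the suite.

# Three-component lateral-inhibition cell: explicit neighbourhood input
# nb_Red, internal Green := nb_Red and Red := !Green. Exercises the general
# input/internal split at the single-cell level.
dn3_model <- function(priorities = NULL) {
  logical_model(
    components = c(nb_Red = 1, Green = 1, Red = 1),
    inputs = "nb_Red",
    functions = list(Green = "nb_Red", Red = "!Green"),
    priorities = priorities,
    name = "dn3")
}

# Multi-valued fixture: Boolean input sig, 3-level A, Boolean B.
mv_model <- function(priorities = NULL) {
  logical_model(
    components = c(sig = 1, A = 2, B = 1),
    inputs = "sig",
    functions = list(
      A = list("2" = "B & sig", "1" = "B | sig"),
      B = "A<2"),
    priorities = priorities,
    name = "mv")
}

# Independent single-cell oracle: target of each internal component computed
# straight from the written rules, then one +/-1 step. Covers dn3 and mv.
oracle_cell_step <- function(model_name, state) {
  s <- as.list(state)
  tg <- list()
  if (model_name == "dn3") {
    tg$Green <- if (s$nb_Red >= 1) 1L else 0L
    tg$Red <- if (s$Green >= 1) 0L else 1L
  } else if (model_name == "mv") {
    tg$A <- if (s$B >= 1 && s$sig >= 1) 2L else if (s$B >= 1 || s$sig >= 1) 1L else 0L
    tg$B <- if (s$A < 2) 1L else 0L
  } else stop("unknown model")
  out <- state
  for (cn in names(tg)) out[cn] <- state[cn] + sign(tg[[cn]] - state[cn])
  out
}

# Brute-force oracle for the two-cell lateral-inhibition tissue (contact
# rule, 1x2 grid). States are c(g1, r1, g2, r2); the input Green of a cell is
# 1 iff its single neighbour is Red. Written from the rules, independent of
# the engine.
oracle_two_cell_resolve <- function(s) {
  c(g1 = unname(s[4]), r1 = unname(s[2]), g2 = unname(s[2]), r2 = unname(s[4]))
}
oracle_two_cell_step <- function(s) {
  r <- oracle_two_cell_resolve(s)
  nxt <- c(g1 = NA, r1 = 1L - r[["g1"]], g2 = NA, r2 = 1L - r[["g2"]])
  oracle_two_cell_resolve(nxt)
}
oracle_two_cell_stable <- function(s) {
  r <- oracle_two_cell_resolve(s)
  all(oracle_two_cell_step(s)[c(2, 4)] == r[c(2, 4)])
}

# Extract c(g1, r1, g2, r2) from an engine grid state of the 1x2 fixture.
two_cell_vec <- function(state) {
  c(g1 = unname(state[1, "Green"]), r1 = unname(state[1, "Red"]),
    g2 = unname(state[2, "Green"]), r2 = unname(state[2, "Red"]))
}

# BFS distances over the public neighbour API; independent of the internal
# band/adjacency machinery.
oracle_bfs_distances <- function(topo, from_col, from_row) {
  n <- topo$width * topo$height
  idx <- function(c0, r0) r0 * topo$width + c0 + 1L
  dist <- rep(NA_integer_, n)
  dist[idx(from_col, from_row)] <- 0L
  frontier <- list(c(from_col, from_row))
  d <- 0L
  while (length(frontier)) {
    nxt <- list()
    for (cell in frontier) {
      nb <- hex_neighbors(topo, cell)
      for (i in seq_len(nrow(nb))) {
        j <- idx(nb[i, "col"], nb[i, "row"])
        if (is.na(dist[j])) {
          dist[j] <- d + 1L
          nxt[[length(nxt) + 1L]] <- c(nb[i, "col"], nb[i, "row"])
        }
      }
    }
    frontier <- nxt
    d <- d + 1L
  }
  dist
}

# Random small lateral-inhibition instance (epithelium + randomized internal
# state), for scheme-equivalence properties.
random_dn_instance <- function(i) {
  set.seed(i)
  w <- sample(2:6, 1)
  h <- sample(c(2L, 4L, 6L), 1)
  wrap <- sample(c("none", "horizontal", "vertical", "torus"), 1)
  rule <- sample(c("contact1", "contactall", "dist3-12"), 1)
  fx <- fixture_delta_notch(w, h, wrap = wrap, rule = rule)
  init <- fx$epithelium$initial
  init[, "Red"] <- sample(0:1, nrow(init), replace = TRUE)
  clone_epithelium(fx$epithelium, init)
}

# Adjacency list of a topology built from the public API (used by the
# maximal-independent-set check).
adjacency_from_api <- function(topo) {
  n <- topo$width * topo$height
  lapply(seq_len(n), function(i) {
    c0 <- (i - 1L) %% topo$width
    r0 <- (i - 1L) %/% topo$width
    nb <- hex_neighbors(topo, c(c0, r0))
    nb[, "row"] * topo$width + nb[, "col"] + 1L
  })
}

# Red set of a stable lateral-inhibition pattern must be a maximal
# independent set of the grid graph; returns TRUE/FALSE.
is_maximal_independent_red <- function(topo, state,
                                       adj = adjacency_from_api(topo)) {
  red <- unclass(state)[, "Red"] == 1L
  green <- unclass(state)[, "Green"] == 1L
  if (!all(red == !green)) return(FALSE)
  for (i in seq_along(adj)) {
    if (red[i] && any(red[adj[[i]]])) return(FALSE)        # independence
    if (!red[i] && !any(red[adj[[i]]])) return(FALSE)      # maximality
  }
  TRUE
}
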