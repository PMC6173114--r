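# Tissue dynamics: synchronous and alpha-asynchronous updating, stability
# and cycle detection, trajectories, clones.
#
# Every tissue update is two-phase: first all input components are resolved
# from the full current grid state (so the result is independent of cell
# iteration order), then the selected cells step their internal components
# from that shared snapshot, then perturbation clamps are re-applied.

#' Simulation settings
#'
#' @param scheme `"synchronous"` (every cell updated, deterministic) or
#'   `"alpha"` (alpha-asynchronous: at each tissue step a random subset of
#'   cells is updated).
#' @param alpha Proportion of cells chosen for update per step, in (0, 1];
#'   `alpha = 1` reproduces the synchronous scheme. Ignored when
#'   `scheme = "synchronous"`.
#' @param seed Integer seed; mandatory for the stochastic scheme (identical
#'   seed and model give an identical trajectory). Ignored when synchronous.
#' @param max_steps Maximum number of tissue updates (default 1000).
#' @param sampling `"exact"` draws exactly `round(alpha * n_cells)` cells
#'   without replacement (the default); `"bernoulli"` updates each cell
#'   independently with probability `alpha`.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(scheme = c("synchronous", "alpha"), alpha = 0.25,
                              seed = NULL, max_steps = 1000L,
                              sampling = c("exact", "bernoulli")) {
  scheme <- match.arg(scheme)
  sampling <- match.arg(sampling)
  alpha <- as.numeric(alpha)
  if (scheme == "alpha") {
    if (is.na(alpha) || alpha <= 0 || alpha > 1)
      stop("'alpha' must lie in (0, 1]", call. = FALSE)
    if (is.null(seed))
      stop("the alpha-asynchronous scheme requires a 'seed' (reproducibility contract)",
           call. = FALSE)
  }
  max_steps <- as.integer(max_steps)
  if (is.na(max_steps) || max_steps < 1L)
    stop("'max_steps' must be an integer >= 1", call. = FALSE)
  structure(list(scheme = scheme, alpha = alpha,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 max_steps = max_steps, sampling = sampling),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  if (x$scheme == "synchronous") {
    cat(sprintf("Simulation: synchronous, max %d steps\n", x$max_steps))
  } else {
    cat(sprintf("Simulation: alpha-asynchronous (alpha = %g, %s sampling, seed = %d), max %d steps\n",
                x$alpha, x$sampling, x$seed, x$max_steps))
  }
  invisible(x)
}

# Pinned RNG so trajectories are reproducible across R versions/processes.
.set_seed <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
}

#' Is a tissue state a stable pattern?
#'
#' A state is stable when, after input resolution and perturbation clamping,
#' every cell is at a fixed point of its cellular update - equivalently, the
#' full synchronous tissue update returns the state unchanged. Stable
#' patterns are absorbing under every updating scheme and any alpha.
#'
#' @param epi An [epithelium()].
#' @param state Tissue state matrix (defaults to the initial state).
#' @return `TRUE` or `FALSE`.
#' @export
is_stable <- function(epi, state = epi$initial) {
  ctx <- .epi_context(epi)
  mat <- .clamp(ctx, .state_mat(epi, state))
  resolved <- .clamp(ctx, .resolve(ctx, mat))
  .int_equal(ctx, .full_step(ctx, resolved), mat)
}

#' One synchronous tissue update
#'
#' Resolves all inputs from `state`, applies the cellular update to every
#' cell from that snapshot, and re-applies perturbation clamps. Deterministic;
#' the result does not depend on any cell iteration order.
#'
#' @inheritParams is_stable
#' @return The successor state (class `grid_state`, inputs resolved from its
#'   own internal levels).
#' @export
step_synchronous <- function(epi, state = epi$initial) {
  ctx <- .epi_context(epi)
  mat <- .clamp(ctx, .state_mat(epi, state))
  resolved <- .clamp(ctx, .resolve(ctx, mat))
  nxt <- .full_step(ctx, resolved)
  .as_grid_state(ctx, .clamp(ctx, .resolve(ctx, nxt)))
}

#' One alpha-asynchronous tissue update
#'
#' Inputs are resolved from `state` exactly as in the synchronous scheme;
#' then a random subset of cells (exactly `round(alpha * n_cells)` drawn
#' without replacement, or per-cell Bernoulli draws with
#' `sampling = "bernoulli"`) applies the cellular update while every other
#' cell keeps its internal levels. Uses R's current RNG stream; seed it with
#' `set.seed()` or run through [run_simulation()] for the reproducibility
#' contract.
#'
#' @inheritParams is_stable
#' @param alpha Proportion of cells to update, in (0, 1]; `alpha = 1` equals
#'   [step_synchronous()].
#' @param sampling `"exact"` or `"bernoulli"`.
#' @return The successor state (class `grid_state`).
#' @export
step_alpha_async <- function(epi, state = epi$initial, alpha = 0.25,
                             sampling = c("exact", "bernoulli")) {
  sampling <- match.arg(sampling)
  if (is.na(alpha) || alpha <= 0 || alpha > 1)
    stop("'alpha' must lie in (0, 1]", call. = FALSE)
  ctx <- .epi_context(epi)
  mat <- .clamp(ctx, .state_mat(epi, state))
  resolved <- .clamp(ctx, .resolve(ctx, mat))
  full <- .full_step(ctx, resolved)
  sel <- .draw_cells(ctx$n, alpha, sampling)
  nxt <- .apply_selection(ctx, mat, full, sel)
  .as_grid_state(ctx, .clamp(ctx, .resolve(ctx, nxt)))
}

.draw_cells <- function(n, alpha, sampling) {
  if (sampling == "bernoulli") return(which(stats::runif(n) < alpha))
  k <- round(alpha * n)
  if (k >= n) return(seq_len(n))
  sample.int(n, k)
}

# Keep internal levels of unselected cells; selected cells take the fully
# updated levels. Inputs are carried from the resolved snapshot.
.apply_selection <- function(ctx, current, full, sel) {
  out <- full
  unsel <- setdiff(seq_len(ctx$n), sel)
  if (length(unsel)) {
    m <- ctx$imask
    m[sel, ] <- FALSE
    out[m] <- current[m]
  }
  out
}

#' Run a tissue simulation
#'
#' Iterates the configured step operator from the model's initial state
#' (after perturbation clamping). The run stops at the first stable pattern
#' (`converged = TRUE`), at a revisited state under the synchronous scheme
#' (`cycle_length` = revisit distance), or after `max_steps` updates.
#' Identical model and configuration (including seed) yield an identical
#' trajectory, also across processes.
#'
#' @param epi An [epithelium()]; must pass [validate_epithelium()].
#' @param config A [simulation_config()]; alternatively pass its fields via
#'   `...`.
#' @param ... Fields forwarded to [simulation_config()] when `config` is
#'   `NULL`.
#' @param record `"all"` keeps every visited state in the trajectory,
#'   `"last"` only the initial and final states (use for long batch runs).
#' @return An object of class `epi_trajectory`: list with `states` (each a
#'   `grid_state` with inputs resolved; state 1 is the clamped initial
#'   state), `steps` (tissue updates applied), `converged`,
#'   `steps_to_stability` (`NA` if not converged), `cycle_length` (`NA`
#'   unless a synchronous revisit was found), `changed_cells` (per-step count
#'   of cells whose internal levels changed), `scheme`, `alpha`, `seed`.
#' @examples
#' fx <- fixture_delta_notch(1, 2)
#' run_simulation(fx$epithelium, scheme = "synchronous")
#' @export
run_simulation <- function(epi, config = NULL, ..., record = c("all", "last")) {
  record <- match.arg(record)
  if (is.null(config)) config <- simulation_config(...)
  stopifnot(inherits(epi, "epithelium"), inherits(config, "sim_config"))
  findings <- validate_epithelium(epi)
  if (length(findings))
    stop("epithelium model is invalid:\n  ",
         paste(findings, collapse = "\n  "), call. = FALSE)

  ctx <- .epi_context(epi)
  sync <- config$scheme == "synchronous"
  if (!sync) .set_seed(config$seed)

  state <- .clamp(ctx, .state_mat(epi, epi$initial))
  canon <- function(m) .as_grid_state(ctx, .clamp(ctx, .resolve(ctx, m)))
  states <- list(canon(state))
  history <- NULL
  if (sync) {
    history <- new.env(parent = emptyenv())
    assign(.state_key(ctx, state), 0L, envir = history)
  }

  steps <- 0L
  converged <- FALSE
  cycle_length <- NA_integer_
  changed <- integer()

  repeat {
    resolved <- .clamp(ctx, .resolve(ctx, state))
    full <- .full_step(ctx, resolved)
    if (.int_equal(ctx, full, state)) {
      converged <- TRUE
      break
    }
    if (steps >= config$max_steps) break
    nxt <- if (sync) full else {
      sel <- .draw_cells(ctx$n, config$alpha, config$sampling)
      .clamp(ctx, .apply_selection(ctx, state, full, sel))
    }
    steps <- steps + 1L
    changed[steps] <- sum(rowSums((nxt != state) & ctx$imask, na.rm = TRUE) > 0)
    state <- nxt
    if (record == "all") states[[steps + 1L]] <- canon(state)
    if (sync) {
      key <- .state_key(ctx, state)
      prev <- history[[key]]
      if (!is.null(prev)) {
        cycle_length <- steps - prev
        break
      }
      assign(key, steps, envir = history)
    }
  }

  if (record == "last") states[[2L]] <- canon(state)

  structure(
    list(states = states, steps = steps, converged = converged,
         steps_to_stability = if (converged) steps else NA_integer_,
         cycle_length = cycle_length, changed_cells = changed,
         scheme = config$scheme,
         alpha = if (sync) NA_real_ else config$alpha,
         seed = if (sync) NA_integer_ else config$seed,
         record = record, components = ctx$comps, topology = ctx$topo),
    class = "epi_trajectory")
}

#' @export
print.epi_trajectory <- function(x, ...) {
  cat(sprintf("Tissue trajectory (%s%s): %d step%s applied\n",
              x$scheme,
              if (x$scheme == "alpha") sprintf(", alpha = %g, seed = %d", x$alpha, x$seed) else "",
              x$steps, if (x$steps == 1) "" else "s"))
  if (x$converged) {
    cat(sprintf("  converged to a stable pattern after %d step%s\n",
                x$steps_to_stability, if (x$steps_to_stability == 1) "" else "s"))
  } else if (!is.na(x$cycle_length)) {
    cat(sprintf("  cyclic attractor detected: cycle length %d\n", x$cycle_length))
  } else {
    cat("  stopped at max_steps without reaching a stable pattern\n")
  }
  invisible(x)
}

#' @export
summary.epi_trajectory <- function(object, ...) {
  final <- object$states[[length(object$states)]]
  cat(sprintf("Trajectory over %d recorded states; final state:\n",
              length(object$states)))
  print(final)
  invisible(object)
}

#' Plot per-level component counts along a trajectory
#'
#' Requires a trajectory recorded with `record = "all"`.
#'
#' @param x An `epi_trajectory`.
#' @param component Component to plot (default: every component).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.epi_trajectory <- function(x, component = NULL, ...) {
  if (x$record != "all")
    stop("plotting needs a trajectory recorded with record = \"all\"",
         call. = FALSE)
  comps <- if (is.null(component)) x$components else component
  counts <- sapply(comps, function(cn) {
    vapply(x$states, function(s) sum(s[, cn] >= 1, na.rm = TRUE), 0)
  })
  counts <- matrix(counts, nrow = length(x$states),
                   dimnames = list(NULL, comps))
  graphics::matplot(0:(length(x$states) - 1L), counts, type = "l", lty = 1,
                    xlab = "tissue step", ylab = "cells at level >= 1", ...)
  graphics::legend("topright", legend = comps, lty = 1,
                   col = seq_along(comps), bty = "n")
  invisible(x)
}

#' Clone an epithelium model at a given state
#'
#' Returns a deep copy of the model whose initial condition is `state` -
#' the starting point of multi-phase simulations (run to a stable pattern,
#' clone, modify e.g. a positional input, run the clone). Edits to the clone
#' never affect the original.
#'
#' @param epi An [epithelium()].
#' @param state Tissue state conforming to `epi`.
#' @return A new `epithelium`.
#' @export
clone_epithelium <- function(epi, state) {
  mat <- .state_mat(epi, state)
  clone <- epi  # R list copy semantics: fully independent copy-on-write value
  tmpl <- .state_template(epi)
  mat[is.na(tmpl)] <- NA_integer_
  clone$initial <- structure(mat, class = c("grid_state", "matrix"),
                             topology = epi$topology)
  clone
}

#' Export a trajectory as CSV
#'
#' One row per (step, cell, component): columns `step` (0-based), `col`,
#' `row`, `component`, `level`. Rows are ordered by step, then row-major
#' cell, then component declaration order; the file is UTF-8 and
#' byte-deterministic for a given trajectory.
#'
#' @param trajectory An `epi_trajectory` recorded with `record = "all"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "epi_trajectory"))
  if (trajectory$record != "all")
    stop("export needs a trajectory recorded with record = \"all\"", call. = FALSE)
  topo <- trajectory$topology
  cr <- .cell_coords(topo)
  comps <- trajectory$components
  blocks <- lapply(seq_along(trajectory$states), function(si) {
    s <- trajectory$states[[si]]
    n <- nrow(s)
    step <- rep.int(si - 1L, n * length(comps))
    col <- rep(cr[, "col"], each = length(comps))
    row <- rep(cr[, "row"], each = length(comps))
    component <- rep(comps, times = n)
    level <- as.integer(t(unclass(s)[, comps, drop = FALSE]))
    data.frame(step = step, col = col, row = row, component = component,
               level = level, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  out <- out[!is.na(out$level), , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("step,col,row,component,level", con, sep = "\n")
  writeLines(sprintf("%d,%d,%d,%s,%d", out$step, out$col, out$row,
                     out$component, out$level), con, sep = "\n")
  invisible(path)
}
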