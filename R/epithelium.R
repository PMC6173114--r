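# Epithelium models: a hexagonal grid, cellular logical models assigned to
# its cells, the semantics of their input components (constant positional
# maps or neighbourhood integration rules), perturbations and an initial
# state.
#
# Tissue states are integer matrices (cells x components, row-major cell
# order, columns = the union of the assigned models' components in
# declaration order); NA marks a component absent from a cell's model.

#' Cells of a rectangular region
#'
#' Resolves a region specification to 1-based row-major cell indices.
#' `cols`/`rows` are inclusive 0-based ranges `c(min, max)` (a single value
#' selects one column/row; `NULL` selects all); alternatively `cells` gives
#' explicit coordinates as a 2-column (col, row) matrix.
#'
#' @param topology A [hex_topology()].
#' @param cols,rows Inclusive 0-based ranges, or `NULL`.
#' @param cells 2-column matrix/data.frame of (col, row) pairs, or `NULL`.
#' @return Sorted integer vector of cell indices.
#' @export
region_cells <- function(topology, cols = NULL, rows = NULL, cells = NULL) {
  stopifnot(inherits(topology, "hex_topology"))
  if (!is.null(cells)) {
    cells <- as.matrix(cells)
    storage.mode(cells) <- "integer"
    .check_coord(topology, cells[, 1L], cells[, 2L])
    return(sort(unique(.cell_index(topology, cells[, 1L], cells[, 2L]))))
  }
  crange <- function(r, lim, what) {
    if (is.null(r)) return(0:(lim - 1L))
    r <- as.integer(r)
    if (length(r) == 1L) r <- c(r, r)
    if (length(r) != 2L || any(is.na(r)) || r[1L] > r[2L] ||
        r[1L] < 0L || r[2L] >= lim)
      stop(sprintf("invalid %s range for a %d-wide axis", what, lim),
           call. = FALSE)
    r[1L]:r[2L]
  }
  cc <- crange(cols, topology$width, "cols")
  rr <- crange(rows, topology$height, "rows")
  grid <- expand.grid(col = cc, row = rr)
  sort(.cell_index(topology, grid$col, grid$row))
}

#' Component perturbation
#'
#' Blocks a component at a fixed level, over the whole grid or a region.
#' The clamp is re-applied after every update, so perturbed components never
#' move (knock-out at level 0, ectopic expression at a higher level).
#'
#' @param component Component name.
#' @param level Level the component is blocked at.
#' @param cols,rows,cells Region (see [region_cells()]); all `NULL` = every cell.
#' @return An object of class `perturbation`.
#' @export
perturbation <- function(component, level, cols = NULL, rows = NULL,
                         cells = NULL) {
  structure(list(component = as.character(component), level = as.integer(level),
                 cols = cols, rows = rows, cells = cells),
            class = "perturbation")
}

#' Compose an epithelium model
#'
#' @param topology A [hex_topology()].
#' @param models A single [logical_model()] applied to every cell, or a named
#'   list of models for region-based assignment.
#' @param assignment With several models: either a model name per cell
#'   (length `width * height`, row-major), or a list of
#'   `list(model = <name>, cols = , rows = , cells = )` region entries
#'   (later entries override earlier ones; unassigned cells get the first
#'   model).
#' @param positional Named list, one entry per positional input component:
#'   a single level (constant over the grid), a full per-cell vector
#'   (row-major), or `list(default = , regions = list(list(level = , cols = ,
#'   rows = , cells = )))`.
#' @param integration Named list, one entry per integration input component:
#'   a rule string (asserting level 1), a [parse_integration_rule()]
#'   object, or a list named
#'   by level with one rule per level (the input takes the highest level whose
#'   rule holds, else 0).
#' @param perturbations List of [perturbation()] objects.
#' @param initial Initial levels of the internal components: `NULL` (all 0), a
#'   named vector of per-component defaults, a full cells x components
#'   matrix, or `list(default = , components = , regions = list(list(component
#'   = , level = , cols = , rows = , cells = )))`.
#' @return An object of class `epithelium`.
#' @seealso [validate_epithelium()], [run_simulation()], [fixture_delta_notch()]
#' @export
epithelium <- function(topology, models, assignment = NULL,
                       positional = list(), integration = list(),
                       perturbations = list(), initial = NULL) {
  stopifnot(inherits(topology, "hex_topology"))
  if (inherits(models, "logical_model")) {
    models <- stats::setNames(list(models), models$name)
  }
  if (!is.list(models) || !length(models) ||
      !all(vapply(models, inherits, TRUE, "logical_model")))
    stop("'models' must be a logical_model or a named list of them", call. = FALSE)
  if (is.null(names(models)) || any(!nzchar(names(models))))
    names(models) <- vapply(models, `[[`, "", "name")

  n <- .n_cells(topology)
  assignment <- .normalize_assignment(topology, names(models), assignment, n)

  comps <- .union_components(models)

  positional <- .normalize_positional(positional, n, topology)
  integration <- .normalize_integration(integration)

  perturbations <- lapply(perturbations, function(p) {
    if (!inherits(p, "perturbation")) p <- do.call(perturbation, p)
    p$cell_idx <- region_cells(topology, p$cols, p$rows, p$cells)
    p
  })

  epi <- structure(
    list(topology = topology, models = models, assignment = assignment,
         components = comps, positional = positional,
         integration = integration, perturbations = perturbations,
         initial = NULL),
    class = "epithelium")
  epi$initial <- .normalize_initial(epi, initial)
  epi
}

.normalize_assignment <- function(topology, model_names, assignment, n) {
  if (is.null(assignment)) {
    if (length(model_names) > 1L)
      stop("'assignment' is required when several models are given", call. = FALSE)
    return(rep(model_names[1L], n))
  }
  if (is.character(assignment) && length(assignment) == 1L)
    assignment <- rep(assignment, n)
  if (is.list(assignment)) {
    out <- rep(model_names[1L], n)
    for (a in assignment) {
      if (is.null(a$model))
        stop("each assignment entry needs a 'model' name", call. = FALSE)
      out[region_cells(topology, a$cols, a$rows, a$cells)] <- a$model
    }
    assignment <- out
  }
  if (length(assignment) != n)
    stop(sprintf("'assignment' must name a model for each of the %d cells", n),
         call. = FALSE)
  if (length(bad <- setdiff(unique(assignment), model_names)))
    stop("assignment references unknown model(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  assignment
}

# Union of model components, first model's declaration order first; max
# levels must agree across models sharing a name.
.union_components <- function(models) {
  out <- NULL
  for (m in models) {
    cm <- m$components
    if (is.null(out)) {
      out <- cm[, c("name", "max_level")]
      next
    }
    for (i in seq_len(nrow(cm))) {
      j <- match(cm$name[i], out$name)
      if (is.na(j)) {
        out <- rbind(out, cm[i, c("name", "max_level")])
      } else if (out$max_level[j] != cm$max_level[i]) {
        stop(sprintf("component '%s' has conflicting maximum levels (%d vs %d) across models",
                     cm$name[i], out$max_level[j], cm$max_level[i]), call. = FALSE)
      }
    }
  }
  rownames(out) <- NULL
  out
}

.normalize_positional <- function(positional, n, topology) {
  if (!length(positional)) return(stats::setNames(list(), character()))
  if (is.null(names(positional)))
    stop("'positional' must be a named list (one entry per input component)",
         call. = FALSE)
  lapply(positional, function(p) {
    if (is.numeric(p)) {
      if (length(p) == 1L) p <- rep(p, n)
      if (length(p) != n)
        stop(sprintf("positional map must have 1 or %d values", n), call. = FALSE)
      return(as.integer(p))
    }
    if (is.list(p)) {
      v <- rep(as.integer(if (is.null(p$default)) 0L else p$default), n)
      for (r in p$regions) {
        if (is.null(r$level))
          stop("positional region overrides need a 'level'", call. = FALSE)
        v[region_cells(topology, r$cols, r$rows, r$cells)] <- as.integer(r$level)
      }
      return(v)
    }
    stop("invalid positional map specification", call. = FALSE)
  })
}

.normalize_integration <- function(integration) {
  if (!length(integration)) return(stats::setNames(list(), character()))
  if (is.null(names(integration)))
    stop("'integration' must be a named list (one entry per input component)",
         call. = FALSE)
  out <- lapply(names(integration), function(u) {
    spec <- integration[[u]]
    if (is.character(spec) && length(spec) == 1L)
      spec <- list("1" = spec)
    if (inherits(spec, "integration_rule"))
      spec <- stats::setNames(list(spec), as.character(spec$level))
    if (!is.list(spec) || is.null(names(spec)))
      stop(sprintf("integration rules for '%s' must be a rule or a list named by level", u),
           call. = FALSE)
    lv <- as.integer(names(spec))
    if (any(is.na(lv)) || any(lv < 1L))
      stop(sprintf("integration rule levels for '%s' must be integers >= 1", u),
           call. = FALSE)
    if (anyDuplicated(lv))
      stop(sprintf("duplicate integration rule levels for '%s'", u), call. = FALSE)
    o <- order(lv, decreasing = TRUE)
    lapply(o, function(i) {
      r <- spec[[i]]
      if (is.character(r)) r <- parse_integration_rule(r, target = u, level = lv[i])
      if (!inherits(r, "integration_rule"))
        stop(sprintf("invalid integration rule for '%s' level %d", u, lv[i]),
             call. = FALSE)
      r$target <- u
      r$level <- lv[i]
      r
    })
  })
  stats::setNames(out, names(integration))
}

.normalize_initial <- function(epi, initial) {
  as_state <- function(m) structure(m, class = c("grid_state", "matrix"),
                                    topology = epi$topology)
  tmpl <- .state_template(epi)
  if (is.matrix(initial)) {
    m <- initial
    if (is.null(colnames(m)) || nrow(m) != nrow(tmpl))
      stop("initial state matrix must be cells x components with named columns",
           call. = FALSE)
    out <- tmpl
    shared <- intersect(colnames(m), colnames(tmpl))
    out[, shared] <- m[, shared]
    out[is.na(tmpl)] <- NA_integer_
    return(as_state(out))
  }
  out <- tmpl
  out[!is.na(out)] <- 0L
  spec <- NULL
  if (is.numeric(initial) && !is.null(names(initial))) {
    spec <- list(components = as.list(initial))
  } else if (is.list(initial)) {
    spec <- initial
  } else if (!is.null(initial)) {
    stop("invalid 'initial' specification", call. = FALSE)
  }
  if (!is.null(spec)) {
    if (!is.null(spec$default))
      out[!is.na(out)] <- as.integer(spec$default)
    for (cn in names(spec$components)) {
      if (!cn %in% colnames(out))
        stop("initial state names unknown component: ", cn, call. = FALSE)
      v <- out[, cn]
      v[!is.na(v)] <- as.integer(spec$components[[cn]])
      out[, cn] <- v
    }
    for (r in spec$regions) {
      if (is.null(r$component) || is.null(r$level))
        stop("initial region overrides need 'component' and 'level'", call. = FALSE)
      if (!r$component %in% colnames(out))
        stop("initial state names unknown component: ", r$component, call. = FALSE)
      idx <- region_cells(epi$topology, r$cols, r$rows, r$cells)
      v <- out[idx, r$component]
      v[!is.na(v)] <- as.integer(r$level)
      out[idx, r$component] <- v
    }
  }
  as_state(out)
}

# Template matrix: NA everywhere a component is absent from the cell's model,
# 0 elsewhere (then overwritten by initial specs).
.state_template <- function(epi) {
  n <- .n_cells(epi$topology)
  out <- matrix(NA_integer_, n, nrow(epi$components),
                dimnames = list(NULL, epi$components$name))
  for (mn in names(epi$models)) {
    cells <- which(epi$assignment == mn)
    out[cells, epi$models[[mn]]$components$name] <- 0L
  }
  out
}

#' @export
print.epithelium <- function(x, ...) {
  t <- x$topology
  cat(sprintf("Epithelium model: %dx%d hexagonal grid (%s)\n", t$width, t$height,
              if (t$wrap_horizontal && t$wrap_vertical) "torus"
              else if (t$wrap_horizontal || t$wrap_vertical) "cylinder"
              else "rectangle"))
  cat(sprintf("  models: %s\n", paste(names(x$models), collapse = ", ")))
  if (length(x$positional))
    cat("  positional inputs:", paste(names(x$positional), collapse = ", "), "\n")
  for (u in names(x$integration)) {
    for (r in x$integration[[u]])
      cat(sprintf("  integration input %s >= %d when %s\n", u, r$level,
                  format_expression(r$expression)))
  }
  if (length(x$perturbations)) {
    for (p in x$perturbations)
      cat(sprintf("  perturbation: %s blocked at %d (%s)\n", p$component,
                  p$level, if (length(p$cell_idx) == .n_cells(x$topology))
                    "all cells" else sprintf("%d cells", length(p$cell_idx))))
  }
  invisible(x)
}

## ---- compiled context ------------------------------------------------------

# Precomputed structures shared by every step of a simulation. Built fresh
# per run (epithelium objects stay plain, copy-safe lists).
.epi_context <- function(epi) {
  topo <- epi$topology
  n <- .n_cells(topo)
  comps <- epi$components$name
  tmpl <- .state_template(epi)
  imask <- matrix(FALSE, n, length(comps), dimnames = list(NULL, comps))
  model_cells <- lapply(names(epi$models), function(mn) which(epi$assignment == mn))
  names(model_cells) <- names(epi$models)
  input_cells <- list()  # input component -> cells whose model declares it as input
  for (mn in names(epi$models)) {
    m <- epi$models[[mn]]
    imask[model_cells[[mn]], .model_internal(m)] <- TRUE
    for (u in .model_inputs(m)) {
      input_cells[[u]] <- sort(unique(c(input_cells[[u]], model_cells[[mn]])))
    }
  }
  pert <- lapply(epi$perturbations, function(p) {
    idx <- p$cell_idx
    if (p$component %in% colnames(tmpl))
      idx <- idx[!is.na(tmpl[idx, p$component])]
    list(component = p$component, level = p$level, cells = idx)
  })
  bands <- new.env(parent = emptyenv())
  list(epi = epi, topo = topo, n = n, comps = comps, tmpl = tmpl,
       imask = imask, model_cells = model_cells, input_cells = input_cells,
       pert = pert, adj = .adjacency_list(topo), bands = bands)
}

.ctx_band <- function(ctx, dmin, dmax) {
  key <- paste0(dmin, ":", dmax)
  b <- ctx$bands[[key]]
  if (is.null(b)) {
    b <- .cached_band_matrix(ctx$topo, dmin, dmax, ctx$adj)
    assign(key, b, envir = ctx$bands)
  }
  b
}

# Band matrices depend only on the topology; cache them package-wide so
# repeated runs over the same grid (parameter scans, seed batches) do not
# rebuild the neighbourhood structure.
.pkg_cache <- new.env(parent = emptyenv())

.cached_band_matrix <- function(topo, dmin, dmax, adj) {
  key <- sprintf("band:%d:%d:%d:%d:%d:%d", topo$width, topo$height,
                 topo$wrap_horizontal, topo$wrap_vertical, dmin, dmax)
  b <- .pkg_cache[[key]]
  if (is.null(b)) {
    b <- .band_matrix(topo, dmin, dmax, adj)
    assign(key, b, envir = .pkg_cache)
  }
  b
}

.as_grid_state <- function(ctx, mat) {
  structure(mat, class = c("grid_state", "matrix"),
            topology = ctx$topo)
}

.state_mat <- function(epi, state) {
  mat <- unclass(state)
  attr(mat, "topology") <- NULL
  if (!is.matrix(mat) || is.null(colnames(mat)))
    stop("a grid state must be a cells x components matrix with named columns",
         call. = FALSE)
  if (nrow(mat) != .n_cells(epi$topology))
    stop("grid state has the wrong number of cells for this topology",
         call. = FALSE)
  storage.mode(mat) <- "integer"
  mat
}

## ---- input resolution, clamping --------------------------------------------

# Compute one input component's value for every cell, from internal
# components of `mat` only (two-phase contract).
.integration_values <- function(ctx, rules, mat) {
  val <- integer(ctx$n)
  assigned <- rep(FALSE, ctx$n)
  for (r in rules) {
    sat <- .eval_expr(r$expression, mat, ctx)
    pick <- !assigned & sat
    val[pick] <- r$level
    assigned <- assigned | pick
  }
  val
}

# Set every declared input component of every cell: positional inputs to
# their per-cell map value, integration inputs by their rules evaluated on
# the argument state. Internal components are untouched.
.resolve <- function(ctx, mat) {
  epi <- ctx$epi
  for (u in names(ctx$input_cells)) {
    cells <- ctx$input_cells[[u]]
    if (u %in% names(epi$positional)) {
      mat[cells, u] <- epi$positional[[u]][cells]
    } else if (u %in% names(epi$integration)) {
      v <- .integration_values(ctx, epi$integration[[u]], mat)
      mat[cells, u] <- v[cells]
    } else {
      stop(sprintf("input component '%s' is declared neither positional nor integration",
                   u), call. = FALSE)
    }
  }
  mat
}

.clamp <- function(ctx, mat) {
  for (p in ctx$pert) mat[p$cells, p$component] <- p$level
  mat
}

# One synchronous tissue update from an already resolved+clamped state:
# every cell's internal components stepped from the same snapshot.
.full_step <- function(ctx, resolved) {
  out <- resolved
  for (mn in names(ctx$epi$models)) {
    cells <- ctx$model_cells[[mn]]
    if (!length(cells)) next
    stepped <- .step_matrix(ctx$epi$models[[mn]], resolved[cells, , drop = FALSE])
    if (ncol(stepped)) out[cells, colnames(stepped)] <- stepped
  }
  .clamp(ctx, out)
}

.int_equal <- function(ctx, a, b) {
  all(a[ctx$imask] == b[ctx$imask])
}

.state_key <- function(ctx, mat) paste(mat[ctx$imask], collapse = ",")

#' Resolve the input components of a tissue state
#'
#' Returns `state` with every cell's input components set: positional inputs
#' to their fixed per-cell map value, integration inputs to the highest level
#' whose rule holds over the cell's neighbourhood - computed entirely from the
#' internal components of the argument state (two-phase semantics). Internal
#' components are untouched; perturbation clamps are re-applied.
#'
#' @param epi An [epithelium()].
#' @param state Tissue state matrix (defaults to the model's initial state).
#' @return The resolved state (class `grid_state`).
#' @export
resolve_inputs <- function(epi, state = epi$initial) {
  ctx <- .epi_context(epi)
  mat <- .state_mat(epi, state)
  .as_grid_state(ctx, .clamp(ctx, .resolve(ctx, .clamp(ctx, mat))))
}

#' Apply perturbation clamps to a tissue state
#'
#' @inheritParams resolve_inputs
#' @return The clamped state (class `grid_state`).
#' @export
apply_perturbations <- function(epi, state = epi$initial) {
  ctx <- .epi_context(epi)
  .as_grid_state(ctx, .clamp(ctx, .state_mat(epi, state)))
}

#' Value of an integration input for one cell
#'
#' @param epi An [epithelium()].
#' @param state Tissue state matrix.
#' @param cell `c(col, row)`, 0-based.
#' @param input Name of an integration input component.
#' @return Integer level: the highest rule level satisfied over the cell's
#'   neighbourhood in `state`, else 0.
#' @export
eval_integration_input <- function(epi, state, cell, input) {
  if (!input %in% names(epi$integration))
    stop(sprintf("'%s' is not declared as an integration input", input),
         call. = FALSE)
  ctx <- .epi_context(epi)
  mat <- .state_mat(epi, state)
  .check_coord(epi$topology, as.integer(cell[1L]), as.integer(cell[2L]))
  idx <- .cell_index(epi$topology, as.integer(cell[1L]), as.integer(cell[2L]))
  .integration_values(ctx, epi$integration[[input]], mat)[idx]
}

## ---- validation ------------------------------------------------------------

#' Validate an epithelium model
#'
#' Checks the model's structural invariants and returns human-readable
#' findings (an empty character vector means the model is valid). Simulations
#' refuse to run on models with findings.
#'
#' @param epi An [epithelium()].
#' @return Character vector of findings.
#' @export
validate_epithelium <- function(epi) {
  f <- character()
  comps <- epi$components
  n <- .n_cells(epi$topology)

  input_names <- unique(unlist(lapply(epi$models, .model_inputs)))
  internal_names <- unique(unlist(lapply(epi$models, .model_internal)))

  for (u in intersect(input_names, internal_names))
    f <- c(f, sprintf("component '%s' is an input in one model and internal in another", u))

  both <- intersect(names(epi$positional), names(epi$integration))
  for (u in both)
    f <- c(f, sprintf("input '%s' is declared both positional and integration", u))

  for (u in input_names)
    if (!u %in% c(names(epi$positional), names(epi$integration)))
      f <- c(f, sprintf("input '%s' is declared neither positional nor integration", u))

  for (u in names(epi$positional)) {
    if (!u %in% input_names) {
      f <- c(f, sprintf("positional map given for '%s', which is not an input of any model", u))
      next
    }
    ml <- comps$max_level[match(u, comps$name)]
    v <- epi$positional[[u]]
    if (any(v < 0L | v > ml))
      f <- c(f, sprintf("positional map of '%s' has values outside 0..%d", u, ml))
  }

  for (u in names(epi$integration)) {
    if (!u %in% input_names)
      f <- c(f, sprintf("integration rules given for '%s', which is not an input of any model", u))
    ml <- comps$max_level[match(u, comps$name)]
    for (r in epi$integration[[u]]) {
      if (!is.na(ml) && r$level > ml)
        f <- c(f, sprintf("integration rule level %d exceeds maximum level %d of '%s'",
                          r$level, ml, u))
      for (a in .expr_card_atoms(r$expression)) {
        j <- match(a$comp, comps$name)
        if (is.na(j)) {
          f <- c(f, sprintf("integration rule for '%s' references unknown component '%s'",
                            u, a$comp))
        } else {
          if (!a$comp %in% internal_names)
            f <- c(f, sprintf("integration rule for '%s' references '%s', which is not an internal component (signals come from internal components of neighbouring cells)",
                              u, a$comp))
          if (a$level > comps$max_level[j])
            f <- c(f, sprintf("integration rule for '%s' tests '%s' at level %d, above its maximum %d",
                              u, a$comp, a$level, comps$max_level[j]))
        }
      }
    }
  }

  seen <- list()
  for (p in epi$perturbations) {
    j <- match(p$component, comps$name)
    if (is.na(j)) {
      f <- c(f, sprintf("perturbation targets unknown component '%s'", p$component))
      next
    }
    if (p$level < 0L || p$level > comps$max_level[j])
      f <- c(f, sprintf("perturbation blocks '%s' at %d, outside 0..%d",
                        p$component, p$level, comps$max_level[j]))
    prev <- seen[[p$component]]
    if (!is.null(prev) && length(intersect(prev, p$cell_idx)))
      f <- c(f, sprintf("overlapping perturbation regions for component '%s'",
                        p$component))
    seen[[p$component]] <- c(prev, p$cell_idx)
  }

  tmpl <- .state_template(epi)
  init <- epi$initial
  for (j in seq_len(ncol(init))) {
    v <- init[, j]
    ml <- comps$max_level[j]
    if (any(!is.na(v) & (v < 0L | v > ml)))
      f <- c(f, sprintf("initial state of '%s' has values outside 0..%d",
                        comps$name[j], ml))
    if (any(is.na(v) != is.na(tmpl[, j])))
      f <- c(f, sprintf("initial state of '%s' defined for cells whose model lacks it",
                        comps$name[j]))
  }

  f
}

## ---- grid_state methods ----------------------------------------------------

#' @export
print.grid_state <- function(x, ...) {
  topo <- attr(x, "topology")
  cat(sprintf("Grid state: %d cells x %d components\n", nrow(x), ncol(x)))
  for (cn in colnames(x)) {
    v <- x[, cn]
    tb <- table(v[!is.na(v)])
    cat(sprintf("  %s: %s\n", cn,
                paste(sprintf("level %s x%d", names(tb), as.integer(tb)),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
as.data.frame.grid_state <- function(x, ...) {
  topo <- attr(x, "topology")
  cr <- .cell_coords(topo)
  out <- do.call(rbind, lapply(colnames(x), function(cn) {
    data.frame(col = cr[, "col"], row = cr[, "row"], component = cn,
               level = as.integer(x[, cn]), stringsAsFactors = FALSE)
  }))
  out <- out[!is.na(out$level), , drop = FALSE]
  out <- out[order(out$row, out$col, match(out$component, colnames(x))), ]
  rownames(out) <- NULL
  out
}

#' Override component levels over a region of a state
#'
#' @param state A `grid_state` (or cells x components matrix with a
#'   `topology` attribute).
#' @param component Component name.
#' @param level New level.
#' @param cols,rows,cells Region (see [region_cells()]); all `NULL` = every cell.
#' @return The modified state.
#' @export
set_region <- function(state, component, level, cols = NULL, rows = NULL,
                       cells = NULL) {
  topo <- attr(state, "topology")
  if (is.null(topo))
    stop("'state' carries no topology; use a state produced by this package",
         call. = FALSE)
  if (!component %in% colnames(state))
    stop("unknown component: ", component, call. = FALSE)
  idx <- region_cells(topo, cols, rows, cells)
  v <- state[idx, component]
  v[!is.na(v)] <- as.integer(level)
  state[idx, component] <- v
  state
}

#' Replace a positional input map
#'
#' Convenience setter used in multi-phase (clone) workflows, e.g. removing a
#' morphogen signal before re-running from a stable pattern.
#'
#' @param epi An [epithelium()].
#' @param component Positional input name.
#' @param values Single level or per-cell vector (row-major).
#' @return The modified epithelium.
#' @export
set_positional_input <- function(epi, component, values) {
  if (!component %in% names(epi$positional))
    stop(sprintf("'%s' is not a positional input of this epithelium", component),
         call. = FALSE)
  n <- .n_cells(epi$topology)
  if (length(values) == 1L) values <- rep(values, n)
  if (length(values) != n)
    stop(sprintf("positional map must have 1 or %d values", n), call. = FALSE)
  epi$positional[[component]] <- as.integer(values)
  epi
}
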