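# Cellular logical (Boolean / multi-valued) regulatory models.
#
# A model holds an ordered set of components, each with a maximum level, split
# into inputs (no regulatory rule; value imposed from outside the cell) and
# internal components (one regulatory function each). Multi-valued functions
# are ordered (level, expression) lists: the target value of a component is
# the highest level whose expression holds, else 0. Updates are stepwise:
# a component moves by at most one level per update, toward its target.

#' Construct a cellular logical model
#'
#' @param components Named integer vector of maximum levels, one entry per
#'   component; declaration order is the canonical state-vector order. Boolean
#'   components have maximum level 1.
#' @param inputs Character vector naming the input components (components with
#'   no regulatory function, whose values are imposed externally).
#' @param functions Named list with one entry per internal (non-input)
#'   component. Each entry is either a single expression (string or parsed
#'   tree) defining when the component's target is 1, or, for multi-valued
#'   components, a list named by level (e.g. `list("2" = ..., "1" = ...)`);
#'   the target is the highest level whose expression is true, else 0.
#' @param priorities Optional priority scheme: a list of character vectors
#'   (ordered classes, first = highest priority). Entries are component names,
#'   optionally suffixed `+` (increase only) or `-` (decrease only); a bare
#'   name covers both directions. Every internal component's increase and
#'   decrease must appear in exactly one class. `NULL` means a plain
#'   synchronous cell update.
#' @param name Model identifier (used in project files and SBML export).
#' @return An object of class `logical_model`.
#' @examples
#' dn <- logical_model(
#'   components = c(nb_Red = 1, Green = 1, Red = 1),
#'   inputs = "nb_Red",
#'   functions = list(Green = "nb_Red", Red = "!Green"))
#' update_cell(dn, c(nb_Red = 0, Green = 0, Red = 0))
#' @export
logical_model <- function(components, inputs = character(), functions = list(),
                          priorities = NULL, name = "cell_model") {
  if (is.null(names(components)) || any(!nzchar(names(components))))
    stop("'components' must be a named vector of maximum levels", call. = FALSE)
  nm <- names(components)
  if (anyDuplicated(nm))
    stop("duplicate component names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  maxlev <- as.integer(components)
  if (any(is.na(maxlev)) || any(maxlev < 1L))
    stop("maximum levels must be integers >= 1", call. = FALSE)
  if (length(bad <- setdiff(inputs, nm)))
    stop("unknown input component(s): ", paste(bad, collapse = ", "), call. = FALSE)

  comp <- data.frame(name = nm, max_level = maxlev,
                     is_input = nm %in% inputs, stringsAsFactors = FALSE)
  internal <- comp$name[!comp$is_input]

  if (length(miss <- setdiff(internal, names(functions))))
    stop("missing regulatory function for internal component(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (length(extra <- setdiff(names(functions), internal)))
    stop("function given for non-internal component(s): ",
         paste(extra, collapse = ", "), call. = FALSE)

  funs <- lapply(internal, function(cn) {
    .normalize_function(functions[[cn]], cn, comp)
  })
  names(funs) <- internal

  pr <- if (!is.null(priorities)) .normalize_priorities(priorities, internal)

  structure(list(components = comp, functions = funs, priorities = pr,
                 name = name),
            class = "logical_model")
}

# One function = list of list(level, expr), levels distinct, sorted descending.
.normalize_function <- function(f, owner, comp) {
  maxl <- comp$max_level[match(owner, comp$name)]
  as_expr <- function(x) if (is.character(x)) parse_logic_expression(x) else x
  if (is.character(f) || (is.list(f) && !is.null(f$type))) {
    pairs <- list(list(level = 1L, expr = as_expr(f)))
  } else if (is.list(f)) {
    if (is.null(names(f)) || any(!nzchar(names(f))))
      stop(sprintf("multi-valued function for '%s' must be a list named by level",
                   owner), call. = FALSE)
    lv <- as.integer(names(f))
    if (any(is.na(lv)) || any(lv < 1L) || any(lv > maxl))
      stop(sprintf("function levels for '%s' must lie in 1..%d", owner, maxl),
           call. = FALSE)
    if (anyDuplicated(lv))
      stop(sprintf("duplicate function levels for '%s'", owner), call. = FALSE)
    o <- order(lv, decreasing = TRUE)
    pairs <- lapply(o, function(i) list(level = lv[i], expr = as_expr(f[[i]])))
  } else {
    stop(sprintf("invalid function specification for '%s'", owner), call. = FALSE)
  }
  for (p in pairs) .check_cell_expr(p$expr, owner, comp)
  pairs
}

.check_cell_expr <- function(expr, owner, comp) {
  walk <- function(e) {
    if (e$type == "card")
      stop(sprintf("function of '%s' uses a neighbourhood atom; those belong in integration rules",
                   owner), call. = FALSE)
    if (e$type == "atom") {
      i <- match(e$comp, comp$name)
      if (is.na(i))
        stop(sprintf("function of '%s' references undeclared component '%s'",
                     owner, e$comp), call. = FALSE)
      if (e$level < 0L || e$level > comp$max_level[i])
        stop(sprintf("function of '%s': level %d outside range 0..%d of '%s'",
                     owner, e$level, comp$max_level[i], e$comp), call. = FALSE)
    }
    if (e$type == "not") walk(e$x)
    if (e$type %in% c("and", "or")) lapply(e$args, walk)
    invisible(NULL)
  }
  walk(expr)
}

# Priorities -> list of data.frames (comp, dir in "+"/"-"), one per class.
.normalize_priorities <- function(priorities, internal) {
  if (!is.list(priorities))
    stop("'priorities' must be a list of character vectors", call. = FALSE)
  classes <- lapply(priorities, function(cl) {
    if (!is.character(cl) || !length(cl))
      stop("each priority class must be a non-empty character vector", call. = FALSE)
    comp <- sub("[+-]$", "", cl)
    sfx <- ifelse(grepl("\\+$", cl), "+", ifelse(grepl("-$", cl), "-", "both"))
    out <- data.frame(comp = rep(comp, ifelse(sfx == "both", 2L, 1L)),
                      dir = unlist(Map(function(c0, s)
                        if (s == "both") c("+", "-") else s, comp, sfx)),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
  seen <- do.call(rbind, classes)
  if (length(bad <- setdiff(seen$comp, internal)))
    stop("priority classes mention non-internal component(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  key <- paste(seen$comp, seen$dir)
  need <- c(paste(internal, "+"), paste(internal, "-"))
  if (anyDuplicated(key))
    stop("component direction listed in more than one priority class: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  if (length(miss <- setdiff(need, key)))
    stop("priority classes must cover every internal component in both directions; missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  classes
}

#' @export
print.logical_model <- function(x, ...) {
  ni <- sum(x$components$is_input)
  cat(sprintf("Logical model '%s': %d components (%d input%s, %d internal)\n",
              x$name, nrow(x$components), ni, if (ni == 1) "" else "s",
              nrow(x$components) - ni))
  for (i in seq_len(nrow(x$components))) {
    cn <- x$components$name[i]
    ml <- x$components$max_level[i]
    if (x$components$is_input[i]) {
      cat(sprintf("  %s [0..%d] <- input\n", cn, ml))
    } else {
      for (p in x$functions[[cn]])
        cat(sprintf("  %s := %d when %s\n", cn, p$level, format_expression(p$expr)))
    }
  }
  if (!is.null(x$priorities)) {
    cat("  priority classes:",
        paste(vapply(x$priorities, function(cl)
          paste0("{", paste0(cl$comp, cl$dir, collapse = ","), "}"), ""),
          collapse = " > "), "\n")
  }
  invisible(x)
}

.model_internal <- function(model) model$components$name[!model$components$is_input]
.model_inputs <- function(model) model$components$name[model$components$is_input]

# Coerce a named cell-state vector to a 1-row matrix in canonical order.
.as_state_row <- function(model, state) {
  nm <- model$components$name
  if (is.null(names(state))) {
    if (length(state) != length(nm))
      stop("unnamed cell state must have one value per component", call. = FALSE)
    names(state) <- nm
  }
  if (length(miss <- setdiff(nm, names(state))))
    stop("cell state is missing component(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  matrix(as.integer(state[nm]), nrow = 1L, dimnames = list(NULL, nm))
}

#' Evaluate a logical expression in a cell state
#'
#' @param expr Expression tree or string (see [parse_logic_expression()]).
#' @param state Named integer vector of component levels.
#' @return `TRUE` or `FALSE`.
#' @examples
#' eval_expression("Red>=1", c(Red = 1, Green = 0))
#' @export
eval_expression <- function(expr, state) {
  if (is.character(expr)) expr <- parse_logic_expression(expr)
  mat <- matrix(as.integer(state), nrow = 1L,
                dimnames = list(NULL, names(state)))
  as.logical(.eval_expr(expr, mat))
}

# Target levels for all internal components over a block of states.
# `mat`: cells x components (canonical columns present). Returns a
# cells x internal matrix.
.targets_matrix <- function(model, mat) {
  internal <- .model_internal(model)
  n <- nrow(mat)
  out <- matrix(0L, n, length(internal), dimnames = list(NULL, internal))
  for (cn in internal) {
    assigned <- rep(FALSE, n)
    tg <- integer(n)
    for (p in model$functions[[cn]]) {       # levels descending: highest wins
      sat <- .eval_expr(p$expr, mat)
      pick <- !assigned & sat
      tg[pick] <- p$level
      assigned <- assigned | pick
    }
    out[, cn] <- tg
  }
  out
}

# Stepwise update of all internal components for a block of states, honouring
# priority classes. Returns the cells x internal matrix of new levels.
.step_matrix <- function(model, mat) {
  internal <- .model_internal(model)
  if (!length(internal))
    return(matrix(integer(), nrow(mat), 0L))
  cur <- mat[, internal, drop = FALSE]
  tg <- .targets_matrix(model, mat)
  pending <- sign(tg - cur)
  if (is.null(model$priorities))
    return(cur + pending)
  new <- cur
  remaining <- rep(TRUE, nrow(mat))
  for (cl in model$priorities) {
    hit <- matrix(FALSE, nrow(mat), nrow(cl))
    for (j in seq_len(nrow(cl))) {
      p <- pending[, cl$comp[j]]
      hit[, j] <- if (cl$dir[j] == "+") p > 0 else p < 0
    }
    fire <- remaining & rowSums(hit) > 0
    if (any(fire)) {
      for (j in seq_len(nrow(cl))) {
        rows <- fire & hit[, j]
        cn <- cl$comp[j]
        new[rows, cn] <- cur[rows, cn] + pending[rows, cn]
      }
    }
    remaining <- remaining & !fire
  }
  new
}

#' Target level of an internal component
#'
#' The value toward which a component moves: the highest declared level of its
#' regulatory function whose expression holds in `state`, else 0.
#'
#' @param model A [logical_model()].
#' @param component Name of an internal component.
#' @param state Named integer vector with every component (inputs resolved).
#' @return Integer target level.
#' @export
target_level <- function(model, component, state) {
  comp <- model$components
  i <- match(component, comp$name)
  if (is.na(i)) stop("unknown component: ", component, call. = FALSE)
  if (comp$is_input[i])
    stop(sprintf("'%s' is an input component; inputs have no regulatory function",
                 component), call. = FALSE)
  mat <- .as_state_row(model, state)
  .check_state_range(model, mat)
  as.integer(.targets_matrix(model, mat)[1L, component])
}

.check_state_range <- function(model, mat) {
  ml <- model$components$max_level
  bad <- which(mat < 0L | sweep(mat, 2L, ml, `>`), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("component '%s' out of range 0..%d",
                 model$components$name[bad[1L, 2L]], ml[bad[1L, 2L]]),
         call. = FALSE)
  invisible(NULL)
}

#' Stepwise component update
#'
#' Multi-valued components move by at most one level per update, toward their
#' target: `current + sign(target - current)`. For Boolean components this
#' coincides with jumping straight to the target.
#'
#' @param current,target Integer level(s); vectorized.
#' @return Updated level(s).
#' @export
step_component <- function(current, target) {
  as.integer(current + sign(target - current))
}

#' Update a single cell
#'
#' Applies one stepwise update of all internal components toward their targets,
#' computed from the given state (inputs must already be resolved). With
#' priority classes, classes are scanned in order and only the members of the
#' first class with a pending update in a matching direction are stepped;
#' all other components keep their levels. Inputs are never modified.
#'
#' @param model A [logical_model()].
#' @param state Named integer vector over all components.
#' @return The successor cell state (named integer vector, canonical order).
#' @export
update_cell <- function(model, state) {
  mat <- .as_state_row(model, state)
  .check_state_range(model, mat)
  new <- mat[1L, ]
  stepped <- .step_matrix(model, mat)
  if (ncol(stepped)) new[colnames(stepped)] <- stepped[1L, ]
  new
}

#' Is a cell state stable?
#'
#' A cell state is stable when every internal component already sits at its
#' target level, i.e. the cell update is a fixed point.
#'
#' @inheritParams update_cell
#' @return `TRUE` or `FALSE`.
#' @export
is_cell_stable <- function(model, state) {
  mat <- .as_state_row(model, state)
  .check_state_range(model, mat)
  internal <- .model_internal(model)
  if (!length(internal)) return(TRUE)
  all(.targets_matrix(model, mat)[1L, ] == mat[1L, internal])
}

#' Enumerate all states of a logical model
#'
#' Every combination of component levels, inputs included; useful for
#' exhaustive checks on small models.
#'
#' @param model A [logical_model()].
#' @return Integer matrix, one row per state, columns in canonical order.
#' @export
enumerate_states <- function(model) {
  comp <- model$components
  grid <- do.call(expand.grid, c(lapply(comp$max_level, function(m) 0:m),
                                 KEEP.OUT.ATTRS = FALSE))
  m <- as.matrix(grid)
  storage.mode(m) <- "integer"
  colnames(m) <- comp$name
  m
}
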