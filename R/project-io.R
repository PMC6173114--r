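# Project files: a plain-text YAML dialect binding together a grid, cellular
# models (as SBML qual files or inline documents), input semantics,
# perturbations, an initial state and simulation settings. Saving is
# deterministic (fixed key order, canonical value forms) so project files
# diff cleanly and two saves of the same model are byte-identical.
#
# Layout:
#   grid:        {width, height, wrap: none|horizontal|vertical|torus}
#   models:      name -> {file: path} | {inline: "<sbml ...>"}
#   assignment:  model name | list of {model, cols, rows, cells} regions
#   inputs:      name -> {kind: positional, default, regions: [{level, ...}]}
#                name -> {kind: integration, rules: {level: "rule text"}}
#   perturbations: [{component, level, cols, rows, cells}]
#   initial:     {default, components: {...}, regions: [{component, level, ...}]}
#   simulation:  {scheme, alpha, seed, max_steps, sampling}

#' Load an epithelium project
#'
#' Reads a project document (see the package README for the dialect), loads
#' its cellular models (relative SBML paths are resolved against the project
#' file's directory), assembles the epithelium and validates it. All
#' validation findings are reported together on failure.
#'
#' @param path Project file path.
#' @return List with elements `epithelium` and `config`.
#' @export
load_project <- function(path) {
  if (!file.exists(path))
    stop("project file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  dir <- dirname(normalizePath(path))

  g <- doc$grid
  if (is.null(g$width) || is.null(g$height))
    stop("project error: 'grid' must give 'width' and 'height'", call. = FALSE)
  wrap <- if (is.null(g$wrap)) "none" else g$wrap
  if (!wrap %in% c("none", "horizontal", "vertical", "torus"))
    stop("project error: grid 'wrap' must be none, horizontal, vertical or torus",
         call. = FALSE)
  topo <- tryCatch(
    hex_topology(g$width, g$height,
                 wrap_horizontal = wrap %in% c("horizontal", "torus"),
                 wrap_vertical = wrap %in% c("vertical", "torus")),
    error = function(e) stop("project error in 'grid': ", conditionMessage(e),
                             call. = FALSE))

  if (is.null(doc$models) || !length(doc$models))
    stop("project error: no 'models' section", call. = FALSE)
  models <- lapply(names(doc$models), function(mn) {
    m <- doc$models[[mn]]
    src <- if (!is.null(m$inline)) m$inline
    else if (!is.null(m$file)) {
      p <- m$file
      if (!file.exists(p)) p <- file.path(dir, m$file)
      if (!file.exists(p))
        stop("project error: model file not found: ", m$file, call. = FALSE)
      p
    } else stop("project error: model '", mn, "' needs 'file' or 'inline'",
                call. = FALSE)
    mdl <- read_sbml_qual(src)
    mdl$name <- mn
    mdl
  })
  names(models) <- names(doc$models)

  assignment <- doc$assignment
  if (is.null(assignment)) assignment <- names(models)[1L]
  if (is.list(assignment) && !any(vapply(assignment, is.list, TRUE)))
    assignment <- unlist(assignment)  # per-cell list of model names

  positional <- list()
  integration <- list()
  for (u in names(doc$inputs)) {
    spec <- doc$inputs[[u]]
    kind <- spec$kind
    if (identical(kind, "positional")) {
      positional[[u]] <-
        if (!is.null(spec$values)) unlist(spec$values)
        else list(default = if (is.null(spec$default)) 0L else spec$default,
                  regions = spec$regions)
    } else if (identical(kind, "integration")) {
      rules <- spec$rules
      if (is.null(rules))
        stop("project error: integration input '", u, "' has no 'rules'",
             call. = FALSE)
      integration[[u]] <- lapply(rules, identity)
    } else {
      stop("project error: input '", u,
           "' must have kind 'positional' or 'integration'", call. = FALSE)
    }
  }

  perturbations <- lapply(doc$perturbations, function(p) {
    if (is.null(p$component) || is.null(p$level))
      stop("project error: perturbations need 'component' and 'level'",
           call. = FALSE)
    perturbation(p$component, p$level, cols = .yaml_range(p$cols),
                 rows = .yaml_range(p$rows), cells = .yaml_cells(p$cells))
  })

  initial <- doc$initial
  if (!is.null(initial)) {
    initial$regions <- lapply(initial$regions, function(r) {
      r$cols <- .yaml_range(r$cols)
      r$rows <- .yaml_range(r$rows)
      r$cells <- .yaml_cells(r$cells)
      r
    })
  }

  epi <- epithelium(topo, models, assignment = assignment,
                    positional = positional, integration = integration,
                    perturbations = perturbations, initial = initial)
  findings <- validate_epithelium(epi)
  if (length(findings))
    stop("project '", basename(path), "' is invalid:\n  ",
         paste(findings, collapse = "\n  "), call. = FALSE)

  s <- doc$simulation
  cfg <- if (is.null(s)) simulation_config("synchronous")
  else tryCatch(
    simulation_config(
      scheme = if (is.null(s$scheme)) "synchronous" else s$scheme,
      alpha = if (is.null(s$alpha)) 0.25 else s$alpha,
      seed = s$seed,
      max_steps = if (is.null(s$max_steps)) 1000L else s$max_steps,
      sampling = if (is.null(s$sampling)) "exact" else s$sampling),
    error = function(e) stop("project error in 'simulation': ",
                             conditionMessage(e), call. = FALSE))

  list(epithelium = epi, config = cfg)
}

.yaml_range <- function(x) if (is.null(x)) NULL else as.integer(unlist(x))
.yaml_cells <- function(x) {
  if (is.null(x)) return(NULL)
  do.call(rbind, lapply(x, function(p) as.integer(unlist(p))))
}

#' Save an epithelium project
#'
#' Writes the project document plus one SBML qual sidecar file per cellular
#' model (named `<project>-<model>.sbml`, referenced relatively). Key order
#' and value forms are canonical, so saving the same model twice produces
#' byte-identical files.
#'
#' @param epi An [epithelium()] passing [validate_epithelium()].
#' @param config A [simulation_config()].
#' @param path Output project file path.
#' @return `path`, invisibly.
#' @export
save_project <- function(epi, config, path) {
  stopifnot(inherits(epi, "epithelium"), inherits(config, "sim_config"))
  findings <- validate_epithelium(epi)
  if (length(findings))
    stop("refusing to save an invalid epithelium:\n  ",
         paste(findings, collapse = "\n  "), call. = FALSE)
  topo <- epi$topology
  n <- .n_cells(topo)
  base <- sub("\\.[A-Za-z0-9]+$", "", basename(path))
  dir <- dirname(path)

  doc <- list()
  doc$grid <- list(width = topo$width, height = topo$height,
                   wrap = if (topo$wrap_horizontal && topo$wrap_vertical) "torus"
                   else if (topo$wrap_horizontal) "horizontal"
                   else if (topo$wrap_vertical) "vertical" else "none")

  doc$models <- list()
  for (mn in names(epi$models)) {
    fn <- paste0(base, "-", mn, ".sbml")
    write_sbml_qual(epi$models[[mn]], file.path(dir, fn))
    doc$models[[mn]] <- list(file = fn)
  }

  doc$assignment <- if (length(unique(epi$assignment)) == 1L)
    epi$assignment[1L] else as.list(epi$assignment)

  inputs <- list()
  for (u in names(epi$positional)) {
    v <- epi$positional[[u]]
    inputs[[u]] <- if (length(unique(v)) == 1L)
      list(kind = "positional", default = v[1L])
    else list(kind = "positional", values = as.list(v))
  }
  for (u in names(epi$integration)) {
    rules <- epi$integration[[u]]
    rl <- lapply(rules, function(r) format_expression(r$expression))
    names(rl) <- vapply(rules, function(r) as.character(r$level), "")
    rl <- rl[order(as.integer(names(rl)))]
    inputs[[u]] <- list(kind = "integration", rules = rl)
  }
  if (length(inputs)) doc$inputs <- inputs

  if (length(epi$perturbations)) {
    doc$perturbations <- lapply(epi$perturbations, function(p) {
      out <- list(component = p$component, level = p$level)
      if (length(p$cell_idx) < n) {
        cr <- .cell_coords(topo, p$cell_idx)
        out$cells <- lapply(seq_len(nrow(cr)),
                            function(i) as.list(unname(cr[i, ])))
      }
      out
    })
  }

  doc$initial <- .initial_spec(epi)
  doc$simulation <- c(list(scheme = config$scheme),
                      if (config$scheme == "alpha")
                        list(alpha = config$alpha, seed = config$seed,
                             sampling = config$sampling),
                      list(max_steps = config$max_steps))

  txt <- yaml::as.yaml(doc, indent.mapping.sequence = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "")
  invisible(path)
}

# Canonical compact form of the initial state: per-component default plus
# explicit per-cell overrides where a component deviates from its default.
.initial_spec <- function(epi) {
  init <- epi$initial
  topo <- epi$topology
  comps <- list()
  regions <- list()
  for (cn in colnames(init)) {
    v <- init[, cn]
    def <- if (all(is.na(v))) 0L else as.integer(names(sort(table(v), decreasing = TRUE))[1L])
    comps[[cn]] <- def
    dev <- which(!is.na(v) & v != def)
    for (i in dev) {
      cr <- .cell_coords(topo, i)
      regions[[length(regions) + 1L]] <-
        list(component = cn, level = as.integer(v[i]),
             cells = list(as.list(unname(cr[1L, ]))))
    }
  }
  out <- list(components = comps)
  if (length(regions)) out$regions <- regions
  out
}
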