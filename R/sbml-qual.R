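# SBML Level 3 "qual" (Qualitative Models) import/export of cellular logical
# models. Navigation is namespace-prefix agnostic (local names + attribute
# local names), since tools emit the qual prefix differently. Only the model
# structure is exchanged: qualitative species (with maxLevel), transitions
# with MathML function terms; layout and annotations are ignored.

.XMLNS_SBML <- "http://www.sbml.org/sbml/level3/version1/core"
.XMLNS_QUAL <- "http://www.sbml.org/sbml/level3/version1/qual/version1"
.XMLNS_MATH <- "http://www.w3.org/1998/Math/MathML"

# Attribute lookup by local name, ignoring any namespace prefix.
.qattr <- function(node, name) {
  a <- xml2::xml_attrs(node)
  hit <- which(names(a) == name | grepl(paste0(":", name, "$"), names(a)))
  if (!length(hit)) NA_character_ else unname(a[hit[1L]])
}

.lname <- function(name) sprintf("*[local-name()='%s']", name)
.xfind <- function(node, ...) {
  xml2::xml_find_all(node, paste0(".//", paste(vapply(list(...), .lname, ""),
                                               collapse = "/")))
}

#' Read a cellular logical model from SBML qual
#'
#' Imports an SBML Level 3 document using the Qualitative Models package.
#' Each qualitative species becomes a component (maximum level from its
#' `maxLevel` attribute, default 1). Species that are the output of no
#' transition are identified as input components. Each transition's function
#' terms become the (level, expression) list of its output component, with
#' the default term as level 0; the MathML condition is normalised to the
#' atom algebra over `>=`, `=`, `<`.
#'
#' @param x Path to an SBML file, or a string containing the document.
#' @return A [logical_model()].
#' @export
read_sbml_qual <- function(x) {
  doc <- if (length(x) == 1L && grepl("^\\s*<", x)) xml2::read_xml(x)
  else xml2::read_xml(x)

  species <- .xfind(doc, "listOfQualitativeSpecies", "qualitativeSpecies")
  if (!length(species))
    stop("SBML qual parse error: no qualitativeSpecies found", call. = FALSE)
  ids <- vapply(species, .qattr, "", "id")
  if (any(is.na(ids) | !nzchar(ids)))
    stop("SBML qual parse error: qualitativeSpecies without an id", call. = FALSE)
  if (anyDuplicated(ids))
    stop("SBML qual parse error: duplicate qualitativeSpecies id '",
         ids[duplicated(ids)][1L], "'", call. = FALSE)
  maxlev <- vapply(species, function(s) {
    ml <- .qattr(s, "maxLevel")
    if (is.na(ml)) 1L else as.integer(ml)
  }, 0L)
  if (any(is.na(maxlev) | maxlev < 1L))
    stop("SBML qual parse error: invalid maxLevel on species '",
         ids[which(is.na(maxlev) | maxlev < 1L)[1L]], "'", call. = FALSE)
  comp <- stats::setNames(maxlev, ids)

  transitions <- .xfind(doc, "listOfTransitions", "transition")
  functions <- list()
  outputs_seen <- character()
  for (tr in transitions) {
    outs <- .xfind(tr, "listOfOutputs", "output")
    out_ids <- vapply(outs, .qattr, "", "qualitativeSpecies")
    if (!length(out_ids))
      stop("SBML qual parse error: transition '", .qattr(tr, "id"),
           "' has no output", call. = FALSE)
    terms <- .xfind(tr, "listOfFunctionTerms", "functionTerm")
    dft <- .xfind(tr, "listOfFunctionTerms", "defaultTerm")
    if (length(dft)) {
      dl <- as.integer(.qattr(dft[[1L]], "resultLevel"))
      if (!is.na(dl) && dl != 0L)
        stop("SBML qual parse error: non-zero defaultTerm resultLevel in transition '",
             .qattr(tr, "id"), "' is not supported", call. = FALSE)
    }
    pairs <- list()
    for (ft in terms) {
      lvl <- as.integer(.qattr(ft, "resultLevel"))
      if (is.na(lvl))
        stop("SBML qual parse error: functionTerm without resultLevel in transition '",
             .qattr(tr, "id"), "'", call. = FALSE)
      if (lvl == 0L) next
      math <- xml2::xml_find_first(ft, paste0("./", .lname("math")))
      if (inherits(math, "xml_missing"))
        stop("SBML qual parse error: functionTerm without math in transition '",
             .qattr(tr, "id"), "'", call. = FALSE)
      kids <- xml2::xml_children(math)
      if (length(kids) != 1L)
        stop("SBML qual parse error: math element must have one child", call. = FALSE)
      pairs[[as.character(lvl)]] <- .mathml_to_expr(kids[[1L]], names(comp))
    }
    if (!length(pairs)) {
      # transition with only a default term: component is constantly 0
      pairs <- list("1" = .econst(FALSE))
    }
    for (oid in out_ids) {
      if (!oid %in% names(comp))
        stop("SBML qual parse error: transition output '", oid,
             "' is not a declared species", call. = FALSE)
      if (oid %in% outputs_seen)
        stop("SBML qual parse error: species '", oid,
             "' is the output of more than one transition", call. = FALSE)
      outputs_seen <- c(outputs_seen, oid)
      functions[[oid]] <- pairs
    }
  }

  constant <- vapply(species, function(s) identical(.qattr(s, "constant"), "true"), FALSE)
  if (any(constant & ids %in% outputs_seen))
    stop("SBML qual parse error: constant species '",
         ids[constant & ids %in% outputs_seen][1L],
         "' is the output of a transition", call. = FALSE)
  inputs <- ids[!(ids %in% outputs_seen)]

  mid <- .qattr(xml2::xml_find_first(doc, paste0("//", .lname("model"))), "id")
  logical_model(components = comp, inputs = inputs, functions = functions,
                name = if (is.na(mid) || !nzchar(mid)) "sbml_model" else mid)
}

# MathML -> expression tree over atoms (comp >= k / = k / < k).
.mathml_to_expr <- function(node, species) {
  nm <- xml2::xml_name(node)
  if (nm == "true") return(.econst(TRUE))
  if (nm == "false") return(.econst(FALSE))
  if (nm != "apply")
    stop("SBML qual parse error: unsupported MathML element <", nm, ">",
         call. = FALSE)
  kids <- xml2::xml_children(node)
  op <- xml2::xml_name(kids[[1L]])
  args <- kids[-1L]
  if (op %in% c("and", "or")) {
    sub <- lapply(args, .mathml_to_expr, species = species)
    return(if (op == "and") .eand(sub) else .eor(sub))
  }
  if (op == "not") {
    if (length(args) != 1L)
      stop("SBML qual parse error: <not> takes one operand", call. = FALSE)
    return(.enot(.mathml_to_expr(args[[1L]], species)))
  }
  if (op %in% c("geq", "leq", "gt", "lt", "eq")) {
    if (length(args) != 2L)
      stop("SBML qual parse error: <", op, "> takes two operands", call. = FALSE)
    side <- lapply(args, function(a) {
      an <- xml2::xml_name(a)
      if (an == "ci") {
        id <- trimws(xml2::xml_text(a))
        if (!id %in% species)
          stop("SBML qual parse error: math references unknown species '",
               id, "'", call. = FALSE)
        list(kind = "ci", id = id)
      } else if (an == "cn") {
        v <- suppressWarnings(as.integer(trimws(xml2::xml_text(a))))
        if (is.na(v))
          stop("SBML qual parse error: non-integer <cn> value", call. = FALSE)
        list(kind = "cn", value = v)
      } else {
        stop("SBML qual parse error: unsupported operand <", an,
             "> in comparison", call. = FALSE)
      }
    })
    kinds <- vapply(side, `[[`, "", "kind")
    if (identical(kinds, c("ci", "cn"))) {
      id <- side[[1L]]$id; k <- side[[2L]]$value
    } else if (identical(kinds, c("cn", "ci"))) {
      # mirror the comparison so the species is on the left
      id <- side[[2L]]$id; k <- side[[1L]]$value
      op <- switch(op, geq = "leq", leq = "geq", gt = "lt", lt = "gt", eq = "eq")
    } else {
      stop("SBML qual parse error: comparison must relate a species and an integer",
           call. = FALSE)
    }
    return(switch(op,
      geq = .eatom(id, ">=", k),
      gt = .eatom(id, ">=", k + 1L),
      lt = .eatom(id, "<", k),
      leq = .eatom(id, "<", k + 1L),
      eq = .eatom(id, "=", k)))
  }
  stop("SBML qual parse error: unsupported MathML operator <", op, ">",
       call. = FALSE)
}

#' Write a cellular logical model as SBML qual
#'
#' Emits an SBML Level 3 Version 1 document with the Qualitative Models
#' package: one qualitative species per component (inputs marked
#' `constant="true"`), one transition per internal component with a function
#' term per declared level and a level-0 default term. Output bytes are
#' deterministic for a given model.
#'
#' @param model A [logical_model()].
#' @param path Output file path; `NULL` returns the document as a string.
#' @return `path` (or the XML string), invisibly.
#' @export
write_sbml_qual <- function(model, path = NULL) {
  stopifnot(inherits(model, "logical_model"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  math_of <- function(e, ind) {
    pad <- strrep(" ", ind)
    switch(e$type,
      const = paste0(pad, if (e$value) "<true/>" else "<false/>"),
      atom = {
        op <- switch(e$op, ">=" = "geq", "=" = "eq", "<" = "lt")
        paste0(pad, "<apply>\n",
               pad, "  <", op, "/>\n",
               pad, "  <ci> ", esc(e$comp), " </ci>\n",
               pad, "  <cn type=\"integer\"> ", e$level, " </cn>\n",
               pad, "</apply>")
      },
      not = paste0(pad, "<apply>\n", pad, "  <not/>\n",
                   math_of(e$x, ind + 2L), "\n", pad, "</apply>"),
      and = ,
      or = paste0(pad, "<apply>\n", pad, "  <", e$type, "/>\n",
                  paste(vapply(e$args, math_of, "", ind = ind + 2L),
                        collapse = "\n"), "\n", pad, "</apply>"),
      stop("cannot serialise expression node of type '", e$type,
           "' to SBML math", call. = FALSE))
  }

  comp <- model$components
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<sbml xmlns=\"%s\" level=\"3\" version=\"1\" ",
                   "xmlns:qual=\"%s\" qual:required=\"true\">"),
            .XMLNS_SBML, .XMLNS_QUAL),
    sprintf("  <model id=\"%s\">", esc(model$name)),
    "    <qual:listOfQualitativeSpecies>")
  for (i in seq_len(nrow(comp))) {
    out <- c(out, sprintf(
      "      <qual:qualitativeSpecies qual:id=\"%s\" qual:maxLevel=\"%d\" qual:constant=\"%s\"/>",
      esc(comp$name[i]), comp$max_level[i],
      if (comp$is_input[i]) "true" else "false"))
  }
  out <- c(out, "    </qual:listOfQualitativeSpecies>",
           "    <qual:listOfTransitions>")
  for (cn in .model_internal(model)) {
    pairs <- model$functions[[cn]]
    regs <- sort(unique(unlist(lapply(pairs, function(p) .expr_components(p$expr)))))
    out <- c(out, sprintf("      <qual:transition qual:id=\"tr_%s\">", esc(cn)))
    if (length(regs)) {
      out <- c(out, "        <qual:listOfInputs>")
      for (rg in regs)
        out <- c(out, sprintf(
          "          <qual:input qual:qualitativeSpecies=\"%s\" qual:transitionEffect=\"none\"/>",
          esc(rg)))
      out <- c(out, "        </qual:listOfInputs>")
    }
    out <- c(out,
      "        <qual:listOfOutputs>",
      sprintf("          <qual:output qual:qualitativeSpecies=\"%s\" qual:transitionEffect=\"assignmentLevel\"/>",
              esc(cn)),
      "        </qual:listOfOutputs>",
      "        <qual:listOfFunctionTerms>",
      "          <qual:defaultTerm qual:resultLevel=\"0\"/>")
    for (p in pairs) {
      out <- c(out,
        sprintf("          <qual:functionTerm qual:resultLevel=\"%d\">", p$level),
        sprintf("            <math xmlns=\"%s\">", .XMLNS_MATH),
        math_of(p$expr, 14L),
        "            </math>",
        "          </qual:functionTerm>")
    }
    out <- c(out, "        </qual:listOfFunctionTerms>",
             "      </qual:transition>")
  }
  out <- c(out, "    </qual:listOfTransitions>", "  </model>", "</sbml>", "")
  txt <- paste(out, collapse = "\n")
  if (is.null(path)) return(invisible(txt))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "")
  invisible(path)
}
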