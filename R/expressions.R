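# Logical expression trees shared by cellular regulatory functions and
# tissue-level integration rules.
#
# Node types (plain lists, `type` field):
#   const : value TRUE/FALSE
#   atom  : comp, op (">=", "=", "<"), level      -- test on the cell's own state
#   card  : comp, level, dmin, dmax, quant ("atleast"/"all"), k
#           -- neighbourhood cardinality test used only in integration rules
#   not   : x
#   and   : args (list of nodes)
#   or    : args (list of nodes)

.econst <- function(value) list(type = "const", value = isTRUE(value))
.eatom <- function(comp, op, level) {
  list(type = "atom", comp = comp, op = op, level = as.integer(level))
}
.ecard <- function(comp, level, dmin, dmax, quant, k = NA_integer_) {
  list(type = "card", comp = comp, level = as.integer(level),
       dmin = as.integer(dmin), dmax = as.integer(dmax),
       quant = quant, k = as.integer(k))
}
.enot <- function(x) list(type = "not", x = x)
.eand <- function(args) if (length(args) == 1L) args[[1L]] else list(type = "and", args = args)
.eor <- function(args) if (length(args) == 1L) args[[1L]] else list(type = "or", args = args)

## ---- tokenizer -------------------------------------------------------------

.tokenize <- function(text) {
  pats <- c(
    ws = "\\s+",
    name = "[A-Za-z_][A-Za-z0-9_]*",
    int = "[0-9]+",
    ge = ">=",
    eqeq = "==",
    eq = "=",
    lt = "<",
    and = "&",
    or = "\\|",
    not = "!",
    lpar = "\\(",
    rpar = "\\)",
    lbrk = "\\[",
    rbrk = "\\]",
    colon = ":"
  )
  toks <- list()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    hit <- NULL
    for (ty in names(pats)) {
      m <- regmatches(rest, regexpr(paste0("^(", pats[[ty]], ")"), rest))
      if (length(m) == 1L) {
        hit <- list(type = ty, value = m, pos = pos)
        break
      }
    }
    if (is.null(hit)) {
      stop(sprintf("syntax error at position %d: unexpected character '%s'",
                   pos, substr(text, pos, pos)), call. = FALSE)
    }
    if (hit$type != "ws") toks[[length(toks) + 1L]] <- hit
    pos <- pos + nchar(hit$value)
  }
  toks[[length(toks) + 1L]] <- list(type = "end", value = "", pos = pos)
  toks
}

## ---- recursive-descent parser ----------------------------------------------

.parser <- function(text) {
  env <- new.env(parent = emptyenv())
  env$toks <- .tokenize(text)
  env$i <- 1L
  env$text <- text
  env
}

.peek <- function(P) P$toks[[P$i]]
.take <- function(P) {
  t <- P$toks[[P$i]]
  P$i <- P$i + 1L
  t
}
.expect <- function(P, type, what = type) {
  t <- .peek(P)
  if (t$type != type) .pfail(P, sprintf("expected %s", what))
  .take(P)
}
.pfail <- function(P, msg) {
  t <- .peek(P)
  shown <- if (t$type == "end") "end of input" else sprintf("'%s'", t$value)
  stop(sprintf("syntax error at position %d (%s): %s", t$pos, shown, msg),
       call. = FALSE)
}

# expr := term ('|' term)* ; term := factor ('&' factor)* ;
# factor := '!' factor | '(' expr ')' | atom
.parse_or <- function(P, card) {
  args <- list(.parse_and(P, card))
  while (.peek(P)$type == "or") {
    .take(P)
    args[[length(args) + 1L]] <- .parse_and(P, card)
  }
  .eor(args)
}

.parse_and <- function(P, card) {
  args <- list(.parse_factor(P, card))
  while (.peek(P)$type == "and") {
    .take(P)
    args[[length(args) + 1L]] <- .parse_factor(P, card)
  }
  .eand(args)
}

.parse_factor <- function(P, card) {
  t <- .peek(P)
  if (t$type == "not") {
    .take(P)
    return(.enot(.parse_factor(P, card)))
  }
  if (t$type == "lpar") {
    .take(P)
    e <- .parse_or(P, card)
    .expect(P, "rpar", "')'")
    return(e)
  }
  .parse_atom(P, card)
}

# cellular atom : NAME (('>='|'='|'=='|'<') INT)? ; bare NAME is NAME>=1;
#                 'true'/'false' are constants
# integration atom : NAME '>=' INT '[' INT ':' INT ']' ('atleast' INT | 'all')
.parse_atom <- function(P, card) {
  t <- .peek(P)
  if (t$type != "name") .pfail(P, "expected a component name")
  name <- .take(P)$value
  if (!card && name %in% c("true", "false")) return(.econst(name == "true"))
  if (card) {
    .expect(P, "ge", "'>=' after component name in an integration atom")
    lvl <- as.integer(.expect(P, "int", "a level")$value)
    .expect(P, "lbrk", "'[' opening the distance band")
    dmin <- as.integer(.expect(P, "int", "minimum distance")$value)
    .expect(P, "colon", "':' in the distance band")
    dmax <- as.integer(.expect(P, "int", "maximum distance")$value)
    brk <- .peek(P)
    .expect(P, "rbrk", "']' closing the distance band")
    if (dmin < 1L)
      stop(sprintf("syntax error at position %d: distance band [%d:%d] must have minimum >= 1",
                   brk$pos, dmin, dmax), call. = FALSE)
    if (dmin > dmax)
      stop(sprintf("syntax error at position %d: distance band [%d:%d] is inverted",
                   brk$pos, dmin, dmax), call. = FALSE)
    q <- .peek(P)
    if (q$type != "name" || !(q$value %in% c("atleast", "all")))
      .pfail(P, "expected quantifier 'atleast <k>' or 'all'")
    .take(P)
    if (q$value == "atleast") {
      k <- as.integer(.expect(P, "int", "a count after 'atleast'")$value)
      if (k < 1L)
        stop(sprintf("syntax error at position %d: 'atleast' count must be >= 1", q$pos),
             call. = FALSE)
      return(.ecard(name, lvl, dmin, dmax, "atleast", k))
    }
    return(.ecard(name, lvl, dmin, dmax, "all"))
  }
  op <- .peek(P)
  if (op$type %in% c("ge", "eq", "eqeq", "lt")) {
    .take(P)
    lvl <- as.integer(.expect(P, "int", "a level")$value)
    opc <- switch(op$type, ge = ">=", eq = "=", eqeq = "=", lt = "<")
    return(.eatom(name, opc, lvl))
  }
  .eatom(name, ">=", 1L)  # bare name shorthand for Boolean activity
}

#' Parse a cellular logical expression
#'
#' Parses the textual form of a regulatory rule: atoms test a component of the
#' same cell against a level (`Name>=k`, `Name=k`, `Name<k`; a bare `Name`
#' abbreviates `Name>=1`), combined with `!`, `&`, `|` and parentheses
#' (`&` binds tighter than `|`). The literals `true` and `false` are accepted.
#'
#' @param text Expression string.
#' @return An expression tree (nested list) usable in [logical_model()].
#' @examples
#' parse_logic_expression("!Green")
#' parse_logic_expression("A>=2 & (B | !C<1)")
#' @export
parse_logic_expression <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  P <- .parser(text)
  e <- .parse_or(P, card = FALSE)
  if (.peek(P)$type != "end") .pfail(P, "trailing input after expression")
  e
}

#' Parse an integration rule
#'
#' Integration rules give the value of a cellular input component as a logical
#' combination of neighbourhood signal counts. The grammar is
#' \preformatted{
#' expr   := term ('|' term)*
#' term   := factor ('&' factor)*
#' factor := '!' factor | '(' expr ')' | atom
#' atom   := NAME '>=' INT '[' INT ':' INT ']' ('atleast' INT | 'all')
#' }
#' An atom `Red>=1 [1:3] atleast 12` is true for a cell when at least 12 cells
#' at distance 1 to 3 have their `Red` component at level 1 or above;
#' `all` requires every cell of the (non-empty) band to pass the test.
#'
#' @param text Rule string.
#' @param target Optional name of the input component the rule feeds.
#' @param level Input level this rule asserts (default 1).
#' @return An object of class `integration_rule` with fields `target`, `level`,
#'   `expression` and `text`.
#' @examples
#' parse_integration_rule("Red>=1 [1:1] atleast 1")
#' parse_integration_rule("Red>=1 [1:1] all")
#' @export
parse_integration_rule <- function(text, target = NULL, level = 1L) {
  stopifnot(is.character(text), length(text) == 1L)
  P <- .parser(text)
  e <- .parse_or(P, card = TRUE)
  if (.peek(P)$type != "end") .pfail(P, "trailing input after rule")
  structure(
    list(target = target, level = as.integer(level), expression = e, text = text),
    class = "integration_rule")
}

#' @export
print.integration_rule <- function(x, ...) {
  tgt <- if (is.null(x$target)) "<input>" else x$target
  cat(sprintf("Integration rule: %s >= %d  when  %s\n",
              tgt, x$level, format_expression(x$expression)))
  invisible(x)
}

## ---- evaluation ------------------------------------------------------------

# Evaluate an expression over a block of cell states.
# `mat`: numeric matrix (cells x components, named columns). NA marks a
# component absent from that cell's model; any atom on it is FALSE.
# `ctx`: epithelium context providing distance-band matrices (card atoms only).
.eval_expr <- function(expr, mat, ctx = NULL) {
  n <- nrow(mat)
  switch(expr$type,
    const = rep(expr$value, n),
    atom = {
      if (!expr$comp %in% colnames(mat))
        stop(sprintf("expression references unknown component '%s'", expr$comp),
             call. = FALSE)
      v <- mat[, expr$comp]
      r <- switch(expr$op,
                  ">=" = v >= expr$level,
                  "=" = v == expr$level,
                  "<" = v < expr$level)
      r & !is.na(v)
    },
    card = {
      if (is.null(ctx))
        stop("integration atoms can only be evaluated within an epithelium",
             call. = FALSE)
      if (!expr$comp %in% colnames(mat))
        stop(sprintf("integration rule references unknown component '%s'", expr$comp),
             call. = FALSE)
      v <- mat[, expr$comp]
      ind <- !is.na(v) & v >= expr$level
      b <- .ctx_band(ctx, expr$dmin, expr$dmax)
      cnt <- as.numeric(b$M %*% ind)
      if (expr$quant == "atleast") cnt >= expr$k else b$size > 0 & cnt == b$size
    },
    not = !.eval_expr(expr$x, mat, ctx),
    and = Reduce(`&`, lapply(expr$args, .eval_expr, mat = mat, ctx = ctx)),
    or = Reduce(`|`, lapply(expr$args, .eval_expr, mat = mat, ctx = ctx)),
    stop("unknown expression node type: ", expr$type)
  )
}

# Component names referenced by atoms/cardinality atoms of an expression.
.expr_components <- function(expr) {
  switch(expr$type,
    const = character(),
    atom = expr$comp,
    card = expr$comp,
    not = .expr_components(expr$x),
    and = unique(unlist(lapply(expr$args, .expr_components))),
    or = unique(unlist(lapply(expr$args, .expr_components))))
}

# Collect the card atoms of an integration expression (for validation and
# band precomputation).
.expr_card_atoms <- function(expr) {
  switch(expr$type,
    const = list(),
    atom = list(),
    card = list(expr),
    not = .expr_card_atoms(expr$x),
    and = do.call(c, lapply(expr$args, .expr_card_atoms)),
    or = do.call(c, lapply(expr$args, .expr_card_atoms)))
}

## ---- formatting ------------------------------------------------------------

#' Render an expression tree back to its textual form
#'
#' @param expr An expression tree from [parse_logic_expression()],
#'   [parse_integration_rule()] or a model imported from SBML.
#' @return A single string; reparsing it yields a structurally equal tree.
#' @export
format_expression <- function(expr) {
  prec <- function(e) switch(e$type, or = 1L, and = 2L, not = 3L, 4L)
  fmt <- function(e, parent_prec) {
    s <- switch(e$type,
      const = if (e$value) "true" else "false",
      atom = sprintf("%s%s%d", e$comp, e$op, e$level),
      card = if (e$quant == "atleast")
        sprintf("%s>=%d [%d:%d] atleast %d", e$comp, e$level, e$dmin, e$dmax, e$k)
      else
        sprintf("%s>=%d [%d:%d] all", e$comp, e$level, e$dmin, e$dmax),
      not = paste0("!", fmt(e$x, prec(e))),
      and = paste(vapply(e$args, fmt, "", parent_prec = prec(e)), collapse = " & "),
      or = paste(vapply(e$args, fmt, "", parent_prec = prec(e)), collapse = " | "))
    if (prec(e) < parent_prec) paste0("(", s, ")") else s
  }
  fmt(expr, 0L)
}
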