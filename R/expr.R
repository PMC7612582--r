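# Target-function expression grammar: constants, node references, + - * /
# (real division), unary minus, ceil/floor, and n-ary avg/min/max.  This is
# the arithmetic language in which every node's target value is written; a
# node moves one level per step toward the value its expression takes on the
# current state.

#' Construct target-function expression nodes
#'
#' Low-level constructors for the abstract syntax tree of a target-function
#' expression. Most users will write expressions as text and call
#' [parse_target()] instead.
#'
#' @param value Numeric constant (integers in the surface syntax).
#' @param name Node name referenced by the expression.
#' @param op One of `"add"`, `"sub"`, `"mul"`, `"div"`, `"neg"`, `"ceil"`,
#'   `"floor"`, `"avg"`, `"min"`, `"max"`.
#' @param args List of `qn_expr` operands.
#' @return An object of class `qn_expr`.
#' @seealso [parse_target()], [deparse_target()], [eval_target()]
#' @export
qn_const <- function(value) {
  structure(list(op = "const", value = as.numeric(value)), class = "qn_expr")
}

#' @rdname qn_const
#' @export
qn_var <- function(name) {
  structure(list(op = "var", name = as.character(name)), class = "qn_expr")
}

#' @rdname qn_const
#' @export
qn_call <- function(op, args) {
  op <- match.arg(op, c("add", "sub", "mul", "div", "neg",
                        "ceil", "floor", "avg", "min", "max"))
  stopifnot(is.list(args), all(vapply(args, inherits, logical(1), "qn_expr")))
  arity <- c(add = 2, sub = 2, mul = 2, div = 2, neg = 1, ceil = 1, floor = 1)
  if (op %in% names(arity) && length(args) != arity[[op]]) {
    stop("operator '", op, "' takes exactly ", arity[[op]], " operand(s)",
         call. = FALSE)
  }
  structure(list(op = op, args = args), class = "qn_expr")
}

# -- tokenizer ---------------------------------------------------------------

qn_tokenize <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value, at) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value, at = at)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[ \t\r\n]$", ch)) {
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      j <- i
      while (j <= n && grepl("^[0-9]$", substr(text, j, j))) j <- j + 1L
      if (j <= n && substr(text, j, j) == ".") {
        stop("parse error at position ", i,
             ": non-integer constant '", substr(text, i, j), "'", call. = FALSE)
      }
      push("num", substr(text, i, j - 1L), i)
      i <- j
    } else if (grepl("^[A-Za-z_]$", ch)) {
      j <- i
      while (j <= n && grepl("^[A-Za-z0-9_]$", substr(text, j, j))) j <- j + 1L
      push("ident", substr(text, i, j - 1L), i)
      i <- j
    } else if (ch %in% c("+", "-", "*", "/", "(", ")", ",")) {
      push(ch, ch, i)
      i <- i + 1L
    } else {
      stop("parse error at position ", i, ": unexpected character '", ch, "'",
           call. = FALSE)
    }
  }
  push("eof", "", n + 1L)
  tokens
}

# -- recursive-descent parser ------------------------------------------------

#' Parse a target-function expression from text
#'
#' The surface syntax is whitespace-insensitive: integer constants, node
#' names (`A`, `Int_Lactate`), `+ - * /` with the usual precedence,
#' parentheses, unary minus, and the functions `ceil(x)`, `floor(x)`,
#' `avg(...)`, `min(...)`, `max(...)` (function names case-insensitive).
#' `var(Name)` is accepted as an alias for a bare node name, for
#' compatibility with BMA formula strings. Expressions round-trip through
#' [deparse_target()].
#'
#' @param text A single string, e.g. `"avg(A, B) - avg(C)"`.
#' @return A `qn_expr` expression tree.
#' @examples
#' parse_target("min(NADH, 4 - Gradient)")
#' parse_target("ceil(x / 2)")
#' @export
parse_target <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- qn_tokenize(text)
  pos <- 1L
  peek <- function() tokens[[pos]]
  take <- function(type = NULL) {
    tok <- tokens[[pos]]
    if (!is.null(type) && tok$type != type) {
      stop("parse error at position ", tok$at, ": expected '", type,
           "', found '", tok$value, "'", call. = FALSE)
    }
    pos <<- pos + 1L
    tok
  }

  parse_expr <- function() {
    left <- parse_term()
    while (peek()$type %in% c("+", "-")) {
      op <- take()$type
      right <- parse_term()
      left <- qn_call(if (op == "+") "add" else "sub", list(left, right))
    }
    left
  }
  parse_term <- function() {
    left <- parse_unary()
    while (peek()$type %in% c("*", "/")) {
      op <- take()$type
      right <- parse_unary()
      left <- qn_call(if (op == "*") "mul" else "div", list(left, right))
    }
    left
  }
  parse_unary <- function() {
    if (peek()$type == "-") {
      take()
      return(qn_call("neg", list(parse_unary())))
    }
    parse_primary()
  }
  parse_primary <- function() {
    tok <- peek()
    if (tok$type == "num") {
      take()
      return(qn_const(as.numeric(tok$value)))
    }
    if (tok$type == "(") {
      take()
      e <- parse_expr()
      take(")")
      return(e)
    }
    if (tok$type == "ident") {
      take()
      fname <- tolower(tok$value)
      if (peek()$type == "(") {
        take("(")
        args <- list()
        if (peek()$type != ")") {
          args[[1L]] <- parse_expr()
          while (peek()$type == ",") {
            take()
            args[[length(args) + 1L]] <- parse_expr()
          }
        }
        take(")")
        if (fname == "var") {
          if (length(args) != 1L ||
              !(args[[1L]]$op %in% c("var", "const"))) {
            stop("parse error at position ", tok$at,
                 ": var() takes a single node name or id", call. = FALSE)
          }
          a <- args[[1L]]
          return(if (a$op == "var") a else qn_var(format(a$value)))
        }
        if (fname %in% c("ceil", "floor", "avg", "min", "max")) {
          if (fname %in% c("ceil", "floor") && length(args) != 1L) {
            stop("parse error at position ", tok$at, ": ", fname,
                 "() takes one argument", call. = FALSE)
          }
          return(qn_call(fname, args))
        }
        stop("parse error at position ", tok$at, ": unknown function '",
             tok$value, "'", call. = FALSE)
      }
      if (fname == "const") {
        stop("parse error at position ", tok$at,
             ": const must be written as a bare integer", call. = FALSE)
      }
      return(qn_var(tok$value))
    }
    stop("parse error at position ", tok$at, ": unexpected '", tok$value, "'",
         call. = FALSE)
  }

  out <- parse_expr()
  take("eof")
  out
}

# -- deparser ----------------------------------------------------------------

qn_precedence <- function(op) {
  switch(op,
         add = 1L, sub = 1L,
         mul = 2L, div = 2L,
         neg = 3L,
         4L)
}

#' Render a target-function expression as canonical text
#'
#' Produces the canonical surface syntax, inserting parentheses only where
#' precedence requires them. `parse_target(deparse_target(e))` reproduces
#' `e` exactly.
#'
#' @param expr A `qn_expr`.
#' @return A single string.
#' @export
deparse_target <- function(expr) {
  stopifnot(inherits(expr, "qn_expr"))
  dep <- function(e, parent_prec, right_side) {
    p <- qn_precedence(e$op)
    txt <- switch(
      e$op,
      const = {
        v <- e$value
        if (v == floor(v)) format(as.integer(v)) else format(v)
      },
      var = e$name,
      add = paste0(dep(e$args[[1L]], p, FALSE), " + ", dep(e$args[[2L]], p, TRUE)),
      sub = paste0(dep(e$args[[1L]], p, FALSE), " - ", dep(e$args[[2L]], p, TRUE)),
      mul = paste0(dep(e$args[[1L]], p, FALSE), " * ", dep(e$args[[2L]], p, TRUE)),
      div = paste0(dep(e$args[[1L]], p, FALSE), " / ", dep(e$args[[2L]], p, TRUE)),
      neg = paste0("-", dep(e$args[[1L]], p, TRUE)),
      paste0(e$op, "(",
             paste(vapply(e$args, dep, character(1), 0L, FALSE), collapse = ", "),
             ")")
    )
    needs_paren <- p < parent_prec ||
      (p == parent_prec && right_side && e$op %in% c("add", "sub", "mul", "div"))
    if (e$op %in% c("const", "var") || p == 4L) needs_paren <- FALSE
    if (needs_paren) paste0("(", txt, ")") else txt
  }
  dep(expr, 0L, FALSE)
}

#' @export
print.qn_expr <- function(x, ...) {
  cat("<target expression> ", deparse_target(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.qn_expr <- function(x, ...) deparse_target(x)

# -- evaluation --------------------------------------------------------------

#' Evaluate a target-function expression on a state
#'
#' Evaluates the expression over node levels. `state` may be a named numeric
#' vector (one state) or a numeric matrix with named columns (one row per
#' state; evaluation is vectorised over rows). The average of an empty
#' operand list is defined as 0.
#'
#' @param expr A `qn_expr` or a string parsed with [parse_target()].
#' @param state Named numeric vector, or matrix with one column per node.
#' @param node Optional node name used to attribute evaluation errors.
#' @return A numeric vector of target values (length 1 for a vector state).
#' @examples
#' eval_target("avg(A, B)", c(A = 1, B = 4))
#' @export
eval_target <- function(expr, state, node = NULL) {
  if (is.character(expr)) expr <- parse_target(expr)
  stopifnot(inherits(expr, "qn_expr"))
  is_mat <- is.matrix(state)
  who <- if (is.null(node)) "" else paste0(" (target of node '", node, "')")
  lookup <- function(name) {
    if (is_mat) {
      if (!name %in% colnames(state)) {
        stop("unresolved variable '", name, "'", who, call. = FALSE)
      }
      state[, name]
    } else {
      if (!name %in% names(state)) {
        stop("unresolved variable '", name, "'", who, call. = FALSE)
      }
      unname(state[[name]])
    }
  }
  ev <- function(e) {
    switch(
      e$op,
      const = e$value,
      var = lookup(e$name),
      add = ev(e$args[[1L]]) + ev(e$args[[2L]]),
      sub = ev(e$args[[1L]]) - ev(e$args[[2L]]),
      mul = ev(e$args[[1L]]) * ev(e$args[[2L]]),
      div = {
        den <- ev(e$args[[2L]])
        if (any(den == 0)) {
          stop("division by zero", who, call. = FALSE)
        }
        ev(e$args[[1L]]) / den
      },
      neg = -ev(e$args[[1L]]),
      ceil = ceiling(ev(e$args[[1L]])),
      floor = floor(ev(e$args[[1L]])),
      avg = {
        if (length(e$args) == 0L) return(0)
        vals <- lapply(e$args, ev)
        Reduce(`+`, vals) / length(vals)
      },
      min = do.call(pmin, lapply(e$args, ev)),
      max = do.call(pmax, lapply(e$args, ev)),
      stop("unknown operator '", e$op, "'", call. = FALSE)
    )
  }
  out <- ev(expr)
  if (is_mat && length(out) == 1L) out <- rep(out, nrow(state))
  out
}

# Names of the nodes an expression reads.
expr_vars <- function(expr) {
  if (expr$op == "var") return(expr$name)
  if (expr$op == "const") return(character(0))
  unique(unlist(lapply(expr$args, expr_vars)))
}
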