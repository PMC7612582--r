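# Qualitative-network data model: nodes with bounded integer ranges and
# target functions, signed influence edges, and model-level validation.

#' Declare a qualitative-network node
#'
#' A node holds an integer activity level within `range`; on the 0--4
#' default range, 2 is read as normal activity/concentration, 0--1 as low
#' and 3--4 as high. Non-default ranges are used for readout and clock
#' nodes (an OCR readout on 0--10, a counter on 0--100).
#'
#' @param name Node name (letters, digits, underscore; must start with a
#'   letter or underscore).
#' @param range Integer vector `c(lo, hi)` with `lo <= hi`. Default `c(0, 4)`.
#' @param target The string `"default"`, a target-function string, or a
#'   `qn_expr`. The default target is `avg(activators) - avg(inhibitors)`
#'   derived from the model's edges; a node with no incoming edges holds its
#'   value.
#' @param description Free-text annotation.
#' @return A `qn_node` object.
#' @seealso [qn_model()], [default_target()]
#' @export
qn_node <- function(name, range = c(0L, 4L), target = "default",
                    description = "") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", name)) {
    stop("invalid node name '", name, "'", call. = FALSE)
  }
  range <- as.integer(range)
  stopifnot(length(range) == 2L, !anyNA(range))
  if (is.character(target) && identical(target, "default")) {
    tgt <- "default"
  } else if (is.character(target)) {
    tgt <- parse_target(target)
  } else if (inherits(target, "qn_expr")) {
    tgt <- target
  } else {
    stop("target must be \"default\", a string, or a qn_expr", call. = FALSE)
  }
  structure(
    list(name = name, range_lo = range[1L], range_hi = range[2L],
         target = tgt, description = as.character(description)),
    class = "qn_node"
  )
}

#' Declare a signed influence edge
#'
#' @param from,to Node names.
#' @param sign `"activator"` or `"inhibitor"`.
#' @return A one-row data frame with columns `from`, `to`, `sign`.
#' @export
qn_edge <- function(from, to, sign = c("activator", "inhibitor")) {
  sign <- match.arg(sign)
  data.frame(from = from, to = to, sign = sign, stringsAsFactors = FALSE)
}

#' Assemble a qualitative network
#'
#' Builds the executable model from node declarations and signed edges,
#' resolves every `"default"` target against the edge list, and validates
#' the result (see [validate_qn_model()]). Node order is declaration order
#' and is preserved by all operations.
#'
#' @param nodes A list of [qn_node()] objects.
#' @param edges A data frame with columns `from`, `to`, `sign` (rows from
#'   [qn_edge()] may be `rbind`ed), or `NULL` for no edges.
#' @param name Model name.
#' @param notes Free-text provenance notes.
#' @return A `qn_model` object.
#' @examples
#' m <- qn_model(
#'   nodes = list(qn_node("A", target = "2"), qn_node("B")),
#'   edges = qn_edge("A", "B", "activator"),
#'   name = "relay"
#' )
#' @export
qn_model <- function(nodes, edges = NULL, name = "", notes = character(0)) {
  if (inherits(nodes, "qn_node")) nodes <- list(nodes)
  stopifnot(is.list(nodes), all(vapply(nodes, inherits, logical(1), "qn_node")))
  if (is.null(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        sign = character(0), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges), all(c("from", "to", "sign") %in% names(edges)))
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to),
                      sign = as.character(edges$sign),
                      stringsAsFactors = FALSE)
  names(nodes) <- vapply(nodes, `[[`, character(1), "name")
  model <- structure(
    list(nodes = nodes, edges = edges,
         name = as.character(name), notes = as.character(notes)),
    class = "qn_model"
  )
  problems <- validate_qn_model(model)
  if (length(problems) > 0L) {
    stop("invalid model:\n", paste0("  - ", problems, collapse = "\n"),
         call. = FALSE)
  }
  model$targets <- resolved_targets(model)
  model
}

#' Node names of a model
#' @param model A `qn_model`.
#' @return Character vector in declaration order.
#' @export
node_names <- function(model) {
  stopifnot(inherits(model, "qn_model"))
  names(model$nodes)
}

#' The default target function of a node
#'
#' Returns `avg(activator inputs) - avg(inhibitor inputs)`; for a node with
#' no incoming edges, the node's own value (the node holds its level), so
#' that unperturbed environment and drug nodes stay constant. The average
#' of an empty operand list is 0, so a node with only inhibitors tends to
#' `-avg(inhibitors)` (and is clamped at its range floor).
#'
#' @param node A node name.
#' @param model A `qn_model`.
#' @return A `qn_expr`.
#' @export
default_target <- function(node, model) {
  stopifnot(inherits(model, "qn_model"))
  if (!node %in% names(model$nodes)) {
    stop("unknown node '", node, "'", call. = FALSE)
  }
  incoming <- model$edges[model$edges$to == node, , drop = FALSE]
  if (nrow(incoming) == 0L) {
    return(qn_var(node))
  }
  act <- incoming$from[incoming$sign == "activator"]
  inh <- incoming$from[incoming$sign == "inhibitor"]
  avg_of <- function(v) qn_call("avg", lapply(v, qn_var))
  if (length(inh) == 0L) {
    avg_of(act)
  } else if (length(act) == 0L) {
    qn_call("neg", list(avg_of(inh)))
  } else {
    qn_call("sub", list(avg_of(act), avg_of(inh)))
  }
}

# Materialize the target expression of every node (defaults resolved).
resolved_targets <- function(model) {
  lapply(names(model$nodes), function(nm) {
    tgt <- model$nodes[[nm]]$target
    if (identical(tgt, "default")) default_target(nm, model) else tgt
  }) |> stats::setNames(names(model$nodes))
}

#' Validate a qualitative network
#'
#' Checks name uniqueness, edge endpoint existence, edge uniqueness, range
#' sanity, resolvability of every variable referenced by a target
#' expression, and that every node has a target (explicit or default).
#'
#' @param model A `qn_model` (or the unvalidated list structure).
#' @return A character vector of violations; empty means the model is valid.
#' @export
validate_qn_model <- function(model) {
  problems <- character(0)
  nms <- vapply(model$nodes, `[[`, character(1), "name")
  dup <- unique(nms[duplicated(nms)])
  for (d in dup) problems <- c(problems, paste0("duplicate node name '", d, "'"))
  for (nd in model$nodes) {
    if (nd$range_lo > nd$range_hi) {
      problems <- c(problems, paste0("node '", nd$name, "' has inverted range [",
                                     nd$range_lo, ", ", nd$range_hi, "]"))
    }
  }
  e <- model$edges
  if (nrow(e) > 0L) {
    for (i in seq_len(nrow(e))) {
      if (!e$from[i] %in% nms) {
        problems <- c(problems, paste0("edge ", i, " (", e$from[i], " -> ",
                                       e$to[i], "): unknown source '", e$from[i], "'"))
      }
      if (!e$to[i] %in% nms) {
        problems <- c(problems, paste0("edge ", i, " (", e$from[i], " -> ",
                                       e$to[i], "): unknown target '", e$to[i], "'"))
      }
      if (!e$sign[i] %in% c("activator", "inhibitor")) {
        problems <- c(problems, paste0("edge ", i, ": invalid sign '", e$sign[i], "'"))
      }
    }
    key <- paste(e$from, e$to, e$sign)
    if (anyDuplicated(key)) {
      problems <- c(problems, paste0("duplicate edge: ", key[duplicated(key)]))
    }
  }
  for (nd in model$nodes) {
    tgt <- nd$target
    if (identical(tgt, "default")) next
    if (!inherits(tgt, "qn_expr")) {
      problems <- c(problems, paste0("node '", nd$name, "' has no usable target"))
      next
    }
    missing <- setdiff(expr_vars(tgt), nms)
    for (v in missing) {
      problems <- c(problems, paste0("target of node '", nd$name,
                                     "' references undeclared node '", v, "'"))
    }
  }
  problems
}

#' @export
print.qn_model <- function(x, ...) {
  cat("Qualitative network", if (nzchar(x$name)) paste0(" '", x$name, "'"),
      ": ", length(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  for (nd in x$nodes) {
    tgt <- if (identical(nd$target, "default")) "default" else deparse_target(nd$target)
    cat(sprintf("  %-16s [%d..%d]  %s\n", nd$name, nd$range_lo, nd$range_hi, tgt))
  }
  invisible(x)
}

# -- states ------------------------------------------------------------------

#' Construct and validate a state
#'
#' A state maps every node of the model to an integer level within the
#' node's declared range.
#'
#' @param model A `qn_model`.
#' @param levels Named integer vector covering exactly the model's nodes
#'   (order is normalised to declaration order).
#' @return Named integer vector of class `qn_state`.
#' @export
qn_state <- function(model, levels) {
  stopifnot(inherits(model, "qn_model"))
  nms <- node_names(model)
  if (is.null(names(levels)) || !setequal(names(levels), nms) ||
      length(levels) != length(nms)) {
    stop("state must name exactly the model's nodes", call. = FALSE)
  }
  lv <- as.integer(levels[nms])
  names(lv) <- nms
  lo <- vapply(model$nodes, `[[`, integer(1), "range_lo")
  hi <- vapply(model$nodes, `[[`, integer(1), "range_hi")
  bad <- which(lv < lo | lv > hi)
  if (length(bad) > 0L) {
    stop("levels out of range for node(s): ",
         paste(nms[bad], collapse = ", "), call. = FALSE)
  }
  structure(lv, class = "qn_state")
}

node_range_lo <- function(model) {
  vapply(model$nodes, `[[`, integer(1), "range_lo")
}
node_range_hi <- function(model) {
  vapply(model$nodes, `[[`, integer(1), "range_hi")
}

#' Advance a qualitative network by one synchronous step
#'
#' Every node's target expression is evaluated on the *input* state; each
#' node then moves one level toward its target (up by one if the target
#' value exceeds the current level, down by one if below, unchanged on
#' exact equality) and is clamped to its declared range. All nodes update
#' simultaneously, so declaration order has no effect on the result.
#'
#' @param model A `qn_model`.
#' @param state Named integer vector over the model's nodes, or a matrix
#'   with one named column per node and one row per state (all rows are
#'   stepped at once).
#' @param clamp Optional named integer vector of levels to force after the
#'   step (used for environment clamps and counterfactual interventions).
#' @return The successor state (vector or matrix, matching the input).
#' @examples
#' m <- qn_model(list(qn_node("A", target = "2")))
#' qn_step(m, c(A = 0))
#' @export
qn_step <- function(model, state, clamp = NULL) {
  stopifnot(inherits(model, "qn_model"))
  nms <- node_names(model)
  targets <- model$targets
  if (is.null(targets)) targets <- resolved_targets(model)
  is_mat <- is.matrix(state)
  if (is_mat) {
    stopifnot(identical(colnames(state), nms))
    cur <- state
  } else {
    cur <- matrix(as.numeric(state[nms]), nrow = 1L,
                  dimnames = list(NULL, nms))
  }
  lo <- node_range_lo(model)
  hi <- node_range_hi(model)
  nxt <- cur
  for (k in seq_along(nms)) {
    tv <- eval_target(targets[[k]], cur, node = nms[k])
    v <- cur[, k]
    nxt[, k] <- pmin(pmax(v + sign(tv - v), lo[k]), hi[k])
  }
  if (!is.null(clamp)) {
    for (nm in names(clamp)) {
      if (!nm %in% nms) stop("clamp names unknown node '", nm, "'", call. = FALSE)
      nxt[, nm] <- clamp[[nm]]
    }
  }
  if (is_mat) {
    nxt
  } else {
    out <- as.integer(nxt[1L, ])
    names(out) <- nms
    out
  }
}
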