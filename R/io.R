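# Model I/O.  Two interchangeable on-disk representations:
#
#  * a native sectioned plain-text format ("*.qn"): one `node` line per node
#    (name, range, target expression or "default", optional description) and
#    one `edge` line per signed influence; round-trips exactly;
#  * the BMA-dialect JSON format as exported by the BioModelAnalyzer web
#    tool: Model.Variables (Id, Name, RangeFrom, RangeTo, Formula) and
#    Model.Relationships (FromVariable, ToVariable, Type); layout and other
#    presentation fields are ignored with a warning count.

new_model_document <- function(model, format, source, warnings = character(0)) {
  structure(
    list(model = model, format = format, source = source, warnings = warnings),
    class = "qn_model_document"
  )
}

#' @export
print.qn_model_document <- function(x, ...) {
  cat("Model document (", x$format, ") from ", x$source, "\n", sep = "")
  if (length(x$warnings) > 0L) {
    cat("Warnings:\n", paste0("  - ", x$warnings, collapse = "\n"), "\n", sep = "")
  }
  print(x$model)
  invisible(x)
}

quote_field <- function(x) {
  paste0("\"", gsub("\"", "\\\\\"", x), "\"")
}

#' Write a model in the native plain-text format
#'
#' @param model A `qn_model`.
#' @param path Output file path, or `NULL` to return the document text.
#' @return Invisibly, the document as a character vector of lines.
#' @seealso [read_qn_model()]
#' @export
write_qn_model <- function(model, path = NULL) {
  stopifnot(inherits(model, "qn_model"))
  lines <- c(
    paste("qnmodel", quote_field(model$name)),
    vapply(model$notes, function(x) paste("note", quote_field(x)), character(1))
  )
  for (nd in model$nodes) {
    tgt <- if (identical(nd$target, "default")) "default" else
      quote_field(deparse_target(nd$target))
    line <- sprintf("node %s range %d %d target %s", nd$name,
                    nd$range_lo, nd$range_hi, tgt)
    if (nzchar(nd$description)) {
      line <- paste(line, "desc", quote_field(nd$description))
    }
    lines <- c(lines, line)
  }
  if (nrow(model$edges) > 0L) {
    lines <- c(lines, sprintf("edge %s -> %s %s", model$edges$from,
                              model$edges$to, model$edges$sign))
  }
  lines <- unname(lines)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# Pull one optionally-quoted field off the front of a string; returns
# list(value, rest) or NULL if none.
take_field <- function(s) {
  s <- sub("^\\s+", "", s)
  if (!nzchar(s)) return(NULL)
  if (substr(s, 1L, 1L) == "\"") {
    m <- regmatches(s, regexpr('^"(\\\\"|[^"])*"', s))
    if (length(m) == 0L) stop("unterminated quote", call. = FALSE)
    value <- gsub("\\\\\"", "\"", substr(m, 2L, nchar(m) - 1L))
    list(value = value, rest = substr(s, nchar(m) + 1L, nchar(s)))
  } else {
    m <- regmatches(s, regexpr("^\\S+", s))
    list(value = m, rest = substr(s, nchar(m) + 1L, nchar(s)))
  }
}

split_fields <- function(s) {
  out <- character(0)
  repeat {
    f <- take_field(s)
    if (is.null(f)) break
    out <- c(out, f$value)
    s <- f$rest
  }
  out
}

#' Read a model from the native plain-text format
#'
#' Inverse of [write_qn_model()]. Unknown directives and unknown keys on
#' known directives are skipped and recorded as warnings in the returned
#' document, never silently dropped. A node line without a `range` defaults
#' to the standard range 0--4; a missing `target` defaults to `"default"`.
#'
#' @param path File path, or a character vector of document lines passed
#'   via `text`.
#' @param text Optional document text (overrides `path`).
#' @return A `qn_model_document`; the model is in `$model`.
#' @export
read_qn_model <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(path))
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    text <- readLines(path, warn = FALSE)
    src <- path
  } else {
    src <- "<text>"
  }
  text <- unname(as.character(text))
  warnings <- character(0)
  name <- ""
  notes <- character(0)
  nodes <- list()
  edges <- list()
  for (i in seq_along(text)) {
    line <- sub("^\\s+|\\s+$", "", text[i])
    line <- sub("^([^\"#]*)#.*$", "\\1", line)  # strip comments (outside quotes)
    line <- sub("\\s+$", "", line)
    if (!nzchar(line)) next
    f <- take_field(line)
    directive <- f$value
    rest <- f$rest
    err <- function(msg) stop("line ", i, ": ", msg, call. = FALSE)
    if (directive == "qnmodel") {
      name <- take_field(rest)$value
    } else if (directive == "note") {
      notes <- c(notes, take_field(rest)$value)
    } else if (directive == "node") {
      fs <- split_fields(rest)
      if (length(fs) < 1L) err("node line without a name")
      nd <- list(name = fs[1L], range = c(0L, 4L), target = "default",
                 desc = "")
      j <- 2L
      while (j <= length(fs)) {
        key <- fs[j]
        if (key == "range") {
          if (j + 2L > length(fs)) err("range needs two integers")
          nd$range <- as.integer(fs[c(j + 1L, j + 2L)])
          if (anyNA(nd$range)) err("range needs two integers")
          j <- j + 3L
        } else if (key == "target") {
          if (j + 1L > length(fs)) err("target needs a value")
          nd$target <- fs[j + 1L]
          j <- j + 2L
        } else if (key == "desc") {
          if (j + 1L > length(fs)) err("desc needs a value")
          nd$desc <- fs[j + 1L]
          j <- j + 2L
        } else {
          warnings <- c(warnings,
                        paste0("line ", i, ": ignored unknown key '", key, "'"))
          j <- j + 1L
        }
      }
      if (nd$name %in% vapply(nodes, `[[`, character(1), "name")) {
        err(paste0("duplicate node name '", nd$name, "'"))
      }
      tgt <- if (identical(nd$target, "default")) "default" else
        tryCatch(parse_target(nd$target),
                 error = function(e) err(paste0("in target of '", nd$name,
                                                "': ", conditionMessage(e))))
      nodes[[length(nodes) + 1L]] <-
        qn_node(nd$name, nd$range, tgt, nd$desc)
    } else if (directive == "edge") {
      fs <- split_fields(rest)
      if (length(fs) != 4L || fs[2L] != "->") {
        err("edge line must be 'edge FROM -> TO activator|inhibitor'")
      }
      if (!fs[4L] %in% c("activator", "inhibitor")) {
        err(paste0("invalid edge sign '", fs[4L], "'"))
      }
      edges[[length(edges) + 1L]] <- qn_edge(fs[1L], fs[3L], fs[4L])
    } else {
      warnings <- c(warnings,
                    paste0("line ", i, ": ignored unknown directive '",
                           directive, "'"))
    }
  }
  edges <- if (length(edges) > 0L) do.call(rbind, edges) else NULL
  model <- qn_model(nodes, edges, name = name, notes = notes)
  new_model_document(model, "native", src, warnings)
}

#' Read a model in the BMA-dialect JSON format
#'
#' Accepts the variables/relationships core of a BioModelAnalyzer model
#' document: a top-level `Model` object with `Variables` (`Id`, `Name`,
#' `RangeFrom`, `RangeTo`, `Formula`) and `Relationships` (`FromVariable`,
#' `ToVariable`, `Type` in Activator/Inhibitor). An empty `Formula` becomes
#' the default target; formulas may reference nodes as `var(Name)` or
#' `var(Id)` (numeric ids are resolved to names). Layout and any other
#' top-level sections are ignored and counted in the document's warnings.
#' Duplicate variable names are disambiguated deterministically by
#' appending `_<Id>`.
#'
#' @param path File path, or JSON text via `text`.
#' @param text Optional JSON string (overrides `path`).
#' @return A `qn_model_document`; the model is in `$model`.
#' @export
read_bma_model <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(path))
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    src <- path
    doc <- tryCatch(
      jsonlite::fromJSON(path, simplifyVector = FALSE),
      error = function(e) stop("malformed BMA document (", path, "): ",
                               conditionMessage(e), call. = FALSE)
    )
  } else {
    src <- "<text>"
    doc <- tryCatch(
      jsonlite::fromJSON(text, simplifyVector = FALSE),
      error = function(e) stop("malformed BMA document: ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  warnings <- character(0)
  if (is.null(doc$Model)) stop("BMA document has no 'Model' section", call. = FALSE)
  extra <- setdiff(names(doc), "Model")
  if (length(extra) > 0L) {
    warnings <- c(warnings, paste0("ignored top-level section(s): ",
                                   paste(extra, collapse = ", ")))
  }
  mdl <- doc$Model
  vars <- mdl$Variables
  if (is.null(vars)) stop("BMA model has no 'Variables'", call. = FALSE)
  rels <- mdl$Relationships
  if (is.null(rels)) rels <- list()
  known_var <- c("Id", "Name", "RangeFrom", "RangeTo", "Formula")
  ids <- vapply(vars, function(v) as.integer(v$Id), integer(1))
  if (anyNA(ids)) stop("BMA variable without an Id", call. = FALSE)
  raw_names <- vapply(vars, function(v) {
    nm <- v$Name
    if (is.null(nm)) "" else as.character(nm)
  }, character(1))
  nms <- raw_names
  nms[!nzchar(nms)] <- paste0("v", ids[!nzchar(nms)])
  nms <- gsub("[^A-Za-z0-9_]", "_", nms)
  nms[grepl("^[0-9]", nms)] <- paste0("v", nms[grepl("^[0-9]", nms)])
  dup <- duplicated(nms) | duplicated(nms, fromLast = TRUE)
  if (any(dup)) {
    warnings <- c(warnings,
                  paste0("duplicate variable name(s) disambiguated by Id: ",
                         paste(unique(nms[dup]), collapse = ", ")))
    nms[dup] <- paste0(nms[dup], "_", ids[dup])
  }
  id_to_name <- stats::setNames(nms, as.character(ids))

  resolve_ids <- function(expr) {
    if (expr$op == "var") {
      if (grepl("^[0-9]+$", expr$name)) {
        nm <- id_to_name[expr$name]
        if (is.na(nm)) {
          stop("formula references unknown variable id ", expr$name,
               call. = FALSE)
        }
        return(qn_var(unname(nm)))
      }
      return(expr)
    }
    if (expr$op == "const") return(expr)
    expr$args <- lapply(expr$args, resolve_ids)
    expr
  }

  n_ignored_fields <- 0L
  nodes <- vector("list", length(vars))
  for (k in seq_along(vars)) {
    v <- vars[[k]]
    n_ignored_fields <- n_ignored_fields + length(setdiff(names(v), known_var))
    lo <- if (is.null(v$RangeFrom)) 0L else as.integer(v$RangeFrom)
    hi <- if (is.null(v$RangeTo)) 4L else as.integer(v$RangeTo)
    formula <- if (is.null(v$Formula)) "" else as.character(v$Formula)
    tgt <- if (!nzchar(trimws(formula))) {
      "default"
    } else {
      e <- tryCatch(parse_target(formula), error = function(err) {
        stop("variable '", nms[k], "' (Id ", ids[k],
             "): formula outside the accepted grammar: ",
             conditionMessage(err), call. = FALSE)
      })
      resolve_ids(e)
    }
    nodes[[k]] <- qn_node(nms[k], c(lo, hi), tgt)
  }
  if (n_ignored_fields > 0L) {
    warnings <- c(warnings, paste0("ignored ", n_ignored_fields,
                                   " layout/visual variable field(s)"))
  }
  edges <- NULL
  if (length(rels) > 0L) {
    known_rel <- c("Id", "FromVariable", "ToVariable", "Type")
    rows <- lapply(rels, function(r) {
      fr <- as.character(r$FromVariable)
      to <- as.character(r$ToVariable)
      for (ref in c(fr, to)) {
        if (is.na(id_to_name[ref])) {
          stop("relationship references undeclared variable id ", ref,
               call. = FALSE)
        }
      }
      ty <- tolower(as.character(r$Type))
      if (!ty %in% c("activator", "inhibitor")) {
        stop("relationship has invalid Type '", r$Type, "'", call. = FALSE)
      }
      qn_edge(unname(id_to_name[fr]), unname(id_to_name[to]), ty)
    })
    n_ignored_rel <- sum(vapply(rels, function(r)
      length(setdiff(names(r), known_rel)), integer(1)))
    if (n_ignored_rel > 0L) {
      warnings <- c(warnings, paste0("ignored ", n_ignored_rel,
                                     " relationship field(s)"))
    }
    edges <- do.call(rbind, rows)
  }
  model_name <- if (is.null(mdl$Name)) "" else as.character(mdl$Name)
  model <- qn_model(nodes, edges, name = model_name)
  new_model_document(model, "bma-dialect", src, warnings)
}

#' Write a model in the BMA-dialect JSON format
#'
#' Emits the variables/relationships core only (no layout). Explicit target
#' expressions are written as `Formula` strings; default targets as empty
#' formulas.
#'
#' @param model A `qn_model`.
#' @param path Output file path, or `NULL` to return the JSON text.
#' @return Invisibly, the JSON text.
#' @export
write_bma_model <- function(model, path = NULL) {
  stopifnot(inherits(model, "qn_model"))
  nms <- node_names(model)
  ids <- stats::setNames(seq_along(nms), nms)
  vars <- lapply(nms, function(nm) {
    nd <- model$nodes[[nm]]
    list(Id = unname(ids[nm]), Name = nm,
         RangeFrom = nd$range_lo, RangeTo = nd$range_hi,
         Formula = if (identical(nd$target, "default")) "" else
           deparse_target(nd$target))
  })
  rels <- NULL
  if (nrow(model$edges) > 0L) {
    rels <- lapply(seq_len(nrow(model$edges)), function(i) {
      list(Id = i,
           FromVariable = unname(ids[model$edges$from[i]]),
           ToVariable = unname(ids[model$edges$to[i]]),
           Type = if (model$edges$sign[i] == "activator") "Activator" else "Inhibitor")
    })
  } else {
    rels <- list()
  }
  doc <- list(Model = list(Name = model$name, Variables = vars,
                           Relationships = rels))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) writeLines(json, path)
  invisible(as.character(json))
}
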