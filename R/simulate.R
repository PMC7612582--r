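# Trajectory simulation and exhaustive attractor enumeration.  The state
# space of a qualitative network is finite, so every synchronous orbit ends
# in a fixed point or a cycle; on small models the full successor map can be
# enumerated, which serves as the package's ground-truth oracle.

state_space_size <- function(model) {
  prod(node_range_hi(model) - node_range_lo(model) + 1)
}

default_max_steps <- function(model) {
  min(10 * state_space_size(model), 100000)
}

#' Simulate a trajectory to a fixed point or cycle
#'
#' Iterates [qn_step()] from `init`, stopping at the first repeated state
#' (classified as a fixed point if the repeat has period 1, otherwise as a
#' cycle with its length and first-occurrence index) or after `max_steps`
#' steps. Entirely deterministic.
#'
#' @param model A `qn_model`.
#' @param init Initial state (named integer vector).
#' @param max_steps Maximum number of steps; defaults to 10 times the state
#'   space size, capped at 100000.
#' @param clamp Optional named levels forced after every step (see
#'   [qn_step()]).
#' @return A `qn_trajectory`: list with `states` (matrix, one row per
#'   visited state including `init`), `terminal` (`"fixed_point"`,
#'   `"cycle"`, or `"max_steps_reached"`), `steps_taken`, and for cycles
#'   `cycle_length` and `cycle_start` (1-based row index of first cycle
#'   state).
#' @examples
#' m <- qn_model(list(qn_node("A", target = "2")))
#' simulate_qn(m, c(A = 0))
#' @export
simulate_qn <- function(model, init, max_steps = NULL, clamp = NULL) {
  stopifnot(inherits(model, "qn_model"))
  if (is.null(max_steps)) max_steps <- default_max_steps(model)
  stopifnot(max_steps >= 1)
  state <- qn_state(model, init)
  if (!is.null(clamp)) {
    state[names(clamp)] <- as.integer(clamp)
    state <- qn_state(model, state)
  }
  nms <- node_names(model)
  states <- matrix(NA_integer_, nrow = min(max_steps + 1L, 4096L),
                   ncol = length(nms), dimnames = list(NULL, nms))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(s) paste(s, collapse = ",")
  states[1L, ] <- state
  assign(key(state), 1L, envir = seen)
  terminal <- "max_steps_reached"
  cycle_length <- NA_integer_
  cycle_start <- NA_integer_
  steps <- 0L
  for (i in seq_len(max_steps)) {
    nxt <- tryCatch(
      qn_step(model, state, clamp = clamp),
      error = function(e) {
        stop("at step ", i, ": ", conditionMessage(e), call. = FALSE)
      }
    )
    steps <- i
    if (i + 1L > nrow(states)) {
      states <- rbind(states,
                      matrix(NA_integer_, nrow = nrow(states),
                             ncol = length(nms), dimnames = list(NULL, nms)))
    }
    states[i + 1L, ] <- nxt
    k <- key(nxt)
    prev <- seen[[k]]
    if (!is.null(prev)) {
      cycle_start <- prev
      cycle_length <- (i + 1L) - prev
      terminal <- if (cycle_length == 1L) "fixed_point" else "cycle"
      break
    }
    assign(k, i + 1L, envir = seen)
    state <- nxt
  }
  states <- states[seq_len(steps + 1L), , drop = FALSE]
  structure(
    list(states = states, terminal = terminal, steps_taken = steps,
         cycle_length = cycle_length, cycle_start = cycle_start),
    class = "qn_trajectory"
  )
}

#' @export
print.qn_trajectory <- function(x, ...) {
  cat("QN trajectory: ", x$steps_taken, " step(s), terminal = ", x$terminal,
      sep = "")
  if (x$terminal == "cycle") {
    cat(" (length ", x$cycle_length, ", entered at state ", x$cycle_start, ")",
        sep = "")
  }
  cat("\n")
  utils::head(x$states, 12L) |> print()
  if (nrow(x$states) > 12L) cat("  ... ", nrow(x$states) - 12L, " more rows\n")
  invisible(x)
}

#' Final (recurrent) state of a trajectory
#' @param trajectory A `qn_trajectory`.
#' @return The last visited state as a named integer vector.
#' @export
final_state <- function(trajectory) {
  s <- trajectory$states[nrow(trajectory$states), ]
  stats::setNames(as.integer(s), colnames(trajectory$states))
}

#' Is a state a fixed point?
#'
#' @param model A `qn_model`.
#' @param state Named integer vector.
#' @param clamp Optional forced levels, as in [qn_step()].
#' @return `TRUE` iff one synchronous step maps the state to itself.
#' @export
is_fixed_point <- function(model, state, clamp = NULL) {
  state <- qn_state(model, state)
  nxt <- qn_step(model, state, clamp = clamp)
  all(nxt == state)
}

# Enumerate all states as a matrix (mixed-radix order; first node varies
# slowest so rows are in lexicographic order of the state vector).
enumerate_states <- function(model) {
  lo <- node_range_lo(model)
  hi <- node_range_hi(model)
  vals <- mapply(seq.int, lo, hi, SIMPLIFY = FALSE)
  grid <- rev(expand.grid(rev(vals), KEEP.OUT.ATTRS = FALSE))
  m <- as.matrix(grid)
  dimnames(m) <- list(NULL, node_names(model))
  storage.mode(m) <- "integer"
  m
}

# Index (1-based) of each state row in the enumeration above.
state_index <- function(model, states) {
  lo <- node_range_lo(model)
  hi <- node_range_hi(model)
  widths <- hi - lo + 1
  idx <- rep(0, nrow(states))
  for (k in seq_along(widths)) {
    idx <- idx * widths[k] + (states[, k] - lo[k])
  }
  as.integer(idx + 1)
}

#' Enumerate all attractors of a small qualitative network
#'
#' Builds the full synchronous successor map over the model's state space
#' and partitions every state into the basin of exactly one attractor
#' (fixed point or cycle). Each attractor is reported as a matrix of its
#' cycle states, rotated to start at the lexicographically smallest state;
#' attractors are sorted by that representative.
#'
#' @param model A `qn_model`.
#' @param limit Refuse to enumerate state spaces larger than this
#'   (default 2e6).
#' @return A `qn_attractors` object: list with `attractors` (list of state
#'   matrices), `basin_sizes` (integer vector, summing to the state-space
#'   size), and `state_space_size`.
#' @export
find_attractors <- function(model, limit = 2e6) {
  stopifnot(inherits(model, "qn_model"))
  n <- state_space_size(model)
  if (n > limit) {
    stop("state space has ", format(n, scientific = FALSE),
         " states, exceeding the enumeration limit of ",
         format(limit, scientific = FALSE), call. = FALSE)
  }
  states <- enumerate_states(model)
  succ_states <- qn_step(model, states)
  succ <- state_index(model, succ_states)

  # Functional-graph attractor labelling: walk unresolved states until a
  # labelled state or a state on the current walk (a new cycle) is found.
  label <- integer(n)          # 0 = unresolved; else attractor id
  on_path <- integer(n)        # position in the current walk, 0 if not
  cycles <- list()
  for (s0 in seq_len(n)) {
    if (label[s0] != 0L) next
    path <- integer(64L)
    len <- 0L
    s <- s0
    while (label[s] == 0L && on_path[s] == 0L) {
      len <- len + 1L
      if (len > length(path)) path <- c(path, integer(length(path)))
      path[len] <- s
      on_path[s] <- len
      s <- succ[s]
    }
    if (label[s] != 0L) {
      id <- label[s]
    } else {
      # new cycle: states from the walk position of s to the end of path
      id <- length(cycles) + 1L
      cycles[[id]] <- path[on_path[s]:len]
    }
    for (i in seq_len(len)) {
      label[path[i]] <- id
      on_path[path[i]] <- 0L
    }
  }

  # Canonicalize: rotate each cycle to its lexicographically smallest state
  # (= smallest enumeration index) and sort attractors by that state.
  canon <- lapply(cycles, function(cyc) {
    j <- which.min(cyc)
    if (j > 1L) cyc <- c(cyc[j:length(cyc)], cyc[seq_len(j - 1L)])
    cyc
  })
  ord <- order(vapply(canon, `[`, integer(1), 1L))
  canon <- canon[ord]
  relabel <- integer(length(canon))
  relabel[ord] <- seq_along(canon)
  basin <- tabulate(relabel[label], nbins = length(canon))
  attractors <- lapply(canon, function(cyc) {
    states[cyc, , drop = FALSE]
  })
  structure(
    list(attractors = attractors, basin_sizes = basin, state_space_size = n),
    class = "qn_attractors"
  )
}

#' @export
print.qn_attractors <- function(x, ...) {
  cat("Attractors over ", x$state_space_size, " states:\n", sep = "")
  for (i in seq_along(x$attractors)) {
    a <- x$attractors[[i]]
    kind <- if (nrow(a) == 1L) "fixed point" else paste0("cycle (length ", nrow(a), ")")
    cat("  [", i, "] ", kind, ", basin ", x$basin_sizes[i], ": ",
        paste(apply(a, 1L, paste, collapse = ","), collapse = " -> "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Which attractor contains a state?
#'
#' @param attractor_set A `qn_attractors` object.
#' @param state Named integer vector.
#' @return The 1-based attractor index, or `NA` if the state lies in no
#'   attractor cycle (i.e. it is transient).
#' @export
attractor_of <- function(attractor_set, state) {
  for (i in seq_along(attractor_set$attractors)) {
    a <- attractor_set$attractors[[i]]
    s <- as.integer(state[colnames(a)])
    if (any(apply(a, 1L, function(r) all(r == s)))) return(i)
  }
  NA_integer_
}
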