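# Shared fixture builders.  All fixtures are constructed in code; the
# brute-force attractor oracle (independent of qn_step's internals below)
# re-derives expected behaviour where a test needs ground truth.

toggle_model <- function() make_fixture("toggle")$model

two_node_relay <- function() {
  qn_model(
    list(qn_node("A"), qn_node("B")),
    qn_edge("A", "B", "activator"),
    name = "relay2"
  )
}

# Independent single-state oracle for the synchronous update: evaluates each
# node's resolved target by direct recursive interpretation of the
# expression tree (no matrix path, no pmin/pmax vectorisation) and applies
# the +/-1 move and clamp by hand.
oracle_step <- function(model, state) {
  targets <- lapply(node_names(model), function(nm) {
    tgt <- model$nodes[[nm]]$target
    if (identical(tgt, "default")) default_target(nm, model) else tgt
  })
  names(targets) <- node_names(model)
  ev <- function(e) {
    switch(e$op,
      const = e$value,
      var = as.numeric(state[[e$name]]),
      add = ev(e$args[[1]]) + ev(e$args[[2]]),
      sub = ev(e$args[[1]]) - ev(e$args[[2]]),
      mul = ev(e$args[[1]]) * ev(e$args[[2]]),
      div = ev(e$args[[1]]) / ev(e$args[[2]]),
      neg = -ev(e$args[[1]]),
      ceil = ceiling(ev(e$args[[1]])),
      floor = floor(ev(e$args[[1]])),
      avg = if (length(e$args) == 0) 0 else
        mean(vapply(e$args, ev, numeric(1))),
      min = min(vapply(e$args, ev, numeric(1))),
      max = max(vapply(e$args, ev, numeric(1)))
    )
  }
  out <- state
  for (nm in node_names(model)) {
    v <- state[[nm]]
    tv <- ev(targets[[nm]])
    nxt <- if (tv > v) v + 1L else if (tv < v) v - 1L else v
    nd <- model$nodes[[nm]]
    out[nm] <- min(max(nxt, nd$range_lo), nd$range_hi)
  }
  out
}

# Orbit endpoint by repeated oracle stepping until a state repeats.
oracle_orbit_end <- function(model, state, max_steps = 100000) {
  seen <- character(0)
  for (i in seq_len(max_steps)) {
    key <- paste(state, collapse = ",")
    if (key %in% seen) return(state)
    seen <- c(seen, key)
    state <- oracle_step(model, state)
  }
  stop("oracle orbit did not repeat")
}

random_state <- function(model) {
  lo <- vapply(model$nodes, `[[`, integer(1), "range_lo")
  hi <- vapply(model$nodes, `[[`, integer(1), "range_hi")
  s <- mapply(function(a, b) sample(a:b, 1L), lo, hi)
  stats::setNames(as.integer(s), node_names(model))
}
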