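# Synthetic fixtures: small qualitative networks with analytically known
# attractors (self-certified against the brute-force oracle) and synthetic
# noisy OCR traces with the canonical four-phase stress-test shape.  These
# stand in for external model files and instrument exports so that every
# module is testable offline.

#' Generate a fixture network with known behaviour
#'
#' Kinds:
#' * `constant_chain`: node 1 has the constant target `c` (default 2), each
#'   later node follows its predecessor; from any state the chain converges
#'   to all-`c`, within range-width times chain-length steps.
#' * `toggle`: two nodes with targets `4 - 2*other`; a mutual-inhibition
#'   switch whose only fixed points are the saturated states (4,0) and
#'   (0,4) (a symmetric period-2 cycle also exists).
#' * `relay`: node 1 holds its value (no inputs); each later node follows
#'   its predecessor, so the held level propagates down the chain.
#' * `negative_feedback`: A activates B, B inhibits A (targets `A` and
#'   `4 - 2*B`), giving sustained oscillation: no reachable fixed point
#'   from the centre state (2,2).
#' * `random`: a seeded sparse random network (default targets over random
#'   signed edges) with ranges constrained so the state space stays
#'   enumerable by [find_attractors()].
#'
#' @param kind Fixture kind (see above).
#' @param size Node count (chains and random; toggle and feedback are 2).
#' @param seed Integer seed, required for `kind = "random"`.
#' @param constant Driven level for `constant_chain`.
#' @return A list with `model` (a `qn_model`) and `expected` (a list of
#'   known facts: named entries among `fixed_points` (list of states),
#'   `has_cycle`, `convergence_bound`, `driven_level`).
#' @export
make_fixture <- function(kind = c("constant_chain", "toggle", "relay",
                                  "negative_feedback", "random"),
                         size = 3L, seed = NULL, constant = 2L) {
  kind <- match.arg(kind)
  stopifnot(size >= 1L)
  chain_names <- function(n) paste0("N", seq_len(n))
  if (kind == "constant_chain") {
    nms <- chain_names(size)
    nodes <- c(
      list(qn_node(nms[1L], target = as.character(constant))),
      lapply(seq_len(size - 1L) + 1L,
             function(i) qn_node(nms[i], target = nms[i - 1L]))
    )
    model <- qn_model(nodes, name = paste0("constant_chain_", size))
    expected <- list(
      fixed_points = list(stats::setNames(rep(as.integer(constant), size), nms)),
      has_cycle = FALSE,
      driven_level = as.integer(constant),
      convergence_bound = 5L * size
    )
  } else if (kind == "toggle") {
    nodes <- list(qn_node("A", target = "4 - 2*B"),
                  qn_node("B", target = "4 - 2*A"))
    edges <- rbind(qn_edge("B", "A", "inhibitor"),
                   qn_edge("A", "B", "inhibitor"))
    model <- qn_model(nodes, edges, name = "toggle")
    expected <- list(
      fixed_points = list(c(A = 4L, B = 0L), c(A = 0L, B = 4L)),
      has_cycle = TRUE
    )
  } else if (kind == "relay") {
    nms <- chain_names(size)
    nodes <- c(
      list(qn_node(nms[1L])),
      lapply(seq_len(size - 1L) + 1L,
             function(i) qn_node(nms[i], target = "default"))
    )
    edges <- if (size > 1L) {
      do.call(rbind, lapply(seq_len(size - 1L), function(i)
        qn_edge(nms[i], nms[i + 1L], "activator")))
    } else NULL
    model <- qn_model(nodes, edges, name = paste0("relay_", size))
    expected <- list(
      # every uniform state is fixed: the head holds and the chain copies it
      fixed_points = lapply(0:4, function(v)
        stats::setNames(rep(v, size), nms)),
      has_cycle = FALSE,
      convergence_bound = 5L * size
    )
  } else if (kind == "negative_feedback") {
    nodes <- list(qn_node("A", target = "4 - 2*B"),
                  qn_node("B", target = "A"))
    edges <- rbind(qn_edge("B", "A", "inhibitor"),
                   qn_edge("A", "B", "activator"))
    model <- qn_model(nodes, edges, name = "negative_feedback")
    expected <- list(fixed_points = list(), has_cycle = TRUE)
  } else { # random
    if (is.null(seed)) stop("kind = 'random' requires a seed", call. = FALSE)
    set.seed(as.integer(seed))
    nms <- chain_names(size)
    # Ranges capped so the state space stays well under the oracle limit.
    his <- sample(2:4, size, replace = TRUE)
    while (prod(his + 1) > 1e5) his[which.max(his)] <- his[which.max(his)] - 1L
    nodes <- lapply(seq_len(size), function(i) qn_node(nms[i], c(0L, his[i])))
    pairs <- expand.grid(from = nms, to = nms, stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(pairs)) < min(1, 2 / size)
    edges <- if (any(keep)) {
      data.frame(from = pairs$from[keep], to = pairs$to[keep],
                 sign = sample(c("activator", "inhibitor"), sum(keep),
                               replace = TRUE),
                 stringsAsFactors = FALSE)
    } else NULL
    model <- qn_model(nodes, edges, name = paste0("random_", size, "_", seed))
    expected <- list()
  }
  list(model = model, expected = expected)
}

#' Generate a synthetic OCR trace
#'
#' A piecewise-constant trace at the four phase levels (basal,
#' post-oligomycin, maximal, post-rotenone/antimycin tail), aligned to the
#' protocol's injection counters, with optional additive Gaussian noise.
#' Noise is applied on the continuous scale, then the trace is rounded to
#' integer OCR levels and clamped to [0, 10], because the qualitative
#' network world is integer-valued. With `noise_sd = 0`,
#' [compute_metrics()] recovers the phase levels exactly.
#'
#' @param levels Numeric length-4 vector: basal, post-oligomycin, maximal,
#'   tail; each within [0, 10].
#' @param noise_sd Standard deviation of the additive noise (>= 0).
#' @param protocol A `qn_protocol` giving event times and duration.
#' @param seed Optional integer seed for reproducibility.
#' @return A `qn_ocr_trace` data frame (`counter`, `OCR`) with the protocol
#'   attached.
#' @examples
#' tr <- make_synthetic_trace(c(4, 2, 8, 0))
#' compute_metrics(tr)
#' @export
make_synthetic_trace <- function(levels, noise_sd = 0,
                                 protocol = stress_protocol(), seed = NULL) {
  stopifnot(length(levels) == 4L, all(levels >= 0 & levels <= 10))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  stopifnot(inherits(protocol, "qn_protocol"))
  ev <- stats::setNames(protocol$events$at, protocol$events$drug)
  stopifnot(all(c("oligomycin", "fccp", "rot_aa") %in% names(ev)))
  counter <- 0:protocol$duration
  phase <- findInterval(counter, c(ev[["oligomycin"]], ev[["fccp"]],
                                   ev[["rot_aa"]])) + 1L
  ocr <- levels[phase]
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (noise_sd > 0) ocr <- ocr + stats::rnorm(length(ocr), sd = noise_sd)
  ocr <- pmin(pmax(round(ocr), 0L), 10L)
  structure(data.frame(counter = counter, OCR = as.integer(ocr)),
            class = c("qn_ocr_trace", "data.frame"),
            condition = "synthetic",
            protocol = protocol)
}
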