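# In-silico mitochondrial stress test: counter-scheduled drug perturbations
# over a pre-equilibrated condition, an OCR trace per counter unit, and the
# standard extracellular-flux summaries (basal, ATP-linked, maximal, spare,
# non-mitochondrial respiration).

#' Define a stress-test protocol
#'
#' Drug injections are keyed to the assay counter (one unit per step, one
#' nominal minute). The defaults place oligomycin at 20, FCCP at 50 and
#' rotenone + antimycin A at 80 within a 100-unit run, matching the phase
#' structure of a standard extracellular-flux assay. Once injected, a drug
#' stays active to the end of the run (sequential injections into a sealed
#' plate). `lag` is the settling window excluded after each injection
#' before plateaus are measured.
#'
#' @param oligomycin,fccp,rot_aa Injection counters (strictly increasing).
#'   `NA` omits the event.
#' @param duration Run length in counter units (final counter value).
#' @param lag Settling lag in counter units.
#' @return A `qn_protocol`: list with `events` (data frame `at`, `drug`,
#'   `node`, `level`), `duration`, `lag`.
#' @export
stress_protocol <- function(oligomycin = 20, fccp = 50, rot_aa = 80,
                            duration = 100, lag = 5) {
  drugs <- c(oligomycin = "Oligomycin", fccp = "FCCP", rot_aa = "RotAA")
  at <- c(oligomycin = oligomycin, fccp = fccp, rot_aa = rot_aa)
  keep <- !is.na(at)
  events <- data.frame(
    at = as.integer(unname(at[keep])),
    drug = names(at)[keep],
    node = unname(drugs[names(at)[keep]]),
    level = rep(1L, sum(keep)),
    stringsAsFactors = FALSE
  )
  events <- events[order(events$at), , drop = FALSE]
  rownames(events) <- NULL
  if (any(events$at < 0 | events$at > duration)) {
    stop("event counters must lie in [0, duration]", call. = FALSE)
  }
  if (nrow(events) > 1L && any(diff(events$at) <= 0)) {
    stop("protocol events must be strictly increasing in counter time",
         call. = FALSE)
  }
  stopifnot(duration >= 1, lag >= 0)
  structure(list(events = events, duration = as.integer(duration),
                 lag = as.integer(lag)),
            class = "qn_protocol")
}

#' Read a protocol from a key/value text file
#'
#' Lines of the form `key = value` with keys `oligomycin`, `fccp`,
#' `rot_aa`, `duration`, `lag`; `#` starts a comment. Missing keys take the
#' [stress_protocol()] defaults; a drug key set to `none` omits the event.
#'
#' @param path File path.
#' @return A `qn_protocol`.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  args <- formals(stress_protocol)
  for (pair in kv) {
    if (length(pair) != 2L) stop("malformed protocol line: ", paste(pair, collapse = "="),
                                 call. = FALSE)
    key <- pair[1L]
    if (!key %in% names(args)) stop("unknown protocol key '", key, "'", call. = FALSE)
    args[[key]] <- if (identical(pair[2L], "none")) NA else as.numeric(pair[2L])
  }
  do.call(stress_protocol, as.list(args))
}

#' @export
print.qn_protocol <- function(x, ...) {
  cat("Stress-test protocol: duration ", x$duration, ", settling lag ",
      x$lag, "\n", sep = "")
  for (i in seq_len(nrow(x$events))) {
    cat("  counter ", x$events$at[i], ": ", x$events$drug[i],
        " (", x$events$node[i], " -> ", x$events$level[i], ")\n", sep = "")
  }
  invisible(x)
}

#' Run an in-silico mitochondrial stress test
#'
#' The model is first settled to a fixed point under the condition's
#' environment clamps (with the counter held at 0), so the basal phase
#' reflects the settled treatment. The counter then advances by exactly one
#' unit per step from 0 to `duration`; when it reaches an event's counter
#' the corresponding drug switch is forced and held for the remainder of
#' the run. The OCR node is recorded at every counter value.
#'
#' @param model A model containing `OCR`, `Counter` and the drug nodes
#'   named by the protocol events.
#' @param condition A `qn_condition` or condition name (see
#'   [frc_condition()]).
#' @param protocol A `qn_protocol` (default [stress_protocol()]).
#' @param clamp Optional extra named clamps forced throughout the run, e.g.
#'   `c(H_in = 2)` for the proton-mediation counterfactual.
#' @param full_state If `TRUE`, record every node, not just OCR.
#' @return A `qn_ocr_trace`: data frame with columns `counter`, `OCR` (and
#'   all nodes if `full_state`), with attributes `condition`, `protocol`,
#'   `settled_state` and `basal_level` (the settled pre-injection OCR
#'   level, an integer).
#' @examples
#' \donttest{
#' trace <- run_stress_test(frc_reference_model(), "control")
#' head(trace)
#' }
#' @export
run_stress_test <- function(model, condition, protocol = stress_protocol(),
                            clamp = NULL, full_state = FALSE) {
  stopifnot(inherits(model, "qn_model"), inherits(protocol, "qn_protocol"))
  if (is.character(condition)) condition <- frc_condition(condition)
  stopifnot(inherits(condition, "qn_condition"))
  required <- c("OCR", "Counter", protocol$events$node)
  missing <- setdiff(required, node_names(model))
  if (length(missing) > 0L) {
    stop("model lacks required node(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (protocol$duration > model$nodes$Counter$range_hi) {
    stop("protocol duration exceeds the counter range", call. = FALSE)
  }
  run_clamp <- c(condition$clamps, clamp)
  init <- frc_baseline_state(model, condition)
  state <- settle_state(model, init, clamp = run_clamp)
  basal_level <- unname(state[["OCR"]])

  nms <- node_names(model)
  records <- matrix(NA_integer_, nrow = protocol$duration + 1L,
                    ncol = length(nms), dimnames = list(NULL, nms))
  for (counter in 0:protocol$duration) {
    state["Counter"] <- counter
    hit <- protocol$events$at == counter
    if (any(hit)) {
      state[protocol$events$node[hit]] <- protocol$events$level[hit]
    }
    records[counter + 1L, ] <- state
    if (counter < protocol$duration) {
      state <- qn_step(model, state, clamp = run_clamp)
    }
  }
  cols <- if (full_state) nms else "OCR"
  trace <- data.frame(counter = 0:protocol$duration,
                      records[, cols, drop = FALSE])
  structure(trace,
            class = c("qn_ocr_trace", "data.frame"),
            condition = condition$name,
            protocol = protocol,
            settled_state = stats::setNames(as.integer(records[1L, ]), nms),
            basal_level = basal_level)
}

#' Summarise an OCR trace into stress-test metrics
#'
#' Measurement windows are derived from the protocol's event counters with
#' the settling lag `L`: basal is the mean OCR over `[L, t_oligo)`; the
#' post-oligomycin plateau is the mean over `[t_oligo + L, t_fccp)`;
#' maximal respiration is the maximum over `[t_fccp, t_rot)`;
#' non-mitochondrial respiration is the mean over `[t_rot + L, duration]`.
#' ATP-linked respiration is basal minus the post-oligomycin plateau and
#' spare capacity is maximal minus basal, exactly.
#'
#' @param trace A `qn_ocr_trace` (or data frame with `counter` and `OCR`).
#' @param protocol The protocol the trace was run under; defaults to the
#'   protocol attached to the trace.
#' @return A `qn_stress_metrics`: list with `basal`, `atp_linked`,
#'   `maximal`, `spare`, `non_mito` in model OCR levels (0--10).
#' @export
compute_metrics <- function(trace, protocol = attr(trace, "protocol")) {
  stopifnot(is.data.frame(trace), all(c("counter", "OCR") %in% names(trace)))
  if (is.null(protocol)) stop("no protocol supplied or attached to the trace",
                              call. = FALSE)
  stopifnot(inherits(protocol, "qn_protocol"))
  ev <- stats::setNames(protocol$events$at, protocol$events$drug)
  L <- protocol$lag
  dur <- protocol$duration
  ocr_in <- function(from, to_excl = NULL, to_incl = NULL) {
    upper <- if (!is.null(to_excl)) trace$counter < to_excl else trace$counter <= to_incl
    vals <- trace$OCR[trace$counter >= from & upper]
    if (length(vals) == 0L) {
      stop("empty measurement window [", from, ", ",
           if (!is.null(to_excl)) to_excl else to_incl,
           "): protocol events too close together", call. = FALSE)
    }
    vals
  }
  t_oligo <- if ("oligomycin" %in% names(ev)) ev[["oligomycin"]] else dur + 1L
  basal <- mean(ocr_in(L, to_excl = min(t_oligo, dur + 1L)))
  if (all(c("oligomycin", "fccp", "rot_aa") %in% names(ev))) {
    post_oligo <- mean(ocr_in(ev[["oligomycin"]] + L, to_excl = ev[["fccp"]]))
    maximal <- max(ocr_in(ev[["fccp"]], to_excl = ev[["rot_aa"]]))
    non_mito <- mean(ocr_in(ev[["rot_aa"]] + L, to_incl = dur))
  } else if (length(ev) == 0L) {
    post_oligo <- basal
    maximal <- max(ocr_in(L, to_incl = dur))
    non_mito <- 0
  } else {
    stop("protocol must carry either all three injections or none",
         call. = FALSE)
  }
  structure(
    list(basal = basal, atp_linked = basal - post_oligo,
         maximal = maximal, spare = maximal - basal, non_mito = non_mito,
         post_oligo_plateau = post_oligo),
    class = "qn_stress_metrics"
  )
}

#' @export
print.qn_stress_metrics <- function(x, ...) {
  cat("Stress-test metrics (model OCR levels, 0-10):\n")
  cat(sprintf("  basal                %6.2f\n", x$basal))
  cat(sprintf("  ATP-linked           %6.2f\n", x$atp_linked))
  cat(sprintf("  maximal              %6.2f\n", x$maximal))
  cat(sprintf("  spare capacity       %6.2f\n", x$spare))
  cat(sprintf("  non-mitochondrial    %6.2f\n", x$non_mito))
  invisible(x)
}

#' Compare experimental conditions on one model
#'
#' Runs the stress test for every condition, computes metrics, and reports
#' one row per condition with signed deltas versus control, plus the three
#' directional predictions evaluated by exact integer comparison of the
#' settled basal OCR levels: lactic acid lowers basal OCR, protons alone
#' lower basal OCR, sodium lactate leaves basal OCR unchanged (each
#' reported only when the relevant condition is included).
#'
#' @param model A `qn_model` with the stress-test nodes.
#' @param conditions Character vector of condition names; must contain
#'   `"control"`. At least two conditions.
#' @param protocol A `qn_protocol`.
#' @return A data frame (one row per condition) with the metric columns,
#'   `basal_settled` (integer), `delta_basal` vs control, and attribute
#'   `verdicts` (named logical vector).
#' @examples
#' \donttest{
#' cmp <- compare_conditions(frc_reference_model(),
#'                           c("control", "lactic_acid"))
#' attr(cmp, "verdicts")
#' }
#' @export
compare_conditions <- function(model,
                               conditions = c("control", "lactic_acid",
                                              "sodium_lactate", "protons_only"),
                               protocol = stress_protocol()) {
  stopifnot(length(conditions) >= 2L)
  if (!"control" %in% conditions) {
    stop("'control' must be among the conditions compared", call. = FALSE)
  }
  rows <- lapply(conditions, function(cn) {
    trace <- run_stress_test(model, cn, protocol)
    m <- compute_metrics(trace, protocol)
    data.frame(condition = cn,
               basal_settled = as.integer(attr(trace, "basal_level")),
               basal = m$basal, atp_linked = m$atp_linked,
               maximal = m$maximal, spare = m$spare, non_mito = m$non_mito,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ctrl <- out$basal_settled[out$condition == "control"]
  out$delta_basal <- out$basal_settled - ctrl
  verdicts <- logical(0)
  if ("lactic_acid" %in% conditions) {
    verdicts["LA_lowers_basal"] <-
      out$basal_settled[out$condition == "lactic_acid"] < ctrl
  }
  if ("protons_only" %in% conditions) {
    verdicts["protons_lower_basal"] <-
      out$basal_settled[out$condition == "protons_only"] < ctrl
  }
  if ("sodium_lactate" %in% conditions) {
    verdicts["sodium_lactate_neutral"] <-
      out$basal_settled[out$condition == "sodium_lactate"] == ctrl
  }
  structure(out, verdicts = verdicts)
}

#' Plot an OCR trace
#'
#' OCR level against the assay counter, with injection times marked.
#'
#' @param x A `qn_ocr_trace`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.qn_ocr_trace <- function(x, ...) {
  protocol <- attr(x, "protocol")
  graphics::plot(x$counter, x$OCR, type = "s", ylim = c(0, 10),
                 xlab = "counter (nominal minutes)", ylab = "OCR (0-10)",
                 main = paste0("In-silico stress test",
                               if (!is.null(attr(x, "condition")))
                                 paste0(" - ", attr(x, "condition"))),
                 ...)
  if (!is.null(protocol) && nrow(protocol$events) > 0L) {
    graphics::abline(v = protocol$events$at, lty = 3, col = "grey40")
    graphics::mtext(protocol$events$drug, side = 3, at = protocol$events$at,
                    cex = 0.7, col = "grey20")
  }
  invisible(x)
}
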