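# Reference qualitative network of fibroblastic reticular cell (FRC)
# central carbon metabolism: glycolysis, pyruvate/acetyl-CoA handling with
# an acetylcarnitine shunt, TCA flux, the electron transport chain with
# proton-gradient back-pressure, ATP synthase, an uncoupling node, an OCR
# readout on 0-10, a 0-100 assay clock, and 0/1 drug switches for
# oligomycin, FCCP and rotenone + antimycin A.
#
# The network topology and every target function here are a literature-based
# reconstruction of the mechanism (MCT1-coupled lactate/proton import
# acidifying the cytosol and throttling glycolysis and TCA flux); they are
# shipped as readable model documents in inst/extdata/models/ and can be
# swapped for externally supplied BMA files run through the same protocol.

#' Build the reference FRC metabolism model
#'
#' Key design points, all visible in the shipped target functions:
#' * `H_in` encodes intracellular proton *concentration* (high node = low
#'   pH) and follows the extracellular proton load: MCT1 co-imports a
#'   proton with each lactate only when extracellular protons are elevated,
#'   so lactic acid and a pure proton load acidify the cytosol while sodium
#'   lactate (lactate at neutral pH) does not.
#' * `MCT1` is induced by extracellular lactate and gates lactate import
#'   (`Int_Lactate = avg(MCT1, Ext_Lactate)`).
#' * Elevated `H_in` inhibits `Glycolysis` (`4 - H_in`) and caps
#'   `TCA_flux` (`min(AcetylCoA, 5 - H_in, 2)`; the constant 2 is the
#'   ADP-limited normal flux). Acetyl-CoA in excess of TCA entry
#'   accumulates as `Acetylcarnitine` (`AcetylCoA - TCA_flux + 2`).
#' * `ETC` follows NADH but is throttled by `ProtonGradient` back-pressure
#'   and relieved by uncoupling; `ATP_Synthase` dissipates the gradient.
#'   `RotAA = 1` forces the chain off, `Oligomycin = 1` forces ATP synthase
#'   off, `FCCP = 1` drives `Uncoupling` to its maximum.
#' * `OCR = ceil(5 * ETC / 2)` scales chain activity to the 0-10 readout;
#'   `Counter` advances one unit (one nominal assay minute) per step.
#'
#' @return A validated `qn_model`.
#' @examples
#' m <- frc_reference_model()
#' m$nodes$OCR$range_hi
#' @export
frc_reference_model <- function() {
  nodes <- list(
    qn_node("Ext_Lactate", c(0, 4), "default",
            "extracellular lactate load; environment node (2 = normal)"),
    qn_node("Ext_Protons", c(0, 4), "default",
            "extracellular proton load; environment node (2 = neutral pH)"),
    qn_node("MCT1", c(0, 4), "default",
            "monocarboxylate transporter 1 activity, induced by lactate"),
    qn_node("Int_Lactate", c(0, 4), "default",
            "intracellular lactate, imported via MCT1"),
    qn_node("H_in", c(0, 4), "default",
            "intracellular proton concentration (high = acidic); protons enter with MCT1-borne lactate only under extracellular acid load"),
    qn_node("Glycolysis", c(0, 4), "4 - H_in",
            "glycolytic flux, inhibited by cytosolic acidification"),
    qn_node("Pyruvate", c(0, 4), "ceil(avg(Glycolysis, Int_Lactate))",
            "pyruvate pool fed by glycolysis and imported lactate"),
    qn_node("AcetylCoA", c(0, 4), "default",
            "acetyl-CoA produced from pyruvate"),
    qn_node("TCA_flux", c(0, 4), "min(AcetylCoA, 5 - H_in, 2)",
            "TCA cycle flux: substrate-limited, acid-inhibited, ADP-capped at normal"),
    qn_node("Acetylcarnitine", c(0, 4), "AcetylCoA - TCA_flux + 2",
            "acetylcarnitine shunt: sink for acetyl-CoA exceeding TCA entry"),
    qn_node("NADH", c(0, 4), "default",
            "reducing equivalents delivered to the chain"),
    qn_node("ETC", c(0, 4),
            "min(NADH + Uncoupling, 5 - ProtonGradient + Uncoupling) * (1 - RotAA)",
            "electron transport chain (complexes I-IV): NADH-driven, gradient-throttled, uncoupling-relieved, ablated by rotenone/antimycin A"),
    qn_node("ProtonGradient", c(0, 4),
            "2 * ETC + 2 - 2 * ATP_Synthase - 3 * Uncoupling",
            "inner-membrane proton-motive force: built by the chain, dissipated by ATP synthase and uncoupling"),
    qn_node("ATP_Synthase", c(0, 4), "2 * (1 - Oligomycin)",
            "ATP synthase activity, shut off by oligomycin"),
    qn_node("Uncoupling", c(0, 4), "4 * FCCP",
            "proton permeability of the inner membrane, driven to maximum by FCCP"),
    qn_node("ATP", c(0, 4), "default",
            "cellular ATP supply from oxidative and glycolytic routes"),
    qn_node("OCR", c(0, 10), "ceil(5 * ETC / 2)",
            "oxygen consumption rate readout, chain activity scaled to 0-10"),
    qn_node("Counter", c(0, 100), "Counter + 1",
            "assay clock: one unit per step, roughly one minute"),
    qn_node("Oligomycin", c(0, 1), "default",
            "drug switch: ATP synthase inhibitor (set by the protocol only)"),
    qn_node("FCCP", c(0, 1), "default",
            "drug switch: protonophore uncoupler (set by the protocol only)"),
    qn_node("RotAA", c(0, 1), "default",
            "drug switch: rotenone + antimycin A (set by the protocol only)")
  )
  edges <- rbind(
    qn_edge("Ext_Lactate", "MCT1", "activator"),
    qn_edge("MCT1", "Int_Lactate", "activator"),
    qn_edge("Ext_Lactate", "Int_Lactate", "activator"),
    qn_edge("Ext_Protons", "H_in", "activator"),
    qn_edge("H_in", "Glycolysis", "inhibitor"),
    qn_edge("Glycolysis", "Pyruvate", "activator"),
    qn_edge("Int_Lactate", "Pyruvate", "activator"),
    qn_edge("Pyruvate", "AcetylCoA", "activator"),
    qn_edge("AcetylCoA", "TCA_flux", "activator"),
    qn_edge("H_in", "TCA_flux", "inhibitor"),
    qn_edge("AcetylCoA", "Acetylcarnitine", "activator"),
    qn_edge("TCA_flux", "Acetylcarnitine", "inhibitor"),
    qn_edge("TCA_flux", "NADH", "activator"),
    qn_edge("NADH", "ETC", "activator"),
    qn_edge("ProtonGradient", "ETC", "inhibitor"),
    qn_edge("Uncoupling", "ETC", "activator"),
    qn_edge("RotAA", "ETC", "inhibitor"),
    qn_edge("ETC", "ProtonGradient", "activator"),
    qn_edge("ATP_Synthase", "ProtonGradient", "inhibitor"),
    qn_edge("Uncoupling", "ProtonGradient", "inhibitor"),
    qn_edge("Oligomycin", "ATP_Synthase", "inhibitor"),
    qn_edge("FCCP", "Uncoupling", "activator"),
    qn_edge("ATP_Synthase", "ATP", "activator"),
    qn_edge("Glycolysis", "ATP", "activator"),
    qn_edge("ETC", "OCR", "activator"),
    qn_edge("Counter", "Counter", "activator")
  )
  qn_model(
    nodes, edges, name = "FRC_metabolism",
    notes = c(
      "Reconstruction of an executable model of FRC central carbon metabolism",
      "with an in-silico mitochondrial stress test readout (OCR, 0-10).",
      "H_in encodes proton concentration: a HIGH level means LOW pH."
    )
  )
}

frc_environment_nodes <- c("Ext_Lactate", "Ext_Protons")
frc_drug_nodes <- c("Oligomycin", "FCCP", "RotAA")

#' Named experimental conditions
#'
#' Conditions are encoded as clamps on the two environment nodes, on the
#' 0--4 scale where 2 is normal and 4 high:
#' * `control`: lactate 2, protons 2;
#' * `lactic_acid`: lactate 4, protons 4 (the free acid delivers both; the
#'   in-vitro analogue is 15 mmol/L LA);
#' * `sodium_lactate`: lactate 4, protons 2 (the salt delivers lactate at
#'   neutral pH);
#' * `protons_only`: lactate 2, protons 4 (acid load without extra
#'   lactate, the in-silico analogue of direct intracellular acidification).
#'
#' @param name One of `"control"`, `"lactic_acid"`, `"sodium_lactate"`,
#'   `"protons_only"`.
#' @return A `qn_condition`: list with `name`, `clamps` (named integer
#'   vector over environment nodes) and `analogue` (free-text experimental
#'   analogue).
#' @export
frc_condition <- function(name) {
  conditions <- list(
    control = list(
      clamps = c(Ext_Lactate = 2L, Ext_Protons = 2L),
      analogue = "vehicle / unconditioned medium"),
    lactic_acid = list(
      clamps = c(Ext_Lactate = 4L, Ext_Protons = 4L),
      analogue = "15 mmol/L lactic acid"),
    sodium_lactate = list(
      clamps = c(Ext_Lactate = 4L, Ext_Protons = 2L),
      analogue = "15 mmol/L sodium lactate (lactate at neutral pH)"),
    protons_only = list(
      clamps = c(Ext_Lactate = 2L, Ext_Protons = 4L),
      analogue = "intracellular proton addition / low-pH medium")
  )
  if (!name %in% names(conditions)) {
    stop("unknown condition '", name, "'; valid conditions: ",
         paste(names(conditions), collapse = ", "), call. = FALSE)
  }
  structure(
    list(name = name, clamps = conditions[[name]]$clamps,
         analogue = conditions[[name]]$analogue),
    class = "qn_condition"
  )
}

#' @export
print.qn_condition <- function(x, ...) {
  cat("Condition '", x$name, "' (", x$analogue, "): ",
      paste(names(x$clamps), x$clamps, sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Baseline state for a condition
#'
#' Environment nodes at the condition's clamps, drug switches at 0, the
#' counter at 0, and every other node at the midpoint of its range (level 2
#' on the default range, the "normal" level; OCR at 5). This is the state
#' from which the model is pre-equilibrated before a stress test; under
#' control clamps the settled state is a fixed point.
#'
#' @param model The reference model (or any model sharing its node roles).
#' @param condition A `qn_condition` from [frc_condition()], or a condition
#'   name.
#' @return A named integer state vector.
#' @export
frc_baseline_state <- function(model, condition = "control") {
  if (is.character(condition)) condition <- frc_condition(condition)
  stopifnot(inherits(condition, "qn_condition"))
  lo <- node_range_lo(model)
  hi <- node_range_hi(model)
  levels <- as.integer(floor((lo + hi) / 2))
  names(levels) <- node_names(model)
  for (nm in names(condition$clamps)) {
    if (!nm %in% names(levels)) {
      stop("model lacks environment node '", nm, "'", call. = FALSE)
    }
    levels[nm] <- condition$clamps[[nm]]
  }
  levels[intersect(frc_drug_nodes, names(levels))] <- 0L
  if ("Counter" %in% names(levels)) levels["Counter"] <- 0L
  qn_state(model, levels)
}

#' Settle a model under clamps
#'
#' Advances the model until a fixed point of the clamped system is reached
#' (the counter, if present, is held at 0 so that settling does not consume
#' assay time). Errors if the clamped dynamics cycle instead of settling.
#'
#' @param model A `qn_model`.
#' @param state Initial state.
#' @param clamp Named forced levels (environment clamps, counterfactual
#'   interventions). The counter is clamped to its current value
#'   automatically.
#' @param max_steps Settling bound (default 1000).
#' @return The settled state (named integer vector).
#' @export
settle_state <- function(model, state, clamp = NULL, max_steps = 1000) {
  state <- qn_state(model, state)
  if ("Counter" %in% node_names(model) && !"Counter" %in% names(clamp)) {
    clamp <- c(clamp, c(Counter = unname(state[["Counter"]])))
  }
  traj <- simulate_qn(model, state, max_steps = max_steps, clamp = clamp)
  if (traj$terminal == "cycle") {
    stop("model does not settle under these clamps: entered a cycle of length ",
         traj$cycle_length, call. = FALSE)
  }
  if (traj$terminal == "max_steps_reached") {
    stop("model did not settle within ", max_steps, " steps", call. = FALSE)
  }
  final_state(traj)
}
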