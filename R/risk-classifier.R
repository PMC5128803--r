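## Torsadogenic-risk classification.
##
## Two complementary classifiers: (i) a patch-clamp decision tree on the
## drug's pD2 profile that triages compounds cheaply, and (ii) the
## simulation-based grouping of the paired drug-vs-control AP effect into
## the A1 / A2 / B / C torsadogenic-risk groups (A1: exaggerated, > 40%,
## APD prolongation; A2: triangulation without APD shortening; B:
## unexacerbated prolongation or triangulation with shortening; C:
## shortening or no effect).

.TREE_OUTCOMES <- c("SAFE_LIKELY", "A1_CANDIDATE", "GROUP_C",
                    "NEEDS_FULL_PANEL", "NEEDS_SIMULATION")

#' pD2-threshold decision tree
#'
#' Triage of a multichannel potency profile:
#' \itemize{
#'   \item no measurable I_Kr block: `SAFE_LIKELY` (a trafficking effect
#'     cannot be excluded; noted in the trail);
#'   \item pD2(I_Kr) < 6 and no other current blocked: `A1_CANDIDATE`
#'     (pure, weak hERG blocker); with other currents blocked:
#'     `NEEDS_FULL_PANEL`;
#'   \item pD2(I_Kr) >= 6 and pD2(I_CaL) > pD2(I_Kr): `GROUP_C` (the loss
#'     of repolarizing current is compensated by the loss of depolarizing
#'     current); otherwise `NEEDS_SIMULATION` (with a "pure potent IKr
#'     blocker" note when nothing else is blocked).
#' }
#'
#' @param drug a [drug_profile()].
#' @return List of class `torsim_tree`: `outcome` and `trail` (ordered
#'   decisions taken).
#' @export
classify_by_tree <- function(drug) {
  stopifnot(inherits(drug, "torsim_drug"))
  if (!"kr" %in% names(drug$ic50)) stop("profile lacks an I_Kr field",
                                        call. = FALSE)
  trail <- character(0)
  others_blocked <- any(!is.na(drug$ic50[c("na", "ks")])) ||
    drug$ik1_block_pct > 0
  cal_blocked <- !is.na(drug$ic50[["cal"]])
  if (is.na(drug$ic50[["kr"]])) {
    trail <- c(trail, "I_Kr assay negative: no measurable IC50",
               "probability of safety high; trafficking effect not excluded")
    return(.tree_result("SAFE_LIKELY", trail))
  }
  p_kr <- pd2(drug$ic50[["kr"]])
  trail <- c(trail, sprintf("I_Kr blocked, pD2 = %.2f", p_kr))
  if (p_kr < 6) {
    trail <- c(trail, "pD2(I_Kr) < 6: test all other currents")
    if (!others_blocked && !cal_blocked) {
      trail <- c(trail,
                 "no other current blocked: pure weak I_Kr blocker",
                 "literal tree branch: weak pure blockers flagged A1")
      return(.tree_result("A1_CANDIDATE", trail))
    }
    trail <- c(trail, "other currents blocked: full panel required")
    return(.tree_result("NEEDS_FULL_PANEL", trail))
  }
  trail <- c(trail, "pD2(I_Kr) >= 6: test I_CaL")
  if (cal_blocked && pd2(drug$ic50[["cal"]]) > p_kr) {
    trail <- c(trail, sprintf(
      "pD2(I_CaL) = %.2f > pD2(I_Kr): depolarizing loss compensates",
      pd2(drug$ic50[["cal"]])))
    return(.tree_result("GROUP_C", trail))
  }
  if (others_blocked) {
    trail <- c(trail, "I_Na/I_Ks/I_K1 sensitive: simulate to discriminate")
  } else {
    trail <- c(trail, "pure potent I_Kr blocker: simulate to discriminate")
  }
  .tree_result("NEEDS_SIMULATION", trail)
}

.tree_result <- function(outcome, trail) {
  stopifnot(outcome %in% .TREE_OUTCOMES, length(trail) > 0)
  structure(list(outcome = outcome, trail = trail), class = "torsim_tree")
}

#' @export
print.torsim_tree <- function(x, ...) {
  cat("<torsim_tree:", x$outcome, ">\n")
  cat(paste0("  - ", x$trail, collapse = "\n"), "\n")
  invisible(x)
}

#' Simulation-based torsadogenic-risk group
#'
#' Classifies a paired drug-vs-control effect, with precedence
#' A1 > A2 > B > C at boundaries:
#' \itemize{
#'   \item A1: APD90 prolongation above +40%;
#'   \item A2: triangulation present without APD shortening
#'     (delta APD90 >= 0);
#'   \item B: unexacerbated prolongation (above the +5% no-effect band, up
#'     to +40%), or triangulation with shortening;
#'   \item C: shortening or no effect (|delta APD90| <= 5% without
#'     triangulation).
#' }
#'
#' @param effect a [compare_effects()] result.
#' @param no_effect_band percent half-width of the "no effect" band
#'   (default 5).
#' @return `"A1"`, `"A2"`, `"B"` or `"C"`.
#' @export
classify_by_simulation <- function(effect, no_effect_band = 5) {
  stopifnot(inherits(effect, "torsim_effect"))
  d <- effect$delta_apd90_pct
  tri <- isTRUE(effect$triangulation_present)
  if (d > 40) return("A1")
  if (tri && d >= 0) return("A2")
  if ((d > no_effect_band && d <= 40) || (tri && d < 0)) return("B")
  "C"
}

#' Full classification pipeline for one drug
#'
#' Runs the decision tree; when the tree defers (`NEEDS_SIMULATION` /
#' `NEEDS_FULL_PANEL`), runs paired steady-pacing simulations (control and
#' drug) and grades the effect with [classify_by_simulation()].
#'
#' @inheritParams run_paced_to_steady
#' @param drug a [drug_profile()].
#' @param simulate force (`TRUE`) or forbid (`FALSE`) the simulation stage
#'   regardless of the tree outcome; default `NA` follows the tree.
#' @return List of class `torsim_classification`: `drug`, `tree_outcome`,
#'   `trail`, `simulated_group` (NA when not simulated), `effect`.
#' @export
classify_drug <- function(model, drug, params = NULL, protocol = NULL,
                          simulate = NA) {
  stopifnot(inherits(model, "torsim_model"), inherits(drug, "torsim_drug"))
  tree <- classify_by_tree(drug)
  do_sim <- if (is.na(simulate)) {
    tree$outcome %in% c("NEEDS_SIMULATION", "NEEDS_FULL_PANEL")
  } else {
    isTRUE(simulate)
  }
  group <- NA_character_
  eff <- NULL
  if (do_sim) {
    tr_c <- run_paced_to_steady(model, params, NULL, protocol)
    tr_d <- run_paced_to_steady(model, params, drug, protocol)
    m_c <- .last_beat_metrics(tr_c)
    m_d <- .last_beat_metrics(tr_d)
    eff <- compare_effects(m_c, m_d)
    group <- classify_by_simulation(eff)
  }
  structure(
    list(drug = drug$name, tree_outcome = tree$outcome, trail = tree$trail,
         simulated_group = group, effect = eff),
    class = "torsim_classification"
  )
}

.last_beat_metrics <- function(trace) {
  seg <- segment_beats(trace)
  ms <- lapply(seg$windows, ap_metrics)
  m <- ms[[length(ms)]]
  ## carry EADs seen on any recorded beat (2:1 alternans would otherwise
  ## hide every other event)
  m$ead <- any(vapply(ms, function(x) x$ead, TRUE))
  m
}
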