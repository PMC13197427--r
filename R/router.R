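# Red-flag trigger and offline routing strategies over stored persona
# outputs, with simulated-call accounting. All routing is pure and
# deterministic: strategies are controller rules replayed over a scored run
# log, never live re-queries.

STRATEGY_IDS <- c("BASE_HL", "BASE_HS", "BASE_LL", "BASE_LS",
                  "ROUTER_R1", "ROUTER_R2_AUDIT", "ROUTER_R2_CF",
                  "ROUTER_R3_ARBITER")

#' Routing strategy configuration
#'
#' @param strategy_id One of `BASE_HL`, `BASE_HS`, `BASE_LL`, `BASE_LS`,
#'   `ROUTER_R1`, `ROUTER_R2_AUDIT`, `ROUTER_R2_CF`, `ROUTER_R3_ARBITER`.
#' @param safety_net_threshold Red-flag cutoff on the 0-5 safety-net scale;
#'   default 3 (sensitivity range 2-4).
#' @param admission_min_level Lowest disposition level counted as
#'   "admission" in the discharge-vs-admission disagreement clauses;
#'   default 2, so ED observation (level 1) is neither discharge nor
#'   admission.
#' @return An object of class `pr_strategy_config`.
#' @export
strategy_config <- function(strategy_id, safety_net_threshold = 3L,
                            admission_min_level = 2L) {
  if (!strategy_id %in% STRATEGY_IDS) {
    pr_abort(paste0("unknown strategy '", strategy_id, "'"), "pr_config_error")
  }
  if (!is_scalar_num(safety_net_threshold) ||
      safety_net_threshold < 0 || safety_net_threshold > 5) {
    pr_abort("safety_net_threshold must lie in 0..5", "pr_config_error")
  }
  structure(
    list(strategy_id = strategy_id,
         safety_net_threshold = as.integer(safety_net_threshold),
         admission_min_level = as.integer(admission_min_level)),
    class = "pr_strategy_config"
  )
}

#' Red-flag trigger
#'
#' The escalation trigger evaluated on the lean persona's scored metrics:
#' `red_flag = (contra_seq_severity_0to3 > 0) OR
#' (discharge_flag = 1 AND safety_net_score_v2 < threshold)`.
#' Vectorized over records. The safety-net score enters only for discharge
#' records, so an `NA` score on an admitted record never propagates.
#'
#' @param severity Integer vector, contraindication/sequence severity 0-3.
#' @param discharge_flag Integer/logical vector (1 = discharge).
#' @param safety_net Integer vector 0-5 (may be `NA` where
#'   `discharge_flag = 0`).
#' @param threshold Safety-net cutoff, default 3.
#' @return Logical vector.
#' @export
red_flag <- function(severity, discharge_flag, safety_net, threshold = 3L) {
  disch <- as.integer(discharge_flag) == 1L
  weak <- disch & !is.na(safety_net) & safety_net < threshold
  # a discharge with no recorded safety-net score counts as maximally weak
  weak <- weak | (disch & is.na(safety_net) & 0 < threshold)
  (severity > 0) | weak
}

red_flag_row <- function(m, cfg) {
  red_flag(m$contra_seq_severity_0to3, m$discharge_flag,
           m$safety_net_score_v2, cfg$safety_net_threshold)
}

weak_net_row <- function(m, cfg) {
  m$discharge_flag == 1L &&
    (is.na(m$safety_net_score_v2) ||
       m$safety_net_score_v2 < cfg$safety_net_threshold)
}

check_same_scenario <- function(...) {
  rows <- list(...)
  ids <- vapply(rows, function(r) r$scenario_id, character(1))
  if (length(unique(ids)) != 1) {
    pr_abort(paste("records belong to different scenarios:",
                   paste(ids, collapse = " vs ")), "pr_pairing_error")
  }
  ids[1]
}

decision_row <- function(scenario_id, selected_persona, simulated_calls, reasons) {
  tibble::tibble(
    scenario_id = scenario_id,
    selected_persona = selected_persona,
    simulated_calls = as.integer(simulated_calls),
    trigger_reasons = paste(reasons, collapse = ",")
  )
}

#' Route one scenario with strategy R1 (red-flag escalation)
#'
#' The lean persona P_HL is run first; the safe persona P_HS is run and
#' returned only when P_HL's output triggers a red flag (2 simulated calls),
#' otherwise P_HL's output is retained (1 call).
#'
#' @param hl,hs One-row scored-metric tibbles (see [score_record()]) for
#'   P_HL and P_HS on the same scenario.
#' @param cfg A [strategy_config()].
#' @return One-row decision tibble (`scenario_id`, `selected_persona`,
#'   `simulated_calls`, `trigger_reasons`).
#' @export
route_r1 <- function(hl, hs, cfg = strategy_config("ROUTER_R1")) {
  sid <- check_same_scenario(hl, hs)
  if (red_flag_row(hl, cfg)) {
    reasons <- c(
      if (hl$contra_seq_severity_0to3 > 0) "severity_positive",
      if (weak_net_row(hl, cfg)) "weak_safety_net_discharge"
    )
    decision_row(sid, "P_HS", 2L, reasons)
  } else {
    decision_row(sid, "P_HL", 1L, character(0))
  }
}

is_admission <- function(m, cfg) m$disposition_level >= cfg$admission_min_level

#' Route one scenario with strategy R2 (dual-run audit)
#'
#' P_HL and P_HS are always both run (2 simulated calls). P_HS's output is
#' returned when P_HL triggers a red flag or when P_HL recommends discharge
#' while P_HS recommends admission; otherwise P_HL is retained.
#'
#' @inheritParams route_r1
#' @return One-row decision tibble.
#' @export
route_r2_audit <- function(hl, hs, cfg = strategy_config("ROUTER_R2_AUDIT")) {
  sid <- check_same_scenario(hl, hs)
  flagged <- red_flag_row(hl, cfg)
  override <- hl$discharge_flag == 1L && is_admission(hs, cfg)
  if (flagged || override) {
    reasons <- c(
      if (flagged && hl$contra_seq_severity_0to3 > 0) "severity_positive",
      if (flagged && weak_net_row(hl, cfg)) "weak_safety_net_discharge",
      if (override) "disposition_disagreement"
    )
    decision_row(sid, "P_HS", 2L, reasons)
  } else {
    decision_row(sid, "P_HL", 2L, character(0))
  }
}

#' Route one scenario with the counterfactual comparator R2_CF
#'
#' The conservative offline comparator used in the counterfactual
#' experiment: the low-time-pressure safe persona P_LS is selected when
#' P_HL triggers a red flag or when P_HL and P_HS disagree on disposition
#' level (any level difference); otherwise P_HL is retained. Simulated
#' calls are recorded as 3 when P_LS is selected and 2 otherwise, but this
#' strategy is an offline analysis rule and its call count is reported
#' separately from R1/R2/R3.
#'
#' @inheritParams route_r1
#' @param ls One-row scored-metric tibble for P_LS on the same scenario.
#' @return One-row decision tibble.
#' @export
route_r2_cf <- function(hl, hs, ls, cfg = strategy_config("ROUTER_R2_CF")) {
  sid <- check_same_scenario(hl, hs, ls)
  flagged <- red_flag_row(hl, cfg)
  disagree <- hl$disposition_level != hs$disposition_level
  if (flagged || disagree) {
    reasons <- c(
      if (flagged && hl$contra_seq_severity_0to3 > 0) "severity_positive",
      if (flagged && weak_net_row(hl, cfg)) "weak_safety_net_discharge",
      if (disagree) "disposition_disagreement"
    )
    decision_row(sid, "P_LS", 3L, reasons)
  } else {
    decision_row(sid, "P_HL", 2L, character(0))
  }
}

#' Route one scenario with strategy R3 (arbiter)
#'
#' P_HL and P_HS are run first. If they disagree on disposition in the
#' strict discharge-versus-admission sense (one at level 0, the other at or
#' above `admission_min_level`), the low-time-pressure safe persona P_LS is
#' run as an arbiter and returned (3 simulated calls). Absent such
#' disagreement, P_HS is returned only when P_HL triggers a red flag, and
#' P_HL is retained otherwise (2 calls either way).
#'
#' @inheritParams route_r2_cf
#' @return One-row decision tibble.
#' @export
route_r3 <- function(hl, hs, ls, cfg = strategy_config("ROUTER_R3_ARBITER")) {
  sid <- check_same_scenario(hl, hs, ls)
  disagreement <-
    (hl$discharge_flag == 1L && is_admission(hs, cfg)) ||
    (hs$disposition_level == 0L && is_admission(hl, cfg))
  if (disagreement) {
    return(decision_row(sid, "P_LS", 3L, "arbiter_invoked"))
  }
  if (red_flag_row(hl, cfg)) {
    reasons <- c(
      if (hl$contra_seq_severity_0to3 > 0) "severity_positive",
      if (weak_net_row(hl, cfg)) "weak_safety_net_discharge"
    )
    decision_row(sid, "P_HS", 2L, reasons)
  } else {
    decision_row(sid, "P_HL", 2L, character(0))
  }
}

strategy_personas <- function(strategy_id) {
  switch(strategy_id,
    BASE_HL = "P_HL", BASE_HS = "P_HS", BASE_LL = "P_LL", BASE_LS = "P_LS",
    ROUTER_R1 = c("P_HL", "P_HS"),
    ROUTER_R2_AUDIT = c("P_HL", "P_HS"),
    ROUTER_R2_CF = c("P_HL", "P_HS", "P_LS"),
    ROUTER_R3_ARBITER = c("P_HL", "P_HS", "P_LS")
  )
}

#' Simulate a routing strategy over a scored run log
#'
#' Replays an offline controller rule over stored, scored persona outputs:
#' one decision per scenario, deterministic given its inputs. BASE
#' strategies select the named persona with 1 simulated call. A scenario
#' missing a persona record the strategy needs raises a coverage error
#' naming the scenario and persona.
#'
#' @param scored Scored run-log tibble from [score_runlog()] containing all
#'   personas the strategy needs, any mix of variants.
#' @param cfg A [strategy_config()] (or a strategy id string, with default
#'   thresholds).
#' @return List with `decisions` (one row per scenario) and `selected` (the
#'   scored rows of the selected persona records, joined with
#'   `selected_persona`, `simulated_calls`, `trigger_reasons` and
#'   `strategy_id`).
#' @export
simulate_strategy <- function(scored, cfg) {
  if (is.character(cfg)) cfg <- strategy_config(cfg)
  needed <- strategy_personas(cfg$strategy_id)
  scenario_ids <- unique(scored$scenario_id)

  decisions <- vector("list", length(scenario_ids))
  for (i in seq_along(scenario_ids)) {
    sid <- scenario_ids[[i]]
    rows <- scored[scored$scenario_id == sid, , drop = FALSE]
    by_persona <- lapply(needed, function(p) {
      r <- rows[rows$persona_id == p, , drop = FALSE]
      if (nrow(r) != 1) {
        pr_abort(sprintf("scenario '%s' lacks a unique record for persona %s",
                         sid, p), "pr_coverage_error",
                 scenario_id = sid, persona_id = p)
      }
      r
    })
    names(by_persona) <- needed
    decisions[[i]] <- switch(cfg$strategy_id,
      BASE_HL = , BASE_HS = , BASE_LL = , BASE_LS =
        decision_row(sid, needed, 1L, character(0)),
      ROUTER_R1 = route_r1(by_persona$P_HL, by_persona$P_HS, cfg),
      ROUTER_R2_AUDIT = route_r2_audit(by_persona$P_HL, by_persona$P_HS, cfg),
      ROUTER_R2_CF = route_r2_cf(by_persona$P_HL, by_persona$P_HS,
                                 by_persona$P_LS, cfg),
      ROUTER_R3_ARBITER = route_r3(by_persona$P_HL, by_persona$P_HS,
                                   by_persona$P_LS, cfg)
    )
  }
  decisions <- dplyr::bind_rows(decisions)

  selected <- dplyr::inner_join(
    scored, decisions,
    by = c("scenario_id", "persona_id" = "selected_persona")
  )
  selected$selected_persona <- selected$persona_id
  selected$strategy_id <- cfg$strategy_id
  list(decisions = decisions, selected = selected)
}
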