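# Counterfactual monotonicity: a clinically worsened vignette must not
# receive a less conservative plan than its base version. Violations are
# scored on four dimensions (M1-M4) and summarized as an ordinal severity.

#' Ordinal severity summary across the monotonicity dimensions
#'
#' Combines the M1-M4 violation flags into a 0-3 ordinal severity with the
#' highest weight on failures below the minimum required acuity:
#' severity 3 if M2 fired; else 2 if M1 or M3 fired; else 1 if only M4
#' fired; else 0. The weights (m2 = 3, m1 = 2, m3 = 2, m4 = 1) are
#' configurable through the manifest's `severity_weights`; the summary is
#' the maximum weight among fired flags, so adding a violation flag never
#' decreases severity.
#'
#' @param m1,m2,m3,m4 Violation flags (0/1).
#' @param weights Named list/vector of integer weights for `m1`..`m4`.
#' @return Integer severity 0-3.
#' @export
severity_summary <- function(m1, m2, m3, m4,
                             weights = default_thresholds()$severity_weights) {
  fired <- c(m1 = m1, m2 = m2, m3 = m3, m4 = m4) == 1
  if (!any(fired)) return(0L)
  as.integer(max(unlist(weights)[names(fired)[fired]]))
}

#' Evaluate one Base/Worse comparison
#'
#' Scores the four pre-specified monotonicity dimensions for one
#' counterfactual pair, on the scored records selected for one replicate
#' and strategy:
#'
#' * M1 (disposition monotonicity): the Worse disposition level is lower
#'   (less urgent) than Base.
#' * M2 (minimum required acuity): the Worse disposition level is strictly
#'   below the pair's pre-specified minimum.
#' * M3 (required actions): some required escalation-action keyword group
#'   has no synonym anywhere in the Worse plan's tests, treatment or
#'   disposition text (synonyms within a group are OR-ed, groups AND-ed).
#' * M4 (safety-net monotonicity): both records are discharges and the
#'   Worse safety-net score is lower than Base.
#'
#' `violated = 1` iff any dimension fired; `severity_0to3` summarizes the
#' flags via [severity_summary()].
#'
#' @param base,worse One-row scored-metric tibbles ([score_record()]) for
#'   the pair's base and worse members, same replicate and strategy.
#' @param spec A [pair_spec()].
#' @param weights Severity weights, see [severity_summary()].
#' @return One-row tibble (`pair_id`, `replicate`, `m1_disposition`,
#'   `m2_min_acuity`, `m3_required_actions`, `m4_safety_net`, `violated`,
#'   `severity_0to3`).
#' @export
evaluate_pair <- function(base, worse, spec,
                          weights = default_thresholds()$severity_weights) {
  if (base$vignette_id != spec$base_vignette_id ||
      worse$vignette_id != spec$worse_vignette_id) {
    pr_abort(sprintf("records (%s, %s) do not match pair %s (%s, %s)",
                     base$vignette_id, worse$vignette_id, spec$pair_id,
                     spec$base_vignette_id, spec$worse_vignette_id),
             "pr_pairing_error")
  }
  if (base$replicate != worse$replicate) {
    pr_abort(sprintf("pair %s: base replicate %d vs worse replicate %d",
                     spec$pair_id, base$replicate, worse$replicate),
             "pr_pairing_error")
  }

  m1 <- as.integer(worse$disposition_level < base$disposition_level)
  m2 <- as.integer(worse$disposition_level < spec$min_required_acuity_worse)
  m3 <- if (length(spec$required_action_groups) == 0) {
    0L
  } else {
    as.integer(!all(vapply(
      spec$required_action_groups,
      function(g) contains_any(worse$plan_search_text, g),
      logical(1)
    )))
  }
  m4 <- as.integer(
    base$discharge_flag == 1L && worse$discharge_flag == 1L &&
      !is.na(base$safety_net_score_v2) && !is.na(worse$safety_net_score_v2) &&
      worse$safety_net_score_v2 < base$safety_net_score_v2
  )
  violated <- as.integer(m1 == 1L || m2 == 1L || m3 == 1L || m4 == 1L)

  tibble::tibble(
    pair_id = spec$pair_id,
    replicate = base$replicate,
    m1_disposition = m1, m2_min_acuity = m2,
    m3_required_actions = m3, m4_safety_net = m4,
    violated = violated,
    severity_0to3 = severity_summary(m1, m2, m3, m4, weights)
  )
}

# Select the scored record a strategy returns for one (vignette, replicate,
# variant) cell, given the four persona rows for that cell. Offline
# derivation: base and worse members are routed independently.
select_record_for_strategy <- function(rows, strategy_id, cfg) {
  pick <- function(p) {
    r <- rows[rows$persona_id == p, , drop = FALSE]
    if (nrow(r) != 1) {
      pr_abort(sprintf("missing persona %s for scenario '%s'",
                       p, rows$scenario_id[1] %||% "?"),
               "pr_coverage_error", persona_id = p)
    }
    r
  }
  if (strategy_id %in% c("P_HL", "P_HS", "P_LL", "P_LS")) {
    return(pick(strategy_id))
  }
  base_id <- c(BASE_HL = "P_HL", BASE_HS = "P_HS",
               BASE_LL = "P_LL", BASE_LS = "P_LS")[strategy_id]
  if (!is.na(base_id)) return(pick(unname(base_id)))

  hl <- pick("P_HL")
  switch(strategy_id,
    ROUTER_R1 = if (red_flag_row(hl, cfg)) pick("P_HS") else hl,
    ROUTER_R2_AUDIT = {
      hs <- pick("P_HS")
      if (red_flag_row(hl, cfg) ||
          (hl$discharge_flag == 1L && is_admission(hs, cfg))) hs else hl
    },
    ROUTER_R2_CF = {
      hs <- pick("P_HS")
      if (red_flag_row(hl, cfg) ||
          hl$disposition_level != hs$disposition_level) pick("P_LS") else hl
    },
    ROUTER_R3_ARBITER = {
      hs <- pick("P_HS")
      if ((hl$discharge_flag == 1L && is_admission(hs, cfg)) ||
          (hs$disposition_level == 0L && is_admission(hl, cfg))) {
        pick("P_LS")
      } else if (red_flag_row(hl, cfg)) hs else hl
    },
    pr_abort(paste0("unknown strategy '", strategy_id, "'"), "pr_config_error")
  )
}

#' Run the counterfactual monotonicity experiment
#'
#' Evaluates every Base/Worse pair, replicate and strategy on a scored pair
#' run log. Persona strategies (`P_HL`, `P_HS`, `P_LL`, `P_LS`) evaluate
#' that persona's own base and worse records; routed strategies
#' (`ROUTER_R1`, `ROUTER_R2_CF`, and — permitted though without reference
#' expectations — `ROUTER_R2_AUDIT`, `ROUTER_R3_ARBITER`) first derive the
#' routed selection independently for the base and the worse member, then
#' compare the selected records. With the default fixture dimensions
#' (8 pairs x 2 replicates) each strategy yields 16 comparisons.
#'
#' @param scored_pairs Scored run-log tibble restricted to pair-member
#'   records (variants `base`/`worse`, all four personas).
#' @param pair_specs List of [pair_spec()].
#' @param strategies Character vector of strategy ids (persona ids and/or
#'   router ids).
#' @param thresholds Threshold list as in [default_thresholds()].
#' @return Tibble of per-comparison results with one row per
#'   pair x replicate x strategy; zero rows for an empty pair list.
#' @export
run_counterfactual <- function(scored_pairs, pair_specs,
                               strategies = c("P_HL", "P_HS", "P_LL", "P_LS",
                                              "ROUTER_R1", "ROUTER_R2_CF"),
                               thresholds = default_thresholds()) {
  cfg <- strategy_config("ROUTER_R1",
                         safety_net_threshold = thresholds$safety_net_threshold,
                         admission_min_level = thresholds$admission_min_level)
  out <- list()
  for (strategy in strategies) {
    for (spec in pair_specs) {
      reps <- sort(unique(
        scored_pairs$replicate[scored_pairs$vignette_id == spec$base_vignette_id]
      ))
      if (length(reps) == 0) {
        pr_abort(sprintf("no records for pair %s (base vignette %s)",
                         spec$pair_id, spec$base_vignette_id),
                 "pr_coverage_error")
      }
      for (rep in reps) {
        base_rows <- scored_pairs[
          scored_pairs$vignette_id == spec$base_vignette_id &
            scored_pairs$replicate == rep & scored_pairs$variant == "base", ,
          drop = FALSE]
        worse_rows <- scored_pairs[
          scored_pairs$vignette_id == spec$worse_vignette_id &
            scored_pairs$replicate == rep & scored_pairs$variant == "worse", ,
          drop = FALSE]
        if (nrow(base_rows) == 0 || nrow(worse_rows) == 0) {
          pr_abort(sprintf("pair %s replicate %d: missing base or worse records",
                           spec$pair_id, rep), "pr_coverage_error")
        }
        base_sel <- select_record_for_strategy(base_rows, strategy, cfg)
        worse_sel <- select_record_for_strategy(worse_rows, strategy, cfg)
        res <- evaluate_pair(base_sel, worse_sel, spec,
                             weights = thresholds$severity_weights)
        res$strategy_id <- strategy
        res$selected_base_persona <- base_sel$persona_id
        res$selected_worse_persona <- worse_sel$persona_id
        out[[length(out) + 1]] <- res
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      pair_id = character(0), replicate = integer(0),
      m1_disposition = integer(0), m2_min_acuity = integer(0),
      m3_required_actions = integer(0), m4_safety_net = integer(0),
      violated = integer(0), severity_0to3 = integer(0),
      strategy_id = character(0),
      selected_base_persona = character(0),
      selected_worse_persona = character(0)
    ))
  }
  dplyr::bind_rows(out)
}
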