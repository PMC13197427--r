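# Per-record rule-based metrics: test counts, diagnostic-breadth entropy,
# ordinal disposition acuity, discharge safety-net specificity, order
# markers and contraindication/sequence trap severity.

#' Count suggested tests
#'
#' Length of the plan's `tests` list after dropping empty or whitespace-only
#' entries (robust to generator artifacts).
#'
#' @param plan A `pr_plan_record`.
#' @return Non-negative integer.
#' @export
compute_tests_count <- function(plan) {
  sum(nzchar(trimws(plan$tests)))
}

#' Shannon entropy of the top-5 differential probabilities
#'
#' Diagnostic breadth in bits: the five highest probabilities (fewer if
#' fewer differentials are listed) are renormalized to sum to one and their
#' Shannon entropy is taken in base 2. Zero-probability entries contribute
#' nothing. The result lies in \[0, log2(5)\]: 0 for a single confident
#' diagnosis, log2(5) ~ 2.32 bits for five equally-weighted differentials.
#'
#' @param differentials Data frame with a `probability` column, or a bare
#'   numeric vector of probabilities.
#' @return Entropy in bits.
#' @export
compute_entropy_top5 <- function(differentials) {
  p <- if (is.data.frame(differentials)) differentials$probability else differentials
  p <- as.numeric(p)
  if (length(p) == 0 || all(p <= 0)) {
    pr_abort("entropy undefined: no differential has positive probability",
             "pr_domain_error")
  }
  p <- sort(p, decreasing = TRUE)[seq_len(min(5, length(p)))]
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Map disposition text to the ordinal acuity scale
#'
#' Maps free disposition text onto the 0-3 acuity scale (0 = home or
#' outpatient care, 1 = emergency department observation or re-evaluation,
#' 2 = monitored admission/ward/HCU/CCU, 3 = ICU or procedural/resuscitative
#' intervention) by keyword matching. When keywords from several levels
#' match, the highest level wins (conservative max rule). Text matching no
#' level at all raises an unmapped-disposition error so the record is
#' flagged rather than silently scored.
#'
#' @param disposition_text Character scalar.
#' @param lexicon A [lexicon()].
#' @return Integer 0-3.
#' @export
map_disposition <- function(disposition_text, lexicon) {
  if (!is_scalar_chr(disposition_text) || !nzchar(disposition_text)) {
    pr_abort("disposition text must be non-empty", "pr_unmapped_disposition")
  }
  matched <- vapply(as.character(0:3), function(lv) {
    contains_any(disposition_text, lexicon$acuity_keywords[[lv]])
  }, logical(1))
  if (!any(matched)) {
    pr_abort(sprintf("disposition text matched no acuity level: '%s'",
                     disposition_text),
             "pr_unmapped_disposition")
  }
  max(which(matched)) - 1L
}

#' Score discharge safety-net specificity (0-5)
#'
#' Keyword rubric for return-precaution quality: 1 point for one trigger
#' symptom keyword or 2 points for two or more, plus 1 point each for
#' urgency wording, an explicit time window and a specific care-site
#' instruction, capped at 5. Empty text scores 0. Adding rubric keywords to
#' the text never decreases the score.
#'
#' @param safety_net_text Character scalar (may be empty).
#' @param lexicon A [lexicon()].
#' @return Integer 0-5.
#' @export
score_safety_net <- function(safety_net_text, lexicon) {
  if (length(safety_net_text) == 0 || !nzchar(safety_net_text)) return(0L)
  symptom_types <- count_matching_types(safety_net_text, lexicon$trigger_symptom_keywords)
  symptom_points <- min(2L, symptom_types)
  pts <- symptom_points +
    as.integer(contains_any(safety_net_text, lexicon$urgency_keywords)) +
    as.integer(contains_any(safety_net_text, lexicon$time_window_patterns)) +
    as.integer(contains_any(safety_net_text, lexicon$care_site_keywords))
  min(5L, as.integer(pts))
}

#' Count sequencing-marker occurrences
#'
#' Total occurrences (tokens, not distinct types) of order-marker keywords
#' ("first"/"before"/"after" equivalents) across the treatment and tests
#' text. Computed and exported for completeness; it feeds no trigger.
#'
#' @param plan A `pr_plan_record`.
#' @param lexicon A [lexicon()].
#' @return Non-negative integer.
#' @export
count_order_markers <- function(plan, lexicon) {
  count_occurrences(c(plan$treatment, plan$tests), lexicon$order_marker_keywords)
}

plan_all_text <- function(plan) {
  c(plan$problem_representation, plan$differentials$label, plan$must_not_miss,
    plan$questions_exam, plan$tests, plan$treatment, plan$disposition_text,
    plan$safety_net_text, plan$bias_check, plan$unknowns)
}

# First position at which any keyword of a group occurs in the ordered
# sequence of plan entries; position is (entry index, char offset) collapsed
# to a single comparable number. NA if the group is absent.
first_group_position <- function(entries, group) {
  entries <- normalize_text(entries)
  group <- normalize_text(group)
  for (i in seq_along(entries)) {
    offs <- vapply(group, function(k) {
      m <- regexpr(k, entries[[i]], fixed = TRUE)
      if (m[1] == -1L) Inf else as.numeric(m[1])
    }, numeric(1))
    if (any(is.finite(offs))) return(i * 1e6 + min(offs))
  }
  NA_real_
}

#' Apply a contraindication/sequence trap rule to a plan
#'
#' Deterministically returns the rule's fixed severity when any of its
#' trigger mechanisms fires, and 0 otherwise — never any other value.
#' Mechanisms (see [trap_rule()]):
#'
#' * forbidden-without-caveat: a forbidden keyword appears in the tests or
#'   treatment lists and no exclusion-caveat keyword appears anywhere in the
#'   plan text;
#' * precedence: both keyword groups appear in the ordered concatenation of
#'   tests then treatment, but the group that must come first occurs after
#'   the other (first-occurrence positions; if either group is absent the
#'   precedence clause does not fire);
#' * required-action absence: none of the required-action keywords appears
#'   in tests or treatment.
#'
#' @param plan A `pr_plan_record`.
#' @param rule A [trap_rule()].
#' @return Integer severity: 0 or `rule$severity_on_trigger`.
#' @export
apply_trap_rule <- function(plan, rule) {
  if (!inherits(rule, "pr_trap_rule")) {
    pr_abort("rule must be a pr_trap_rule", "pr_config_error")
  }
  action_text <- c(plan$tests, plan$treatment)
  triggered <- FALSE

  if (length(rule$forbidden_keywords) > 0 &&
      contains_any(action_text, rule$forbidden_keywords) &&
      !contains_any(plan_all_text(plan), rule$exclusion_caveat_keywords)) {
    triggered <- TRUE
  }

  if (!triggered && !is.null(rule$required_precedence)) {
    pos_first <- first_group_position(action_text, rule$required_precedence$first)
    pos_then <- first_group_position(action_text, rule$required_precedence$then)
    if (!is.na(pos_first) && !is.na(pos_then) && pos_then < pos_first) {
      triggered <- TRUE
    }
  }

  if (!triggered && length(rule$required_action_keywords) > 0 &&
      !contains_any(action_text, rule$required_action_keywords)) {
    triggered <- TRUE
  }

  if (triggered) rule$severity_on_trigger else 0L
}

#' Score one run-log record
#'
#' Derives the full per-record metric set from the structured plan:
#' `tests_count`, `entropy_top5_bits`, `disposition_level`,
#' `discharge_flag` (1 iff disposition level 0), `safety_net_score_v2`
#' (0-5; recorded as `NA` when the record is not a discharge),
#' `order_marker_count` and `contra_seq_severity_0to3` (the triggered trap
#' rule's severity, or 0 for vignettes without a trap rule). Scoring is pure:
#' the same record always yields identical metrics.
#'
#' @param record A `pr_runlog_record`.
#' @param lexicon A [lexicon()].
#' @param trap_rules Named list of [trap_rule()] objects.
#' @param trap_map Optional named character vector mapping `vignette_id` to
#'   rule id; by default a vignette is checked against the rule sharing its
#'   id, if one exists.
#' @return One-row tibble of scenario identity plus metrics, including a
#'   `plan_search_text` column (tests + treatment + disposition text) used
#'   by the monotonicity module's required-action check.
#' @export
score_record <- function(record, lexicon, trap_rules = list(), trap_map = NULL) {
  plan <- record$plan
  level <- map_disposition(plan$disposition_text, lexicon)
  discharge <- as.integer(level == 0L)

  rule_id <- if (!is.null(trap_map)) {
    unname(trap_map[record$vignette_id])
  } else if (record$vignette_id %in% names(trap_rules)) {
    record$vignette_id
  } else {
    NA_character_
  }
  severity <- 0L
  if (!is.na(rule_id) && nzchar(rule_id)) {
    rule <- trap_rules[[rule_id]]
    if (is.null(rule)) {
      pr_abort(sprintf("trap rule '%s' for vignette '%s' is not defined",
                       rule_id, record$vignette_id), "pr_config_error")
    }
    severity <- apply_trap_rule(plan, rule)
  }

  tibble::tibble(
    scenario_id = record$scenario_id,
    vignette_id = record$vignette_id,
    category = record$category,
    replicate = record$replicate,
    persona_id = record$persona_id,
    variant = record$variant,
    tests_count = as.integer(compute_tests_count(plan)),
    entropy_top5_bits = compute_entropy_top5(plan$differentials),
    disposition_level = as.integer(level),
    discharge_flag = discharge,
    safety_net_score_v2 = if (discharge == 1L) {
      score_safety_net(plan$safety_net_text, lexicon)
    } else {
      NA_integer_
    },
    order_marker_count = as.integer(count_order_markers(plan, lexicon)),
    contra_seq_severity_0to3 = as.integer(severity),
    plan_search_text = paste(
      c(plan$tests, plan$treatment, plan$disposition_text), collapse = " | "
    )
  )
}

#' Score a whole run log
#'
#' Applies [score_record()] to every record and binds the results into a
#' flat table (one row per record), ready for routing, monotonicity
#' evaluation and CSV export.
#'
#' @param records List of `pr_runlog_record` (e.g. from [read_runlog()]).
#' @param lexicon A [lexicon()].
#' @param trap_rules Named list of [trap_rule()] objects.
#' @param trap_map Optional vignette-to-rule mapping, see [score_record()].
#' @return Tibble with one row per record; zero-row tibble for an empty log.
#' @export
score_runlog <- function(records, lexicon, trap_rules = list(), trap_map = NULL) {
  if (length(records) == 0) {
    return(score_record(
      run_log_record("s", "v", CATEGORIES[1], 1L, "P_HL", "none",
                     plan_record(differentials = data.frame(label = "x", probability = 1),
                                 disposition_text = demo_lexicon()$acuity_keywords[["0"]][1])),
      demo_lexicon()
    )[0, ])
  }
  dplyr::bind_rows(lapply(records, score_record, lexicon = lexicon,
                          trap_rules = trap_rules, trap_map = trap_map))
}
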