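#' Construct a scoring lexicon
#'
#' A lexicon bundles every keyword set the rule-based scorer needs: the
#' ordinal acuity mapping (disposition level 0 = home/outpatient care,
#' 1 = emergency department observation or re-evaluation, 2 = monitored
#' admission/ward/HCU/CCU, 3 = ICU/procedural/resuscitative intervention),
#' the discharge safety-net rubric components (trigger symptoms, urgency
#' wording, explicit time windows, care-site instructions) and sequencing
#' markers. Lexicon content is configuration: a Japanese lexicon and the
#' English demonstration lexicon shipped with the package are
#' interchangeable because all matching is case-insensitive substring
#' matching on NFKC-normalized text.
#'
#' @param acuity_keywords Named list with elements `"0"`..`"3"`, each a
#'   non-empty character vector of disposition keywords for that level.
#' @param trigger_symptom_keywords Character vector of return-precaution
#'   symptom keywords (safety-net rubric: 1 point for one, 2 for two or
#'   more distinct matches).
#' @param urgency_keywords Character vector of urgency wording (1 point).
#' @param time_window_patterns Character vector of explicit time-window
#'   phrases (1 point).
#' @param care_site_keywords Character vector of specific care-site
#'   instructions (1 point).
#' @param order_marker_keywords Character vector of sequencing words
#'   ("first"/"before"/"after" equivalents) counted by
#'   [count_order_markers()].
#' @return An object of class `pr_lexicon`.
#' @seealso [demo_lexicon()] for the shipped demonstration lexicon.
#' @export
lexicon <- function(acuity_keywords,
                    trigger_symptom_keywords,
                    urgency_keywords,
                    time_window_patterns,
                    care_site_keywords,
                    order_marker_keywords = character(0)) {
  levels <- as.character(0:3)
  if (!is.list(acuity_keywords) || !all(levels %in% names(acuity_keywords))) {
    pr_abort("acuity_keywords must be a named list covering levels \"0\"..\"3\"",
             "pr_config_error")
  }
  for (lv in levels) {
    kw <- acuity_keywords[[lv]]
    if (!is.character(kw) || length(kw) == 0) {
      pr_abort(sprintf("acuity_keywords[[\"%s\"]] must be a non-empty character vector", lv),
               "pr_config_error")
    }
  }
  for (nm in c("trigger_symptom_keywords", "urgency_keywords",
               "time_window_patterns", "care_site_keywords")) {
    v <- get(nm)
    if (!is.character(v) || length(v) == 0) {
      pr_abort(sprintf("%s must be a non-empty character vector", nm),
               "pr_config_error")
    }
  }
  structure(
    list(
      acuity_keywords = acuity_keywords[levels],
      trigger_symptom_keywords = trigger_symptom_keywords,
      urgency_keywords = urgency_keywords,
      time_window_patterns = time_window_patterns,
      care_site_keywords = care_site_keywords,
      order_marker_keywords = as.character(order_marker_keywords)
    ),
    class = "pr_lexicon"
  )
}

#' @export
print.pr_lexicon <- function(x, ...) {
  cat("<pr_lexicon>\n")
  for (lv in names(x$acuity_keywords)) {
    cat(sprintf("  acuity %s: %s\n", lv,
                paste(x$acuity_keywords[[lv]], collapse = ", ")))
  }
  cat(sprintf("  trigger symptoms: %d | urgency: %d | time windows: %d | care sites: %d | order markers: %d\n",
              length(x$trigger_symptom_keywords), length(x$urgency_keywords),
              length(x$time_window_patterns), length(x$care_site_keywords),
              length(x$order_marker_keywords)))
  invisible(x)
}

#' Demonstration English lexicon
#'
#' The study this package operationalizes used Japanese keyword rules that
#' were never published; lexicon content is therefore configuration. This
#' English demonstration lexicon is designed so the synthetic generator and
#' the scorer agree exactly: generated plan text is composed from these
#' tokens.
#'
#' @return A `pr_lexicon`.
#' @export
demo_lexicon <- function() {
  lexicon(
    acuity_keywords = list(
      "0" = c("discharge home", "home with instructions", "outpatient follow-up"),
      "1" = c("ed observation", "re-evaluation in the emergency department",
              "observe and recheck"),
      "2" = c("admit to the ward", "monitored admission", "admit to hcu",
              "admit to ccu"),
      "3" = c("admit to icu", "immediate resuscitation", "emergency intervention",
              "take to the operating room")
    ),
    trigger_symptom_keywords = c(
      "worsening pain", "shortness of breath", "high fever",
      "repeated vomiting", "fainting", "new weakness", "confusion"
    ),
    urgency_keywords = c("immediately", "right away", "call 911",
                         "as soon as possible"),
    time_window_patterns = c("within 24 hours", "within 48 hours",
                             "within 2 days"),
    care_site_keywords = c("emergency department", "nearest hospital"),
    order_marker_keywords = c("first", "then", "before", "after")
  )
}

#' Construct a contraindication/sequence trap rule
#'
#' A trap rule encodes one vignette-specific unsafe pattern in a structured
#' plan and the ordinal severity (1 = minor, 2 = moderate, 3 = potentially
#' life-threatening) assigned when it triggers. Three trigger mechanisms are
#' supported and any may be combined; the rule fires if any mechanism fires:
#'
#' * `forbidden_keywords` without `exclusion_caveat_keywords`: a forbidden
#'   therapy appears in the tests/treatment lists and no exclusion caveat
#'   appears anywhere in the plan (e.g. antithrombotics without documented
#'   dissection exclusion).
#' * `required_precedence`: a `list(first =, then =)` pair of keyword
#'   groups; fires when both groups appear in the ordered concatenation of
#'   tests then treatment but the `then` group occurs before the `first`
#'   group (e.g. lumbar puncture before head imaging).
#' * `required_action_keywords`: fires when none of these keywords appears
#'   in tests/treatment (e.g. a plan that omits intramuscular epinephrine).
#'
#' @param rule_id Rule identifier, conventionally the vignette id it guards
#'   (e.g. `"CP07"`).
#' @param severity_on_trigger Integer 1-3.
#' @param forbidden_keywords,exclusion_caveat_keywords,required_action_keywords
#'   Character vectors (optional, see above).
#' @param required_precedence Optional `list(first = <chr>, then = <chr>)`.
#' @return An object of class `pr_trap_rule`.
#' @export
trap_rule <- function(rule_id,
                      severity_on_trigger,
                      forbidden_keywords = character(0),
                      exclusion_caveat_keywords = character(0),
                      required_precedence = NULL,
                      required_action_keywords = character(0)) {
  if (!is_scalar_chr(rule_id)) pr_abort("rule_id must be a string", "pr_config_error")
  if (!is_scalar_num(severity_on_trigger) ||
      !(severity_on_trigger %in% 1:3)) {
    pr_abort("severity_on_trigger must be 1, 2 or 3", "pr_config_error")
  }
  if (!is.null(required_precedence)) {
    ok <- is.list(required_precedence) &&
      all(c("first", "then") %in% names(required_precedence)) &&
      length(required_precedence$first) > 0 &&
      length(required_precedence$then) > 0
    if (!ok) {
      pr_abort("required_precedence must be list(first = <keywords>, then = <keywords>)",
               "pr_config_error")
    }
  }
  has_mechanism <- length(forbidden_keywords) > 0 ||
    !is.null(required_precedence) || length(required_action_keywords) > 0
  if (!has_mechanism) {
    pr_abort("trap rule needs at least one trigger mechanism", "pr_config_error")
  }
  structure(
    list(
      rule_id = rule_id,
      severity_on_trigger = as.integer(severity_on_trigger),
      forbidden_keywords = as.character(forbidden_keywords),
      exclusion_caveat_keywords = as.character(exclusion_caveat_keywords),
      required_precedence = required_precedence,
      required_action_keywords = as.character(required_action_keywords)
    ),
    class = "pr_trap_rule"
  )
}

#' @export
print.pr_trap_rule <- function(x, ...) {
  mech <- c(
    if (length(x$forbidden_keywords)) "forbidden-without-caveat",
    if (!is.null(x$required_precedence)) "precedence",
    if (length(x$required_action_keywords)) "required-action-absence"
  )
  cat(sprintf("<pr_trap_rule %s> severity %d, mechanisms: %s\n",
              x$rule_id, x$severity_on_trigger, paste(mech, collapse = ", ")))
  invisible(x)
}

#' Demonstration trap-rule table
#'
#' Four vignette-specific rules covering the classic emergency traps, one
#' per chief-complaint category:
#'
#' * `CP07` (chest pain, possible aortic dissection vs ACS): antithrombotic
#'   therapy without explicit dissection exclusion; severity 2.
#' * `AP07` (abdominal pain, hypotension, known AAA): anticoagulation or
#'   thrombolysis while rupture remains possible; severity 3.
#' * `HA07` (fever + headache + altered mental status): lumbar puncture
#'   ordered before head imaging; severity 3.
#' * `DY07` (dyspnea + hypotension after food exposure, anaphylaxis):
#'   intramuscular epinephrine omitted; severity 3.
#'
#' @return Named list of [trap_rule()] objects keyed by rule id.
#' @export
demo_trap_rules <- function() {
  rules <- list(
    trap_rule(
      "CP07", 2L,
      forbidden_keywords = c("aspirin", "heparin", "anticoagulation",
                             "clopidogrel", "antiplatelet"),
      exclusion_caveat_keywords = c("dissection excluded", "ct angiography",
                                    "rule out dissection",
                                    "transesophageal echocardiography")
    ),
    trap_rule(
      "AP07", 3L,
      forbidden_keywords = c("heparin", "anticoagulation", "thrombolysis"),
      exclusion_caveat_keywords = c("rupture excluded", "vascular surgery consult",
                                    "definitive imaging")
    ),
    trap_rule(
      "HA07", 3L,
      required_precedence = list(
        first = c("head ct", "head imaging", "brain ct"),
        then = c("lumbar puncture")
      )
    ),
    trap_rule(
      "DY07", 3L,
      required_action_keywords = c("intramuscular epinephrine", "im epinephrine",
                                   "epinephrine")
    )
  )
  names(rules) <- vapply(rules, `[[`, character(1), "rule_id")
  rules
}
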