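# Fixed clinical-plan JSON schema, JSONL run logs and the fixture manifest.

PLAN_FIELDS <- c(
  "problem_representation", "differentials", "must_not_miss",
  "questions_exam", "tests", "treatment", "disposition_text",
  "safety_net_text", "bias_check", "confidence", "unknowns"
)

PERSONA_IDS <- c("P_HL", "P_HS", "P_LL", "P_LS")
CATEGORIES <- c("chest pain", "abdominal pain", "headache", "dyspnea")
VARIANTS <- c("base", "worse", "none")

#' Construct a clinical-plan record
#'
#' One structured persona output: a problem representation, the top
#' differentials with probabilities, a must-not-miss list, questions and
#' examination, a plan (tests, treatment, disposition, safety net), a bias
#' check, a confidence estimate and unknowns. The constructor enforces the
#' schema invariants (all keys present, at least one differential, every
#' probability and the confidence in \[0, 1\]); `tests` and `treatment` may
#' be empty but never absent.
#'
#' @param problem_representation,disposition_text,safety_net_text,bias_check
#'   Character scalars (may be empty strings except the disposition, which
#'   the scorer requires non-empty).
#' @param differentials Data frame (or tibble) with columns `label`
#'   (character) and `probability` (numeric in \[0, 1\]), ordered from most
#'   to least likely.
#' @param must_not_miss,questions_exam,tests,treatment,unknowns Character
#'   vectors (possibly empty).
#' @param confidence Numeric scalar in \[0, 1\].
#' @return An object of class `pr_plan_record`.
#' @export
plan_record <- function(problem_representation = "",
                        differentials,
                        must_not_miss = character(0),
                        questions_exam = character(0),
                        tests = character(0),
                        treatment = character(0),
                        disposition_text = "",
                        safety_net_text = "",
                        bias_check = "",
                        confidence = 0.5,
                        unknowns = character(0)) {
  validate_plan_record(list(
    problem_representation = problem_representation,
    differentials = differentials,
    must_not_miss = must_not_miss,
    questions_exam = questions_exam,
    tests = tests,
    treatment = treatment,
    disposition_text = disposition_text,
    safety_net_text = safety_net_text,
    bias_check = bias_check,
    confidence = confidence,
    unknowns = unknowns
  ))
}

schema_violation <- function(field, why) {
  pr_abort(sprintf("schema violation in field '%s': %s", field, why),
           "pr_schema_error", field = field)
}

#' Validate a clinical-plan record
#'
#' Validation is total: the input either comes back as a fully-populated
#' `pr_plan_record` or a typed schema-violation error naming the offending
#' field is thrown. No partially-populated record escapes.
#'
#' @param x Named list with the schema fields (see [plan_record()]).
#' @return A `pr_plan_record`.
#' @export
validate_plan_record <- function(x) {
  if (!is.list(x)) pr_abort("plan record must be a list", "pr_schema_error")
  for (f in PLAN_FIELDS) {
    if (!f %in% names(x) || is.null(x[[f]])) {
      schema_violation(f, "required key missing")
    }
  }

  d <- x$differentials
  if (is.list(d) && !is.data.frame(d)) {
    # un-simplified JSON: list of {label, probability} objects
    d <- tryCatch(
      do.call(rbind, lapply(d, function(e) {
        data.frame(label = as.character(e$label),
                   probability = as.numeric(e$probability))
      })),
      error = function(e) NULL
    )
  }
  if (!is.data.frame(d) || !all(c("label", "probability") %in% names(d))) {
    schema_violation("differentials", "must be records with label and probability")
  }
  if (nrow(d) == 0) schema_violation("differentials", "must be non-empty")
  p <- as.numeric(d$probability)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    schema_violation("differentials", "every probability must lie in [0, 1]")
  }
  d <- tibble::tibble(label = as.character(d$label), probability = p)

  for (f in c("problem_representation", "disposition_text",
              "safety_net_text", "bias_check")) {
    if (!is_scalar_chr(as.character(x[[f]])[1]) || length(x[[f]]) != 1) {
      schema_violation(f, "must be a single text value")
    }
  }
  conf <- x$confidence
  if (!is_scalar_num(conf) || conf < 0 || conf > 1) {
    schema_violation("confidence", "must be a number in [0, 1]")
  }

  as_chr_vec <- function(f) {
    v <- x[[f]]
    if (is.list(v) && length(v) == 0) v <- character(0)
    if (is.list(v)) v <- unlist(v, use.names = FALSE)
    if (length(v) > 0 && !is.character(v)) {
      schema_violation(f, "must be a list of text values")
    }
    as.character(v)
  }

  structure(
    list(
      problem_representation = as.character(x$problem_representation),
      differentials = d,
      must_not_miss = as_chr_vec("must_not_miss"),
      questions_exam = as_chr_vec("questions_exam"),
      tests = as_chr_vec("tests"),
      treatment = as_chr_vec("treatment"),
      disposition_text = as.character(x$disposition_text),
      safety_net_text = as.character(x$safety_net_text),
      bias_check = as.character(x$bias_check),
      confidence = as.numeric(conf),
      unknowns = as_chr_vec("unknowns")
    ),
    class = "pr_plan_record"
  )
}

#' @export
print.pr_plan_record <- function(x, ...) {
  cat(sprintf("<pr_plan_record> %d differentials, %d tests, %d treatment steps\n",
              nrow(x$differentials), length(x$tests), length(x$treatment)))
  cat(sprintf("  disposition: %s\n", x$disposition_text))
  invisible(x)
}

#' Parse one clinical-plan JSON object
#'
#' Parses and validates a single JSON object against the fixed plan schema.
#' Run logs produced by an external system whose keys differ from this
#' schema can be mapped with `field_map`.
#'
#' @param json_text A single JSON object as text.
#' @param field_map Optional named character vector mapping external key
#'   names to schema key names (`c(external_key = "schema_key")`).
#' @return A `pr_plan_record`.
#' @export
parse_plan_record <- function(json_text, field_map = NULL) {
  x <- tryCatch(
    jsonlite::fromJSON(json_text, simplifyVector = TRUE),
    error = function(e) {
      pr_abort(paste0("malformed JSON: ", conditionMessage(e)), "pr_parse_error")
    }
  )
  if (!is.list(x)) pr_abort("JSON text must encode an object", "pr_parse_error")
  if (!is.null(field_map)) {
    idx <- match(names(x), names(field_map))
    names(x)[!is.na(idx)] <- unname(field_map[idx[!is.na(idx)]])
  }
  validate_plan_record(x)
}

plan_as_list <- function(plan) {
  list(
    problem_representation = plan$problem_representation,
    differentials = as.data.frame(plan$differentials),
    must_not_miss = as.character(plan$must_not_miss),
    questions_exam = as.character(plan$questions_exam),
    tests = as.character(plan$tests),
    treatment = as.character(plan$treatment),
    disposition_text = plan$disposition_text,
    safety_net_text = plan$safety_net_text,
    bias_check = plan$bias_check,
    confidence = plan$confidence,
    unknowns = as.character(plan$unknowns)
  )
}

#' Construct a run-log record
#'
#' One row of a persona run log: scenario identity plus the structured plan
#' the persona produced. `variant` is `"none"` for the primary vignette
#' dataset; `"base"`/`"worse"` mark counterfactual pair members.
#'
#' @param scenario_id Scenario identifier; the routing layer groups persona
#'   records sharing a `scenario_id`.
#' @param vignette_id Vignette identifier.
#' @param category One of `"chest pain"`, `"abdominal pain"`, `"headache"`,
#'   `"dyspnea"`.
#' @param replicate Integer replicate index (>= 1).
#' @param persona_id One of `"P_HL"`, `"P_HS"`, `"P_LL"`, `"P_LS"`.
#' @param variant One of `"base"`, `"worse"`, `"none"`.
#' @param plan A `pr_plan_record`.
#' @return An object of class `pr_runlog_record`.
#' @export
run_log_record <- function(scenario_id, vignette_id, category, replicate,
                           persona_id, variant = "none", plan) {
  if (!is_scalar_chr(scenario_id)) schema_violation("scenario_id", "must be a string")
  if (!is_scalar_chr(vignette_id)) schema_violation("vignette_id", "must be a string")
  if (!is_scalar_chr(category) || !category %in% CATEGORIES) {
    schema_violation("category", paste("must be one of", paste(CATEGORIES, collapse = ", ")))
  }
  if (!is_scalar_num(replicate) || replicate < 1 || replicate != round(replicate)) {
    schema_violation("replicate", "must be an integer >= 1")
  }
  if (!is_scalar_chr(persona_id) || !persona_id %in% PERSONA_IDS) {
    schema_violation("persona_id", paste("must be one of", paste(PERSONA_IDS, collapse = ", ")))
  }
  if (!is_scalar_chr(variant) || !variant %in% VARIANTS) {
    schema_violation("variant", "must be base, worse or none")
  }
  if (!inherits(plan, "pr_plan_record")) plan <- validate_plan_record(plan)
  structure(
    list(scenario_id = scenario_id, vignette_id = vignette_id,
         category = category, replicate = as.integer(replicate),
         persona_id = persona_id, variant = variant, plan = plan),
    class = "pr_runlog_record"
  )
}

runlog_key <- function(r) {
  paste(r$vignette_id, r$replicate, r$persona_id, r$variant, sep = "|")
}

#' Read a JSONL run log
#'
#' Reads one run-log record per line, in file order. Every line must parse
#' and validate; duplicate `(vignette_id, replicate, persona_id, variant)`
#' keys are rejected with the offending line numbers. An empty file is valid
#' and yields an empty list, so partial pipelines compose.
#'
#' @param path Path to a JSONL file (UTF-8).
#' @param field_map Optional plan-field mapping, see [parse_plan_record()].
#' @return List of `pr_runlog_record`.
#' @export
read_runlog <- function(path, field_map = NULL) {
  if (!file.exists(path)) {
    pr_abort(sprintf("run log not found: %s", path), "pr_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  records <- vector("list", length(lines))
  seen <- character(0)
  for (i in seq_along(lines)) {
    x <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
      error = function(e) {
        pr_abort(sprintf("line %d: malformed JSON: %s", i, conditionMessage(e)),
                 "pr_parse_error", line = i)
      }
    )
    rec <- tryCatch(
      run_log_record(
        scenario_id = x$scenario_id, vignette_id = x$vignette_id,
        category = x$category, replicate = x$replicate,
        persona_id = x$persona_id, variant = x$variant %||% "none",
        plan = {
          if (!is.null(field_map)) {
            idx <- match(names(x$plan), names(field_map))
            names(x$plan)[!is.na(idx)] <- unname(field_map[idx[!is.na(idx)]])
          }
          x$plan
        }
      ),
      pr_error = function(e) {
        pr_abort(sprintf("line %d: %s", i, conditionMessage(e)),
                 class(e)[1], line = i)
      }
    )
    key <- runlog_key(rec)
    dup <- match(key, seen)
    if (!is.na(dup)) {
      pr_abort(sprintf("duplicate record key '%s' on lines %d and %d", key, dup, i),
               "pr_duplicate_key_error", lines = c(dup, i))
    }
    seen <- c(seen, key)
    records[[i]] <- rec
  }
  records
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a JSONL run log
#'
#' One JSON object per line, UTF-8, so that [read_runlog()] reproduces the
#' records field-for-field (non-ASCII text round-trips byte-exact).
#'
#' @param records List of `pr_runlog_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_runlog <- function(records, path) {
  lines <- vapply(records, function(r) {
    if (!inherits(r, "pr_runlog_record")) {
      pr_abort("write_runlog expects pr_runlog_record objects", "pr_schema_error")
    }
    obj <- list(
      scenario_id = r$scenario_id, vignette_id = r$vignette_id,
      category = r$category, replicate = r$replicate,
      persona_id = r$persona_id, variant = r$variant,
      plan = plan_as_list(r$plan)
    )
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                  dataframe = "rows", null = "null"))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines) > 0) {
    writeLines(enc2utf8(lines), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Construct a counterfactual pair specification
#'
#' Links a Base vignette to its clinically worsened Worse counterpart and
#' carries the pair-specific monotonicity expectations: the minimum
#' disposition level the Worse presentation warrants (dimension M2) and the
#' required escalation-action keyword groups (dimension M3; a group is
#' satisfied if any of its synonyms appears, and all groups are required).
#'
#' @param pair_id Pair identifier.
#' @param base_vignette_id,worse_vignette_id Member vignette ids.
#' @param min_required_acuity_worse Integer 0-3.
#' @param required_action_groups List of character vectors (synonym groups).
#' @return An object of class `pr_pair_spec`.
#' @export
pair_spec <- function(pair_id, base_vignette_id, worse_vignette_id,
                      min_required_acuity_worse,
                      required_action_groups = list()) {
  if (!is_scalar_num(min_required_acuity_worse) ||
      !(min_required_acuity_worse %in% 0:3)) {
    pr_abort("min_required_acuity_worse must be an integer in 0..3", "pr_config_error")
  }
  if (!is.list(required_action_groups) ||
      (length(required_action_groups) > 0 &&
       !all(vapply(required_action_groups,
                   function(g) is.character(g) && length(g) > 0, logical(1))))) {
    pr_abort("required_action_groups must be a list of non-empty keyword vectors",
             "pr_config_error")
  }
  structure(
    list(pair_id = pair_id,
         base_vignette_id = base_vignette_id,
         worse_vignette_id = worse_vignette_id,
         min_required_acuity_worse = as.integer(min_required_acuity_worse),
         required_action_groups = required_action_groups),
    class = "pr_pair_spec"
  )
}

#' Assemble a fixture manifest
#'
#' The manifest is the single configuration object the pipeline consumes:
#' vignette specifications, counterfactual pair specifications, the scoring
#' lexicon, the trap-rule table and the routing thresholds. It serializes to
#' YAML via [write_manifest()].
#'
#' @param vignettes Tibble with columns `vignette_id`, `category`,
#'   `trap_rule_id` (NA when the vignette carries no trap), `is_pair_member`
#'   and `base_acuity` (generator-facing intended acuity 0-3).
#' @param pairs List of [pair_spec()] objects.
#' @param lexicon A [lexicon()].
#' @param trap_rules Named list of [trap_rule()] objects.
#' @param thresholds List with `safety_net_threshold` (red-flag cutoff on the
#'   0-5 safety-net scale, default 3), `admission_min_level` (lowest
#'   disposition level counted as "admission" in disagreement clauses,
#'   default 2) and `severity_weights` (monotonicity weights, default
#'   m2 = 3, m1 = 2, m3 = 2, m4 = 1).
#' @param field_mapping Optional named character vector mapping external
#'   plan keys to schema keys.
#' @return An object of class `pr_manifest`.
#' @export
manifest <- function(vignettes, pairs = list(), lexicon = demo_lexicon(),
                     trap_rules = demo_trap_rules(),
                     thresholds = default_thresholds(),
                     field_mapping = NULL) {
  vignettes <- tibble::as_tibble(vignettes)
  needed <- c("vignette_id", "category", "trap_rule_id", "is_pair_member", "base_acuity")
  if (!all(needed %in% names(vignettes))) {
    pr_abort(paste("vignettes must have columns:", paste(needed, collapse = ", ")),
             "pr_config_error")
  }
  unresolved <- setdiff(stats::na.omit(vignettes$trap_rule_id), names(trap_rules))
  if (length(unresolved) > 0) {
    pr_abort(paste("trap_rule_id does not resolve:", paste(unresolved, collapse = ", ")),
             "pr_config_error")
  }
  th <- utils::modifyList(default_thresholds(), thresholds)
  structure(
    list(vignettes = vignettes, pairs = pairs, lexicon = lexicon,
         trap_rules = trap_rules, thresholds = th,
         field_mapping = field_mapping),
    class = "pr_manifest"
  )
}

#' Default routing and scoring thresholds
#' @return Named list; see [manifest()].
#' @export
default_thresholds <- function() {
  list(
    safety_net_threshold = 3L,
    admission_min_level = 2L,
    severity_weights = list(m1 = 2L, m2 = 3L, m3 = 2L, m4 = 1L)
  )
}

#' @export
print.pr_manifest <- function(x, ...) {
  cat(sprintf("<pr_manifest> %d vignettes (%d with traps), %d pairs, %d trap rules, threshold %d\n",
              nrow(x$vignettes), sum(!is.na(x$vignettes$trap_rule_id)),
              length(x$pairs), length(x$trap_rules),
              x$thresholds$safety_net_threshold))
  invisible(x)
}

#' Write a fixture manifest to YAML
#' @param m A `pr_manifest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(m, path) {
  out <- list(
    lexicon = unclass(m$lexicon),
    trap_rules = lapply(unname(m$trap_rules), unclass),
    vignettes = lapply(seq_len(nrow(m$vignettes)), function(i) {
      row <- as.list(m$vignettes[i, ])
      if (is.na(row$trap_rule_id)) row$trap_rule_id <- NULL
      row
    }),
    pairs = lapply(m$pairs, unclass),
    thresholds = m$thresholds,
    field_mapping = if (!is.null(m$field_mapping)) as.list(m$field_mapping)
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a fixture manifest from YAML
#' @param path Path to a manifest written by [write_manifest()] (or authored
#'   by hand with the same keys).
#' @return A `pr_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    pr_abort(sprintf("manifest not found: %s", path), "pr_io_error")
  }
  y <- yaml::read_yaml(path)
  lex <- do.call(lexicon, lapply(y$lexicon, function(v) {
    if (is.list(v)) lapply(v, as.character) else as.character(v)
  }))
  rules <- lapply(y$trap_rules, function(r) {
    trap_rule(
      rule_id = r$rule_id,
      severity_on_trigger = r$severity_on_trigger,
      forbidden_keywords = as.character(r$forbidden_keywords %||% character(0)),
      exclusion_caveat_keywords = as.character(r$exclusion_caveat_keywords %||% character(0)),
      required_precedence = if (!is.null(r$required_precedence)) {
        list(first = as.character(r$required_precedence$first),
             then = as.character(r$required_precedence$then))
      },
      required_action_keywords = as.character(r$required_action_keywords %||% character(0))
    )
  })
  names(rules) <- vapply(rules, `[[`, character(1), "rule_id")
  vignettes <- dplyr::bind_rows(lapply(y$vignettes, function(v) {
    tibble::tibble(
      vignette_id = v$vignette_id, category = v$category,
      trap_rule_id = v$trap_rule_id %||% NA_character_,
      is_pair_member = isTRUE(v$is_pair_member),
      base_acuity = as.integer(v$base_acuity %||% 1L)
    )
  }))
  pairs <- lapply(y$pairs, function(p) {
    pair_spec(
      pair_id = p$pair_id,
      base_vignette_id = p$base_vignette_id,
      worse_vignette_id = p$worse_vignette_id,
      min_required_acuity_worse = p$min_required_acuity_worse,
      required_action_groups = lapply(p$required_action_groups, as.character)
    )
  })
  fm <- if (!is.null(y$field_mapping)) unlist(y$field_mapping)
  manifest(vignettes = vignettes, pairs = pairs, lexicon = lex,
           trap_rules = rules, thresholds = y$thresholds %||% list(),
           field_mapping = fm)
}
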