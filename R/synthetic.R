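# Seeded synthetic persona-output generator. It replaces the language model
# so the whole pipeline runs offline: generated plan text is composed from
# lexicon keywords (concatenated tokens plus filler), which guarantees the
# keyword scorer reads back exactly the intended metrics. The generator
# tests the pipeline; it does not imitate clinical prose.

#' Synthetic behavioral profile for one persona
#'
#' Captures the behavioral contrast the evaluation assumes between LEAN
#' (parsimonious) and SAFE (conservative) personas, crossed with high/low
#' time pressure:
#'
#' @param persona_id One of `P_HL`, `P_HS`, `P_LL`, `P_LS`.
#' @param tests_count_mean Mean of the per-plan suggested-test count
#'   (Poisson; LEAN around 2, SAFE around 3.4-4.3).
#' @param p_trap_violation Probability of emitting the vignette's forbidden
#'   pattern on trap vignettes (SAFE profiles: 0).
#' @param p_under_triage_on_worse Probability of emitting a plan below the
#'   pair minimum acuity on Worse vignettes (SAFE profiles: 0).
#' @param safety_net_completeness Per-component emission probability for the
#'   five safety-net rubric points when discharging.
#' @param discharge_propensity Probability of a level-0 disposition on
#'   low-acuity vignettes.
#' @return An object of class `pr_persona_profile`.
#' @export
persona_profile <- function(persona_id, tests_count_mean, p_trap_violation,
                            p_under_triage_on_worse, safety_net_completeness,
                            discharge_propensity) {
  if (!persona_id %in% PERSONA_IDS) {
    pr_abort(paste0("unknown persona '", persona_id, "'"), "pr_config_error")
  }
  probs <- c(p_trap_violation, p_under_triage_on_worse,
             safety_net_completeness, discharge_propensity)
  if (any(probs < 0 | probs > 1)) {
    pr_abort("profile probabilities must lie in [0, 1]", "pr_config_error")
  }
  if (tests_count_mean < 0) {
    pr_abort("tests_count_mean must be non-negative", "pr_config_error")
  }
  structure(
    list(persona_id = persona_id,
         tests_count_mean = tests_count_mean,
         p_trap_violation = p_trap_violation,
         p_under_triage_on_worse = p_under_triage_on_worse,
         safety_net_completeness = safety_net_completeness,
         discharge_propensity = discharge_propensity),
    class = "pr_persona_profile"
  )
}

#' Default "paper-like" persona profiles
#'
#' Illustrative behavioral parameters reproducing the qualitative contrast
#' between personas, not fitted estimates: LEAN personas suggest around two
#' tests, always fall into vignette traps, under-triage most Worse vignettes
#' and write weak safety nets; SAFE personas suggest more tests, never
#' violate traps or under-triage, and write near-complete safety nets.
#'
#' @return Named list of [persona_profile()] objects.
#' @export
default_profiles <- function() {
  list(
    P_HL = persona_profile("P_HL", tests_count_mean = 2.0,
                           p_trap_violation = 1.0,
                           p_under_triage_on_worse = 0.625,
                           safety_net_completeness = 0.52,
                           discharge_propensity = 0.625),
    P_HS = persona_profile("P_HS", tests_count_mean = 3.4,
                           p_trap_violation = 0,
                           p_under_triage_on_worse = 0,
                           safety_net_completeness = 0.9,
                           discharge_propensity = 0.5),
    P_LL = persona_profile("P_LL", tests_count_mean = 3.0,
                           p_trap_violation = 1.0,
                           p_under_triage_on_worse = 0.625,
                           safety_net_completeness = 0.52,
                           discharge_propensity = 0.625),
    P_LS = persona_profile("P_LS", tests_count_mean = 4.3,
                           p_trap_violation = 0,
                           p_under_triage_on_worse = 0,
                           safety_net_completeness = 0.9,
                           discharge_propensity = 0.5)
  )
}

#' Generator configuration
#'
#' Defaults reproduce the study fixture dimensions: 28 vignettes spread
#' evenly across four chief-complaint categories, two replicates (56
#' scenario runs per persona), four trap vignettes (one per category) and
#' eight Base/Worse counterfactual pairs (16 comparisons per strategy).
#'
#' @param seed Master seed; every record draws from an independent
#'   substream derived from it, so adding personas or replicates never
#'   perturbs other records.
#' @param n_vignettes Number of primary vignettes (default 28).
#' @param n_replicates Replicates per vignette (default 2).
#' @param categories Chief-complaint categories (fixed set of four).
#' @param trap_vignette_ids Vignette ids carrying trap rules; must be among
#'   the generated vignette ids.
#' @param n_pairs Number of Base/Worse pairs (default 8).
#' @param profiles Named list of [persona_profile()] objects.
#' @return An object of class `pr_generator_config`.
#' @export
generator_config <- function(seed = 1L, n_vignettes = 28L, n_replicates = 2L,
                             categories = CATEGORIES,
                             trap_vignette_ids = c("CP07", "AP07", "HA07", "DY07"),
                             n_pairs = 8L,
                             profiles = default_profiles()) {
  structure(
    list(seed = as.integer(seed), n_vignettes = as.integer(n_vignettes),
         n_replicates = as.integer(n_replicates), categories = categories,
         trap_vignette_ids = trap_vignette_ids, n_pairs = as.integer(n_pairs),
         profiles = profiles),
    class = "pr_generator_config"
  )
}

category_prefix <- c("chest pain" = "CP", "abdominal pain" = "AP",
                     "headache" = "HA", "dyspnea" = "DY")

differential_pool <- list(
  "chest pain" = c("acute coronary syndrome", "aortic dissection",
                   "pulmonary embolism", "pericarditis",
                   "musculoskeletal pain", "gastroesophageal reflux"),
  "abdominal pain" = c("appendicitis", "ruptured aortic aneurysm",
                       "cholecystitis", "bowel obstruction",
                       "gastroenteritis", "pancreatitis"),
  "headache" = c("subarachnoid hemorrhage", "bacterial meningitis",
                 "migraine", "tension headache", "temporal arteritis",
                 "cerebral venous thrombosis"),
  "dyspnea" = c("anaphylaxis", "pulmonary embolism", "heart failure",
                "pneumonia", "asthma exacerbation", "copd exacerbation")
)

# Generic pools contain no trap-rule caveat, forbidden or required-action
# keyword and no pair required-action synonym, so trap and under-triage
# intents are controlled solely by the intent-specific insertions below.
generic_tests_pool <- c("ecg", "troponin", "chest x-ray",
                        "complete blood count", "basic metabolic panel",
                        "lactate", "blood cultures", "urinalysis", "d-dimer",
                        "abdominal ultrasound", "venous blood gas",
                        "coagulation panel")
generic_treatment_pool <- c("analgesia", "antiemetics", "observation protocol",
                            "symptomatic care")
required_action_groups_default <- list(
  c("iv fluids", "fluid resuscitation"),
  c("supplemental oxygen", "oxygen therapy")
)

#' Generate the fixture manifest
#'
#' Builds the vignette specifications (ids per category with an intended
#' base acuity), the counterfactual pair specifications (minimum required
#' acuity for the Worse member and required escalation-action keyword
#' groups), the demonstration lexicon and the trap-rule table, bundled as a
#' [manifest()]. Deterministic given the configuration.
#'
#' @param cfg A [generator_config()].
#' @return A `pr_manifest`.
#' @export
generate_fixtures <- function(cfg = generator_config()) {
  n_cat <- length(cfg$categories)
  cat_idx <- rep(seq_len(n_cat), length.out = cfg$n_vignettes)
  within <- as.integer(stats::ave(cat_idx, cat_idx, FUN = seq_along))
  ids <- sprintf("%s%02d", category_prefix[cfg$categories[cat_idx]], within)

  missing_traps <- setdiff(cfg$trap_vignette_ids, ids)
  if (length(missing_traps) > 0) {
    pr_abort(paste("trap vignette ids not among generated vignettes:",
                   paste(missing_traps, collapse = ", ")), "pr_config_error")
  }

  vignettes <- tibble::tibble(
    vignette_id = ids,
    category = cfg$categories[cat_idx],
    trap_rule_id = ifelse(ids %in% cfg$trap_vignette_ids, ids, NA_character_),
    is_pair_member = FALSE,
    # intended acuity: first two vignettes per category are low-acuity
    # (discharge-eligible), then observation, then admission; trap
    # vignettes are high-stakes admissions
    base_acuity = pmin((within - 1L) %/% 2L, 2L)
  )
  vignettes$base_acuity[!is.na(vignettes$trap_rule_id)] <- 2L

  pairs <- list()
  pair_rows <- list()
  if (cfg$n_pairs > 0) {
    for (i in seq_len(cfg$n_pairs)) {
      cat_i <- cfg$categories[((i - 1) %% n_cat) + 1]
      # every fourth pair is a shock-type deterioration requiring ICU level
      min_acuity <- if (i %% 4L == 0L) 3L else 2L
      p <- pair_spec(
        pair_id = sprintf("PR%02d", i),
        base_vignette_id = sprintf("PR%02dB", i),
        worse_vignette_id = sprintf("PR%02dW", i),
        min_required_acuity_worse = min_acuity,
        required_action_groups = required_action_groups_default
      )
      pairs[[i]] <- p
      pair_rows[[i]] <- tibble::tibble(
        vignette_id = c(p$base_vignette_id, p$worse_vignette_id),
        category = cat_i,
        trap_rule_id = NA_character_,
        is_pair_member = TRUE,
        base_acuity = c(1L, min_acuity)
      )
    }
  }
  manifest(
    vignettes = dplyr::bind_rows(list(vignettes), pair_rows),
    pairs = pairs,
    lexicon = demo_lexicon(),
    trap_rules = demo_trap_rules(),
    thresholds = default_thresholds()
  )
}

compose_safety_net <- function(completeness, lex) {
  parts <- "return precautions:"
  symptoms <- lex$trigger_symptom_keywords[1:2]
  if (stats::runif(1) < completeness) parts <- c(parts, symptoms[1])
  if (stats::runif(1) < completeness) parts <- c(parts, symptoms[2])
  if (stats::runif(1) < completeness) {
    parts <- c(parts, paste("seek care", lex$urgency_keywords[1]))
  }
  if (stats::runif(1) < completeness) {
    parts <- c(parts, paste("reassess", lex$time_window_patterns[1]))
  }
  if (stats::runif(1) < completeness) {
    parts <- c(parts, paste("go to the", lex$care_site_keywords[1]))
  }
  paste(parts, collapse = "; ")
}

disposition_phrase <- function(level, lex) {
  paste("disposition:", lex$acuity_keywords[[as.character(level)]][1])
}

#' Generate one synthetic persona output
#'
#' Emits a schema-valid plan whose text is composed from lexicon keywords so
#' that the scoring module recovers exactly the profile's intent: a trap
#' violation is emitted as the forbidden pattern without the caveat, a safe
#' trap response carries the caveat or required action, and an under-triaged
#' Worse plan sits below the pair minimum and omits the required
#' escalation-action groups. Deterministic given `seed`.
#'
#' @param vignette One-row tibble from the manifest's `vignettes` table.
#' @param profile A [persona_profile()].
#' @param variant `"none"`, `"base"` or `"worse"`.
#' @param pair The [pair_spec()] when `variant` is `"base"`/`"worse"`.
#' @param lexicon The scoring [lexicon()] (text is composed from it).
#' @param seed Substream seed for this record.
#' @return List with `plan` (a `pr_plan_record`) and `intent` (logical
#'   `trap_violation`, `under_triage` — the bits the scorer must recover).
#' @export
generate_persona_output <- function(vignette, profile, variant = "none",
                                    pair = NULL, lexicon = demo_lexicon(),
                                    seed = 1L) {
  with_substream(seed, {
    category <- vignette$category
    diffs_pool <- differential_pool[[category]]
    k <- sample(3:5, 1)
    labels <- sample(diffs_pool, k)
    w <- sort(stats::runif(k), decreasing = TRUE)
    differentials <- tibble::tibble(label = labels, probability = w / sum(w))

    trap_violation <- FALSE
    under_triage <- FALSE
    trap_id <- vignette$trap_rule_id

    # disposition level
    if (variant == "none") {
      if (vignette$base_acuity == 0L) {
        level <- if (stats::runif(1) < profile$discharge_propensity) 0L else 1L
      } else {
        level <- vignette$base_acuity
      }
    } else if (variant == "base") {
      level <- vignette$base_acuity
    } else { # worse
      if (is.null(pair)) {
        pr_abort("worse/base variants require a pair spec", "pr_config_error")
      }
      under_triage <- stats::runif(1) < profile$p_under_triage_on_worse
      level <- if (under_triage) {
        sample(0:(pair$min_required_acuity_worse - 1L), 1)
      } else {
        pair$min_required_acuity_worse
      }
    }

    # tests and treatment: generic filler plus intent-specific insertions
    n_tests <- stats::rpois(1, profile$tests_count_mean)
    tests <- sample(generic_tests_pool, min(n_tests, length(generic_tests_pool)))
    treatment <- sample(generic_treatment_pool,
                        min(stats::rpois(1, 1.5), length(generic_treatment_pool)))

    if (!is.na(trap_id) && variant == "none") {
      trap_violation <- stats::runif(1) < profile$p_trap_violation
      if (trap_id == "CP07") {
        if (trap_violation) {
          treatment <- c("aspirin loading dose", treatment)
        } else {
          tests <- c("ct angiography of the chest", tests)
          treatment <- c("aspirin after dissection excluded", treatment)
        }
      } else if (trap_id == "AP07") {
        if (trap_violation) {
          treatment <- c("heparin infusion", treatment)
        } else {
          treatment <- c("fluid resuscitation", "vascular surgery consult",
                         treatment)
        }
      } else if (trap_id == "HA07") {
        tests <- if (trap_violation) {
          c("lumbar puncture", "head ct", tests)
        } else {
          c("head ct", "lumbar puncture", tests)
        }
        treatment <- c("empiric antibiotics", treatment)
      } else if (trap_id == "DY07") {
        treatment <- if (trap_violation) {
          c("nebulized bronchodilator", "antihistamine", "steroids")
        } else {
          c("intramuscular epinephrine", treatment)
        }
      }
    }

    if (variant == "worse" && !under_triage) {
      # full escalation bundle: first synonym of every required group
      treatment <- c(vapply(pair$required_action_groups, `[`, character(1), 1),
                     treatment)
    }

    safety_net_text <- if (level == 0L) {
      compose_safety_net(profile$safety_net_completeness, lexicon)
    } else {
      "follow-up as arranged"
    }

    plan_record(
      problem_representation = paste(category, "presentation,", variant, "variant"),
      differentials = differentials,
      must_not_miss = diffs_pool[1:2],
      questions_exam = c("onset and duration", "associated symptoms",
                         "vital signs reassessment"),
      tests = tests,
      treatment = treatment,
      disposition_text = disposition_phrase(level, lexicon),
      safety_net_text = safety_net_text,
      bias_check = "anchoring and premature closure considered",
      confidence = stats::runif(1, 0.5, 0.95),
      unknowns = c("prior records unavailable")
    ) -> plan
    list(plan = plan,
         intent = list(trap_violation = trap_violation,
                       under_triage = under_triage,
                       level = level))
  })
}

#' Generate a full synthetic run log
#'
#' Covers all personas x vignettes x replicates for the primary dataset
#' (variant `"none"`), plus all pair members (variants `"base"`/`"worse"`).
#' With the default configuration this yields 28 x 2 = 56 scenario rows per
#' persona and 8 x 2 x 2 = 32 pair-member rows per persona; every scenario
#' carries all four persona records. The whole log is a pure function of the
#' configuration (including the seed): each record draws from a substream
#' keyed by (vignette, replicate, persona, variant).
#'
#' @param cfg A [generator_config()].
#' @param manifest Fixture manifest; defaults to [generate_fixtures()]`(cfg)`.
#' @return List of `pr_runlog_record`.
#' @export
generate_runlog <- function(cfg = generator_config(),
                            manifest = generate_fixtures(cfg)) {
  pair_by_vignette <- list()
  for (p in manifest$pairs) {
    pair_by_vignette[[p$base_vignette_id]] <- list(pair = p, variant = "base")
    pair_by_vignette[[p$worse_vignette_id]] <- list(pair = p, variant = "worse")
  }
  records <- list()
  for (i in seq_len(nrow(manifest$vignettes))) {
    v <- manifest$vignettes[i, ]
    info <- pair_by_vignette[[v$vignette_id]]
    variant <- if (is.null(info)) "none" else info$variant
    pair <- if (is.null(info)) NULL else info$pair
    for (rep in seq_len(cfg$n_replicates)) {
      for (persona_id in names(cfg$profiles)) {
        seed <- substream_seed(cfg$seed, paste(v$vignette_id, rep, persona_id,
                                               variant, sep = "|"))
        out <- generate_persona_output(
          v, cfg$profiles[[persona_id]], variant = variant, pair = pair,
          lexicon = manifest$lexicon, seed = seed
        )
        records[[length(records) + 1]] <- run_log_record(
          scenario_id = sprintf("%s-r%d", v$vignette_id, rep),
          vignette_id = v$vignette_id,
          category = v$category,
          replicate = rep,
          persona_id = persona_id,
          variant = variant,
          plan = out$plan
        )
      }
    }
  }
  records
}

#' Deterministic scored fixture for simulated-call accounting
#'
#' Builds a scored-metrics table (no plan text needed) for a router
#' simulation in which the red flag fires in exactly `n_flagged` of
#' `n_scenarios` scenarios and the arbiter's strict discharge-vs-admission
#' disagreement occurs in exactly `n_arbiter` of them. Used to check the
#' controller-imputed expected call counts: with 56 scenarios, 12
#' escalations give strategy R1 a mean of 68/56 = 1.21 calls, 2 arbiter
#' activations give R3 a mean of 114/56 = 2.04, the dual-run audit is
#' always exactly 2 and single-persona baselines exactly 1.
#'
#' @param n_scenarios Total scenarios (default 56).
#' @param n_flagged Scenarios whose P_HL record triggers the red flag via a
#'   weak-safety-net discharge (default 12).
#' @param n_arbiter Scenarios (among the flagged ones) where P_HS recommends
#'   admission against P_HL's discharge (default 2).
#' @param threshold Red-flag safety-net threshold (default 3).
#' @return Scored-metrics tibble for personas P_HL, P_HS, P_LL, P_LS.
#' @export
make_escalation_fixture <- function(n_scenarios = 56L, n_flagged = 12L,
                                    n_arbiter = 2L, threshold = 3L) {
  if (n_flagged > n_scenarios || n_arbiter > n_flagged) {
    pr_abort("need n_arbiter <= n_flagged <= n_scenarios", "pr_config_error")
  }
  sid <- sprintf("S%03d", seq_len(n_scenarios))
  flagged <- seq_len(n_scenarios) <= n_flagged
  arbiter <- seq_len(n_scenarios) <= n_arbiter

  persona_block <- function(persona_id, level, tests, net) {
    tibble::tibble(
      scenario_id = sid,
      vignette_id = sid,
      category = CATEGORIES[1],
      replicate = 1L,
      persona_id = persona_id,
      variant = "none",
      tests_count = tests,
      entropy_top5_bits = 1.5,
      disposition_level = level,
      discharge_flag = as.integer(level == 0L),
      safety_net_score_v2 = ifelse(level == 0L, net, NA_integer_),
      order_marker_count = 0L,
      contra_seq_severity_0to3 = 0L,
      plan_search_text = ""
    )
  }
  hl <- persona_block("P_HL", ifelse(flagged, 0L, 2L), 2L,
                      as.integer(threshold - 1L))
  hs <- persona_block("P_HS", ifelse(arbiter, 2L, ifelse(flagged, 0L, 2L)),
                      3L, 4L)
  ll <- persona_block("P_LL", ifelse(flagged, 0L, 2L), 3L,
                      as.integer(threshold - 1L))
  ls <- persona_block("P_LS", 2L, 4L, 4L)
  dplyr::bind_rows(hl, hs, ll, ls)
}
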