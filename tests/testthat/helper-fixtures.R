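# Shared fixtures, built in code at test time.

simple_plan <- function(tests = c("ecg", "troponin"),
                        treatment = c("analgesia"),
                        disposition_text = "disposition: admit to the ward",
                        safety_net_text = "follow-up as arranged",
                        probs = c(0.5, 0.3, 0.2)) {
  plan_record(
    problem_representation = "test case",
    differentials = data.frame(
      label = paste("dx", seq_along(probs)),
      probability = probs
    ),
    must_not_miss = "bad thing",
    questions_exam = "onset",
    tests = tests,
    treatment = treatment,
    disposition_text = disposition_text,
    safety_net_text = safety_net_text,
    bias_check = "checked",
    confidence = 0.7,
    unknowns = character(0)
  )
}

simple_record <- function(vignette_id = "CP01", persona_id = "P_HL",
                          replicate = 1L, variant = "none",
                          category = "chest pain", ...) {
  run_log_record(
    scenario_id = sprintf("%s-r%d", vignette_id, replicate),
    vignette_id = vignette_id, category = category, replicate = replicate,
    persona_id = persona_id, variant = variant, plan = simple_plan(...)
  )
}

# One-row scored-metrics tibble built directly (router-level tests).
metric_row <- function(scenario_id = "S1", persona_id = "P_HL",
                       severity = 0L, level = 2L,
                       safety_net = NA_integer_, tests = 2L) {
  tibble::tibble(
    scenario_id = scenario_id, vignette_id = scenario_id,
    category = "chest pain", replicate = 1L, persona_id = persona_id,
    variant = "none", tests_count = as.integer(tests),
    entropy_top5_bits = 1, disposition_level = as.integer(level),
    discharge_flag = as.integer(level == 0L),
    safety_net_score_v2 = if (level == 0L) as.integer(safety_net) else NA_integer_,
    order_marker_count = 0L,
    contra_seq_severity_0to3 = as.integer(severity),
    plan_search_text = ""
  )
}

# Generated demo data, cached per session so tests share one build.
demo_env <- new.env()
demo_run <- function(seed = 42) {
  key <- paste0("s", seed)
  if (is.null(demo_env[[key]])) {
    cfg <- generator_config(seed = seed)
    man <- generate_fixtures(cfg)
    recs <- generate_runlog(cfg, man)
    scored <- score_runlog(recs, man$lexicon, man$trap_rules)
    demo_env[[key]] <- list(cfg = cfg, man = man, recs = recs, scored = scored)
  }
  demo_env[[key]]
}
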