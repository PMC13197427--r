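test_that("default fixtures reproduce the designed dataset dimensions", {
  man <- generate_fixtures(generator_config())
  primary <- man$vignettes[!man$vignettes$is_pair_member, ]
  expect_equal(nrow(primary), 28)
  expect_equal(unname(c(table(primary$category))), rep(7L, 4))
  expect_equal(sum(!is.na(primary$trap_rule_id)), 4)
  expect_length(man$pairs, 8)
  expect_length(man$trap_rules, 4)
  expect_true(all(vapply(man$pairs, function(p) length(p$required_action_groups) > 0,
                         logical(1))))

  expect_error(
    generate_fixtures(generator_config(n_vignettes = 8,
                                       trap_vignette_ids = "CP07")),
    class = "pr_config_error"
  )
  empty_pairs <- generate_fixtures(generator_config(n_pairs = 0))
  expect_length(empty_pairs$pairs, 0)
})

test_that("the run log is a pure function of the configuration", {
  cfg <- generator_config(seed = 11)
  man <- generate_fixtures(cfg)
  r1 <- generate_runlog(cfg, man)
  r2 <- generate_runlog(cfg, man)
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_runlog(r1, p1)
  write_runlog(r2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  r3 <- generate_runlog(generator_config(seed = 12), man)
  expect_false(identical(
    r1[[1]]$plan$differentials$probability,
    r3[[1]]$plan$differentials$probability
  ))
})

test_that("run-log coverage: 56 scenario rows per persona, pairs complete", {
  run <- demo_run()
  recs <- run$recs
  expect_length(recs, (28 * 2 + 8 * 2 * 2) * 4)
  persona <- vapply(recs, `[[`, character(1), "persona_id")
  variant <- vapply(recs, `[[`, character(1), "variant")
  expect_equal(sum(persona == "P_HL" & variant == "none"), 56)
  expect_equal(sum(persona == "P_LS" & variant != "none"), 32)
  # every scenario carries all four personas
  sid <- vapply(recs, `[[`, character(1), "scenario_id")
  expect_true(all(table(sid) == 4))
  # every generated record passes schema validation (constructors ran), and
  # re-validating the plain plan list succeeds
  for (r in recs[seq(1, length(recs), by = 37)]) {
    expect_s3_class(validate_plan_record(unclass(r$plan)), "pr_plan_record")
  }
})

test_that("substream per record: other records are unaffected by new replicates", {
  man <- generate_fixtures(generator_config(seed = 5))
  small <- generate_runlog(generator_config(seed = 5, n_replicates = 1), man)
  big <- generate_runlog(generator_config(seed = 5, n_replicates = 2), man)
  key <- function(r) paste(r$vignette_id, r$replicate, r$persona_id, r$variant)
  big_by_key <- setNames(big, vapply(big, key, character(1)))
  for (r in small[seq(1, length(small), by = 19)]) {
    expect_equal(unclass(r$plan), unclass(big_by_key[[key(r)]]$plan))
  }
})

test_that("generator intent and scorer verdict are exact inverses", {
  lex <- demo_lexicon()
  rules <- demo_trap_rules()
  man <- generate_fixtures(generator_config())
  trap_vignettes <- man$vignettes[!is.na(man$vignettes$trap_rule_id), ]
  lean1 <- persona_profile("P_HL", 2, p_trap_violation = 1,
                           p_under_triage_on_worse = 1,
                           safety_net_completeness = 0.5,
                           discharge_propensity = 0.5)
  safe0 <- persona_profile("P_HS", 3, p_trap_violation = 0,
                           p_under_triage_on_worse = 0,
                           safety_net_completeness = 1,
                           discharge_propensity = 0.5)

  for (i in seq_len(nrow(trap_vignettes))) {
    v <- trap_vignettes[i, ]
    for (seed in 1:10) {
      viol <- generate_persona_output(v, lean1, "none", lexicon = lex, seed = seed)
      expect_true(viol$intent$trap_violation)
      expect_equal(apply_trap_rule(viol$plan, rules[[v$trap_rule_id]]),
                   rules[[v$trap_rule_id]]$severity_on_trigger)
      clean <- generate_persona_output(v, safe0, "none", lexicon = lex, seed = seed)
      expect_false(clean$intent$trap_violation)
      expect_equal(apply_trap_rule(clean$plan, rules[[v$trap_rule_id]]), 0)
    }
  }

  # under-triage intent realized as worse level strictly below the pair
  # minimum, with required actions omitted; safe profiles always comply
  pair <- man$pairs[[1]]
  worse_v <- man$vignettes[man$vignettes$vignette_id == pair$worse_vignette_id, ]
  for (seed in 1:10) {
    under <- generate_persona_output(worse_v, lean1, "worse", pair = pair,
                                     lexicon = lex, seed = seed)
    expect_true(under$intent$under_triage)
    expect_lt(map_disposition(under$plan$disposition_text, lex),
              pair$min_required_acuity_worse)
    ok <- generate_persona_output(worse_v, safe0, "worse", pair = pair,
                                  lexicon = lex, seed = seed)
    expect_equal(map_disposition(ok$plan$disposition_text, lex),
                 pair$min_required_acuity_worse)
    for (g in pair$required_action_groups) {
      expect_true(any(vapply(g, grepl, logical(1),
                             x = paste(ok$plan$treatment, collapse = " "),
                             fixed = TRUE)))
    }
  }

  # a full safety net on a discharged record scores 5
  low <- man$vignettes[man$vignettes$base_acuity == 0, ][1, ]
  safe_discharge <- persona_profile("P_HS", 3, 0, 0, 1, 1)
  out <- generate_persona_output(low, safe_discharge, "none", lexicon = lex,
                                 seed = 3)
  expect_equal(map_disposition(out$plan$disposition_text, lex), 0)
  expect_equal(score_safety_net(out$plan$safety_net_text, lex), 5)
})

test_that("paper-like profiles reproduce the qualitative violation pattern", {
  run <- demo_run()
  scored <- run$scored
  primary <- scored[scored$variant == "none", ]

  tab <- summarize_strategies(primary)
  lean <- tab[tab$strategy_id == "BASE_HL", ]
  expect_gt(lean$safety_violation_k, 0)
  expect_equal(tab$safety_violation_k[tab$strategy_id == "BASE_HS"], 0)
  expect_equal(tab$safety_violation_k[tab$strategy_id == "BASE_LS"], 0)
  for (s in c("ROUTER_R1", "ROUTER_R2_AUDIT", "ROUTER_R3_ARBITER")) {
    expect_equal(tab$safety_violation_k[tab$strategy_id == s], 0)
  }
  # routers stay near the lean baseline on tests; SAFE baselines do not
  expect_lt(tab$tests_mean[tab$strategy_id == "ROUTER_R1"],
            tab$tests_mean[tab$strategy_id == "BASE_LS"])

  mono <- monotonicity_table(run_counterfactual(
    scored[scored$variant != "none", ], run$man$pairs,
    c("P_HL", "P_HS", "P_LS", "ROUTER_R1", "ROUTER_R2_CF")
  ))
  k <- setNames(mono$k, mono$strategy_id)
  expect_gt(k[["P_HL"]], 0)
  expect_equal(k[["P_HS"]], 0)
  expect_equal(k[["P_LS"]], 0)
  expect_gt(k[["P_HL"]], k[["ROUTER_R1"]])
  expect_gte(k[["ROUTER_R1"]], k[["ROUTER_R2_CF"]])
  expect_equal(k[["ROUTER_R2_CF"]], 0)
})
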