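test_that("red flag agrees with exhaustive enumeration of the trigger formula", {
  oracle <- function(sev, dis, net, thr) {
    (sev > 0) || (dis == 1 && net < thr)
  }
  grid <- expand.grid(sev = 0:3, dis = 0:1, net = 0:5)
  expect_equal(nrow(grid), 48)
  for (thr in 0:5) {
    got <- red_flag(grid$sev, grid$dis, grid$net, thr)
    want <- mapply(oracle, grid$sev, grid$dis, grid$net, thr)
    expect_identical(got, as.logical(want))
  }
})

test_that("red flag firing sets are nested as the threshold grows", {
  fix <- make_escalation_fixture()
  hl <- fix[fix$persona_id == "P_HL", ]
  run <- demo_run()
  hl2 <- run$scored[run$scored$persona_id == "P_HL", ]
  for (m in list(hl, hl2)) {
    prev <- rep(FALSE, nrow(m))
    means <- numeric(0)
    for (t in 2:4) {
      cur <- red_flag(m$contra_seq_severity_0to3, m$discharge_flag,
                      m$safety_net_score_v2, t)
      expect_true(all(cur[prev])) # firing set at t-1 is a subset at t
      prev <- cur
      means <- c(means, 1 + mean(cur))
    }
    expect_true(all(diff(means) >= 0)) # R1 mean calls non-decreasing in t
  }
})

test_that("single-scenario routing follows the controller rules", {
  cfg1 <- strategy_config("ROUTER_R1")

  hl_flag <- metric_row("S1", "P_HL", severity = 2L, level = 2L)
  hs <- metric_row("S1", "P_HS", level = 2L)
  ls <- metric_row("S1", "P_LS", level = 2L)
  d <- route_r1(hl_flag, hs, cfg1)
  expect_equal(d$selected_persona, "P_HS")
  expect_equal(d$simulated_calls, 2)
  expect_match(d$trigger_reasons, "severity_positive")

  hl_ok <- metric_row("S1", "P_HL", level = 2L)
  d2 <- route_r1(hl_ok, hs, cfg1)
  expect_equal(d2$selected_persona, "P_HL")
  expect_equal(d2$simulated_calls, 1)

  # audit override: lean discharge vs safe admission, even without a flag
  hl_disch <- metric_row("S1", "P_HL", level = 0L, safety_net = 4L)
  hs_admit <- metric_row("S1", "P_HS", level = 2L)
  d3 <- route_r2_audit(hl_disch, hs_admit, strategy_config("ROUTER_R2_AUDIT"))
  expect_equal(d3$selected_persona, "P_HS")
  expect_equal(d3$simulated_calls, 2)
  expect_match(d3$trigger_reasons, "disposition_disagreement")
  # both admitted, no flag: lean retained but both calls spent
  d4 <- route_r2_audit(hl_ok, hs, strategy_config("ROUTER_R2_AUDIT"))
  expect_equal(d4$selected_persona, "P_HL")
  expect_equal(d4$simulated_calls, 2)
  # ED observation (level 1) is not "admission": no override on 0-vs-1
  hs_obs <- metric_row("S1", "P_HS", level = 1L)
  expect_equal(route_r2_audit(hl_disch, hs_obs,
                              strategy_config("ROUTER_R2_AUDIT"))$selected_persona,
               "P_HL")

  # counterfactual comparator: any level disagreement selects P_LS
  hl_obs <- metric_row("S1", "P_HL", level = 1L)
  d5 <- route_r2_cf(hl_obs, hs, ls, strategy_config("ROUTER_R2_CF"))
  expect_equal(d5$selected_persona, "P_LS")
  expect_equal(route_r2_cf(hl_ok, hs, ls,
                           strategy_config("ROUTER_R2_CF"))$selected_persona,
               "P_HL")
  expect_equal(route_r2_cf(hl_flag, hs, ls,
                           strategy_config("ROUTER_R2_CF"))$selected_persona,
               "P_LS")

  # arbiter: strict discharge-vs-admission disagreement invokes P_LS
  cfg3 <- strategy_config("ROUTER_R3_ARBITER")
  d6 <- route_r3(hl_disch, hs_admit, ls, cfg3)
  expect_equal(d6$selected_persona, "P_LS")
  expect_equal(d6$simulated_calls, 3)
  expect_equal(d6$trigger_reasons, "arbiter_invoked")
  d7 <- route_r3(hl_flag, hs, ls, cfg3)
  expect_equal(d7$selected_persona, "P_HS")
  expect_equal(d7$simulated_calls, 2)
  d8 <- route_r3(hl_ok, hs, ls, cfg3)
  expect_equal(d8$selected_persona, "P_HL")
  expect_equal(d8$simulated_calls, 2)

  expect_error(route_r1(metric_row("S1"), metric_row("S2", "P_HS")),
               class = "pr_pairing_error")
})

test_that("strategy simulation is exhaustive, deterministic and bounded", {
  run <- demo_run()
  primary <- run$scored[run$scored$variant == "none", ]

  for (s in c("BASE_HL", "BASE_HS", "BASE_LL", "BASE_LS")) {
    sim <- simulate_strategy(primary, s)
    expect_equal(nrow(sim$decisions), 56)
    expect_true(all(sim$decisions$simulated_calls == 1))
    expect_true(all(sim$selected$persona_id ==
                      sub("BASE_", "P_", s)))
  }

  r1 <- simulate_strategy(primary, "ROUTER_R1")
  expect_true(all(r1$decisions$simulated_calls %in% 1:2))
  r2 <- simulate_strategy(primary, "ROUTER_R2_AUDIT")
  expect_true(all(r2$decisions$simulated_calls == 2))
  r3 <- simulate_strategy(primary, "ROUTER_R3_ARBITER")
  expect_true(all(r3$decisions$simulated_calls %in% 2:3))
  rcf <- simulate_strategy(primary, "ROUTER_R2_CF")
  expect_true(all(rcf$decisions$simulated_calls %in% 2:3))

  expect_identical(simulate_strategy(primary, "ROUTER_R1"),
                   simulate_strategy(primary, "ROUTER_R1"))

  expect_error(
    simulate_strategy(primary[primary$persona_id != "P_HS", ], "ROUTER_R1"),
    class = "pr_coverage_error"
  )
})

test_that("escalating on a positive severity eliminates that violation family", {
  run <- demo_run()
  primary <- run$scored[run$scored$variant == "none", ]
  for (s in c("ROUTER_R1", "ROUTER_R2_AUDIT", "ROUTER_R3_ARBITER")) {
    sim <- simulate_strategy(primary, s)
    sel <- sim$selected
    escalated <- grepl("severity_positive", sel$trigger_reasons)
    # whenever the trigger fired on severity, the routed record is clean
    expect_true(all(sel$contra_seq_severity_0to3[escalated] == 0))
    # and on this fixture routing removes all trap violations
    expect_equal(sum(sel$contra_seq_severity_0to3 > 0), 0)
  }
  base <- simulate_strategy(primary, "BASE_HL")
  expect_gt(sum(base$selected$contra_seq_severity_0to3 > 0), 0)
})
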