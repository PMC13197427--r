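lex <- demo_lexicon()

test_that("tests_count trims empty entries", {
  expect_equal(compute_tests_count(simple_plan(tests = c("ecg", "troponin"))), 2)
  expect_equal(compute_tests_count(simple_plan(tests = character(0))), 0)
  expect_equal(compute_tests_count(simple_plan(tests = c("ecg", "", "  ", "troponin"))), 2)
})

test_that("top-5 entropy matches closed forms and stays in [0, log2 5]", {
  expect_equal(compute_entropy_top5(rep(0.2, 5)), log2(5), tolerance = 1e-12)
  expect_equal(compute_entropy_top5(1.0), 0)
  expect_equal(compute_entropy_top5(c(0.5, 0.25, 0.125, 0.0625, 0.0625)),
               1.875, tolerance = 1e-12)
  # more than five differentials: only the top five enter, renormalized
  expect_equal(compute_entropy_top5(c(rep(0.19, 5), 0.05)), log2(5),
               tolerance = 1e-12)
  expect_error(compute_entropy_top5(c(0, 0)), class = "pr_domain_error")

  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:8, 1))
    h <- compute_entropy_top5(p)
    expect_gte(h, 0)
    expect_lte(h, log2(5) + 1e-12)
  }
})

test_that("disposition maps to the highest matching acuity level", {
  expect_equal(map_disposition("plan: discharge home with instructions", lex), 0)
  expect_equal(map_disposition("admit to icu for monitoring", lex), 3)
  # max rule when several levels match
  expect_equal(map_disposition("admit to the ward, upgrade to admit to icu if unstable", lex), 3)
  expect_error(map_disposition("completely unrelated text", lex),
               class = "pr_unmapped_disposition")
  expect_error(map_disposition("", lex), class = "pr_unmapped_disposition")
})

test_that("safety-net rubric scores 0-5 and is monotone in added keywords", {
  full <- paste("if worsening pain or shortness of breath, seek care",
                "immediately, within 24 hours, at the emergency department")
  expect_equal(score_safety_net(full, lex), 5)
  expect_equal(score_safety_net("call back if worsening pain", lex), 1)
  expect_equal(score_safety_net("", lex), 0)
  # two symptoms alone score 2; each further component adds one
  expect_equal(score_safety_net("worsening pain; fainting", lex), 2)

  base_text <- "worsening pain"
  additions <- c("fainting", "immediately", "within 24 hours",
                 "emergency department")
  prev <- score_safety_net(base_text, lex)
  for (a in additions) {
    base_text <- paste(base_text, a, sep = "; ")
    cur <- score_safety_net(base_text, lex)
    expect_gte(cur, prev)
    prev <- cur
  }
  expect_equal(prev, 5)
})

test_that("order markers are counted as occurrences, not types", {
  p <- simple_plan(tests = c("first imaging"),
                   treatment = c("then antibiotics"))
  expect_equal(count_order_markers(p, lex), 2)
  expect_equal(count_order_markers(simple_plan(), lex), 0)
  p2 <- simple_plan(treatment = c("first fluids", "first antibiotics"))
  expect_equal(count_order_markers(p2, lex), 2)
})

test_that("trap rules trigger on their patterns and only on them", {
  rules <- demo_trap_rules()

  aspirin <- simple_plan(treatment = c("aspirin loading dose"))
  expect_equal(apply_trap_rule(aspirin, rules$CP07), 2)
  caveat <- simple_plan(tests = c("ct angiography of the chest"),
                        treatment = c("aspirin loading dose"))
  expect_equal(apply_trap_rule(caveat, rules$CP07), 0)
  clean <- simple_plan(treatment = c("analgesia"))
  expect_equal(apply_trap_rule(clean, rules$CP07), 0)

  expect_equal(apply_trap_rule(simple_plan(treatment = "heparin infusion"),
                               rules$AP07), 3)
  expect_equal(apply_trap_rule(
    simple_plan(treatment = c("heparin infusion", "after rupture excluded")),
    rules$AP07), 0)

  # precedence: lumbar puncture before head imaging triggers; reverse and
  # absent-imaging plans do not fire the precedence clause
  expect_equal(apply_trap_rule(simple_plan(tests = c("lumbar puncture", "head ct")),
                               rules$HA07), 3)
  expect_equal(apply_trap_rule(simple_plan(tests = c("head ct", "lumbar puncture")),
                               rules$HA07), 0)
  expect_equal(apply_trap_rule(simple_plan(tests = c("lumbar puncture")),
                               rules$HA07), 0)
  # ordering spans the tests-then-treatment concatenation
  expect_equal(apply_trap_rule(
    simple_plan(tests = c("lumbar puncture"), treatment = c("head ct review")),
    rules$HA07), 3)

  expect_equal(apply_trap_rule(
    simple_plan(treatment = c("nebulized bronchodilator", "antihistamine")),
    rules$DY07), 3)
  expect_equal(apply_trap_rule(
    simple_plan(treatment = c("intramuscular epinephrine")),
    rules$DY07), 0)

  # keyword matching is case-insensitive and NFKC-normalized
  expect_equal(apply_trap_rule(simple_plan(treatment = "ASPIRIN now"),
                               rules$CP07), 2)
  expect_equal(apply_trap_rule(simple_plan(treatment = "ａｓｐｉｒｉｎ"),
                               rules$CP07), 2)
})

test_that("record scoring composes the metrics consistently and purely", {
  rules <- demo_trap_rules()
  rec <- simple_record(
    vignette_id = "CP07",
    treatment = c("aspirin loading dose"),
    disposition_text = "disposition: admit to the ward"
  )
  m <- score_record(rec, lex, rules)
  expect_equal(m$contra_seq_severity_0to3, 2)
  expect_equal(m$discharge_flag, 0)
  expect_true(is.na(m$safety_net_score_v2))

  # discharge record: flag 1 iff level 0, full safety net scores 5
  rec2 <- simple_record(
    vignette_id = "CP01",
    disposition_text = "disposition: discharge home",
    safety_net_text = paste("worsening pain; fainting; immediately;",
                            "within 24 hours; emergency department")
  )
  m2 <- score_record(rec2, lex, rules)
  expect_equal(m2$disposition_level, 0)
  expect_equal(m2$discharge_flag, 1)
  expect_equal(m2$safety_net_score_v2, 5)
  expect_equal(m2$contra_seq_severity_0to3, 0) # no trap rule on CP01

  expect_identical(score_record(rec, lex, rules), score_record(rec, lex, rules))
})

test_that("discharge flag equals level-0 on every scored demo record", {
  scored <- demo_run()$scored
  expect_true(all((scored$discharge_flag == 1) ==
                    (scored$disposition_level == 0)))
  expect_true(all(is.na(scored$safety_net_score_v2[scored$discharge_flag == 0])))
  expect_true(all(scored$contra_seq_severity_0to3 %in% c(0, 2, 3)))
})
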