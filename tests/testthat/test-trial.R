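test_that("interval decisions follow the escalate/stay/de-escalate rule", {
  # lambda pair at target 0.3 is (0.2365, 0.3585)
  st <- trial_state(n = c(3, 3, 0), y = c(0, 0, 0), current_dose = 2)
  expect_identical(decide(st, d_boin_03), "escalate")

  st2 <- trial_state(n = c(3, 3, 0), y = c(0, 2, 0), current_dose = 2)
  expect_identical(decide(st2, d_boin_03), "de-escalate")

  st3 <- trial_state(n = c(3, 3, 0), y = c(0, 1, 0), current_dose = 2)
  expect_identical(decide(st3, d_boin_03), "stay")
})

test_that("edge doses stay instead of moving outside the range", {
  top <- trial_state(n = c(3, 3, 3), y = c(0, 0, 0), current_dose = 3)
  expect_identical(decide(top, d_boin_03), "stay")

  bottom <- trial_state(n = c(3, 0, 0), y = c(2, 0, 0), current_dose = 1)
  expect_identical(decide(bottom, d_boin_03), "stay")
})

test_that("escalation never targets an eliminated dose", {
  st <- trial_state(n = c(3, 3, 3), y = c(0, 0, 3), current_dose = 2,
                    eliminated = c(FALSE, FALSE, TRUE))
  expect_identical(decide(st, d_boin_03), "stay")
  st_el <- trial_state(n = c(3, 6, 3), y = c(0, 1, 3), current_dose = 3,
                       eliminated = c(FALSE, FALSE, TRUE))
  expect_identical(decide(st_el, d_boin_03), "de-escalate")
})

test_that("deciding with no data at the current dose is a logic error", {
  st <- trial_state(n = c(3, 0, 0), y = c(0, 0, 0), current_dose = 2)
  expect_error(decide(st, d_boin_03), "no patients")
})

test_that("lead-in keeps fixed boundaries until enough patients are treated", {
  fixed <- boin_boundaries(0.3, 0.18, 0.42)

  early <- trial_state(n = c(3, 0, 0), y = c(0, 0, 0))
  b_early <- effective_boundaries(early, d_aboin_03)
  expect_equal(b_early$lambda1, fixed$lambda1)
  expect_equal(b_early$lambda2, fixed$lambda2)

  at_switch <- trial_state(n = c(6, 0, 0), y = c(1, 0, 0))
  b_sw <- effective_boundaries(at_switch, d_aboin_03)
  a6 <- aboin_boundaries(0.3, n_j = 6)
  expect_equal(b_sw$lambda1, a6$lambda1)
  expect_equal(b_sw$lambda2, a6$lambda2)

  # patients can be spread across doses: the switch counts total accrual
  spread <- trial_state(n = c(3, 3, 0), y = c(0, 0, 0), current_dose = 2)
  b_sp <- effective_boundaries(spread, d_aboin_03)
  a3 <- aboin_boundaries(0.3, n_j = 3)
  expect_equal(b_sp$lambda1, a3$lambda1)

  no_lead <- design_spec(0.3, "aboin", lead_in = 0L)
  first <- trial_state(n = c(3, 0, 0), y = c(0, 0, 0))
  b0 <- effective_boundaries(first, no_lead)
  expect_equal(b0$lambda1, a3$lambda1)
  expect_equal(b0$lambda2, a3$lambda2)
})

test_that("safety rule eliminates on strong posterior evidence of excess toxicity", {
  # 3/3 DLTs at target 0.3: Pr(p > 0.3) = 1 - 0.3^4 = 0.9919 > 0.95
  expect_equal(1 - pbeta(0.3, 4, 1), 0.9919, tolerance = 1e-12)
  st <- trial_state(n = c(3, 3, 0), y = c(0, 3, 0), current_dose = 2)
  out <- safety_eliminate(st, d_boin_03)
  expect_identical(out$eliminated, c(FALSE, TRUE, TRUE))
  expect_false(out$terminated_early)
  expect_identical(out$current_dose, 1L)

  # 0/3 never eliminates; neither does too little data
  clean <- trial_state(n = c(3, 0, 0), y = c(0, 0, 0))
  expect_identical(safety_eliminate(clean, d_boin_03)$eliminated,
                   rep(FALSE, 3))
  thin <- trial_state(n = c(2, 0, 0), y = c(2, 0, 0))
  expect_identical(safety_eliminate(thin, d_boin_03)$eliminated,
                   rep(FALSE, 3))

  # eliminating the lowest dose terminates the trial
  worst <- trial_state(n = c(3, 0, 0), y = c(3, 0, 0))
  expect_true(safety_eliminate(worst, d_boin_03)$terminated_early)
})

test_that("MTD selection picks the isotonic estimate closest to the target", {
  st <- trial_state(n = c(10, 10, 10), y = c(0, 2, 4))
  expect_identical(select_mtd(st, d_boin_02), 2L)

  # monotone-violating raw rates are pooled before comparison; ties break
  # toward the higher dose below target, toward the lower dose above it
  tied <- trial_state(n = c(20, 20), y = c(5, 3))
  expect_identical(select_mtd(tied, d_boin_02), 2L)          # pooled < 0.2
  above <- design_spec(0.15, "boin")
  expect_identical(select_mtd(tied, above), 1L)              # pooled > 0.15

  never <- trial_state(n = c(6, 0, 0), y = c(1, 0, 0))
  expect_identical(select_mtd(never, d_boin_02), 1L)
  expect_error(select_mtd(trial_state(n = c(0, 0), y = c(0, 0)), d_boin_02),
               "no dose")
  dead <- trial_state(n = c(3, 0), y = c(3, 0),
                      eliminated = c(TRUE, TRUE), terminated_early = TRUE)
  expect_identical(select_mtd(dead, d_boin_02), NA_integer_)
})

test_that("weighted pool-adjacent-violators pools exactly the violating blocks", {
  expect_equal(aboin:::.pava(c(0.25, 0.15)), c(0.2, 0.2))
  expect_equal(aboin:::.pava(c(0.25, 0.15), w = c(3, 1)), c(0.225, 0.225))
  expect_equal(aboin:::.pava(c(0.1, 0.3, 0.2, 0.4)), c(0.1, 0.25, 0.25, 0.4))
  x <- c(0.05, 0.1, 0.2, 0.3)
  expect_equal(aboin:::.pava(x), x) # already monotone: untouched
})

test_that("a certain-toxicity scenario terminates with no MTD", {
  res <- run_trial(dose_scenario(rep(1, 5), 1, "all-toxic"), d_boin_03,
                   seed = 7)
  expect_true(res$terminated_early)
  expect_identical(res$selected_mtd, NA_integer_)
  expect_identical(res$total_n, 3L)
  expect_identical(res$log$decision, "terminate")
})

test_that("a toxicity-free scenario escalates straight to the top dose", {
  res <- run_trial(dose_scenario(rep(0, 5), 5, "all-clean"), d_boin_03,
                   seed = 7)
  expect_identical(res$selected_mtd, 5L)
  expect_identical(res$total_n, 30L)
  expect_identical(res$log$decision,
                   c(rep("escalate", 4), rep("stay", 6)))
  expect_identical(res$n, c(3L, 3L, 3L, 3L, 18L))
})

test_that("trials are reproducible from their seed and decisions replay", {
  sc <- builtin_scenarios(0.2)[["s8"]]
  a <- run_trial(sc, d_boin_02, seed = 123)
  b <- run_trial(sc, d_boin_02, seed = 123)
  expect_identical(a$log, b$log)
  expect_identical(a$selected_mtd, b$selected_mtd)

  # the decision log replays: each move follows the recorded decision
  step <- c(escalate = 1L, stay = 0L, `de-escalate` = -1L, terminate = 0L)
  for (seed in 1:20) {
    r <- run_trial(sc, d_aboin_02, seed = seed)
    d <- r$log$dose
    mv <- unname(step[r$log$decision])
    if (nrow(r$log) > 1) {
      expect_identical(d[-1], (d + mv)[-nrow(r$log)])
    }
    expect_true(all(d >= 1 & d <= 5))
  }
})

test_that("decision logs are long-term memory coherent", {
  # never escalate from a dose observed above target, never de-escalate
  # from one observed below (elimination rows included: they only fire
  # when the observed rate is far above target)
  scens <- list(builtin_scenarios(0.2)[["s3"]], builtin_scenarios(0.2)[["s8"]])
  designs <- list(d_boin_02, d_aboin_02)
  violations <- 0L
  for (sc in scens) {
    for (des in designs) {
      for (seed in 1:50) {
        lg <- run_trial(sc, des, seed = seed)$log
        phat <- lg$y_j / lg$n_j
        up <- lg$decision == "escalate" & phat > des$phi
        down <- lg$decision %in% c("de-escalate", "terminate") & phat < des$phi
        violations <- violations + sum(up) + sum(down)
      }
    }
  }
  expect_identical(violations, 0L)
})
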