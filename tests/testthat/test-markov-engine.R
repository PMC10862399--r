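g1 <- "41-65|female|nohx"

test_that("identity schedules keep everyone in NTRD with zero deaths", {
  sch <- setNames(list(constant_schedule(list())), g1)
  tr <- run_closed_cohort(sch, simple_state_inputs(), c("41-65|female|nohx" = 100))
  occ <- tr$occupancy
  expect_true(all(occ$occupancy[occ$state == "NTRD"] == 100))
  expect_true(all(occ$occupancy[occ$state != "NTRD"] == 0))
  expect_equal(sum(tr$outcomes$deaths), 0)
})

test_that("constant death probability accumulates deaths geometrically, exactly", {
  p <- 0.07
  sch <- setNames(list(constant_schedule(list("NTRD->death" = p))), g1)
  tr <- run_closed_cohort(sch, simple_state_inputs(), setNames(1000, g1))
  cum_deaths <- cumsum(tr$outcomes$deaths)
  expect_equal(cum_deaths, 1000 * (1 - (1 - p)^(1:10)), tolerance = 1e-12)
})

test_that("occupancy is conserved and outputs are homogeneous of degree one in entrants", {
  pipe <- test_pipeline()
  ent <- setNames(rep(500, 16), subgroup_table()$subgroup)
  tr <- run_closed_cohort(pipe$schedules, pipe$state_inputs, ent)
  tot <- tapply(tr$occupancy$occupancy, tr$occupancy$cycle, sum)
  expect_true(all(abs(tot - sum(ent)) < 1e-9))
  end <- sum(tr$occupancy_end$occupancy)
  expect_lt(abs(end - sum(ent)), 1e-9)
  # exact 1.25-fold scaling of every outcome
  tr125 <- run_closed_cohort(pipe$schedules, pipe$state_inputs, ent * 1.25)
  for (col in c("cost_allcause", "cost_psychiatric", "deaths", "life_years",
                "qalys", "qalys_trd", "cost_allcause_comorbid")) {
    expect_equal(tr125$outcomes[[col]], 1.25 * tr$outcomes[[col]],
                 tolerance = 1e-12)
  }
})

test_that("cumulative deaths and costs are non-decreasing and discounting shrinks costs", {
  pipe <- test_pipeline()
  ent <- setNames(rep(100, 16), subgroup_table()$subgroup)
  tr <- run_closed_cohort(pipe$schedules, pipe$state_inputs, ent)
  ann <- summary(tr)$annual
  expect_true(all(ann$deaths >= -1e-12))
  expect_true(all(ann$cost_allcause >= 0))
  trd <- run_closed_cohort(pipe$schedules, pipe$state_inputs, ent,
                           discount_rate = 0.025)
  expect_lt(sum(trd$outcomes$cost_allcause_disc),
            sum(tr$outcomes$cost_allcause))
  # undiscounted accruals are identical regardless of the rate
  expect_equal(trd$outcomes$cost_allcause, tr$outcomes$cost_allcause,
               tolerance = 1e-12)
})

test_that("accrual follows the stated conventions", {
  occ <- setNames(c(10, 5, 0, 0, 3, 2), model_states())
  si <- simple_state_inputs()
  rec <- accrue_outcomes(occ, si, cycle = 2, discount_rate = 0.025)
  expect_equal(rec$cost_allcause, 10 * 1000 + 5 * 2000)
  expect_equal(rec$cost_allcause_disc, rec$cost_allcause / 1.025)
  expect_equal(rec$life_years, 18)      # alive states incl. low-intensity
  expect_equal(rec$qalys, 10 * 0.8 + 5 * 0.6 + 3 * 0.85)
  expect_equal(rec$cost_allcause_trd, 5 * 2000)
  expect_equal(rec$life_years_trd, 5)
  # value of 100 at cycle 2 discounts to 97.56
  expect_equal(round(100 / 1.025, 2), 97.56)
  # everyone dead: nothing accrues
  occ_dead <- setNames(c(0, 0, 0, 0, 0, 20), model_states())
  rec0 <- accrue_outcomes(occ_dead, si, cycle = 1)
  expect_equal(rec0$cost_allcause + rec0$life_years + rec0$qalys, 0)
  occ_bad <- occ; occ_bad["TRD"] <- -1
  expect_error(accrue_outcomes(occ_bad, si, 1), "negative occupancy")
})

test_that("open-cohort output is the superposition of shifted closed cohorts", {
  pipe <- test_pipeline()
  subs <- subgroup_table()$subgroup
  plan <- expand.grid(year = 2020:2023, subgroup = subs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  plan$new_patients <- 0
  plan$new_patients[plan$year == 2020] <- 100 * seq(0.5, 2, length.out = 16)
  plan$new_patients[plan$year == 2023] <- 250 * seq(0.5, 2, length.out = 16)
  open <- run_open_cohort(pipe$schedules, pipe$state_inputs, plan,
                          end_year = 2032)
  # oracle: two independent closed runs shifted to calendar time
  shift_closed <- function(y) {
    ent <- setNames(plan$new_patients[plan$year == y], subs)
    tr <- run_closed_cohort(pipe$schedules, pipe$state_inputs, ent)
    out <- tr$outcomes
    out$year <- y + out$cycle - 1L
    out
  }
  both <- rbind(shift_closed(2020L), shift_closed(2023L))
  for (col in c("cost_allcause", "deaths", "qalys", "life_years")) {
    want <- tapply(both[[col]], both$year, sum)
    got <- tapply(open$outcomes[[col]], open$outcomes$year, sum)
    expect_equal(got[names(want)], want, tolerance = 1e-9)
  }
  # single entry year: open equals closed exactly, shifted
  plan1 <- plan[plan$year == 2020, ]
  plan1$new_patients <- 100 * seq(0.5, 2, length.out = 16)
  open1 <- run_open_cohort(pipe$schedules, pipe$state_inputs, plan1,
                           end_year = 2029)
  closed1 <- shift_closed(2020L)
  want <- tapply(closed1$cost_allcause, closed1$year, sum)
  got <- tapply(open1$outcomes$cost_allcause, open1$outcomes$year, sum)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("a plan gap is rejected and constant entrants reach a steady state", {
  pipe <- test_pipeline()
  subs <- subgroup_table()$subgroup
  plan <- expand.grid(year = c(2014:2020, 2022), subgroup = subs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  plan$new_patients <- 10
  expect_error(run_open_cohort(pipe$schedules, pipe$state_inputs, plan),
               "2021")
  plan2 <- expand.grid(year = 2014:2032, subgroup = subs,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  plan2$new_patients <- 10
  open <- run_open_cohort(pipe$schedules, pipe$state_inputs, plan2)
  ann <- tapply(open$outcomes$cost_allcause, open$outcomes$year, sum)
  # once 10 cohorts overlap (from 2023), annual outputs are constant
  late <- ann[as.character(2023:2032)]
  expect_lt(max(abs(late - late[1])) / late[1], 1e-9)
})

test_that("CAGR follows its closed form and guards the zero base", {
  expect_equal(cagr(100, 100, 10), 0)
  expect_equal(cagr(39.5, 24.5, 10), (24.5 / 39.5)^(1 / 9) - 1)
  expect_equal(100 * cagr(39.5, 24.5, 10), -5.17, tolerance = 0.01)
  expect_error(cagr(0, 10, 10), "undefined")
})

test_that("summary reports case fatality and per-patient-year burden by subgroup", {
  p <- 0.0103
  sch <- setNames(list(constant_schedule(list("NTRD->death" = p))), g1)
  tr <- run_closed_cohort(sch, simple_state_inputs(), setNames(9147, g1))
  s <- summary(tr)
  expect_equal(s$cumulative_deaths, 9147 * (1 - (1 - p)^10), tolerance = 1e-9)
  # deaths 899 out of 9147 entrants is a 9.8% case fatality
  expect_equal(round(100 * 899 / 9147, 1), 9.8)
  expect_equal(s$by_subgroup$cost_allcause_per_py,
               s$by_subgroup$cost_allcause / s$by_subgroup$life_years)
})
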