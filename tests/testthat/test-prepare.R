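test_that("nest fates are classified from monitoring evidence", {
  # eggshells indicative of hatching, 3 days after the expected hatch date
  expect_equal(as.character(classify_nest_fate(FALSE, 3, FALSE, TRUE)),
               "successful")
  # all eggs gone mid-incubation with no hatching evidence
  expect_equal(as.character(classify_nest_fate(FALSE, NA, TRUE, TRUE)),
               "failed")
  # monitoring ended 6 days before the expected hatch date
  expect_equal(as.character(classify_nest_fate(FALSE, NA, FALSE, FALSE)),
               "unknown")
  # chick in the nest trumps everything
  expect_equal(as.character(classify_nest_fate(TRUE, NA, FALSE, FALSE)),
               "successful")
  # shells found 6 days late are not hatching evidence
  expect_equal(as.character(classify_nest_fate(FALSE, 6, FALSE, TRUE)),
               "unknown")
})

test_that("capture-timing screen keeps balanced sites and drops shifted ones", {
  bal <- data.frame(site = "B01", taxon = "SESA",
                    group = rep(c("control", "geolocator"), each = 20),
                    capture_day = rep(c(150, 151), 20),
                    nest_age_at_capture = rep(c(4, 5), 20))
  scr <- screen_sites_capture_timing(bal)
  expect_true(scr$eligible)

  set.seed(1)
  shifted <- bal
  shifted$capture_day <- c(rnorm(20, 150, 1), rnorm(20, 140, 1))
  scr <- screen_sites_capture_timing(shifted)
  expect_false(scr$eligible)
  expect_lt(scr$p_capture_day, 0.05)

  tiny <- bal[c(1, 21), ]
  expect_warning(scr <- screen_sites_capture_timing(tiny), "fewer than 2")
  expect_false(scr$eligible)
})

test_that("return-table rules exclude the right events and log them", {
  ev <- make_events(6)
  ev$age_class[1] <- "juvenile"
  ev$returned_without_tag[2] <- TRUE   # geolocator row
  # individual tagged in 2010, then a control event afterwards
  ev$individual_id[3] <- "B002"        # control row for the bird tagged in row 2?
  ev$individual_id[2] <- "B900"
  ev$individual_id[3] <- "B900"
  ev$year[3] <- 2012L
  ev$group[3] <- "control"
  ev$attachment[3] <- "none"

  tab <- build_return_table(ev)
  log <- exclusions(tab)
  expect_equal(nrow(tab) + sum(log$n_excluded), nrow(ev))
  expect_equal(log$n_excluded[log$rule == "juvenile"], 1)
  expect_equal(log$n_excluded[log$rule == "returned_without_tag"], 1)
  expect_equal(log$n_excluded[log$rule == "control_after_tagging"], 1)
  expect_true(all(tab$returned %in% 0:1))

  # single adult control event that returned
  one <- build_return_table(make_events(1))
  expect_equal(nrow(one), 1)
  expect_equal(one$returned, 1L)
  expect_equal(one$geolocator, 0L)
})

test_that("building a table twice is idempotent", {
  ev <- make_events(8)
  a <- build_return_table(ev)
  b <- build_return_table(ev)
  expect_identical(a, b)
})

test_that("nest, partial-hatch and movement filters follow their rules", {
  nst <- make_nests(6)
  nst$fate[5] <- "unknown"
  nst$cause_of_failure[5] <- "none"
  tab <- build_nest_table(nst)
  expect_equal(nrow(tab), 5)
  expect_equal(exclusions(tab)$n_excluded[1], 1)

  elig <- data.frame(site = "B01", taxon = "SESA", eligible = FALSE)
  expect_equal(nrow(build_nest_table(nst, eligible = elig)), 0)

  ph <- make_nests(6)
  ph$unhatched_egg_present <- TRUE
  ph$research_damage[1] <- TRUE        # successful, damaged by research
  tab <- build_partial_hatch_table(ph)
  # of 6 nests: 3 failed, 1 research-damaged successful -> 2 remain
  expect_equal(nrow(tab), 2)
  expect_equal(exclusions(tab)$n_excluded[
    exclusions(tab)$rule == "research_damage"], 1)
  ph$taxon <- "BTGO"                   # taxon outside the pooled pair
  expect_equal(nrow(build_partial_hatch_table(ph)), 0)

  mv <- data.frame(individual_id = c("a", "b"), taxon = "SESA", site = "B01",
                   year_t = 2010L, year_t1 = 2011L, distance_m = c(0, 250),
                   sex = "female", nest_fate_year_t = "hatched",
                   previously_marked = FALSE, group = "control",
                   on_plot_both_years = c(TRUE, FALSE))
  tab <- build_movement_table(mv)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$log_distance, log(1))  # zero-distance nest-cup reuse
})

test_that("attachment-contrast table restricts to leg-mounted tagged birds", {
  ev <- make_events(8)
  ev$attachment[ev$group == "geolocator"] <- rep(c("PAB", "PEF"), 2)
  ev$attachment[8] <- "LLH"
  tab <- build_attachment_table(ev)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$attachment_PEF %in% 0:1))
  log <- exclusions(tab)
  expect_equal(log$n_excluded[log$rule == "control_group"], 4)
  expect_equal(log$n_excluded[log$rule == "other_attachment"], 1)
})
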