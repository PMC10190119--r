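test_that("campaign generation is deterministic given the seed", {
  spec <- campaign_spec(n_buildings = 2, rooms_per_building = 25, seed = 99)
  expect_identical(generate_campaign(spec), generate_campaign(spec))
  other <- campaign_spec(n_buildings = 2, rooms_per_building = 25, seed = 100)
  expect_false(identical(generate_campaign(spec), generate_campaign(other)))
})

test_that("generation does not disturb the global RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(generate_campaign(campaign_spec(n_buildings = 1,
                                            rooms_per_building = 5)))
  expect_identical(runif(1), a)
})

test_that("every generated record validates; basic components always present", {
  camp <- generate_campaign(campaign_spec(n_buildings = 2,
                                          rooms_per_building = 50, seed = 3))
  expect_true(is_clean(validate_campaign(camp)))
  for (r in camp) {
    comps <- vapply(r$observations, function(o) o$component, character(1))
    expect_true(all(c("ceiling", "walls", "floor") %in% comps))
  }
})

test_that("zero prevalence yields an all-clear campaign", {
  spec <- campaign_spec(n_buildings = 1, rooms_per_building = 30,
                        factor_prevalence = c(water_damage_stains = 0,
                                              visible_mold = 0, wet_damp = 0,
                                              mold_odor = 0), seed = 4)
  camp <- generate_campaign(spec)
  expect_true(all(vapply(camp, room_total, integer(1)) == 0L))
})

test_that("generated campaigns recover the spec prevalence within 3 SE", {
  spec <- campaign_spec(n_buildings = 1, rooms_per_building = 1000,
                        factor_prevalence = c(water_damage_stains = 0.5,
                                              visible_mold = 0.1,
                                              wet_damp = 0.05,
                                              mold_odor = 0.2),
                        seed = 20)
  camp <- generate_campaign(spec)
  for (f in c(dmat_factors(), "mold_odor")) {
    p <- spec$factor_prevalence[[f]]
    se <- sqrt(p * (1 - p) / 1000)
    expect_lt(abs(factor_prevalence(camp, f) - p), 3 * se)
  }
})

test_that("severity distribution is recoverable from generated scores", {
  spec <- campaign_spec(n_buildings = 1, rooms_per_building = 1000,
                        severity_distribution = c(0.5, 0.3, 0.2), seed = 8)
  camp <- generate_campaign(spec)
  sc <- unlist(lapply(camp, function(r)
    vapply(r$observations, function(o) o$damage_stain, integer(1))))
  sc <- sc[sc > 0]
  expect_gt(length(sc), 300)
  phat <- as.numeric(table(factor(sc, levels = 1:3)) / length(sc))
  se <- sqrt(c(0.5, 0.3, 0.2) * (1 - c(0.5, 0.3, 0.2)) / length(sc))
  expect_true(all(abs(phat - c(0.5, 0.3, 0.2)) < 3 * se))
})

test_that("default-spec campaigns exercise all scores, components and flags", {
  camp <- generate_campaign(campaign_spec(seed = 2))
  sc <- unlist(lapply(camp, function(r) lapply(r$observations, function(o)
    c(o$damage_stain, o$visible_mold, o$wet_damp))))
  expect_identical(sort(unique(sc)), 0:3)
  comps <- unlist(lapply(camp, function(r)
    vapply(r$observations, function(o) o$component, character(1))))
  expect_setequal(unique(comps), dmat_components())
  expect_true(any(unlist(lapply(camp, function(r)
    vapply(r$observations, function(o) o$near_exterior_wall, logical(1))))))
  expect_true(any(unlist(lapply(camp, function(r)
    vapply(r$observations, function(o) o$nothing_found, logical(1))))))
  expect_true(any(vapply(camp, function(r) r$odor$source_unknown,
                         logical(1))))
})

test_that("observer pairs are deterministic and recover agreement_prob", {
  camp <- generate_campaign(campaign_spec(n_buildings = 1,
                                          rooms_per_building = 1000,
                                          seed = 30))
  expect_identical(generate_observer_pair(camp, 0.75, seed = 5),
                   generate_observer_pair(camp, 0.75, seed = 5))
  b <- generate_observer_pair(camp, 1, seed = 5)
  for (f in c(dmat_factors(), "mold_odor")) {
    expect_identical(concordance_rate(camp, b, f), 100)
  }
  b2 <- generate_observer_pair(camp, 0.75, seed = 6)
  expect_true(is_clean(validate_campaign(b2)))
  se <- sqrt(0.75 * 0.25 / 1000)
  for (f in c(dmat_factors(), "mold_odor")) {
    expect_lt(abs(concordance_rate(camp, b2, f) / 100 - 0.75), 3 * se)
  }
  expect_error(generate_observer_pair(camp, 1.5), "agreement_prob")
})

test_that("microbial generation shifts contamination with room score", {
  camp <- generate_campaign(campaign_spec(n_buildings = 2,
                                          rooms_per_building = 100,
                                          seed = 40))
  mb <- generate_microbial(camp, microbial_spec(score_effect = 0.3,
                                                seed = 41))
  expect_identical(mb, generate_microbial(camp, microbial_spec(
    score_effect = 0.3, seed = 41)))
  m <- mmei(mb)
  # rooms above the median score carry higher median MMEI
  med <- median(mb$room_score)
  hi <- m$mmei[mb$room_score > med]
  lo <- m$mmei[mb$room_score <= med]
  expect_gt(median(hi), median(lo))

  # null effect: MMEI roughly independent of score
  mb0 <- generate_microbial(
    generate_campaign(campaign_spec(n_buildings = 5,
                                    rooms_per_building = 100, seed = 42)),
    microbial_spec(score_effect = 0, seed = 43))
  rho0 <- cor(mb0$room_score, mmei(mb0)$mmei, method = "spearman")
  expect_lt(abs(rho0), 0.2)
})

test_that("invalid generator specifications are rejected", {
  expect_error(campaign_spec(severity_distribution = c(0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(campaign_spec(factor_prevalence = c(
    water_damage_stains = 1.2, visible_mold = 0, wet_damp = 0,
    mold_odor = 0)), "\\[0, 1\\]")
  expect_error(campaign_spec(factor_prevalence = c(visible_mold = 0.5)),
               "must name")
  expect_error(microbial_spec(sdlog = 0), "positive")
})

test_that("room-time tables reference campaign rooms with positive weights", {
  camp <- generate_campaign(campaign_spec(n_buildings = 1,
                                          rooms_per_building = 20, seed = 7))
  rt <- generate_room_time(camp, n_people = 20, seed = 9)
  keys <- vapply(camp, function(r) paste(r$building_id, r$room_id,
                                         sep = "/"), character(1))
  expect_true(all(rt$room_id %in% keys))
  expect_true(all(rt$weight > 0))
  scores <- setNames(vapply(camp, room_total, integer(1)), keys)
  tab <- twa_exposure_table(rt, scores)
  expect_identical(nrow(tab), 20L)
  expect_true(all(tab$exposure >= min(scores) & tab$exposure <= max(scores)))
})
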