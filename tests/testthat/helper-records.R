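# Fixture builders and independent naive oracles. The random record builder
# here deliberately bypasses the package's own campaign generator so that
# scoring/aggregation properties are checked on an independent path.

two_room_fixture <- function() {
  r1 <- room_assessment(
    "A", "101", "2024-05-01", floor_level = "1", room_type = "classroom",
    odor = odor_observation("mild", source_unknown = TRUE),
    observations = list(
      component_observation("ceiling", 2, 1, 0,
                            component_note = "acoustic tile"),
      component_observation("walls", 1, 0, 0, near_exterior_wall = TRUE),
      component_observation("floor"),
      component_observation("windows", 0, 0, 1,
                            assessment_note = "condensation on sill")))
  r2 <- room_assessment(
    "A", "102", "2024-05-01", floor_level = "1", room_type = "office",
    observations = lapply(c("ceiling", "walls", "floor"),
                          component_observation))
  list(r1, r2)
}

fixture_path <- function() {
  system.file("extdata", "two_room_example.csv", package = "dmat")
}

# A random valid room assessment, built directly from the constructors.
random_record <- function(building = "B1", room = "R1",
                          date = "2024-01-15", observer = "obs1") {
  comps <- c(basic <- c("ceiling", "walls", "floor"),
             sample(setdiff(dmat_components(), basic),
                    sample(0:5, 1)))
  comps <- intersect(dmat_components(), comps)  # canonical order
  obs <- lapply(comps, function(cc) {
    sc <- sample(0:3, 3, replace = TRUE, prob = c(0.55, 0.25, 0.12, 0.08))
    component_observation(cc, sc[1], sc[2], sc[3],
                          near_exterior_wall = any(sc > 0) &&
                            runif(1) < 0.3)
  })
  intensity <- sample(dmat_odor_intensities(), 1,
                      prob = c(0.7, 0.15, 0.1, 0.05))
  room_assessment(building, room, date, observer_id = observer,
                  odor = odor_observation(
                    intensity, source_unknown = intensity != "none" &&
                      runif(1) < 0.5),
                  observations = obs)
}

random_campaign <- function(n, buildings = 2) {
  lapply(seq_len(n), function(i) {
    random_record(building = paste0("B", 1 + (i - 1) %% buildings),
                  room = sprintf("R%03d", i))
  })
}

# Naive recomputation of every room summary, written as plain loops over a
# long table of scores — independent of the scoring module's formulas.
oracle_score <- function(record) {
  long <- do.call(rbind, lapply(record$observations, function(o) {
    data.frame(component = o$component,
               factor = c("water_damage_stains", "visible_mold", "wet_damp"),
               score = c(o$damage_stain, o$visible_mold, o$wet_damp))
  }))
  odor <- record$odor$score
  n <- length(unique(long$component))
  comp_tot <- tapply(long$score, long$component, sum)
  fac_avg <- tapply(long$score, long$factor, sum) / n
  total <- sum(long$score) + odor
  facs <- c("water_damage_stains", "visible_mold", "wet_damp")
  list(component_totals = setNames(as.integer(comp_tot[unique(long$component)]),
                                   unique(long$component)),
       room_total = total,
       factor_averages = setNames(as.numeric(fac_avg[facs]), facs),
       room_average = sum(fac_avg) + odor,
       n_components = n,
       color_band = if (total == 0) "none" else if (total <= 2) "green"
       else if (total <= 6) "yellow" else "red")
}
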