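test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(archetype_spectra = matrix(1 / 14, 14, 3)), "15 rows")
  bad <- default_archetype_spectra()
  bad[1, 1] <- bad[1, 1] + 0.1
  expect_error(simulation_config(archetype_spectra = bad), "sum to 1")
  expect_error(simulation_config(intra_series_gap_max = 200, gap_days = 180),
               "intra_series_gap_max")
  expect_error(simulation_config(n_centers = 2), "n_archetypes")
  expect_error(simulation_config(n_centers = 5, n_zip_areas = 3), "n_zip_areas")
})

test_that("a single intended series round-trips through the pipeline", {
  one_hot <- matrix(0, 15, 1, dimnames = list(series_types(), NULL))
  one_hot["E-NI-I", 1] <- 1
  cfg <- simulation_config(n_centers = 1, n_patients = 1,
                           archetype_spectra = one_hot,
                           mortality_by_type = setNames(rep(0, 15), series_types()),
                           seed = 5)
  reg <- generate_registry(cfg)
  cl <- classify_series(extract_event_series(reg$events, 180, 1826))
  expect_equal(cl$series_type, "E-NI-I")
  expect_equal(unname(reg$truth$patient_series_types), "E-NI-I")
})

test_that("generation is deterministic given the seed", {
  cfg <- simulation_config(n_centers = 4, n_patients = 200, spectrum_noise = 40,
                           seed = 9)
  r1 <- generate_registry(cfg)
  r2 <- generate_registry(cfg)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$truth, r2$truth)
  r3 <- generate_registry(simulation_config(n_centers = 4, n_patients = 200,
                                            spectrum_noise = 40, seed = 10))
  expect_false(identical(r1$events, r3$events))
})

test_that("intended series types are recovered exactly without noise or deaths", {
  cfg <- simulation_config(
    n_centers = 6, n_patients = 400, spectrum_noise = 0,
    archetype_spectra = separated_archetype_spectra(),
    mortality_by_type = setNames(rep(0, 15), series_types()), seed = 21
  )
  reg <- generate_registry(cfg)
  cl <- classify_series(extract_event_series(merge_phantom_events(reg$events),
                                             180, cfg$observation_days))
  expect_equal(nrow(cl), cfg$n_patients)
  expect_equal(cl$series_type,
               unname(reg$truth$patient_series_types[cl$patient_id]))
})

test_that("per-center spectra converge to the archetype with patient count", {
  arch <- default_archetype_spectra()[, 1, drop = FALSE]
  l1 <- function(n) {
    cfg <- simulation_config(n_centers = 1, n_patients = n,
                             archetype_spectra = arch, spectrum_noise = 0,
                             seed = 31)
    reg <- generate_registry(cfg)
    cl <- classify_series(extract_event_series(merge_phantom_events(reg$events),
                                               180, cfg$observation_days))
    emp <- spectrum_matrix(compute_spectra(cl, by = NULL))[1, ]
    sum(abs(emp - arch[, 1]))
  }
  d_small <- l1(200)
  d_large <- l1(20000)
  expect_lt(d_large, d_small)
  expect_lt(d_large, 0.02)
})

test_that("the invasive-only share matches its archetype at scale", {
  cfg <- simulation_config(n_centers = 3, n_patients = 20000, spectrum_noise = 0,
                           seed = 13)
  reg <- generate_registry(cfg)
  cl <- classify_series(extract_event_series(merge_phantom_events(reg$events),
                                             180, cfg$observation_days))
  cl <- assign_series_centers(cl, assign_dominant_centers(reg$events, "primary"))
  sp <- compute_spectra(cl)
  arch1_centers <- names(which(reg$truth$center_archetype == 1))
  m <- spectrum_matrix(sp)[arch1_centers, , drop = FALSE]
  i_share <- sum(m[, "I"] * sp$n_series[match(arch1_centers, sp$center_id)]) /
    sum(sp$n_series[match(arch1_centers, sp$center_id)])
  # archetype value: 10.28% renormalized by its column total
  expect_lt(abs(i_share - default_archetype_spectra()["I", 1]), 0.01)
})

test_that("registry CSV round trip is lossless and strict", {
  cfg <- simulation_config(n_centers = 3, n_patients = 40, seed = 2)
  reg <- generate_registry(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(reg$events, path)
  expect_identical(read_registry(path), reg$events)

  # header-only round trip
  write_registry(reg$events[0, ], path)
  rt <- read_registry(path)
  expect_equal(nrow(rt), 0L)
  expect_named(rt, names(reg$events))

  # malformed day field is reported with its file line
  writeLines(c("patient_id,day,zip,provider_id,procedure,death",
               "P1,200,Z1,C1,CA,0",
               "P2,not_a_day,Z1,C1,CA,0"), path)
  expect_error(read_registry(path), "line\\(s\\) 3")

  # unknown procedure codes are rejected
  writeLines(c("patient_id,day,zip,provider_id,procedure,death",
               "P1,200,Z1,C1,XRAY,0"), path)
  expect_error(read_registry(path), "XRAY")
})

test_that("generated events honor the structural contracts", {
  cfg <- simulation_config(n_centers = 5, n_patients = 500, spectrum_noise = 25,
                           seed = 17)
  reg <- generate_registry(cfg)
  ev <- reg$events
  expect_true(all(ev$day >= 0 & ev$day <= cfg$observation_days))
  # at most one death per patient, always last
  deaths <- ev[ev$death == 1L, ]
  expect_false(anyDuplicated(deaths$patient_id) > 0)
  last_care <- tapply(ev$day[ev$death == 0L], ev$patient_id[ev$death == 0L], max)
  expect_true(all(deaths$day >= last_care[deaths$patient_id]))
  # each patient's events all route to their ZIP's serving center
  per_pat <- dplyr::distinct(ev, patient_id, zip, provider_id)
  expect_false(anyDuplicated(per_pat$patient_id) > 0)
  expect_equal(unname(reg$truth$zip_center[per_pat$zip]), per_pat$provider_id)
  # every center appears exactly once in the archetype truth
  expect_named(reg$truth$center_archetype, sprintf("C%03d", 1:5))
})
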