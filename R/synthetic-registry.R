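## Synthetic reimbursement-registry generator with planted regional practice
## archetypes. Ground truth (center -> archetype, patient -> intended series
## type) is returned alongside the event table so every downstream stage can
## be tested for exact recovery.

#' Configure a synthetic registry simulation
#'
#' Builds a validated configuration for [generate_registry()]. Each ZIP area
#' is served by exactly one center; centers belong to practice-style
#' archetypes (contiguous blocks by default, mimicking regional practice
#' styles); every patient receives one intended event series whose type is
#' drawn from their center's pathway spectrum.
#'
#' @param n_centers Number of care centers.
#' @param n_zip_areas Number of ZIP areas (>= `n_centers`); ZIP areas are
#'   dealt to centers round-robin so each ZIP has exactly one serving center.
#' @param n_patients Number of patients.
#' @param archetype_spectra 15 x k matrix of archetype pathway spectra
#'   (columns sum to 1); defaults to the three reference cluster profiles of
#'   [default_archetype_spectra()].
#' @param spectrum_noise Dirichlet concentration controlling per-center
#'   deviation from its archetype: center spectra are drawn from
#'   Dirichlet(`spectrum_noise` * archetype). `0` disables deviation (every
#'   center uses its archetype spectrum exactly); larger values mean tighter
#'   adherence when noise is enabled.
#' @param zip_archetype_map Optional integer vector of length `n_zip_areas`
#'   assigning each ZIP area's center to an archetype; default: contiguous
#'   blocks of centers per archetype.
#' @param observation_days Observation horizon in days (day 0 = start).
#' @param gap_days Event-free gap (days) delimiting event series.
#' @param intra_series_gap_max Maximum gap between consecutive events inside
#'   one intended series; must be `< gap_days` so series never split.
#' @param mortality_by_type Named per-type 365-day death probability.
#' @param revasc_prob Conditional probability that a coronary angiography in
#'   an invasive block is followed by a revascularization (PCI or CABG).
#' @param repeat_event_prob Probability that a category block contains one
#'   duplicate event of the same category (exercises classification
#'   invariance to repeats).
#' @param seed RNG seed; the whole simulation is a deterministic function of
#'   the configuration.
#' @return A list of class `careflow_sim_config`.
#' @export
#' @examples
#' cfg <- simulation_config(n_centers = 6, n_patients = 300, seed = 1)
simulation_config <- function(n_centers = 30,
                              n_zip_areas = n_centers,
                              n_patients = 200 * n_centers,
                              archetype_spectra = default_archetype_spectra(),
                              spectrum_noise = 0,
                              zip_archetype_map = NULL,
                              observation_days = 1826,
                              gap_days = 180,
                              intra_series_gap_max = 30,
                              mortality_by_type = reference_mortality_by_type(),
                              revasc_prob = 0.04,
                              repeat_event_prob = 0.15,
                              seed = 1) {
  archetype_spectra <- as.matrix(archetype_spectra)
  n_archetypes <- ncol(archetype_spectra)
  if (nrow(archetype_spectra) != 15) {
    stop("archetype_spectra must have 15 rows (one per pathway type)", call. = FALSE)
  }
  if (any(archetype_spectra < 0) ||
      any(abs(colSums(archetype_spectra) - 1) > 1e-9)) {
    stop("each archetype spectrum must be nonnegative and sum to 1", call. = FALSE)
  }
  if (n_archetypes > n_centers) {
    stop("n_archetypes must not exceed n_centers", call. = FALSE)
  }
  if (n_zip_areas < n_centers) {
    stop("n_zip_areas must be >= n_centers (each center serves >= 1 ZIP)", call. = FALSE)
  }
  if (intra_series_gap_max >= gap_days) {
    stop("intra_series_gap_max must be < gap_days (one intended series would split)",
         call. = FALSE)
  }
  if (is.null(rownames(archetype_spectra))) rownames(archetype_spectra) <- .SERIES_TYPES
  mortality_by_type <- mortality_by_type[.SERIES_TYPES]
  if (anyNA(mortality_by_type) || any(mortality_by_type < 0 | mortality_by_type > 1)) {
    stop("mortality_by_type must give a probability for each of the 15 types",
         call. = FALSE)
  }
  # contiguous archetype blocks over centers, then zip -> center round-robin
  center_archetype <- as.integer(ceiling(seq_len(n_centers) * n_archetypes / n_centers))
  zip_center <- ((seq_len(n_zip_areas) - 1L) %% n_centers) + 1L
  if (!is.null(zip_archetype_map)) {
    stopifnot(length(zip_archetype_map) == n_zip_areas)
    # archetype is a property of the serving center; derive it from ZIPs
    for (z in seq_len(n_zip_areas)) {
      center_archetype[zip_center[z]] <- as.integer(zip_archetype_map[z])
    }
    if (any(center_archetype < 1L | center_archetype > n_archetypes)) {
      stop("zip_archetype_map entries must index archetypes", call. = FALSE)
    }
  }
  structure(list(
    n_centers = as.integer(n_centers),
    n_zip_areas = as.integer(n_zip_areas),
    n_patients = as.integer(n_patients),
    n_archetypes = n_archetypes,
    archetype_spectra = archetype_spectra,
    spectrum_noise = spectrum_noise,
    center_archetype = center_archetype,
    zip_center = zip_center,
    observation_days = as.integer(observation_days),
    gap_days = as.integer(gap_days),
    intra_series_gap_max = as.integer(intra_series_gap_max),
    mortality_by_type = mortality_by_type,
    revasc_prob = revasc_prob,
    repeat_event_prob = repeat_event_prob,
    seed = as.integer(seed)
  ), class = "careflow_sim_config")
}

#' @export
print.careflow_sim_config <- function(x, ...) {
  cat("<careflow simulation config>\n")
  cat(sprintf("  %d patients, %d centers (%d archetypes), %d ZIP areas\n",
              x$n_patients, x$n_centers, x$n_archetypes, x$n_zip_areas))
  cat(sprintf("  horizon %d days, series gap %d days, seed %d\n",
              x$observation_days, x$gap_days, x$seed))
  invisible(x)
}

#' Generate a synthetic reimbursement registry
#'
#' Simulates a time-stamped care-event table with planted ground truth. Each
#' patient has one intended event series: its type is drawn from the serving
#' center's spectrum, its events appear in the intended first-occurrence
#' order with intra-series gaps `<=` `intra_series_gap_max`, and it starts at
#' least `gap_days` days after observation start so that extraction +
#' classification reproduce the intended type exactly. Deaths are Bernoulli
#' draws per intended type, placed within 365 days of the index event (never
#' before the last care event, so a death cannot truncate a series).
#'
#' @param config A [simulation_config()].
#' @return A list with components
#'   \describe{
#'     \item{events}{tibble with columns `patient_id`, `day`, `zip`,
#'       `provider_id`, `procedure`, `death`, sorted canonically.}
#'     \item{truth}{list with `center_archetype` (named integer vector),
#'       `patient_series_types` (named character vector of intended types)
#'       and `zip_center` (named character vector, ZIP -> serving center).}
#'   }
#' @export
#' @examples
#' reg <- generate_registry(simulation_config(n_centers = 4, n_patients = 50, seed = 7))
#' head(reg$events)
generate_registry <- function(config) {
  stopifnot(inherits(config, "careflow_sim_config"))
  withr::with_seed(config$seed, .generate_registry_impl(config))
}

.generate_registry_impl <- function(cfg) {
  center_ids <- sprintf("C%03d", seq_len(cfg$n_centers))
  zip_ids <- sprintf("Z%04d", seq_len(cfg$n_zip_areas))
  patient_ids <- sprintf("P%06d", seq_len(cfg$n_patients))

  # per-center spectra: archetype, optionally Dirichlet-perturbed
  base <- cfg$archetype_spectra[, cfg$center_archetype, drop = FALSE]
  if (cfg$spectrum_noise > 0) {
    spectra <- .rdirichlet_cols(base, cfg$spectrum_noise)
  } else {
    spectra <- t(base)
  }
  # spectra: n_centers x 15

  zip_idx <- sample.int(cfg$n_zip_areas, cfg$n_patients, replace = TRUE)
  center_idx <- cfg$zip_center[zip_idx]

  labels <- character(cfg$n_patients)
  for (c in seq_len(cfg$n_centers)) {
    rows <- which(center_idx == c)
    if (length(rows) > 0) {
      labels[rows] <- sample(.SERIES_TYPES, length(rows), replace = TRUE,
                             prob = spectra[c, ])
    }
  }

  ev <- .build_series_events(labels, cfg)
  ev$zip <- zip_ids[zip_idx[ev$patient]]
  ev$provider_id <- center_ids[center_idx[ev$patient]]
  ev$patient_id <- patient_ids[ev$patient]

  events <- tibble::tibble(
    patient_id = ev$patient_id,
    day = as.integer(ev$day),
    zip = ev$zip,
    provider_id = ev$provider_id,
    procedure = ev$procedure,
    death = as.integer(ev$procedure == .DEATH_CODE)
  )
  events <- arrange_timeline(events)

  truth <- list(
    center_archetype = setNames(cfg$center_archetype, center_ids),
    patient_series_types = setNames(labels, patient_ids),
    zip_center = setNames(center_ids[cfg$zip_center], zip_ids)
  )
  list(events = events, truth = truth)
}

# Dirichlet draw per column of a 15 x n mean matrix with concentration kappa
.rdirichlet_cols <- function(means, kappa) {
  out <- apply(means, 2, function(p) {
    g <- rgamma(length(p), shape = kappa * p)
    if (sum(g) == 0) p else g / sum(g)
  })
  t(out)  # n x 15
}

# Expand intended labels into concrete per-patient event streams.
# Returns a data frame with columns patient (index), day, procedure.
.build_series_events <- function(labels, cfg) {
  n <- length(labels)
  cats_list <- strsplit(labels, "-", fixed = TRUE)
  n_cats <- lengths(cats_list)

  # one row per (patient, category block)
  pat <- rep.int(seq_len(n), n_cats)
  cat <- unlist(cats_list, use.names = FALSE)
  pos <- sequence(n_cats)

  # events per block: base event, optional duplicate, optional revasc after CA
  dup <- runif(length(cat)) < cfg$repeat_event_prob
  revasc <- cat == "I" & runif(length(cat)) < cfg$revasc_prob

  base_proc <- character(length(cat))
  base_proc[cat == "E"] <- "ECG_STRESS"
  ni <- cat == "NI"
  base_proc[ni] <- sample(c("ECHO_STRESS", "SPECT"), sum(ni), replace = TRUE)
  base_proc[cat == "I"] <- "CA"

  n_ev <- 1L + dup + revasc
  epat <- rep.int(pat, n_ev)
  epos <- rep.int(pos, n_ev)
  eproc <- character(sum(n_ev))
  idx <- cumsum(n_ev)
  start <- idx - n_ev + 1L
  eproc[start] <- base_proc
  # duplicates repeat the block's base procedure (for I, a second CA)
  eproc[start[dup] + 1L] <- base_proc[dup]
  rv_slot <- start[revasc] + 1L + dup[revasc]
  eproc[rv_slot] <- sample(c("PCI", "CABG"), sum(revasc), replace = TRUE)

  # order within patient = block order, then slot order; draw gaps
  ord <- order(epat, epos, seq_along(epat))
  epat <- epat[ord]; eproc <- eproc[ord]
  first_of_patient <- !duplicated(epat)
  gaps <- sample.int(cfg$intra_series_gap_max, length(epat), replace = TRUE)
  gaps[first_of_patient] <- 0L
  rel_day <- stats::ave(gaps, epat, FUN = cumsum)
  span <- stats::ave(rel_day, epat, FUN = max)[first_of_patient]

  upper <- cfg$observation_days - 366L - span
  if (any(upper < cfg$gap_days)) {
    stop("observation_days too short for the configured series length; ",
         "increase the horizon or reduce intra_series_gap_max", call. = FALSE)
  }
  index_day <- cfg$gap_days + floor(runif(n) * (upper - cfg$gap_days + 1L))
  day <- index_day[epat] + rel_day

  out <- data.frame(patient = epat, day = day, procedure = eproc)

  # deaths: Bernoulli per intended type, placed in (last event, index + 365]
  p_die <- cfg$mortality_by_type[labels]
  dies <- runif(n) < p_die
  if (any(dies)) {
    last_day <- index_day + span
    room <- pmax(1L, index_day + 365L - last_day)
    death_day <- last_day[dies] + 1L + floor(runif(sum(dies)) * (room[dies] - 1L + 1L)) - 1L
    death_day <- pmin(death_day, index_day[dies] + 365L)
    death_day <- pmax(death_day, last_day[dies] + 1L)
    out <- rbind(out, data.frame(
      patient = which(dies), day = death_day, procedure = .DEATH_CODE
    ))
  }
  out
}

#' Write / read a registry event table
#'
#' CSV round trip for the six-column registry schema
#' (`patient_id,day,zip,provider_id,procedure,death`). Reading validates the
#' schema strictly and reports malformed rows with their file line numbers.
#'
#' @param events Registry event tibble.
#' @param path File path.
#' @return `write_registry()` returns `path` invisibly; `read_registry()`
#'   returns the event tibble.
#' @export
write_registry <- function(events, path) {
  .validate_registry_cols(events)
  readr::write_csv(events[.REGISTRY_COLS], path)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  # parsing issues are re-raised below as errors with line numbers
  events <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      day = readr::col_integer(),
      zip = readr::col_character(),
      provider_id = readr::col_character(),
      procedure = readr::col_character(),
      death = readr::col_integer()
    )
  ))
  probs <- readr::problems(events)
  if (nrow(probs) > 0) {
    lines <- paste(utils::head(unique(probs$row), 5), collapse = ", ")
    stop("malformed registry rows at file line(s) ", lines,
         " (first issue: expected ", probs$expected[1],
         ", got '", probs$actual[1], "')", call. = FALSE)
  }
  .validate_registry_cols(events)
  attr(events, "spec") <- NULL
  attr(events, "problems") <- NULL
  events
}

.validate_registry_cols <- function(events) {
  missing <- setdiff(.REGISTRY_COLS, names(events))
  if (length(missing) > 0) {
    stop("registry table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(events$procedure), c(names(.PROC_CATEGORY), .DEATH_CODE))
  if (length(bad) > 0) {
    stop("unknown procedure code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (nrow(events) > 0 && any(events$day < 0)) {
    stop("event days must be >= 0", call. = FALSE)
  }
  invisible(events)
}
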