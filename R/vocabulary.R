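## Procedure vocabulary, category scheme, canonical pathway-type order and
## the reference tariff / cluster tables used as fixtures throughout.

# procedure -> category lookup; DEATH is a marker, not a care procedure
.PROC_CATEGORY <- c(
  ECG_STRESS  = "E",
  ECHO_STRESS = "NI",
  SPECT       = "NI",
  CA          = "I",
  CABG        = "I",
  PCI         = "I"
)

.DEATH_CODE <- "DEATH"

.CATEGORIES <- c("E", "NI", "I")

# canonical order of the 15 pathway types; every spectrum, table and report
# uses this ordering
.SERIES_TYPES <- c(
  "E", "E-NI", "E-NI-I", "E-I", "E-I-NI",
  "NI", "NI-E", "NI-E-I", "NI-I", "NI-I-E",
  "I", "I-E", "I-E-NI", "I-NI", "I-NI-E"
)

.REGISTRY_COLS <- c("patient_id", "day", "zip", "provider_id", "procedure", "death")

#' Procedure codes and their care categories
#'
#' The event vocabulary covers six ischemic-heart-disease work-up procedures
#' in three categories: `E` (non-invasive, non-imaging: stress ECG), `NI`
#' (non-invasive imaging: stress echocardiography, SPECT) and `I` (invasive:
#' coronary angiography, PCI, CABG). A seventh code, `"DEATH"`, marks a
#' patient's death event; it carries no care category.
#'
#' @return A tibble with columns `procedure` and `category`.
#' @export
#' @examples
#' procedure_categories()
procedure_categories <- function() {
  tibble::tibble(
    procedure = names(.PROC_CATEGORY),
    category = unname(.PROC_CATEGORY)
  )
}

#' The 15 pathway (event-series) types in canonical order
#'
#' A series type is the hyphen-join of the distinct care categories of a
#' series' events in order of first occurrence, so the label space is the
#' set of non-empty ordered selections of distinct elements of
#' \{E, NI, I\}: 3 + 6 + 6 = 15 labels.
#'
#' @return Character vector of length 15.
#' @export
series_types <- function() .SERIES_TYPES

#' Map procedure codes to care categories
#'
#' @param procedure Character vector of procedure codes (see
#'   [procedure_categories()]). `"DEATH"` is not a care procedure and is
#'   rejected here; death rows are handled by the series machinery.
#' @return Character vector of categories (`"E"`, `"NI"` or `"I"`).
#' @export
#' @examples
#' categorize_event(c("ECG_STRESS", "SPECT", "CABG"))
categorize_event <- function(procedure) {
  bad <- setdiff(unique(procedure), names(.PROC_CATEGORY))
  if (length(bad) > 0) {
    stop("unknown procedure code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(.PROC_CATEGORY[procedure])
}

# categories for a mixed event stream; DEATH -> NA
.event_category <- function(procedure) {
  out <- .PROC_CATEGORY[procedure]
  out[procedure == .DEATH_CODE] <- NA_character_
  unname(out)
}

#' Per-procedure reimbursement tariff
#'
#' Averaged official reimbursement costs of the six procedures in Hungarian
#' forint (HUF) and euro (December 2008 exchange rate).
#'
#' @return A tibble with columns `procedure`, `cost_huf`, `cost_eur`.
#' @export
#' @examples
#' default_tariff()
default_tariff <- function() {
  tibble::tibble(
    procedure = c("ECG_STRESS", "ECHO_STRESS", "SPECT", "CA", "PCI", "CABG"),
    cost_huf = c(3408, 12962, 35379, 145274, 804834, 1262914),
    cost_eur = c(13, 49, 134, 549, 3040, 4770)
  )
}

#' Reference per-cluster characterization table
#'
#' The published characterization of the three Hungarian provider clusters:
#' per-cluster percentage of each of the 15 pathway types, series counts,
#' revascularization rate, 365-day mortality, average series cost (HUF) and
#' average intra-cluster correlation, together with the pooled
#' whole-population column. Used as the default archetype definition of the
#' synthetic generator and as the input of the in-table arithmetic
#' consistency checks.
#'
#' @return A tibble with columns `feature`, `cluster_1`, `cluster_2`,
#'   `cluster_3`, `pooled`. The first 15 rows are pathway-type percentages;
#'   the remaining rows are `n_series`, `revasc_rate_pct`, `mort365_pct`,
#'   `avg_cost_huf` and `intra_corr` (pooled intra-correlation is `NA`).
#' @export
reference_cluster_table <- function() {
  tibble::tribble(
    ~feature,          ~cluster_1, ~cluster_2, ~cluster_3, ~pooled,
    "E",                    75.61,      76.49,      75.99,   76.11,
    "E-NI",                  2.32,       3.84,       3.44,    3.33,
    "E-NI-I",                0.51,       0.80,       0.71,    0.70,
    "E-I",                   5.09,       3.39,       4.41,    4.15,
    "E-I-NI",                0.08,       0.12,       0.17,    0.12,
    "NI",                    3.27,       6.55,       4.30,    5.00,
    "NI-E",                  0.02,       0.14,       0.08,    0.09,
    "NI-E-I",                0.01,       0.04,       0.02,    0.02,
    "NI-I",                  0.58,       1.15,       0.75,    0.88,
    "NI-I-E",                0.09,       0.12,       0.11,    0.11,
    "I",                    10.28,       6.04,       8.18,    7.80,
    "I-E",                   1.88,       1.02,       1.40,    1.36,
    "I-E-NI",                0.03,       0.04,       0.05,    0.04,
    "I-NI",                  0.16,       0.17,       0.26,    0.19,
    "I-NI-E",                0.01,       0.01,       0.05,    0.02,
    "n_series",            130327,     217514,     158246,  506087,
    "revasc_rate_pct",       4.63,       3.09,       4.05,    3.79,
    "mort365_pct",           1.38,       1.45,       1.61,    1.48,
    "avg_cost_huf",         75783,      54182,      66953,   63738,
    "intra_corr",            0.38,       0.12,       0.37,      NA
  )
}

#' Reference 365-day mortality by pathway type
#'
#' Whole-population 365-day mortality of each pathway type, used as the
#' generator's default per-type death probability.
#'
#' @return Named numeric vector (proportions) over the 15 types.
#' @export
reference_mortality_by_type <- function() {
  setNames(
    c(0.0077, 0.0076, 0.0064, 0.0162, 0.0045,
      0.0233, 0.0119, 0.0072, 0.0283, 0.0071,
      0.0803, 0.0164, 0.0175, 0.0456, 0),
    .SERIES_TYPES
  )
}

#' Default practice-style archetype spectra
#'
#' The three reference cluster columns of [reference_cluster_table()],
#' renormalized to probability vectors over the 15 pathway types. These are
#' the default planted archetypes of the synthetic registry.
#'
#' @return A 15 x 3 matrix; rows are pathway types in canonical order,
#'   columns are archetypes, each column sums to 1.
#' @export
default_archetype_spectra <- function() {
  tab <- reference_cluster_table()
  m <- as.matrix(tab[match(.SERIES_TYPES, tab$feature), c("cluster_1", "cluster_2", "cluster_3")])
  m <- sweep(m, 2, colSums(m), "/")
  dimnames(m) <- list(.SERIES_TYPES, paste0("archetype_", 1:3))
  m
}

#' Well-separated practice archetypes (test scaffolding)
#'
#' Constructs archetype spectra with low pairwise Pearson correlation by
#' concentrating each archetype's mass on a different pathway family
#' (E-led, NI-led, I-led). Real cluster profiles are far more collinear;
#' this construction exists to exercise planted-partition recovery, where a
#' detectable community structure mathematically requires the archetype
#' spectra themselves to be weakly correlated.
#'
#' @param n_archetypes Number of archetypes (2 to 3).
#' @param weight Mass placed on each archetype's anchor types (rest spread
#'   uniformly).
#' @return A 15 x `n_archetypes` column-stochastic matrix.
#' @export
separated_archetype_spectra <- function(n_archetypes = 3, weight = 0.75) {
  stopifnot(n_archetypes >= 2, n_archetypes <= 3, weight > 0, weight < 1)
  anchors <- list(
    c("E", "E-NI", "E-I"),
    c("NI", "NI-E", "NI-I"),
    c("I", "I-E", "I-NI")
  )[seq_len(n_archetypes)]
  m <- vapply(anchors, function(a) {
    p <- rep((1 - weight) / (15 - length(a)), 15)
    names(p) <- .SERIES_TYPES
    p[a] <- weight / length(a)
    p
  }, numeric(15))
  dimnames(m) <- list(.SERIES_TYPES, paste0("archetype_", seq_len(n_archetypes)))
  m
}
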