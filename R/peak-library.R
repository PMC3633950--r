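#' Curated 13C assignment table for stratum corneum components
#'
#' Loads the shipped chemical-shift assignment table covering the prominent
#' resonances of intact stratum corneum: lipid-chain methylene/methyl peaks,
#' cholesterol ring carbons, and the keratin coiled-coil core and
#' glycine/serine-rich terminal-domain markers.  The table is seeded from the
#' shifts printed in the running text and figure captions of the underlying
#' assignment work; each entry carries a `source` tag so user-supplied
#' extension tables (e.g. a complete supplementary assignment) can be merged
#' with [merge_peak_tables()].
#'
#' @param path Optional path to a user CSV with the same columns
#'   (`shift_ppm`, `moiety`, `component_class`, `multiplicity`, `source`,
#'   optionally `notes`); when supplied it is merged over the shipped table,
#'   user entries taking precedence on matching moiety names.
#'
#' @return Tibble with columns `shift_ppm`, `moiety`, `component_class`,
#'   `multiplicity`, `source`, `notes`.  `multiplicity` is `NA` for carbons
#'   without directly bonded protons (carbonyls).
#' @examples
#' sc_peak_table()
#' @export
sc_peak_table <- function(path = NULL) {
  base <- .read_peak_csv(system.file("extdata", "sc_assignments.csv",
                                     package = "ptnmr", mustWork = TRUE))
  if (is.null(path)) return(base)
  merge_peak_tables(.read_peak_csv(path), base)
}

.read_peak_csv <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           shift_ppm = readr::col_double(),
                           moiety = readr::col_character(),
                           component_class = readr::col_character(),
                           multiplicity = readr::col_integer(),
                           .default = readr::col_character()))
  classes <- c("lipid_chain", "cholesterol", "keratin_core",
               "keratin_terminal", "cornified_envelope", "mixed")
  if (!all(c("shift_ppm", "moiety", "component_class", "multiplicity") %in%
           names(tbl))) {
    pt_data_error("Assignment table must have columns shift_ppm, moiety, component_class, multiplicity.")
  }
  if (any(tbl$shift_ppm < 0 | tbl$shift_ppm > 220)) {
    pt_data_error("Assignment shifts must lie in [0, 220] ppm.")
  }
  bad <- setdiff(unique(tbl$component_class), classes)
  if (length(bad) > 0) {
    pt_data_error(sprintf("Unknown component_class value(s): %s",
                          paste(bad, collapse = ", ")))
  }
  if (any(!is.na(tbl$multiplicity) & !tbl$multiplicity %in% 1:3)) {
    pt_data_error("`multiplicity` must be 1, 2, 3 or NA.")
  }
  if (anyDuplicated(tbl[, c("shift_ppm", "moiety")])) {
    pt_data_error("Assignment entries must be unique on (shift_ppm, moiety).")
  }
  if (!"notes" %in% names(tbl)) tbl$notes <- NA_character_
  dplyr::arrange(tbl, .data$shift_ppm)
}

#' Merge assignment tables by precedence
#'
#' @param user,base Assignment tibbles as returned by [sc_peak_table()];
#'   `user` entries replace `base` entries whose normalized moiety name
#'   matches.
#' @return Merged tibble sorted by shift.
#' @export
merge_peak_tables <- function(user, base) {
  keep <- !(.normalize_moiety(base$moiety) %in% .normalize_moiety(user$moiety))
  dplyr::arrange(dplyr::bind_rows(base[keep, ], user), .data$shift_ppm)
}

.normalize_moiety <- function(x) {
  gsub("[ _()/-]", "", tolower(x))
}

#' Look up the tabulated shift of a moiety
#'
#' Case-, space- and punctuation-insensitive lookup in the assignment table.
#'
#' @param moiety Moiety name, e.g. `"Gly C_alpha"` or `"(CH2)n all-trans"`.
#' @param table Assignment table; defaults to [sc_peak_table()].
#' @return The tabulated shift in ppm.
#' @examples
#' lookup_shift("Gly C_alpha")   # 43.7
#' lookup_shift("Ser C_beta")    # 62.4
#' @export
lookup_shift <- function(moiety, table = sc_peak_table()) {
  key <- .normalize_moiety(moiety)
  hit <- which(.normalize_moiety(table$moiety) == key)
  if (length(hit) == 0) {
    dist <- utils::adist(key, .normalize_moiety(table$moiety))
    near <- table$moiety[order(dist)][1:min(3, nrow(table))]
    abort(sprintf("Unknown moiety \"%s\". Nearest names: %s.",
                  moiety, paste(near, collapse = ", ")),
          class = c("ptnmr_lookup_error", "ptnmr_error"))
  }
  table$shift_ppm[hit[1]]
}

#' All assignment entries within a chemical-shift window
#'
#' @param lo_ppm,hi_ppm Window bounds in ppm, `lo_ppm < hi_ppm`.
#' @inheritParams lookup_shift
#' @return Entries with `shift_ppm` in `[lo_ppm, hi_ppm]`, sorted by shift.
#' @examples
#' peaks_in_window(14, 15)
#' @export
peaks_in_window <- function(lo_ppm, hi_ppm, table = sc_peak_table()) {
  if (!is.numeric(lo_ppm) || !is.numeric(hi_ppm) || lo_ppm >= hi_ppm) {
    pt_usage_error("`lo_ppm` must be smaller than `hi_ppm`.")
  }
  dplyr::arrange(
    dplyr::filter(table, .data$shift_ppm >= lo_ppm, .data$shift_ppm <= hi_ppm),
    .data$shift_ppm)
}

#' Signature-peak windows for one component group
#'
#' Returns the canonical signature windows used to follow one component
#' group across a hydration or temperature series: lipids (all-trans and
#' trans/gauche `(CH2)n`, `(omega-1)CH2`, `omega CH3`), keratin terminal
#' domains (Gly C_alpha, Ser C_alpha, Ser C_beta), the keratin core
#' (Leu C_beta / Lys C_epsilon, plus the broad backbone C_alpha region) and
#' the mobile-cholesterol lines.  Windows flagged `use_for_calls = FALSE`
#' (the 53-60 ppm C_alpha envelope and the cholesterol line overlapping the
#' 40.6 ppm core peak) are context windows: they overlap other groups'
#' markers and are excluded from default per-window state calls.
#'
#' @param group One of `"lipids"`, `"keratin_core"`, `"keratin_terminals"`,
#'   `"cholesterol_mobile"`.
#' @param window_half_width_ppm Half width of each call window, ppm.
#' @param calpha_region Bounds of the keratin backbone C_alpha context
#'   window, ppm.
#' @inheritParams lookup_shift
#'
#' @return Tibble of class `signature_set` with columns `group`, `moiety`,
#'   `shift_ppm`, `lo_ppm`, `hi_ppm`, `use_for_calls`.
#' @examples
#' signature_set("lipids")
#' @export
signature_set <- function(group,
                          window_half_width_ppm = 0.3,
                          calpha_region = c(53, 60),
                          table = sc_peak_table()) {
  groups <- list(
    lipids = c("(CH2)n all-trans", "(CH2)n trans/gauche",
               "(omega-1) CH2", "omega CH3"),
    keratin_terminals = c("Gly C_alpha", "Ser C_alpha", "Ser C_beta"),
    keratin_core = c("Leu C_beta / Lys C_epsilon", "keratin C_alpha region"),
    cholesterol_mobile = c("cholesterol C4", "cholesterol C9",
                           "cholesterol C14/C17", "cholesterol C24/C12")
  )
  if (!is.character(group) || length(group) != 1 || !group %in% names(groups)) {
    pt_usage_error(sprintf("`group` must be one of: %s.",
                           paste(names(groups), collapse = ", ")))
  }
  moieties <- groups[[group]]
  shifts <- vapply(moieties, lookup_shift, numeric(1), table = table)
  out <- tibble(
    group = group, moiety = moieties, shift_ppm = unname(shifts),
    lo_ppm = shifts - window_half_width_ppm,
    hi_ppm = shifts + window_half_width_ppm,
    use_for_calls = TRUE
  )
  # context windows that overlap other groups' markers
  if (group == "keratin_core") {
    i <- out$moiety == "keratin C_alpha region"
    out$lo_ppm[i] <- calpha_region[1]
    out$hi_ppm[i] <- calpha_region[2]
    out$use_for_calls[i] <- FALSE
  }
  if (group == "cholesterol_mobile") {
    i <- out$moiety == "cholesterol C24/C12"
    out$lo_ppm[i] <- 40.4
    out$hi_ppm[i] <- 40.9
    out$use_for_calls[i] <- FALSE
  }
  class(out) <- c("signature_set", class(out))
  out
}

#' All signature windows of the four canonical groups
#'
#' Convenience wrapper binding [signature_set()] over all groups; the
#' default window set used by [classify_peaks()] and [series_report()].
#'
#' @inheritParams signature_set
#' @return Tibble with one row per signature window.
#' @export
sc_signatures <- function(window_half_width_ppm = 0.3,
                          table = sc_peak_table()) {
  dplyr::bind_rows(lapply(
    c("lipids", "keratin_terminals", "keratin_core", "cholesterol_mobile"),
    signature_set, window_half_width_ppm = window_half_width_ppm,
    table = table))
}
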