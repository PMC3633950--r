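#' Bundle DP, CP and INEPT spectra of one sample
#'
#' @param dp,cp,inept `nmr_spectrum` objects on identical ppm axes.
#' @param sample_state Optional list of state metadata (RH, water content,
#'   temperature, seed).
#' @return List of class `spectrum_triplet`.
#' @export
spectrum_triplet <- function(dp, cp, inept, sample_state = NULL) {
  for (s in list(dp, cp, inept)) stopifnot(inherits(s, "nmr_spectrum"))
  if (!isTRUE(all.equal(dp$ppm, cp$ppm)) ||
      !isTRUE(all.equal(dp$ppm, inept$ppm))) {
    pt_data_error("DP, CP and INEPT spectra must share the same ppm axis.")
  }
  structure(list(dp = dp, cp = cp, inept = inept,
                 sample_state = sample_state),
            class = "spectrum_triplet")
}

#' @export
print.spectrum_triplet <- function(x, ...) {
  st <- x$sample_state
  cat(sprintf("<spectrum_triplet> %d points%s\n", nrow(x$dp),
              if (!is.null(st)) sprintf(", RH %g%%, %g C",
                                        st$rh_percent, st$temperature_c) else ""))
  invisible(x)
}

#' Integrated peak area in a chemical-shift window
#'
#' Trapezoidal integration over `[lo_ppm, hi_ppm]` after subtracting the
#' local linear baseline through the window edges (each edge level is the
#' median of a few outermost points).  Negative net areas are floored at
#' zero; the signed value is returned in the `"signed"` attribute.
#'
#' @param spectrum An `nmr_spectrum`.
#' @param lo_ppm,hi_ppm Window bounds, ppm, inside the axis.
#' @param edge_points Number of points defining each edge level.
#' @return Non-negative area (intensity x ppm).
#' @export
measure_peak <- function(spectrum, lo_ppm, hi_ppm, edge_points = 3) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  if (lo_ppm >= hi_ppm) pt_usage_error("`lo_ppm` must be smaller than `hi_ppm`.")
  if (lo_ppm < min(spectrum$ppm) || hi_ppm > max(spectrum$ppm)) {
    pt_data_error("Window lies (partly) outside the spectral axis.")
  }
  sel <- which(spectrum$ppm >= lo_ppm & spectrum$ppm <= hi_ppm)
  if (length(sel) < 2) pt_data_error("Window contains fewer than 2 axis points.")
  # axis is descending; integrate over ascending ppm
  ppm <- rev(spectrum$ppm[sel])
  y <- rev(spectrum$intensity[sel])
  k <- min(edge_points, length(y))
  left <- stats::median(head(y, k))
  right <- stats::median(tail(y, k))
  base <- left + (right - left) * (ppm - ppm[1]) / (ppm[length(ppm)] - ppm[1])
  yc <- y - base
  area <- sum(diff(ppm) * (head(yc, -1) + tail(yc, -1)) / 2)
  structure(max(0, area), signed = area)
}

#' Per-window DP/CP/INEPT amplitudes and dynamic-state calls
#'
#' Measures every signature window in the three spectra of a triplet and
#' converts each DP/CP/INEPT area triplet into a dynamic-state call with
#' [classify_regime()].  Presence thresholds are a fraction of the
#' per-scheme maximum area across call windows, after normalizing every
#' scheme by the sample's total DP area, which makes the calls invariant to
#' any common intensity rescaling.  A window showing INEPT without a
#' comparable CP counterpart is read as nearly isotropic reorientation
#' (`mobile_isotropic`); INEPT presence is the operational definition of
#' "mobile" throughout.
#'
#' @param triplet A [spectrum_triplet()].
#' @param signatures Signature windows (tibble with `group`, `moiety`,
#'   `lo_ppm`, `hi_ppm`, `use_for_calls`); defaults to [sc_signatures()].
#' @param frac Presence threshold as fraction of the per-scheme maximum.
#' @param comparable_band CP/INEPT ratio band read as comparable amplitudes.
#' @param calls_only Drop context windows (`use_for_calls = FALSE`)?
#'
#' @return Tibble with one row per window: group, moiety, window bounds,
#'   `amp_dp`, `amp_cp`, `amp_inept` (normalized areas) and `state_call`.
#' @export
classify_peaks <- function(triplet, signatures = sc_signatures(),
                           frac = 0.05, comparable_band = c(0.5, 2),
                           calls_only = TRUE) {
  stopifnot(inherits(triplet, "spectrum_triplet"))
  sig <- signatures
  if (calls_only && "use_for_calls" %in% names(sig)) {
    sig <- sig[sig$use_for_calls, ]
  }
  total_dp <- sum(abs(triplet$dp$intensity))
  if (total_dp == 0) total_dp <- 1
  amps <- purrr::pmap_dfr(
    sig[, c("lo_ppm", "hi_ppm")],
    function(lo_ppm, hi_ppm) {
      tibble(
        amp_dp = as.numeric(measure_peak(triplet$dp, lo_ppm, hi_ppm)) / total_dp,
        amp_cp = as.numeric(measure_peak(triplet$cp, lo_ppm, hi_ppm)) / total_dp,
        amp_inept = as.numeric(measure_peak(triplet$inept, lo_ppm, hi_ppm)) / total_dp
      )
    })
  out <- dplyr::bind_cols(
    sig[, intersect(c("group", "moiety", "shift_ppm", "lo_ppm", "hi_ppm"),
                    names(sig))],
    amps)
  cp_max <- max(out$amp_cp, 1e-300)
  in_max <- max(out$amp_inept, 1e-300)
  dp_max <- max(out$amp_dp, 1e-300)
  out$state_call <- classify_regime(
    out$amp_dp, out$amp_cp, out$amp_inept, frac = frac,
    cp_max = cp_max, inept_max = in_max, dp_max = dp_max,
    comparable_band = comparable_band)
  out
}

#' Series-level dynamics report over hydration or temperature states
#'
#' Applies [classify_peaks()] to an ordered series of spectrum triplets and
#' summarizes, per signature group: the state calls at every series point,
#' the per-group INEPT amplitude trend (sum over the group's call windows),
#' and whether the group's mobile signature increases monotonically along
#' the series.
#'
#' @param triplets List of [spectrum_triplet()]s ordered by RH or
#'   temperature; at least two.
#' @param by Name of the ordering variable in each triplet's
#'   `sample_state` (`"rh_percent"` or `"temperature_c"`).
#' @inheritParams classify_peaks
#'
#' @return List of class `series_report` with elements `calls` (long tibble
#'   of per-window calls with the series variable), `groups` (per-group
#'   INEPT trend summary) and `by`.
#' @export
series_report <- function(triplets, by = "rh_percent",
                          signatures = sc_signatures(), frac = 0.05) {
  if (!is.list(triplets) || length(triplets) < 2) {
    pt_usage_error("`series_report()` needs at least two states.")
  }
  vals <- vapply(triplets, function(tr) {
    stopifnot(inherits(tr, "spectrum_triplet"))
    v <- tr$sample_state[[by]]
    if (is.null(v)) pt_usage_error(sprintf("sample_state lacks `%s`.", by))
    as.numeric(v)
  }, numeric(1))
  if (is.unsorted(vals)) {
    pt_usage_error(sprintf("Triplets must be ordered by increasing `%s`.", by))
  }
  calls <- purrr::map2_dfr(triplets, vals, function(tr, v) {
    out <- classify_peaks(tr, signatures = signatures, frac = frac)
    out[[by]] <- v
    out
  })
  groups <- calls |>
    dplyr::group_by(.data$group, .data[[by]]) |>
    dplyr::summarise(inept = sum(.data$amp_inept), cp = sum(.data$amp_cp),
                     .groups = "drop_last") |>
    dplyr::summarise(
      inept_first = dplyr::first(.data$inept),
      inept_last = dplyr::last(.data$inept),
      monotone_increase = !is.unsorted(.data$inept, strictly = FALSE),
      trend = dplyr::case_when(
        dplyr::last(.data$inept) > 1.2 * dplyr::first(.data$inept) + 1e-12 ~ "increasing",
        dplyr::last(.data$inept) < 0.8 * dplyr::first(.data$inept) - 1e-12 ~ "decreasing",
        TRUE ~ "flat"),
      .groups = "drop")
  structure(list(calls = calls, groups = groups, by = by),
            class = "series_report")
}

#' @export
print.series_report <- function(x, ...) {
  cat(sprintf("<series_report> over %s (%d states)\n", x$by,
              length(unique(x$calls[[x$by]]))))
  print(x$groups)
  invisible(x)
}

#' @method tidy series_report
#' @export
tidy.series_report <- function(x, ...) x$calls

#' @method glance series_report
#' @export
glance.series_report <- function(x, ...) x$groups

#' Detect an abrupt mobility onset along a hydration series
#'
#' Scans a group's summed INEPT signature area along the ordered series and
#' returns the first adjacent pair of series values where the area rises
#' from below to at or above `onset_frac` of the series maximum — the
#' signature of an abrupt rigid-to-mobile transition.  Returns `NULL` when
#' the series never crosses (flat series, or gradual growth already above
#' the onset at the first state).
#'
#' @param report A [series_report()].
#' @param group Signature group to scan (e.g. `"keratin_terminals"`).
#' @param onset_frac Onset fraction of the series maximum; default 0.2.
#' @param floor_frac A group whose peak INEPT area stays below this fraction
#'   of the strongest group's is treated as INEPT-silent (noise), not as a
#'   candidate transition.
#' @return A named numeric vector `c(lo, hi)` of the bracketing series
#'   values, or `NULL`.
#' @export
detect_transition <- function(report, group, onset_frac = 0.2,
                              floor_frac = 0.02) {
  stopifnot(inherits(report, "series_report"))
  by <- report$by
  prof <- report$calls |>
    dplyr::filter(.data$group == !!group) |>
    dplyr::group_by(.data[[by]]) |>
    dplyr::summarise(inept = sum(.data$amp_inept), .groups = "drop") |>
    dplyr::arrange(.data[[by]])
  if (nrow(prof) < 2) pt_usage_error("Need at least two series points.")
  all_prof <- report$calls |>
    dplyr::group_by(.data$group, .data[[by]]) |>
    dplyr::summarise(inept = sum(.data$amp_inept), .groups = "drop")
  thr <- onset_frac * max(prof$inept)
  if (max(prof$inept) <= floor_frac * max(all_prof$inept)) return(NULL)
  below <- prof$inept < thr
  for (i in seq_len(nrow(prof) - 1)) {
    # a state change, not a spike: the signature must stay mobile from the
    # onset to the end of the series
    if (below[i] && !any(below[seq(i + 1, nrow(prof))])) {
      return(c(lo = prof[[by]][i], hi = prof[[by]][i + 1]))
    }
  }
  NULL
}
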