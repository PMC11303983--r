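#' Detect the tipping point along a stable-state sequence
#'
#' For every pair of consecutive gradient steps the change in system state
#' is measured as the larger of the two substrate changes (oxygen and
#' sulfide), by default on a log10 concentration scale.  The tipping point
#' is the pair with the maximum change, provided that change exceeds the
#' no-tipping floor; otherwise the response is classified as monostable and
#' a no-tipping result is returned (not an error).
#'
#' Ties in the maximum are broken toward the pair closest to the midpoint of
#' the scanned log10 oxygen-diffusivity range (and toward the lower step
#' index if still tied); tied detections are flagged.
#'
#' @param states A `stable_states` data frame (see [run_direction()]), or
#'   any data frame with columns `a_O`, `O`, `S` ordered along the gradient.
#' @param metric `"log10"` (default) or `"raw"`: scale on which substrate
#'   changes and shift magnitudes are measured.
#' @param no_tipping_floor Minimum state change, across one gradient step,
#'   that counts as a regime shift: 0.5 log10 units by default, 10 uM under
#'   the raw metric.
#' @return An object of class `tipping_point`: a list with elements
#'   `detected`, `transition` (`"anoxic_to_oxic"` or `"oxic_to_anoxic"`),
#'   `index` (step index before the jump), `location_a_O`,
#'   `location_log10_a_O` (log10 midpoint of the bracketing diffusivities),
#'   `magnitude_O`, `magnitude_S`, `total_magnitude`, `metric` and `tie`.
#'   When no change exceeds the floor, `detected` is `FALSE` and the
#'   numeric fields are `NA`.
#' @export
detect_tipping <- function(states, metric = c("log10", "raw"),
                           no_tipping_floor = NULL) {
  metric <- match.arg(metric)
  if (nrow(states) < 2L)
    stop("at least two stable states are required", call. = FALSE)
  if (is.null(no_tipping_floor))
    no_tipping_floor <- if (metric == "log10") 0.5 else 10
  tr <- if (metric == "log10") function(x) log10(pmax(x, 1e-12)) else identity
  dO <- diff(tr(states$O))
  dS <- diff(tr(states$S))
  change <- pmax(abs(dO), abs(dS))

  no_tip <- structure(
    list(detected = FALSE, transition = NA_character_, index = NA_integer_,
         location_a_O = NA_real_, location_log10_a_O = NA_real_,
         magnitude_O = NA_real_, magnitude_S = NA_real_,
         total_magnitude = NA_real_, metric = metric, tie = FALSE),
    class = "tipping_point")
  if (all(change < no_tipping_floor))
    return(no_tip)

  la <- log10(states$a_O)
  centre <- mean(range(la))
  mid <- (la[-length(la)] + la[-1L]) / 2
  best <- max(change)
  cand <- which(change >= best - 1e-12 * max(1, best))
  tie <- length(cand) > 1L
  # tie-break: closest to the centre of the gradient, then lowest index
  cand <- cand[order(abs(mid[cand] - centre), cand)]
  i <- cand[1L]

  structure(
    list(detected = TRUE,
         transition = if (dO[i] > 0) "anoxic_to_oxic" else "oxic_to_anoxic",
         index = i,
         location_a_O = 10^mid[i],
         location_log10_a_O = mid[i],
         magnitude_O = abs(dO[i]),
         magnitude_S = abs(dS[i]),
         total_magnitude = abs(dO[i]) + abs(dS[i]),
         metric = metric, tie = tie),
    class = "tipping_point")
}

#' @export
print.tipping_point <- function(x, ...) {
  if (!x$detected) {
    cat("No tipping point detected (monostable response)\n")
  } else {
    cat(sprintf(
      "Tipping point (%s): a_O = %.4g (log10 %.3f), magnitudes O %.3f, S %.3f (%s), total %.3f%s\n",
      x$transition, x$location_a_O, x$location_log10_a_O, x$magnitude_O,
      x$magnitude_S, x$metric, x$total_magnitude,
      if (x$tie) " [tied maximum]" else ""))
  }
  invisible(x)
}

#' Total shift magnitude of a tipping point
#'
#' The sum of the oxygen and sulfide shift magnitudes across the tipping
#' step: for an anoxic-to-oxic shift, the oxygen increase plus the sulfide
#' decrease (and conversely for oxic-to-anoxic).
#'
#' @param tp A `tipping_point`.
#' @return A nonnegative number, or `NA` for a no-tipping result.
#' @export
total_shift_magnitude <- function(tp) {
  stopifnot(inherits(tp, "tipping_point"))
  if (!tp$detected) return(NA_real_)
  tp$magnitude_O + tp$magnitude_S
}

#' Concentration attained on the branch established after a shift
#'
#' The stable-state concentration that a substrate reaches after its upward
#' shift: the maximum of the substrate over the gradient steps beyond the
#' tipping step.  This is the post-shift plateau read off a hysteresis
#' branch.
#'
#' @param states A `stable_states` data frame.
#' @param tp The `tipping_point` detected on `states`.
#' @param substance `"O"` or `"S"`.
#' @return Concentration in uM.
#' @export
post_shift_plateau <- function(states, tp, substance = c("O", "S")) {
  substance <- match.arg(substance)
  stopifnot(inherits(tp, "tipping_point"))
  if (!tp$detected)
    stop("no tipping point: there is no post-shift branch", call. = FALSE)
  max(states[[substance]][(tp$index + 1L):nrow(states)])
}

#' Response-symmetry report for a hysteresis experiment
#'
#' Detects the tipping point of each driver direction and assembles the
#' direction-to-direction comparison: the signed difference of the two total
#' shift magnitudes (zero for a perfectly symmetric response) and the
#' bistability width (distance between the two tipping locations on the
#' log10 oxygen-diffusivity axis).  Location shifts relative to a symmetric
#' reference run are filled in by [compare_to_symmetric()].
#'
#' @param hyst A `symtip_hysteresis` object (see [run_hysteresis()]).
#' @param metric,no_tipping_floor Passed to [detect_tipping()].
#' @return An object of class `symmetry_report`: a list with elements
#'   `tp_anoxic_to_oxic`, `tp_oxic_to_anoxic`, `total_anoxic_to_oxic`,
#'   `total_oxic_to_anoxic`, `magnitude_asymmetry`, `bistability_width`,
#'   `location_shift_up`, `location_shift_down` (the latter two `NA` until
#'   compared to a reference), `factor` and `metric`.
#' @export
analyze_hysteresis <- function(hyst, metric = c("log10", "raw"),
                               no_tipping_floor = NULL) {
  stopifnot(inherits(hyst, "symtip_hysteresis"))
  metric <- match.arg(metric)
  tp_up <- detect_tipping(hyst$toward_oxic, metric, no_tipping_floor)
  tp_dn <- detect_tipping(hyst$toward_anoxic, metric, no_tipping_floor)
  if (tp_up$detected && tp_up$transition != "anoxic_to_oxic")
    warning("transition detected on the toward-oxic run is not ",
            "anoxic-to-oxic", call. = FALSE)
  if (tp_dn$detected && tp_dn$transition != "oxic_to_anoxic")
    warning("transition detected on the toward-anoxic run is not ",
            "oxic-to-anoxic", call. = FALSE)
  tot_up <- total_shift_magnitude(tp_up)
  tot_dn <- total_shift_magnitude(tp_dn)
  width <- if (tp_up$detected && tp_dn$detected)
    tp_up$location_log10_a_O - tp_dn$location_log10_a_O else NA_real_
  structure(
    list(tp_anoxic_to_oxic = tp_up, tp_oxic_to_anoxic = tp_dn,
         total_anoxic_to_oxic = tot_up, total_oxic_to_anoxic = tot_dn,
         magnitude_asymmetry = tot_dn - tot_up,
         bistability_width = width,
         location_shift_up = NA_real_, location_shift_down = NA_real_,
         factor = hyst$factor, metric = metric),
    class = "symmetry_report")
}

#' Compare a symmetry report against a symmetric reference
#'
#' Fills in the tipping-location displacements of an (asymmetric)
#' configuration relative to a symmetric reference analyzed on a comparable
#' gradient: positive values mean the tipping point moved to higher oxygen
#' diffusivity.  Missing tipping points in either run leave the affected
#' fields `NA`.
#'
#' @param report A `symmetry_report` for the configuration of interest.
#' @param reference A `symmetry_report` for the symmetric reference run (or
#'   a `symtip_hysteresis`, which is analyzed with the same metric).
#' @return `report` with `location_shift_up` and `location_shift_down`
#'   filled in (log10 1/h units).
#' @export
compare_to_symmetric <- function(report, reference) {
  stopifnot(inherits(report, "symmetry_report"))
  if (inherits(reference, "symtip_hysteresis"))
    reference <- analyze_hysteresis(reference, report$metric)
  stopifnot(inherits(reference, "symmetry_report"))
  shift <- function(tp, tp_ref)
    if (tp$detected && tp_ref$detected)
      tp$location_log10_a_O - tp_ref$location_log10_a_O else NA_real_
  report$location_shift_up <- shift(report$tp_anoxic_to_oxic,
                                    reference$tp_anoxic_to_oxic)
  report$location_shift_down <- shift(report$tp_oxic_to_anoxic,
                                      reference$tp_oxic_to_anoxic)
  report
}

#' @export
print.symmetry_report <- function(x, ...) {
  cat("Response-symmetry report (metric:", x$metric, ")\n")
  cat("  anoxic->oxic: "); print(x$tp_anoxic_to_oxic)
  cat("  oxic->anoxic: "); print(x$tp_oxic_to_anoxic)
  cat(sprintf("  magnitude asymmetry (down - up): %.4f\n",
              x$magnitude_asymmetry))
  if (!is.na(x$bistability_width))
    cat(sprintf("  bistability width: %.3f log10 units\n",
                x$bistability_width))
  if (!is.na(x$location_shift_up))
    cat(sprintf("  location shifts vs reference: up %+.3f, down %+.3f\n",
                x$location_shift_up, x$location_shift_down))
  invisible(x)
}

.report_row <- function(report) {
  flags <- character(0)
  if (!report$tp_anoxic_to_oxic$detected) flags <- c(flags, "no_tipping_up")
  if (!report$tp_oxic_to_anoxic$detected) flags <- c(flags, "no_tipping_down")
  if (isTRUE(report$tp_anoxic_to_oxic$tie)) flags <- c(flags, "tie_up")
  if (isTRUE(report$tp_oxic_to_anoxic$tie)) flags <- c(flags, "tie_down")
  data.frame(
    location_up = report$tp_anoxic_to_oxic$location_log10_a_O,
    location_down = report$tp_oxic_to_anoxic$location_log10_a_O,
    total_up = report$total_anoxic_to_oxic,
    total_down = report$total_oxic_to_anoxic,
    magnitude_asymmetry = report$magnitude_asymmetry,
    location_shift_up = report$location_shift_up,
    location_shift_down = report$location_shift_down,
    bistability_width = report$bistability_width,
    flags = paste(flags, collapse = ";"))
}

.scan_core <- function(values, value_name, make_hyst, ref_value,
                       metric, no_tipping_floor, quiet) {
  reports <- vector("list", length(values))
  errors <- rep(NA_character_, length(values))
  run_one <- function(v) analyze_hysteresis(make_hyst(v), metric,
                                            no_tipping_floor)
  ref <- if (ref_value %in% values) NULL else run_one(ref_value)
  for (j in seq_along(values)) {
    r <- tryCatch(run_one(values[j]), error = function(e)
      conditionMessage(e))
    if (is.character(r)) errors[j] <- r else reports[[j]] <- r
    if (!quiet)
      message(value_name, " = ", values[j], ": ",
              if (is.na(errors[j])) "ok" else paste("FAILED:", errors[j]))
  }
  if (is.null(ref)) {
    jref <- match(ref_value, values)
    ref <- reports[[jref]]
    if (is.null(ref))
      stop("symmetric reference run failed: ", errors[jref], call. = FALSE)
  }
  rows <- lapply(seq_along(values), function(j) {
    if (!is.na(errors[j])) {
      row <- .report_row(structure(
        list(tp_anoxic_to_oxic = detect_no <- structure(
               list(detected = FALSE, location_log10_a_O = NA_real_,
                    tie = FALSE), class = "tipping_point"),
             tp_oxic_to_anoxic = detect_no,
             total_anoxic_to_oxic = NA_real_,
             total_oxic_to_anoxic = NA_real_,
             magnitude_asymmetry = NA_real_,
             bistability_width = NA_real_,
             location_shift_up = NA_real_, location_shift_down = NA_real_),
        class = "symmetry_report"))
      row$flags <- paste0("error: ", errors[j])
      row
    } else {
      .report_row(compare_to_symmetric(reports[[j]], ref))
    }
  })
  out <- cbind(stats::setNames(data.frame(values), value_name),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Scan system asymmetry (oxygen tolerance of the sulfur reducers)
#'
#' Runs the full hysteresis experiment for a sequence of oxygen
#' half-inhibition constants of the sulfur-reducing bacteria (`H_O`), with
#' the cyanobacteria constant and the environment held symmetric, and
#' summarizes each run's tipping points relative to the symmetric reference
#' (`H_O` equal to `H_S`, 100 uM).
#'
#' @param H_O_values Sequence of `H_O` values, uM.
#' @param params Base parameter set (symmetric defaults).
#' @param settings A `symtip_settings` object.
#' @param n_steps Gradient steps per direction.
#' @param metric,no_tipping_floor Passed to [detect_tipping()].
#' @param quiet Suppress per-row progress messages.
#' @return A data frame with one row per `H_O` value and columns `H_O`,
#'   `location_up`, `location_down` (log10 1/h), `total_up`, `total_down`,
#'   `magnitude_asymmetry`, `location_shift_up`, `location_shift_down`,
#'   `bistability_width`, `flags`.  Rows whose simulation failed carry the
#'   error message in `flags`; the scan itself is not aborted.
#' @export
scan_system_asymmetry <- function(H_O_values = seq(30, 170, by = 10),
                                  params = symmetric_parameters(),
                                  settings = sim_settings(),
                                  n_steps = 101L,
                                  metric = c("log10", "raw"),
                                  no_tipping_floor = NULL,
                                  quiet = TRUE) {
  metric <- match.arg(metric)
  if (any(H_O_values <= 0))
    stop("H_O values must be positive", call. = FALSE)
  .scan_core(H_O_values, "H_O",
             function(v) run_hysteresis(update_parameters(params, H_O = v),
                                        factor = 1, settings = settings,
                                        n_steps = n_steps),
             ref_value = params$H_S, metric = metric,
             no_tipping_floor = no_tipping_floor, quiet = quiet)
}

#' Scan environmental asymmetry (sulfide diffusivity range)
#'
#' Runs the hysteresis experiment for a sequence of environmental asymmetry
#' factors scaling the log10 half-width of the sulfide-diffusivity range,
#' with system-symmetric parameters, and summarizes each run relative to the
#' symmetric reference (factor 1).
#'
#' @param factors Sequence of asymmetry factors in `[0, 2]`.
#' @inheritParams scan_system_asymmetry
#' @return A data frame as in [scan_system_asymmetry()] with the first
#'   column named `factor`.
#' @export
scan_environmental_asymmetry <- function(factors = seq(0, 2, by = 0.2),
                                         params = symmetric_parameters(),
                                         settings = sim_settings(),
                                         n_steps = 101L,
                                         metric = c("log10", "raw"),
                                         no_tipping_floor = NULL,
                                         quiet = TRUE) {
  metric <- match.arg(metric)
  if (any(factors < 0))
    stop("asymmetry factors must be nonnegative", call. = FALSE)
  .scan_core(factors, "factor",
             function(v) run_hysteresis(params, factor = v,
                                        settings = settings,
                                        n_steps = n_steps),
             ref_value = 1, metric = metric,
             no_tipping_floor = no_tipping_floor, quiet = quiet)
}
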