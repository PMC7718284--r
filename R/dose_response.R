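# Dose-response summaries: allometric dose conversion, epoch-wise
# frequency/amplitude summaries, percent-change effect tables.

#' Allometric (body-surface-area) scaling parameters
#'
#' Km factors for converting doses between species by body surface area.
#' The printed rat Km is 6.2; note that reproducing every entry of the
#' published rat ladder from the human doses requires Km = 6 (the printed
#' 6.2 yields 2.1 rather than 2.2 mg/kg for the 25 mg/70 kg heroin dose),
#' so the value is configurable and the discrepancy is documented rather
#' than silently corrected.
#'
#' @param km_human,km_rat Km factors (dimensionless).
#' @param body_mass_human_kg reference human body mass.
#' @return an object of class `allometric_params`.
#' @export
allometric_params <- function(km_human = 37, km_rat = 6.2,
                              body_mass_human_kg = 70) {
  stop_if_not(km_human > 0 && km_rat > 0, "Km factors must be positive")
  structure(list(km_human = km_human, km_rat = km_rat,
                 body_mass_human_kg = body_mass_human_kg),
            class = "allometric_params")
}

#' Animal-equivalent dose conversion
#'
#' Human dose (mg/kg) = animal dose (mg/kg) x (rat Km / human Km); the
#' human-to-rat direction therefore multiplies by `km_human / km_rat`.
#' The round trip is the identity. Rounding (to the published precision)
#' is a presentation step: pass `digits` or keep the raw value.
#'
#' @param dose dose in mg/kg (positive).
#' @param direction `"human_to_rat"` or `"rat_to_human"`.
#' @param params an [allometric_params()] object.
#' @param digits optional decimal places for the returned dose.
#' @return converted dose (mg/kg).
#' @examples
#' # second human buprenorphine dose, 0.5 mg per 70 kg:
#' aed_convert(0.5 / 70, "human_to_rat", digits = 2)
#' @export
aed_convert <- function(dose, direction = c("human_to_rat", "rat_to_human"),
                        params = allometric_params(), digits = NULL) {
  direction <- match.arg(direction)
  stop_if_not(all(dose > 0), "`dose` must be positive")
  out <- if (direction == "human_to_rat") {
    dose * params$km_human / params$km_rat
  } else {
    dose * params$km_rat / params$km_human
  }
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Epoch-wise transient summaries
#'
#' Counts detected events into half-open dose epochs
#' `[t_dose, t_dose + epoch_length)` and reports the frequency
#' (transients/min) and mean amplitude per epoch. Events past the final
#' epoch are dropped with a warning; an empty epoch has frequency 0 and an
#' undefined (`NA`) amplitude.
#'
#' @param events a [detect_transients()] result (or any data frame with
#'   `time_s` and `amplitude_nM`).
#' @param schedule a [make_dose_schedule()] object covering the events.
#' @return data frame of class `epoch_summary`: `epoch_index`, `drug`,
#'   `cumulative_dose`, `n_events`, `frequency`, `mean_amplitude`,
#'   `amplitude_defined`.
#' @export
epoch_summary <- function(events, schedule) {
  stop_if_not(inherits(schedule, "dose_schedule"), "need a `dose_schedule`")
  stop_if_not(is.data.frame(events) && all(c("time_s", "amplitude_nM") %in%
                                             names(events)),
              "`events` must have time_s and amplitude_nM")
  stop_if_not(!is.unsorted(events$time_s), "`events` must be time-sorted")
  ep <- epoch_of(events$time_s, schedule)
  if (anyNA(ep)) {
    warning(sprintf("%d event(s) outside the dosing schedule dropped",
                    sum(is.na(ep))))
  }
  k <- n_epochs(schedule)
  mins <- schedule$epoch_length_s / 60
  n_ev <- tabulate(ep[!is.na(ep)], nbins = k)
  amp <- vapply(seq_len(k), function(i) {
    a <- events$amplitude_nM[!is.na(ep) & ep == i]
    if (length(a)) mean(a) else NA_real_
  }, numeric(1))
  out <- data.frame(epoch_index = seq_len(k),
                    drug = schedule$entries$drug,
                    cumulative_dose = schedule$entries$cumulative_dose,
                    n_events = n_ev,
                    frequency = n_ev / mins,
                    mean_amplitude = amp,
                    amplitude_defined = n_ev > 0)
  class(out) <- c("epoch_summary", "data.frame")
  out
}

#' Percent-change effect table versus the vehicle epoch
#'
#' For each subject, the percent change in transient frequency (and, where
#' defined, mean amplitude) of every epoch relative to that subject's
#' vehicle epoch; then the group mean and SEM per epoch. Subjects with a
#' zero vehicle frequency cannot be normalised and are excluded with a
#' warning.
#'
#' @param summaries either one `epoch_summary` or a list of them (one per
#'   subject), or a data frame with a `subject` column bound from several.
#' @return an object of class `effect_table`: `per_subject` and `group`
#'   data frames. The vehicle row of every subject is 0% by construction.
#' @export
percent_change <- function(summaries) {
  if (inherits(summaries, "epoch_summary")) summaries <- list(summaries)
  if (is.data.frame(summaries)) {
    stop_if_not("subject" %in% names(summaries),
                "bound summaries need a `subject` column")
    summaries <- split(summaries, summaries$subject)
  }
  per <- list()
  for (s in seq_along(summaries)) {
    es <- summaries[[s]]
    veh <- which(es$drug == "vehicle")[1]
    stop_if_not(!is.na(veh), "no vehicle epoch present")
    f0 <- es$frequency[veh]
    if (f0 <= 0) {
      warning(sprintf("subject %d has zero vehicle frequency; excluded", s))
      next
    }
    a0 <- es$mean_amplitude[veh]
    per[[length(per) + 1L]] <- data.frame(
      subject = s, epoch_index = es$epoch_index, drug = es$drug,
      cumulative_dose = es$cumulative_dose,
      frequency = es$frequency,
      pct_change_freq = 100 * (es$frequency - f0) / f0,
      pct_change_amp = if (!is.na(a0) && a0 > 0) {
        100 * (es$mean_amplitude - a0) / a0
      } else NA_real_)
  }
  stop_if_not(length(per) > 0, "no subject with a usable vehicle epoch")
  per <- do.call(rbind, per)
  grp <- do.call(rbind, lapply(split(per, per$epoch_index), function(d) {
    data.frame(epoch_index = d$epoch_index[1], drug = d$drug[1],
               cumulative_dose = d$cumulative_dose[1],
               n_subjects = nrow(d),
               mean_pct_change_freq = mean(d$pct_change_freq),
               sem_pct_change_freq = sd(d$pct_change_freq) /
                 sqrt(nrow(d)),
               mean_pct_change_amp = mean(d$pct_change_amp, na.rm = TRUE))
  }))
  rownames(grp) <- NULL
  structure(list(per_subject = per, group = grp), class = "effect_table")
}

#' @export
print.effect_table <- function(x, ...) {
  cat("<effect_table> group means vs vehicle:\n")
  print(x$group, digits = 3)
  invisible(x)
}

#' Write an effect table to CSV
#'
#' @param x an `effect_table`.
#' @param path output file path.
#' @param layer `"group"` or `"per_subject"`.
#' @return `path`, invisibly.
#' @export
write_effect_csv <- function(x, path, layer = c("group", "per_subject")) {
  layer <- match.arg(layer)
  write.csv(x[[layer]], path, row.names = FALSE)
  invisible(path)
}
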