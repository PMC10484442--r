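# Prescribed average daily dose (ADD) from dosing regimens.
#
# The ADD of a prescription with regimen components (d_i, f_i) over a dose
# interval of t days is sum(d_i * f_i) / t: the per-day dose implied by the
# treatment plan, independent of what was actually administered.

# convertible mass units, expressed in mg
.unit_to_mg <- c(g = 1000, mg = 1, mcg = 0.001, ug = 0.001)

#' Construct a dosing regimen
#'
#' A regimen holds one or more components, each a single-administration dose
#' `d` given `f` times per dose interval, plus the interval length in hours and
#' the prescription type. Missing fields (`NA`) are filled by [compute_add()]'s
#' default cascade.
#'
#' @param dose numeric vector of per-administration doses (one per component).
#' @param freq integer vector of administrations per interval (one per
#'   component).
#' @param interval_hours length of the dose interval, in hours.
#' @param unit dose unit label (e.g. `"mg"`).
#' @param rx_type prescription type: `"scheduled"`, `"one-time"`, `"PN"`
#'   (as needed) or `"VAO"` (variable dose).
#' @param strength package label strength per unit of volume, used when `dose`
#'   is missing.
#' @param volume prescribed volume, used with `strength`.
#' @return an object of class `"regimen"`.
#' @examples
#' regimen(dose = 200, freq = 3, interval_hours = 24)            # 600 mg/day
#' regimen(dose = c(50, 100), freq = c(3, 4), interval_hours = 168,
#'         unit = "mcg")                                          # 78.57 mcg/day
#' @export
regimen <- function(dose, freq, interval_hours = NA_real_, unit = "mg",
                    rx_type = "scheduled", strength = NA_real_,
                    volume = NA_real_) {
  if (length(dose) != length(freq)) {
    stop_contract("`dose` and `freq` must have one entry per regimen component")
  }
  structure(
    list(dose = as.numeric(dose), freq = as.numeric(freq),
         interval_hours = as.numeric(interval_hours), unit = unit,
         rx_type = rx_type, strength = as.numeric(strength),
         volume = as.numeric(volume)),
    class = "regimen"
  )
}

#' Compute the prescribed average daily dose of one prescription
#'
#' Applies the default cascade, in this fixed order, to fields that are
#' missing: dose from package strength times prescribed volume; volume assumed
#' 1 unit; interval derived from the frequency (a stated frequency with no
#' interval is read as per-day); interval assumed daily; frequency assumed 1
#' administration per interval. "As needed" (PN) and variable-dose (VAO)
#' prescriptions get a categorical ADD; one-time prescriptions and
#' prescriptions whose ADD still cannot be computed are excluded. Every default
#' actually applied is recorded for audit.
#'
#' @param x a [regimen()].
#' @return a list of class `"add_result"` with elements `kind` (one of
#'   `"numeric"`, `"PN"`, `"VAO"`, `"excluded"`), `value` (mean daily dose, only
#'   when `kind == "numeric"`), `unit`, and `applied_defaults` (character).
#' @examples
#' compute_add(regimen(dose = 200, freq = 3, interval_hours = 24))$value # 600
#' @export
compute_add <- function(x) {
  stopifnot(inherits(x, "regimen"))
  defaults <- character(0)
  res <- function(kind, value = NA_real_) {
    structure(list(kind = kind, value = value, unit = x$unit,
                   applied_defaults = defaults),
              class = "add_result")
  }

  if (x$rx_type %in% c("PN", "VAO")) return(res(x$rx_type))
  if (x$rx_type == "one-time") return(res("excluded"))

  dose <- x$dose
  freq <- x$freq
  interval <- x$interval_hours

  if (all(is.na(dose))) {
    if (!is.na(x$strength)) {
      vol <- x$volume
      if (is.na(vol)) {
        vol <- 1
        defaults <- c(defaults, "volume=1")
      }
      dose <- x$strength * vol
      defaults <- c(defaults, "dose-from-strength")
    } else {
      return(res("excluded"))
    }
  }
  if (is.na(interval)) {
    if (any(!is.na(freq))) {
      interval <- 24
      defaults <- c(defaults, "interval-from-frequency")
    } else {
      interval <- 24
      defaults <- c(defaults, "daily-interval")
    }
  }
  if (all(is.na(freq))) {
    freq <- rep(1, length(dose))
    defaults <- c(defaults, "freq=1")
  }
  if (anyNA(dose) || anyNA(freq)) return(res("excluded"))

  if (any(dose < 0)) stop_data("negative dose in prescription regimen")
  if (interval <= 0) stop_data("non-positive dose interval in prescription regimen")

  t_days <- interval / 24
  res("numeric", sum(dose * freq) / t_days)
}

#' Compute ADDs for a prescriptions table
#'
#' Vectorised, single-component-per-row version of [compute_add()] for the
#' tabular interface. Expected columns: `rx_id`, `drug_atc`, `dose`, `unit`,
#' `freq`, `interval_hours`, `rx_type`, `strength`, `volume` (missing values
#' as `NA`).
#'
#' @param prescriptions a data frame of prescriptions.
#' @return a tibble with one row per prescription: `rx_id`, `kind`,
#'   `add_value`, `unit`, `applied_defaults` (comma-joined).
#' @export
compute_add_table <- function(prescriptions) {
  p <- tibble::as_tibble(prescriptions)
  need <- c("rx_id", "dose", "freq", "interval_hours", "rx_type")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop_contract(paste("prescriptions table lacks columns:",
                        paste(miss, collapse = ", ")))
  }
  if (!"strength" %in% names(p)) p$strength <- NA_real_
  if (!"volume" %in% names(p)) p$volume <- NA_real_
  if (!"unit" %in% names(p)) p$unit <- "mg"

  bad_dose <- which(!is.na(p$dose) & p$dose < 0)
  if (length(bad_dose)) {
    stop_data(paste0("negative dose in prescription row(s): ",
                     paste(p$rx_id[head(bad_dose, 5)], collapse = ", ")))
  }
  bad_int <- which(!is.na(p$interval_hours) & p$interval_hours <= 0)
  if (length(bad_int)) {
    stop_data(paste0("non-positive interval in prescription row(s): ",
                     paste(p$rx_id[head(bad_int, 5)], collapse = ", ")))
  }

  # vectorised default cascade, same order as compute_add()
  n <- nrow(p)
  dose <- p$dose
  freq <- p$freq
  interval <- p$interval_hours
  defs <- character(n)
  tag <- function(sel, label) {
    defs[sel] <<- ifelse(defs[sel] == "", label, paste(defs[sel], label,
                                                       sep = ","))
  }
  from_strength <- is.na(dose) & !is.na(p$strength)
  no_vol <- from_strength & is.na(p$volume)
  vol <- ifelse(no_vol, 1, p$volume)
  tag(no_vol, "volume=1")
  dose[from_strength] <- (p$strength * vol)[from_strength]
  tag(from_strength, "dose-from-strength")
  int_from_freq <- is.na(interval) & !is.na(freq)
  int_daily <- is.na(interval) & is.na(freq)
  interval[is.na(interval)] <- 24
  tag(int_from_freq, "interval-from-frequency")
  tag(int_daily, "daily-interval")
  no_freq <- is.na(freq)
  freq[no_freq] <- 1
  tag(no_freq, "freq=1")

  value <- dose * freq / (interval / 24)
  kind <- rep("numeric", n)
  kind[is.na(value)] <- "excluded"
  kind[p$rx_type == "PN"] <- "PN"
  kind[p$rx_type == "VAO"] <- "VAO"
  kind[p$rx_type == "one-time"] <- "excluded"
  value[kind != "numeric"] <- NA_real_
  defs[kind != "numeric"] <- ""
  tibble::tibble(rx_id = p$rx_id, kind = kind, add_value = value,
                 unit = p$unit, applied_defaults = defs)
}

#' ADD sequence for one drug within one admission
#'
#' Orders of magnitude matter: mixed mass units (g, mg, mcg) within one drug's
#' sequence are converted to mg before comparison; a sequence containing an
#' unconvertible unit mix, a categorical ADD, or an excluded prescription is
#' flagged incomplete and takes no part in change counting.
#'
#' @param add_results tibble as returned by [compute_add_table()], time-ordered.
#' @return a list with `values` (numeric ADDs in a common unit; `NA` where not
#'   numeric) and `complete` (logical).
#' @export
add_sequence <- function(add_results) {
  a <- tibble::as_tibble(add_results)
  .add_seq(a$kind, a$add_value, a$unit)
}

.add_seq <- function(kind, values, units) {
  if (length(kind) == 0L) return(list(values = numeric(0), complete = TRUE))
  complete <- all(kind == "numeric")
  if (complete) {
    conv <- harmonize_units(values, units)
    if (anyNA(conv$values)) {
      complete <- FALSE
    } else {
      values <- conv$values
    }
  }
  list(values = values, complete = complete)
}

# convert dose values to a common unit; unconvertible mixes -> NA values
harmonize_units <- function(values, units) {
  units <- tolower(units)
  if (length(unique(units)) <= 1L) {
    return(list(values = values, unit = units[1] %||% NA_character_))
  }
  if (all(units %in% names(.unit_to_mg))) {
    list(values = values * unname(.unit_to_mg[units]), unit = "mg")
  } else {
    list(values = rep(NA_real_, length(values)), unit = NA_character_)
  }
}
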