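# Candidate fixed-effect structures for the proximity mixed models.
#
# Two fixed enumerations are used, both with crossed random intercepts for
# wind farm, turbine and bird identity:
# * before/after (fix-based): predictors are the turbine-location GET score
#   (`get_turbine`), the operational phase (`postop`), and the GET score at
#   the tag location (`get_location`) - 12 candidates from the null model to
#   the fully saturated three-way-interaction model. Interactions are only
#   fitted among main effects present in the model.
# * after-operation (segment-based): predictors are wind speed
#   (`wind_speed`), turbine GET (`get_turbine`), blade-motion status
#   (`blade_status`) and flight-line GET (`get_location`) - 27 candidates up
#   to the four-way-saturated model.

ba_terms <- c(get_turbine = "get_turbine", postop = "postop",
              get_location = "get_location")

#' Enumerate the 12 before/after candidate models
#'
#' @return A tibble with `label` (`"M0"`..`"M11"`), `fixed` (right-hand-side
#'   formula string) and `description`.
#' @export
enumerate_before_after_candidates <- function() {
  tibble(
    label = paste0("M", 0:11),
    fixed = c(
      "1",
      "get_turbine",
      "postop",
      "get_location",
      "get_turbine + postop",
      "get_turbine + postop + get_turbine:postop",
      "get_turbine + get_location",
      "get_turbine + get_location + get_turbine:get_location",
      "postop + get_location",
      "postop + get_location + postop:get_location",
      "get_turbine + postop + get_location",
      "get_turbine * postop * get_location"
    ),
    description = c(
      "Null model (random effects only)",
      "Turbine GET score",
      "Operational phase",
      "Tag-location GET score",
      "Turbine GET + phase",
      "Turbine GET x phase",
      "Turbine GET + tag GET",
      "Turbine GET x tag GET",
      "Phase + tag GET",
      "Phase x tag GET",
      "All three main effects",
      "Saturated: all two-way and the three-way interaction"
    )
  )
}

#' Enumerate the 27 after-operation candidate models
#'
#' @return A tibble with `label` (`"M0"`..`"M26"`), `fixed` and `description`.
#' @export
enumerate_after_candidates <- function() {
  tibble(
    label = paste0("M", 0:26),
    fixed = c(
      "1",
      "get_location",
      "get_turbine",
      "blade_status",
      "wind_speed",
      "get_turbine + get_location",
      "get_turbine * get_location",
      "get_turbine + blade_status",
      "get_turbine * blade_status",
      "blade_status + get_location",
      "blade_status + get_location + blade_status:get_location",
      "wind_speed + get_location",
      "wind_speed * get_location",
      "wind_speed + get_turbine",
      "wind_speed * get_turbine",
      "wind_speed + blade_status",
      "wind_speed * blade_status",
      "get_turbine + blade_status + get_location",
      "get_turbine * blade_status * get_location",
      "wind_speed + get_location + blade_status",
      "wind_speed * get_location * blade_status",
      "wind_speed + get_turbine + get_location",
      "wind_speed * get_turbine * get_location",
      "wind_speed + get_turbine + blade_status",
      "wind_speed * get_turbine * blade_status",
      "wind_speed + get_location + get_turbine + blade_status",
      "wind_speed * get_location * get_turbine * blade_status"
    ),
    description = c(
      "Null model (random effects only)",
      "Flight-line GET score",
      "Turbine GET score",
      "Blade motion status",
      "Wind speed",
      "Turbine GET + flight-line GET",
      "Turbine GET x flight-line GET",
      "Turbine GET + blade status",
      "Turbine GET x blade status",
      "Blade status + flight-line GET",
      "Blade status x flight-line GET",
      "Wind + flight-line GET",
      "Wind x flight-line GET",
      "Wind + turbine GET",
      "Wind x turbine GET",
      "Wind + blade status",
      "Wind x blade status",
      "Three main effects (turbine GET, blade status, flight-line GET)",
      "Saturated three-way: turbine GET x blade status x flight-line GET",
      "Three main effects (wind, flight-line GET, blade status)",
      "Saturated three-way: wind x flight-line GET x blade status",
      "Three main effects (wind, turbine GET, flight-line GET)",
      "Saturated three-way: wind x turbine GET x flight-line GET",
      "Three main effects (wind, turbine GET, blade status)",
      "Saturated three-way: wind x turbine GET x blade status",
      "All four main effects",
      "Saturated four-way: all interactions"
    )
  )
}

#' Information-criterion differences across a candidate set
#'
#' @param fits A list of fit objects from [fit_lmm()] (or a tibble from
#'   [glance()]-ing them).
#' @return A tibble with `label`, `df`, `AIC`, `BIC`, `dAIC`, `dBIC`; both
#'   `dAIC` and `dBIC` have minimum exactly 0.
#' @export
delta_table <- function(fits) {
  gl <- if (is.data.frame(fits)) fits else purrr::map_dfr(fits, glance)
  gl %>%
    mutate(dAIC = .data$AIC - min(.data$AIC),
           dBIC = .data$BIC - min(.data$BIC)) %>%
    select("label", "df", "AIC", "BIC", "dAIC", "dBIC")
}

#' Select the best candidate model
#'
#' If one model minimises both AIC and BIC it is selected. When the two
#' criteria disagree, the BIC-best model is preferred by default (parsimony:
#' BIC penalises complexity more strongly and eases interpretation);
#' `prefer = "AIC"` flips the rule. Remaining ties break to fewer degrees of
#' freedom.
#'
#' @param fits As in [delta_table()].
#' @param prefer `"BIC"` (default) or `"AIC"`: which criterion wins on
#'   disagreement.
#' @return The selected model's `label`.
#' @export
select_best <- function(fits, prefer = c("BIC", "AIC")) {
  prefer <- match.arg(prefer)
  dt <- delta_table(fits)
  pick <- function(crit) {
    cand <- dt[dt[[crit]] == min(dt[[crit]]), , drop = FALSE]
    cand$label[which.min(cand$df)]
  }
  aic_best <- pick("AIC"); bic_best <- pick("BIC")
  if (aic_best == bic_best) return(aic_best)
  if (prefer == "BIC") bic_best else aic_best
}
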