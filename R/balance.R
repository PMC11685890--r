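#' Carrying-capacity parameters
#'
#' The constants of the seasonal carrying-capacity formula
#' \deqn{GCC = AGB \times A \times u / (Int \times D \times 1000)}
#' where AGB is mean standing biomass (g/m2), A the grassland area (m2),
#' u the usable fraction of standing forage, Int the daily intake of one
#' standard sheep unit (kg/day), D the grazing-season length (days), and
#' 1000 converts grams to kilograms.
#'
#' Defaults: 20% of standing biomass usable (the remainder lost to trampling,
#' decomposition and wild herbivores), 1.8 kg/day intake per standard sheep
#' unit, a 180-day grazing season. With these, per-hectare capacity is
#' exactly AGB/162 SU/ha.
#'
#' @param usable_fraction fraction of standing biomass available to
#'   livestock, in (0, 1].
#' @param intake_kg_per_day daily forage intake of one SU, kg.
#' @param grazing_days grazing-season length, days.
#' @return An object of class \code{carrying_params}.
#' @export
carrying_params <- function(usable_fraction = 0.2, intake_kg_per_day = 1.8,
                            grazing_days = 180) {
  stopifnot(usable_fraction > 0, usable_fraction <= 1,
            intake_kg_per_day > 0, grazing_days > 0)
  structure(list(usable_fraction = usable_fraction,
                 intake_kg_per_day = intake_kg_per_day,
                 grazing_days = grazing_days,
                 kg_per_g_divisor = 1000),
            class = "carrying_params")
}

#' Grassland carrying capacity of a region
#'
#' Number of standard sheep units one grazing season of the region's usable
#' forage can support:
#' \code{gcc_total_su = mean_agb * area_m2 * usable_fraction /
#' (intake * days * 1000)}. Also reports the per-hectare capacity; a
#' zero-area region carries capacity 0 with \code{zero_area = TRUE}.
#'
#' @param mean_agb mean above-ground biomass over the region's grassland,
#'   g/m2 (non-negative).
#' @param area_m2 grassland area, m2 (non-negative).
#' @param params \code{\link{carrying_params}}.
#' @return list with \code{gcc_total_su}, \code{gcc_su_per_ha},
#'   \code{zero_area}.
#' @export
carrying_capacity <- function(mean_agb, area_m2, params = carrying_params()) {
  if (any(mean_agb < 0) || any(area_m2 < 0)) {
    stop("mean AGB and area must be non-negative", call. = FALSE)
  }
  denom <- params$intake_kg_per_day * params$grazing_days *
    params$kg_per_g_divisor
  total <- mean_agb * area_m2 * params$usable_fraction / denom
  per_ha <- ifelse(area_m2 > 0, total / (area_m2 / 1e4),
                   mean_agb * 1e4 * params$usable_fraction / denom)
  list(gcc_total_su = total, gcc_su_per_ha = per_ha,
       zero_area = area_m2 == 0)
}

#' Grassland carrying state index
#'
#' Ratio of actual standard livestock units to carrying capacity; values
#' above 1 mean forage demand exceeds supply. Both arguments must be in
#' absolute SU (convert thousands first — see \code{\link{su_as_absolute}}).
#'
#' @param ln_su actual standard livestock units.
#' @param gcc_total_su carrying capacity in SU.
#' @return the index; \code{Inf} when livestock are present on zero capacity
#'   (infinite overload); \code{NaN} when both are zero (undefined).
#' @export
gcsi <- function(ln_su, gcc_total_su) {
  if (any(ln_su < 0) || any(gcc_total_su < 0)) {
    stop("SU and capacity must be non-negative", call. = FALSE)
  }
  ifelse(gcc_total_su == 0,
         ifelse(ln_su == 0, NaN, Inf),
         ln_su / gcc_total_su)
}

#' Four-level grazing-load classification
#'
#' Maps the carrying state index to the standard four load classes with
#' left-closed bins: light load [0, 0.8), normal [0.8, 1.0),
#' overload [1.0, 1.3), severe overload [1.3, Inf]. An index of exactly 1
#' (demand equals supply) already counts as overload — the conservative
#' choice for management. Infinite overload classifies as severe overload;
#' an undefined index (NaN) returns NA.
#'
#' @param gcsi_value numeric vector of carrying state indices.
#' @return ordered factor with levels \code{light load < normal < overload <
#'   severe overload}.
#' @export
classify_load <- function(gcsi_value) {
  if (any(gcsi_value < 0, na.rm = TRUE)) {
    stop("GCSI must be non-negative", call. = FALSE)
  }
  levels <- c("light load", "normal", "overload", "severe overload")
  idx <- findInterval(gcsi_value, c(0.8, 1.0, 1.3)) + 1L
  idx[is.infinite(gcsi_value)] <- 4L
  idx[is.nan(gcsi_value)] <- NA_integer_
  factor(levels[idx], levels = levels, ordered = TRUE)
}

#' Region-year grazing-balance table
#'
#' Joins per-region carrying capacities with the actual-SU table, computes
#' the carrying state index and load class for every region-year present in
#' both, and reports (rather than silently drops) regions present on only
#' one side.
#'
#' @param capacity data.frame with columns \code{region}, \code{year} (or a
#'   single capacity per region applied to all years), \code{mean_agb_g_m2},
#'   \code{area_ha}, \code{gcc_total_su}.
#' @param su an \code{\link{su_table}} (any units; converted internally).
#' @return data.frame of class \code{balance_table} with columns
#'   \code{region}, \code{year}, \code{mean_agb_g_m2}, \code{area_ha},
#'   \code{gcc_su}, \code{gcc_su_per_ha}, \code{ln_su}, \code{gcsi},
#'   \code{load_class}; attribute \code{unmatched} lists region ids missing
#'   from either side.
#' @export
balance_table <- function(capacity, su) {
  if (!inherits(su, "su_table")) {
    stop("`su` must be an su_table (units flag required)", call. = FALSE)
  }
  su <- su_as_absolute(su)
  if (!"year" %in% names(capacity)) {
    capacity <- merge(capacity, unique(su["year"]))
  }
  joint <- merge(capacity, as.data.frame(su)[c("region", "year", "su")],
                 by = c("region", "year"))
  unmatched <- list(
    capacity_only = setdiff(unique(capacity$region), unique(su$region)),
    su_only = setdiff(unique(su$region), unique(capacity$region)))
  if (length(unmatched$capacity_only) || length(unmatched$su_only)) {
    warning("regions without a match were excluded from the balance table: ",
            paste(unlist(unmatched), collapse = ", "), call. = FALSE)
  }
  idx <- gcsi(joint$su, joint$gcc_total_su)
  out <- data.frame(region = joint$region, year = joint$year,
                    mean_agb_g_m2 = joint$mean_agb_g_m2,
                    area_ha = joint$area_ha,
                    gcc_su = joint$gcc_total_su,
                    gcc_su_per_ha = joint$gcc_total_su / joint$area_ha,
                    ln_su = joint$su, gcsi = idx,
                    load_class = classify_load(idx),
                    stringsAsFactors = FALSE)
  out <- out[order(out$region, out$year), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmatched") <- unmatched
  class(out) <- c("balance_table", "data.frame")
  out
}
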