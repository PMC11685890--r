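#' Standard-livestock-unit table
#'
#' A region-by-year table of standard sheep units (SU) with a mandatory units
#' flag — either absolute SU (\code{"su"}) or thousands (\code{"thousands"}).
#' The flag travels with the object and is checked wherever SU values meet
#' carrying capacities, preventing silent thousand-fold errors.
#'
#' @param df data.frame with columns \code{region}, \code{country},
#'   \code{year}, \code{su}.
#' @param units \code{"su"} or \code{"thousands"}.
#' @return An object of class \code{su_table} (a data.frame).
#' @export
su_table <- function(df, units = c("su", "thousands")) {
  units <- match.arg(units)
  need <- c("region", "country", "year", "su")
  if (!all(need %in% names(df))) {
    stop("su_table needs columns region, country, year, su", call. = FALSE)
  }
  if (any(df$su < 0)) stop("SU values must be non-negative", call. = FALSE)
  structure(df[need], units = units, class = c("su_table", "data.frame"))
}

#' @export
print.su_table <- function(x, ...) {
  cat(sprintf("<su_table> %d records, %d regions, years %d-%d, units: %s\n",
              nrow(x), length(unique(x$region)), min(x$year), max(x$year),
              su_units(x)))
  NextMethod()
}

#' Units flag of an SU table
#' @param su an \code{su_table}.
#' @return \code{"su"} or \code{"thousands"}.
#' @export
su_units <- function(su) attr(su, "units")

#' Convert an SU table to absolute standard units
#' @param su an \code{su_table}.
#' @return the same table with units \code{"su"}.
#' @export
su_as_absolute <- function(su) {
  if (su_units(su) == "su") return(su)
  out <- as.data.frame(su)
  out$su <- out$su * 1000
  su_table(out, units = "su")
}

#' Standard-livestock-unit conversion coefficients
#'
#' National-standard (NY/T 635-2002 dialect) coefficients converting species
#' headcounts to standard sheep units. The two countries keep different
#' species books: Mongolian statistics separate sheep and goats, Inner
#' Mongolian statistics merge them at 0.95 SU per head.
#'
#' @param country \code{"MNG"} or \code{"IMNG"}.
#' @return named numeric vector of SU per head.
#' @export
default_coefficients <- function(country) {
  switch(country,
    MNG = c(sheep = 1, goat = 0.9, horse = 6, cattle = 5, camel = 7),
    IMNG = c(cattle = 5, horse = 6, sheep_goat = 0.95, donkey = 3,
             mule = 5, camel = 7),
    stop("unknown country '", country, "' (use MNG or IMNG)", call. = FALSE))
}

#' Convert species headcounts to standard livestock units
#'
#' Linear conversion: per region and year, SU is the coefficient-weighted sum
#' of species headcounts, using each region's country dialect.
#'
#' @param inventory data.frame with columns \code{region}, \code{country},
#'   \code{year}, \code{species}, \code{headcount}.
#' @param coefficients optional named list \code{MNG}/\code{IMNG} overriding
#'   \code{\link{default_coefficients}}.
#' @return an \code{\link{su_table}} in absolute SU.
#' @export
convert_to_su <- function(inventory, coefficients = NULL) {
  need <- c("region", "country", "year", "species", "headcount")
  if (!all(need %in% names(inventory))) {
    stop("inventory needs columns region, country, year, species, headcount",
         call. = FALSE)
  }
  if (any(inventory$headcount < 0)) {
    stop("headcounts must be non-negative", call. = FALSE)
  }
  coef_for <- function(country) {
    if (!is.null(coefficients) && !is.null(coefficients[[country]])) {
      coefficients[[country]]
    } else {
      default_coefficients(country)
    }
  }
  inv <- inventory
  inv$su <- NA_real_
  for (country in unique(inv$country)) {
    cf <- coef_for(country)
    sel <- inv$country == country
    missing_sp <- setdiff(unique(inv$species[sel]), names(cf))
    if (length(missing_sp)) {
      stop("no SU coefficient for species: ",
           paste(missing_sp, collapse = ", "), " (country ", country, ")",
           call. = FALSE)
    }
    inv$su[sel] <- inv$headcount[sel] * cf[inv$species[sel]]
  }
  agg <- stats::aggregate(su ~ region + country + year, data = inv, FUN = sum)
  # regions with an empty species list contribute nothing; ensure each
  # region-year present in the input appears in the output
  su_table(agg[order(agg$region, agg$year), , drop = FALSE], units = "su")
}

su_lookup <- function(su, region, year) {
  v <- su$su[su$region == region & su$year == year]
  if (length(v) != 1L) {
    stop("no unique SU record for region '", region, "', year ", year,
         call. = FALSE)
  }
  v
}

#' Percentage growth of a region's SU between two years
#'
#' \code{100 * (su(year1) - su(year0)) / su(year0)}; unit-free, so the
#' table's thousands flag does not matter here.
#'
#' @param su an \code{\link{su_table}}.
#' @param region region identifier.
#' @param year0,year1 baseline and comparison years.
#' @return percent growth (NA with a warning when the baseline is zero).
#' @export
growth_rate <- function(su, region, year0, year1) {
  v0 <- su_lookup(su, region, year0)
  v1 <- su_lookup(su, region, year1)
  if (v0 == 0) {
    warning("zero SU baseline for region '", region, "'; growth undefined",
            call. = FALSE)
    return(NA_real_)
  }
  100 * (v1 - v0) / v0
}

#' Unweighted mean SU growth across regions
#'
#' Arithmetic mean of \code{\link{growth_rate}} over every region having both
#' years; regions with a zero baseline are excluded (with the per-region
#' warning).
#'
#' @inheritParams growth_rate
#' @return percent.
#' @export
mean_growth_rate <- function(su, year0, year1) {
  regs <- unique(su$region)
  has_both <- vapply(regs, function(r) {
    sum(su$region == r & su$year == year0) == 1L &&
      sum(su$region == r & su$year == year1) == 1L
  }, logical(1L))
  regs <- regs[has_both]
  if (length(regs) == 0L) {
    stop("no region has records in both years", call. = FALSE)
  }
  rates <- vapply(regs, function(r) growth_rate(su, r, year0, year1),
                  numeric(1L))
  mean(rates, na.rm = TRUE)
}

#' Average annual increase of total headcounts
#'
#' \code{(total(year1) - total(year0)) / (year1 - year0)}, in heads per year;
#' negative when the herd shrinks.
#'
#' @param totals data.frame with columns \code{year} and \code{headcount}
#'   (totals already summed over regions and species), or an inventory
#'   data.frame with a \code{headcount} column to be summed by year.
#' @param year0,year1 endpoints.
#' @return heads per year.
#' @export
annual_average_increase <- function(totals, year0, year1) {
  if (year1 == year0) stop("year1 must differ from year0", call. = FALSE)
  tot <- stats::aggregate(headcount ~ year, data = totals, FUN = sum)
  t0 <- tot$headcount[tot$year == year0]
  t1 <- tot$headcount[tot$year == year1]
  if (length(t0) != 1L || length(t1) != 1L) {
    stop("both endpoint years must be present", call. = FALSE)
  }
  (t1 - t0) / (year1 - year0)
}

#' Read/write SU tables as CSV
#'
#' The CSV stores thousands in a \code{su_thousands} column or absolute units
#' in a \code{su} column, so the units survive the round trip.
#'
#' @param su an \code{\link{su_table}}.
#' @param path file path.
#' @return \code{read_su_csv} returns an \code{su_table}.
#' @export
write_su_csv <- function(su, path) {
  out <- as.data.frame(su)
  names(out)[names(out) == "su"] <-
    if (su_units(su) == "thousands") "su_thousands" else "su"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_su_csv
#' @export
read_su_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("su_thousands" %in% names(df)) {
    names(df)[names(df) == "su_thousands"] <- "su"
    su_table(df, units = "thousands")
  } else {
    su_table(df, units = "su")
  }
}
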