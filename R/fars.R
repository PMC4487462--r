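#' Packaged Fars-province indicator fixture
#'
#' The package ships the structural-indicator list used in the Fars province
#' (Iran) health-resource assessment: 31 indicators in three clusters
#' (8 institutional, 20 human-resource, 3 rural institutional), each with its
#' province-wide summary value from the provincial statistical yearbook. The
#' per-city rate matrix behind that assessment was never published, so the
#' fixture serves documentation and calibration of the synthetic generator,
#' not reanalysis.
#'
#' @return `fars_indicator_table()`: data frame with columns `id`, `label`,
#'   `cluster`, `denominator`, `orientation`, `province_total`.
#'   `fars_schema()`: the same rows as an [indicator_schema()].
#' @export
fars_indicator_table <- function() {
  path <- system.file("extdata", "fars_indicators.csv", package = "scalogram",
                      mustWork = TRUE)
  read_delim_auto(path)
}

#' @rdname fars_indicator_table
#' @export
fars_schema <- function() {
  tab <- fars_indicator_table()
  validate_indicator_schema(tab[, c("id", "label", "cluster", "denominator",
                                    "orientation")])
}

#' Plausible mean rates for the Fars indicators
#'
#' Per-1,000 mean rates used as synthetic-generator baselines, obtained by
#' scaling each indicator's province-wide summary value down by `scale`
#' (default 100, giving means of roughly 0.3--0.65 per 1,000 population --
#' the order of magnitude of facility and specialist densities).
#'
#' @param scale Positive divisor applied to the province totals.
#' @return Named numeric vector, one base rate per indicator id.
#' @export
fars_base_rates <- function(scale = 100) {
  stopifnot(is.finite(scale), scale > 0)
  tab <- fars_indicator_table()
  stats::setNames(tab$province_total / scale, tab$id)
}

#' The 22 Fars-province study regions
#'
#' City names of the Fars province districts covered by the assessment
#' (Fasa and Jahroom fall under a different medical-university catchment and
#' are excluded).
#'
#' @return Character vector of 22 region names.
#' @export
fars_regions <- function() {
  c("Abadeh", "Arsanjan", "Estahban", "Eghlid", "Bavanat", "Pasargad",
    "Khorambid", "Khonj", "Darab", "Zarindasht", "Sepidan", "Shiraz",
    "Firozabad", "Ghirokarzin", "Kazeroon", "Larestan", "Lamerd",
    "Marvdasht", "Mamassani", "Mohr", "Neiriz", "Farashband")
}

#' The published Fars five-tier class scheme
#'
#' The reference development classification for the Fars assessment pins the
#' score range at 33--89.4 and the Sturges item count at N = 21, giving a
#' class width of about 10.5 and tier lower bounds 33, 43.5, 54, 64.5 and 75.
#'
#' @return A [build_class_scheme()] result.
#' @export
fars_class_scheme <- function() {
  build_class_scheme(score_min = 33, score_max = 89.4, n_items = 21)
}
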