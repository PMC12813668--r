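#' Published airspeed summaries
#'
#' Small reference tables of published mean airspeeds, bundled as code so
#' the scaling and variability analyses have worked inputs.
#'
#' `cormorant_airspeed_survey()` lists mean airspeed and body mass for five
#' cormorant species (four literature values plus a great cormorant
#' ornithodolite estimate); it feeds [allometric_speed_exponent()].
#'
#' `ornithodolite_speed_survey()` lists mean airspeed, standard deviation
#' and sample size for bird species measured with the same ornithodolite
#' setup; it feeds [cv_table()].
#'
#' @return A tibble.
#' @examples
#' cormorant_airspeed_survey()
#' @export
cormorant_airspeed_survey <- function() {
  tibble::tribble(
    ~species,                   ~airspeed_mps, ~mass_kg, ~n,
    "Nannopterum brasilianum",  14.2,          1.30,     15,
    "Gulosus aristotelis",      15.4,          1.81,     103,
    "Nannopterum auritum",      14.7,          1.41,     136,
    "Leucocarbo verrucosus",    12.7,          2.35,     24,
    "Phalacrocorax carbo",      17.4,          2.55,     140
  )
}

#' @rdname cormorant_airspeed_survey
#' @export
ornithodolite_speed_survey <- function() {
  tibble::tribble(
    ~species,                  ~mean_mps, ~sd_mps, ~n,
    "Apus apus",               12.0,      2.49,    141,
    "Sterna paradisaea",       11.9,      1.84,    145,
    "Sterna hirundo",          11.7,      1.94,    82,
    "Sterna albifrons",        10.4,      3.19,    36,
    "Sterna sandwichensis",    12.6,      2.25,    56,
    "Calidris alpina",         16.1,      2.40,    161,
    "Calidris canutus",        16.6,      3.88,    32,
    "Haematopus ostralegus",   15.4,      1.94,    95,
    "Phalacrocorax carbo",     17.5,      1.98,    140
  )
}
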