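# shared fixtures, built in code

tax <- default_taxonomy()

# hand-built 3-household, 2-wave panel used by data-model tests
tiny_panel <- function() {
  geo <- data.frame(
    village_id = c("A-D1-T1-V1", "A-D1-T1-V2"),
    town_id = "A-D1-T1", district_id = "A-D1", country = "A",
    distance_urban = c(10, 40), stringsAsFactors = FALSE)
  hh <- function(id, village, wave, farmer, land = 1)
    data.frame(household_id = id, country = "A", district_id = "A-D1",
               town_id = "A-D1-T1", village_id = village, wave = wave,
               head_sex = 0L, head_age = 40L + wave, head_literate = 1L,
               landholding = land, phone = 1L, motorbike = 0L,
               electricity = 0L, offfarm_wage = 0L, self_employment = 0L,
               cash_crop = 0L, weather_shock = 0L,
               distance_urban = geo$distance_urban[geo$village_id == village],
               is_farmer = farmer, stringsAsFactors = FALSE)
  households <- rbind(
    hh("h1", "A-D1-T1-V1", 1L, 1L), hh("h1", "A-D1-T1-V1", 2L, 1L),
    hh("h2", "A-D1-T1-V1", 1L, 1L), hh("h2", "A-D1-T1-V1", 2L, 1L),
    hh("h3", "A-D1-T1-V2", 1L, 0L, land = 0))
  consumption <- data.frame(
    household_id = c("h1", "h1", "h1", "h2", "h2", "h3", "h3"),
    wave = c(1L, 1L, 2L, 1L, 2L, 1L, 1L),
    item_code = c("grain_staple", "pulses", "grain_staple", "milk_fresh",
                  "sugar", "grain_staple", "meat_fresh"),
    source = c("purchase", "own_production", "own_production", "own_production",
               "purchase", "purchase", "other"),
    value = c(40, 60, 50, 30, 10, 80, 20), stringsAsFactors = FALSE)
  production <- data.frame(
    household_id = c("h1", "h1", "h2", "h1"),
    wave = c(1L, 1L, 1L, 2L),
    species_code = c("maize", "beans", "cattle", "maize"),
    stringsAsFactors = FALSE)
  panel_dataset(households, consumption, production, geo, tax,
                wave_calendar = list(A = 1:2))
}

# small linear-mode panel for estimator tests (balanced unless stated)
linear_config <- function(seed, waves = 3L, attrition = 0, ...) {
  generator_config(seed = seed, districts_per_country = 2L,
                   towns_per_district = 3L, villages_per_town = 3L,
                   households_per_village = 8L, waves_per_country = waves,
                   outcome_mode = "linear", attrition_base_rate = attrition,
                   ...)
}

structural_config <- function(seed, attrition = 0, ...) {
  generator_config(seed = seed, districts_per_country = 2L,
                   towns_per_district = 3L, villages_per_town = 3L,
                   households_per_village = 8L, waves_per_country = 3L,
                   attrition_base_rate = attrition, ...)
}
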