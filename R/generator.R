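#' Configuration for the synthetic panel generator
#'
#' Returns the full set of generator parameters with defaults calibrated
#' to the pooled descriptive statistics of rural African LSMS-type
#' surveys: mean farm species diversity about 5.5, mean household
#' dietary diversity score about 5.7 (nine nutritious groups), about a
#' third of consumed food value from own production, mean village
#' distance to the nearest urban centre about 31 km, about seven
#' sampled farm households per village, and over three quarters of
#' farms below 2 ha.
#'
#' Two outcome modes are supported. In `structural` mode the household
#' dietary diversity score emerges from a consumption mechanism (own
#' consumption of produced food groups plus market access that improves
#' with assets and falls with distance); this mode is used for
#' descriptive calibration. In `linear` mode a continuous latent diet
#' index is generated exactly as
#' `alpha + beta*FPD + beta_int*FPD*distance + delta'X + theta_c +
#' tau_t + c_i + eps`, so estimator consistency and coefficient
#' recovery can be verified against known truth without the
#' attenuation a bounded integer count would introduce.
#'
#' The household effect `c_i ~ N(0, sigma_c^2)` shifts the mean of the
#' species count through `kappa`, so with `kappa > 0` farm production
#' diversity is endogenous: estimators that ignore time-invariant
#' heterogeneity are biased, which is precisely what the correlated
#' random effects (Mundlak) and fixed effects estimators are for.
#'
#' @param seed integer root seed; all per-table streams are derived
#'   from it deterministically.
#' @param n_countries,districts_per_country,towns_per_district,villages_per_town,households_per_village
#'   nested geography sizes.
#' @param waves_per_country integer vector (recycled) of survey waves
#'   per country; defaults mirror a six-country panel with 3, 4, 2, 4,
#'   5 and 7 waves.
#' @param farming_share probability a household is a farm household.
#' @param landholding_meanlog,landholding_sdlog lognormal landholding
#'   (ha) for farm households.
#' @param distance_shape,distance_scale gamma distribution of village
#'   distance to the nearest urban centre (km); defaults give mean 31.
#' @param sigma_c SD of the household effect `c_i`.
#' @param kappa strength of the `c_i` -> species-count channel (log
#'   scale); `kappa = 0` removes the confounding.
#' @param mean_species target mean species per farm-wave (includes the
#'   floor of one species); `species_size` is the negative-binomial
#'   dispersion of the count above the floor.
#' @param true_alpha,true_beta_species,true_beta_groups,true_beta_interaction,true_delta,sigma_eps
#'   linear-mode truth: intercept, focal coefficients (per species and
#'   per produced food group), interaction with distance, named
#'   covariate effects and error SD.
#' @param linear_focal which FPD metric drives the linear-mode outcome.
#' @param subsistence_share_target pooled mean own-production share of
#'   consumption value targeted by the structural value model.
#' @param attrition_base_rate per-wave baseline dropout hazard;
#'   `attrition_slopes` named logit slopes on baseline covariates.
#' @param true_country_effects,true_wave_effect linear-mode country
#'   intercept shifts (recycled to `n_countries`) and per-wave trend.
#' @param outcome_mode `"structural"` or `"linear"`.
#' @param own_consume_prob probability a produced nutritious food group
#'   is consumed from own production.
#' @param market_shift global logit shift on market consumption
#'   probabilities (calibration dial for the mean diet score).
#' @param taxonomy a [food_taxonomy]; defaults to [default_taxonomy()].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 42L,
                             n_countries = 6L,
                             districts_per_country = 8L,
                             towns_per_district = 8L,
                             villages_per_town = 27L,
                             households_per_village = 10L,
                             waves_per_country = c(3L, 4L, 2L, 4L, 5L, 7L),
                             farming_share = 0.76,
                             landholding_meanlog = 0,
                             landholding_sdlog = 0.9,
                             distance_shape = 2,
                             distance_scale = 15.5,
                             sigma_c = 1,
                             kappa = 0.3,
                             mean_species = 5.55,
                             species_size = 3,
                             true_alpha = 4,
                             true_beta_species = 0.044,
                             true_beta_groups = 0.10,
                             true_beta_interaction = 0,
                             true_delta = NULL,
                             sigma_eps = 1.5,
                             linear_focal = c("species", "groups"),
                             subsistence_share_target = 0.33,
                             attrition_base_rate = 0.04,
                             attrition_slopes = c(head_literate = -0.3,
                                                  distance_urban = 0.004,
                                                  phone = -0.2),
                             true_country_effects = c(0, 0.3, -0.2, 0.15,
                                                      0.1, -0.1),
                             true_wave_effect = 0.05,
                             outcome_mode = c("structural", "linear"),
                             own_consume_prob = 0.75,
                             market_shift = -0.15,
                             taxonomy = default_taxonomy()) {
  if (is.null(true_delta))
    true_delta <- c(weather_shock = -0.15, cash_crop = 0.10,
                    offfarm_wage = 0.15, self_employment = 0.12,
                    head_literate = 0.30, head_sex = 0.10, phone = 0.20,
                    motorbike = 0.10, electricity = 0.20,
                    landholding = 0.02, head_age = 0,
                    distance_urban = -0.005)
  cfg <- list(seed = as.integer(seed), n_countries = as.integer(n_countries),
              districts_per_country = as.integer(districts_per_country),
              towns_per_district = as.integer(towns_per_district),
              villages_per_town = as.integer(villages_per_town),
              households_per_village = as.integer(households_per_village),
              waves_per_country = rep_len(as.integer(waves_per_country),
                                          n_countries),
              farming_share = farming_share,
              landholding_meanlog = landholding_meanlog,
              landholding_sdlog = landholding_sdlog,
              distance_shape = distance_shape,
              distance_scale = distance_scale,
              sigma_c = sigma_c, kappa = kappa,
              mean_species = mean_species, species_size = species_size,
              true_alpha = true_alpha,
              true_beta_species = true_beta_species,
              true_beta_groups = true_beta_groups,
              true_beta_interaction = true_beta_interaction,
              true_delta = true_delta, sigma_eps = sigma_eps,
              linear_focal = match.arg(linear_focal),
              subsistence_share_target = subsistence_share_target,
              attrition_base_rate = attrition_base_rate,
              attrition_slopes = attrition_slopes,
              true_country_effects = rep_len(true_country_effects,
                                             n_countries),
              true_wave_effect = true_wave_effect,
              outcome_mode = match.arg(outcome_mode),
              own_consume_prob = own_consume_prob,
              market_shift = market_shift,
              taxonomy = taxonomy)
  stopifnot(cfg$farming_share >= 0, cfg$farming_share <= 1,
            cfg$sigma_c >= 0, cfg$sigma_eps >= 0,
            all(cfg$waves_per_country >= 2L),
            cfg$attrition_base_rate >= 0, cfg$attrition_base_rate <= 1)
  class(cfg) <- "generator_config"
  cfg
}

# deterministic child stream per table: adding a table never perturbs others
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629)
}

country_codes <- c("ETH", "MWI", "NER", "NGA", "TZA", "UGA",
                   paste0("C", 7:26))

#' Generate nested survey geography
#'
#' Draws the village/town/district hierarchy and assigns each village a
#' distance to the nearest urban centre (a city of at least 20,000
#' inhabitants) from a gamma law with mean
#' `distance_shape * distance_scale` km.
#'
#' @param config a [generator_config()].
#' @return data.frame `village_id, town_id, district_id, country,
#'   distance_urban`.
#' @export
generate_geography <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(child_seed(config$seed, "geography"))
  co <- country_codes[seq_len(config$n_countries)]
  d <- expand.grid(v = seq_len(config$villages_per_town),
                   t = seq_len(config$towns_per_district),
                   d = seq_len(config$districts_per_country),
                   country = co, stringsAsFactors = FALSE)
  district_id <- sprintf("%s-D%02d", d$country, d$d)
  town_id <- sprintf("%s-T%02d", district_id, d$t)
  village_id <- sprintf("%s-V%02d", town_id, d$v)
  data.frame(village_id = village_id, town_id = town_id,
             district_id = district_id, country = d$country,
             distance_urban = stats::rgamma(nrow(d), shape = config$distance_shape,
                                            scale = config$distance_scale),
             stringsAsFactors = FALSE)
}

#' Generate household-wave observations and latent truth
#'
#' Draws the household roster over the scheduled waves of each
#' country's calendar: the latent household effect `c_i`, farm status,
#' lognormal landholding for farms, head characteristics, asset and
#' income indicators with household-level persistence, and annual
#' weather shocks. The `cash_crop` covariate is filled in later from
#' the production table.
#'
#' @param config a [generator_config()].
#' @param geography output of [generate_geography()].
#' @return list with `households` (one row per scheduled
#'   household-wave) and `truth` (`household_id`, `c_i`).
#' @export
generate_households <- function(config, geography) {
  set.seed(child_seed(config$seed, "households"))
  waves <- config$waves_per_country
  names(waves) <- country_codes[seq_len(config$n_countries)]

  nv <- nrow(geography)
  nh <- nv * config$households_per_village
  hh <- geography[rep(seq_len(nv), each = config$households_per_village), ,
                  drop = FALSE]
  hh$household_id <- sprintf("%s-H%02d", hh$village_id,
                             rep(seq_len(config$households_per_village), nv))
  rownames(hh) <- NULL

  # household-level latents
  c_i <- stats::rnorm(nh, 0, config$sigma_c)
  farmer_base <- stats::rbinom(nh, 1L, config$farming_share)
  land_base <- ifelse(farmer_base == 1L,
                      stats::rlnorm(nh, config$landholding_meanlog,
                                    config$landholding_sdlog), 0)
  head_sex <- stats::rbinom(nh, 1L, 0.2)      # 1 = female head
  head_lit <- stats::rbinom(nh, 1L, 0.55)
  age0 <- round(stats::runif(nh, 25, 68))
  z_wealth <- stats::rnorm(nh)                # persistence in assets/income

  n_waves_hh <- waves[hh$country]
  obs <- hh[rep(seq_len(nh), n_waves_hh), , drop = FALSE]
  widx <- sequence(n_waves_hh)                # wave number within country
  i <- rep(seq_len(nh), n_waves_hh)           # household index per row
  n <- nrow(obs)

  p_pers <- function(base, slope = 0.8)
    stats::plogis(stats::qlogis(base) + slope * z_wealth[i])
  flip <- stats::rbinom(n, 1L, 0.03)
  obs$wave <- widx
  obs$head_sex <- head_sex[i]
  # interview timing varies, so age does not advance in lockstep with wave
  obs$head_age <- pmax(18L, age0[i] + 2L * (widx - 1L) +
                         (stats::rbinom(n, 2L, 0.5) - 1L))
  obs$head_literate <- head_lit[i]
  obs$is_farmer <- ifelse(flip == 1L, 1L - farmer_base[i], farmer_base[i])
  obs$landholding <- ifelse(obs$is_farmer == 1L,
                            ifelse(farmer_base[i] == 1L, land_base[i],
                                   stats::rlnorm(n, config$landholding_meanlog,
                                                 config$landholding_sdlog)), 0)
  obs$phone <- stats::rbinom(n, 1L, p_pers(0.5))
  obs$motorbike <- stats::rbinom(n, 1L, p_pers(0.15))
  obs$electricity <- stats::rbinom(n, 1L, p_pers(0.30))
  obs$offfarm_wage <- stats::rbinom(n, 1L, p_pers(0.30, 0.5))
  obs$self_employment <- stats::rbinom(n, 1L, p_pers(0.35, 0.5))
  obs$weather_shock <- stats::rbinom(n, 1L, 0.2)
  obs$cash_crop <- 0L                          # filled from production
  list(households = obs,
       truth = data.frame(household_id = hh$household_id, c_i = c_i,
                          stringsAsFactors = FALSE))
}

#' Generate farm production records
#'
#' For each farm household-wave the species count is one plus an
#' overdispersed negative-binomial draw whose mean scales with
#' `exp(kappa * c_i)`, inducing the correlation between farm production
#' diversity and the unobserved household effect that the panel
#' estimators must absorb. Species are then sampled without replacement
#' with field-calibrated weights (cereal species dominate, so species
#' diversity exceeds food-group diversity), including non-food cash
#' crops.
#'
#' @param config a [generator_config()].
#' @param households output of [generate_households()].
#' @return data.frame `household_id, wave, species_code`.
#' @export
generate_production <- function(config, households) {
  set.seed(child_seed(config$seed, "production"))
  obs <- households$households
  truth <- households$truth
  farm <- obs[obs$is_farmer == 1L, c("household_id", "wave")]
  if (!nrow(farm))
    return(data.frame(household_id = character(), wave = integer(),
                      species_code = character(), stringsAsFactors = FALSE))
  c_i <- truth$c_i[match(farm$household_id, truth$household_id)]

  sp <- config$taxonomy$species_map
  w <- species_weights(sp)
  n_sp <- nrow(sp)

  mu_floor <- config$mean_species - 1
  mu0 <- mu_floor / exp((config$kappa * config$sigma_c)^2 / 2)
  mu <- mu0 * exp(config$kappa * c_i)
  count <- pmin(1L + stats::rnbinom(nrow(farm), mu = mu,
                                    size = config$species_size), n_sp)

  # weighted sampling without replacement for all farm-waves at once:
  # per row, keep the `count` smallest exponential keys rexp(1)/w
  nr <- nrow(farm)
  keys <- stats::rexp(nr * n_sp) / rep(w, each = nr)
  row <- rep.int(seq_len(nr), n_sp)
  o <- order(row, keys)
  pos <- ((seq_len(nr * n_sp) - 1L) %% n_sp) + 1L  # position within row
  keep <- pos <= count[row[o]]
  sp_idx <- rep.int(seq_len(n_sp), rep(nr, n_sp))[o][keep]
  data.frame(household_id = farm$household_id[row[o][keep]],
             wave = farm$wave[row[o][keep]],
             species_code = sp$code[sp_idx], stringsAsFactors = FALSE)
}

# sampling weights over the species registry: cereals dominate, a
# moderate livestock share, and a small cash-crop share sized so about
# a quarter of farms grow at least one cash crop
species_weights <- function(sp) {
  base <- c(maize = 0.240, sorghum = 0.080, millet = 0.060, teff = 0.030,
            wheat = 0.030, rice = 0.040, barley = 0.020,
            beans = 0.060, cowpea = 0.022, groundnut = 0.025, soybean = 0.008,
            pigeonpea = 0.006, chickpea = 0.006, sesame = 0.005,
            tomato = 0.008, cabbage = 0.005, onion = 0.007, eggplant = 0.003,
            okra = 0.004, leafy_greens = 0.008, pepper = 0.004,
            cassava = 0.028, sweet_potato = 0.016, potato = 0.010,
            yam = 0.010, cocoyam = 0.003,
            banana = 0.012, mango = 0.005, avocado = 0.003, citrus = 0.003,
            papaya = 0.002, pineapple = 0.002,
            oil_palm = 0.008, sunflower = 0.007, sugarcane = 0.008,
            cattle = 0.035, goat = 0.030, camel = 0.003, sheep = 0.025,
            pig = 0.010, chicken = 0.080, duck = 0.005, fish_pond = 0.002,
            cotton = 0.018, coffee = 0.013, tea = 0.005, tobacco = 0.013)
  w <- base[sp$code]
  w[is.na(w)] <- stats::median(base)           # user-extended taxonomies
  unname(w / sum(w))
}

# per-group marginal market-consumption probabilities (logit intercepts
# are calibrated so the pooled structural diet score matches survey
# descriptives; cereals nearly universal, eggs rare)
market_base_probs <- c(cereals = 0.97, legumes_nuts_seeds = 0.55,
                       vegetables = 0.85, roots_tubers = 0.50,
                       fruits = 0.35, eggs = 0.25, milk = 0.35,
                       fish = 0.45, meat = 0.40)

#' Generate 7-day food consumption records
#'
#' In `structural` mode each produced nutritious food group is consumed
#' from own production with probability `own_consume_prob`; market
#' purchases of each group follow a logit whose odds rise with asset
#' and income indicators and the household effect and fall with
#' distance to the nearest urban centre; other sources (gifts, food
#' aid) add each group with a small probability; the three low-nutrient
#' groups are purchased frequently but never scored. Monetary values
#' are assigned so that the own-production share of total consumption
#' value is centred on `subsistence_share_target` pooled over all
#' households.
#'
#' In `linear` mode the same record mechanism is emitted for
#' compatibility with the scoring module, and in addition a continuous
#' latent diet index following the linear data-generating equation is
#' stored per household-wave.
#'
#' @param config a [generator_config()].
#' @param households output of [generate_households()] (with `cash_crop`
#'   possibly still zero; it is recomputed here from production).
#' @param production output of [generate_production()].
#' @return list with `consumption` records, updated `households`
#'   (cash_crop filled), and `latent` (linear mode only) holding
#'   `household_id, wave, latent_hdds`.
#' @export
generate_consumption <- function(config, households, production) {
  set.seed(child_seed(config$seed, "consumption"))
  obs <- households$households
  truth <- households$truth
  tax <- config$taxonomy
  ng <- tax$nutritious_groups
  n <- nrow(obs)
  okey <- paste(obs$household_id, obs$wave, sep = "\r")
  c_i <- truth$c_i[match(obs$household_id, truth$household_id)]

  # produced nutritious groups per household-wave, as an n x 9 indicator
  spg <- species_groups(tax)
  pg <- spg[production$species_code]
  prow <- match(paste(production$household_id, production$wave, sep = "\r"),
                okey)
  long_row <- rep.int(prow, lengths(pg))
  long_grp <- match(unlist(pg, use.names = FALSE), ng)
  produced <- matrix(FALSE, n, length(ng))
  produced[cbind(long_row, long_grp)] <- TRUE

  # cash-crop covariate from production
  cash_sp <- tax$species_map$code[tax$species_map$cash_crop == 1L]
  has_cash <- unique(prow[production$species_code %in% cash_sp])
  obs$cash_crop <- 0L
  obs$cash_crop[has_cash] <- 1L

  # source-specific consumption indicators over the 9 nutritious groups
  own <- produced & matrix(stats::runif(n * length(ng)) < config$own_consume_prob,
                           n, length(ng))
  access <- 0.7 * (obs$phone + obs$motorbike + obs$electricity - 0.95) +
    0.5 * (obs$offfarm_wage + obs$self_employment - 0.65) -
    1.2 * (obs$distance_urban / 100 - 0.31)
  shift <- access + 0.25 * c_i + config$market_shift
  pm <- stats::plogis(outer(shift, stats::qlogis(market_base_probs[ng]), "+"))
  market <- matrix(stats::runif(n * length(ng)), n, length(ng)) < pm
  other <- matrix(stats::runif(n * length(ng)) < 0.07, n, length(ng))

  # low-nutrient groups arrive via purchase; they exercise the
  # exclusion rule but never enter any score
  lows <- c(spices_condiments_beverages = 0.80, sugar_sweets = 0.60,
            oils_fats = 0.70)
  low <- matrix(stats::runif(n * 3), n, 3) <
    matrix(lows, n, 3, byrow = TRUE)

  group_item <- c(cereals = "grain_staple", legumes_nuts_seeds = "pulses",
                  vegetables = "vegetables_fresh", roots_tubers = "tubers",
                  fruits = "fruit_fresh", eggs = "eggs_fresh",
                  milk = "milk_fresh", fish = "fish_dried",
                  meat = "meat_fresh",
                  spices_condiments_beverages = "tea_spices",
                  sugar_sweets = "sugar", oils_fats = "cooking_oil")

  emit <- function(mat, grp_names, source) {
    ix <- which(mat, arr.ind = TRUE)
    data.frame(household_id = obs$household_id[ix[, 1L]],
               wave = obs$wave[ix[, 1L]],
               item_code = unname(group_item[grp_names[ix[, 2L]]]),
               source = source, row = ix[, 1L], stringsAsFactors = FALSE)
  }
  rec <- rbind(emit(own, ng, "own_production"),
               emit(market, ng, "purchase"),
               emit(other, ng, "other"),
               emit(low, names(lows), "purchase"))

  # monetary values: a household total split across sources so the
  # realised own-production value share is centred on the target
  total <- stats::rlnorm(n, log(100), 0.5)
  n_own <- tabulate(rec$row[rec$source == "own_production"], nbins = n)
  n_oth <- tabulate(rec$row[rec$source == "other"], nbins = n)
  n_mkt <- tabulate(rec$row[rec$source == "purchase"], nbins = n)
  p_has_own <- mean(n_own > 0)
  m_own <- min(0.95, config$subsistence_share_target / max(p_has_own, 1e-8))
  # subsistence orientation falls with market access: households with
  # good market access (assets, proximity) buy more and grow less of
  # what they eat; renormalised so the pooled mean stays on target
  # market access (assets, income, proximity) pushes households toward
  # purchases; diverse farms eat more of what they grow
  fpdg <- rowSums(produced)
  m_i <- stats::plogis(stats::qlogis(m_own) - 2.2 * access +
                         0.25 * (fpdg - mean(fpdg[n_own > 0])))
  m_i <- pmin(0.97, pmax(0.02, m_i * m_own / mean(m_i[n_own > 0])))
  a1 <- 2
  s_own <- ifelse(n_own > 0,
                  stats::rbeta(n, a1, a1 * (1 - m_i) / m_i), 0)
  s_oth <- ifelse(n_oth > 0, stats::rbeta(n, 1, 11), 0)   # mean ~8%
  s_oth <- pmin(s_oth, 1 - s_own)
  s_mkt <- ifelse(n_mkt > 0, 1 - s_own - s_oth, 0)
  tot_w <- s_own + s_oth + s_mkt
  tot_w[tot_w == 0] <- 1
  src_share <- cbind(own_production = s_own, other = s_oth,
                     purchase = s_mkt) / tot_w
  n_src <- cbind(own_production = n_own, other = n_oth, purchase = n_mkt)
  ixs <- cbind(rec$row, match(rec$source, colnames(src_share)))
  rec$value <- total[rec$row] * src_share[ixs] / pmax(n_src[ixs], 1L)
  rec <- rec[, c("household_id", "wave", "item_code", "source", "value")]

  latent <- NULL
  if (config$outcome_mode == "linear") {
    fpd_species <- tabulate(prow, nbins = n)
    fpd_groups <- rowSums(produced)
    focal <- if (config$linear_focal == "species") fpd_species else fpd_groups
    beta <- if (config$linear_focal == "species") config$true_beta_species
            else config$true_beta_groups
    d <- config$true_delta
    co <- country_codes[seq_len(config$n_countries)]
    theta <- config$true_country_effects[match(obs$country, co)]
    xb <- config$true_alpha + beta * focal +
      config$true_beta_interaction * focal * obs$distance_urban +
      d["weather_shock"] * obs$weather_shock +
      d["cash_crop"] * obs$cash_crop +
      d["offfarm_wage"] * obs$offfarm_wage +
      d["self_employment"] * obs$self_employment +
      d["head_literate"] * obs$head_literate +
      d["head_sex"] * obs$head_sex +
      d["phone"] * obs$phone + d["motorbike"] * obs$motorbike +
      d["electricity"] * obs$electricity +
      d["landholding"] * obs$landholding +
      d["head_age"] * obs$head_age +
      d["distance_urban"] * obs$distance_urban +
      theta + config$true_wave_effect * (obs$wave - 1L) + c_i +
      stats::rnorm(n, 0, config$sigma_eps)
    latent <- data.frame(household_id = obs$household_id, wave = obs$wave,
                         latent_hdds = unname(xb), stringsAsFactors = FALSE)
  }
  list(consumption = rec, households = obs, latent = latent)
}

#' Apply permanent panel attrition
#'
#' From the second scheduled wave on, each still-present household
#' drops out with a logistic hazard in its baseline covariates; once
#' gone, a household never returns. A retention table over all
#' scheduled waves is kept for inverse-probability weighting.
#'
#' @param config a [generator_config()].
#' @param panel a `panel_dataset` over the full scheduled waves.
#' @return the `panel_dataset` with dropped household-waves removed and
#'   an `attrition` table attached.
#' @export
apply_attrition <- function(config, panel) {
  set.seed(child_seed(config$seed, "attrition"))
  hh <- panel$households
  base <- hh[hh$wave == 1L, , drop = FALSE]
  sl <- config$attrition_slopes
  xb <- stats::qlogis(min(max(config$attrition_base_rate, 1e-12),
                          1 - 1e-12)) +
    sl["head_literate"] * base$head_literate +
    sl["distance_urban"] * (base$distance_urban - 31) +
    sl["phone"] * base$phone
  hazard <- stats::plogis(xb)
  if (config$attrition_base_rate == 0) hazard[] <- 0
  if (config$attrition_base_rate == 1) hazard[] <- 1
  names(hazard) <- base$household_id

  waves <- hh$wave
  h <- hazard[hh$household_id]
  u <- stats::runif(nrow(hh))
  drop_here <- waves > 1L & u < h
  # permanent dropout: absent from the first dropped wave onward
  first_drop <- tapply(ifelse(drop_here, waves, Inf), hh$household_id, min)
  gone <- waves >= first_drop[hh$household_id]
  att <- data.frame(household_id = hh$household_id, wave = waves,
                    retained = as.integer(!gone), stringsAsFactors = FALSE)

  hh2 <- hh[!gone, , drop = FALSE]
  key <- paste(hh2$household_id, hh2$wave, sep = "\r")
  sub <- function(tab)
    tab[paste(tab$household_id, tab$wave, sep = "\r") %in% key, , drop = FALSE]
  truth <- panel$truth
  if (!is.null(truth) && !is.null(truth$latent))
    truth$latent <- sub(truth$latent)
  panel_dataset(hh2, sub(panel$consumption), sub(panel$production),
                panel$geography, panel$taxonomy, panel$wave_calendar,
                truth = truth, attrition = att)
}

#' Simulate a complete synthetic panel
#'
#' Runs geography, household, production, consumption and attrition
#' generation in sequence and assembles a validated [panel_dataset]
#' with generator truth attached. Identical config and seed give a
#' bit-identical panel.
#'
#' @param config a [generator_config()].
#' @return a `panel_dataset` with `truth` (`households`: `c_i` per
#'   household; `latent`: linear-mode latent outcome; `params`: the
#'   config used).
#' @export
simulate_panel <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  geo <- generate_geography(config)
  hhs <- generate_households(config, geo)
  prod <- generate_production(config, hhs)
  cons <- generate_consumption(config, hhs, prod)
  wc <- as.list(config$waves_per_country)
  names(wc) <- country_codes[seq_len(config$n_countries)]
  wc <- lapply(wc, seq_len)
  truth <- list(households = hhs$truth, latent = cons$latent, params = config)
  panel <- panel_dataset(cons$households, cons$consumption, prod, geo,
                         config$taxonomy, wave_calendar = wc, truth = truth)
  if (config$attrition_base_rate > 0) panel <- apply_attrition(config, panel)
  panel
}
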