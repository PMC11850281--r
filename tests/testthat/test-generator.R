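test_that("identical config and seed reproduce the panel bit for bit", {
  p1 <- simulate_panel(structural_config(5))
  p2 <- simulate_panel(structural_config(5))
  expect_identical(p1$households, p2$households)
  expect_identical(p1$consumption, p2$consumption)
  expect_identical(p1$production, p2$production)
  p3 <- simulate_panel(structural_config(6))
  expect_false(identical(p1$consumption, p3$consumption))
})

test_that("geography nests strictly and hits the distance law", {
  cfg <- generator_config(seed = 1, n_countries = 1, districts_per_country = 1,
                          towns_per_district = 1, villages_per_town = 1)
  g <- generate_geography(cfg)
  expect_equal(nrow(g), 1L)
  g2 <- generate_geography(structural_config(7))
  expect_true(all(startsWith(g2$village_id, g2$town_id)))
  expect_true(all(startsWith(g2$town_id, g2$district_id)))
  expect_true(all(g2$distance_urban >= 0))
  # mean of the gamma law ~ shape*scale = 31 km (loose at this n)
  expect_lt(abs(mean(g2$distance_urban) - 31), 3)
})

test_that("degenerate variance and confounding switches behave", {
  cfg <- structural_config(8, sigma_c = 0)
  hhs <- generate_households(cfg, generate_geography(cfg))
  expect_true(all(hhs$truth$c_i == 0))

  cfg0 <- structural_config(9, kappa = 0)
  hh0 <- generate_households(cfg0, generate_geography(cfg0))
  pr0 <- generate_production(cfg0, hh0)
  counts <- table(factor(paste(pr0$household_id, pr0$wave),
                         levels = unique(paste(pr0$household_id, pr0$wave))))
  ids <- sub(" \\d+$", "", names(counts))
  ci <- hh0$truth$c_i[match(ids, hh0$truth$household_id)]
  expect_lt(abs(cor(as.vector(counts), ci)), 0.08)
  # every farmer-wave has at least one species (floor of one)
  farm_waves <- hh0$households[hh0$households$is_farmer == 1L, ]
  expect_equal(nrow(unique(pr0[c("household_id", "wave")])), nrow(farm_waves))
})

test_that("the latent linear outcome reduces to the intercept under null truth", {
  zero_delta <- c(weather_shock = 0, cash_crop = 0, offfarm_wage = 0,
                  self_employment = 0, head_literate = 0, head_sex = 0,
                  phone = 0, motorbike = 0, electricity = 0, landholding = 0,
                  head_age = 0, distance_urban = 0)
  cfg <- linear_config(10, true_beta_species = 0, true_beta_groups = 0,
                       true_beta_interaction = 0, true_delta = zero_delta,
                       sigma_eps = 0, sigma_c = 0, true_alpha = 4,
                       true_country_effects = 0, true_wave_effect = 0)
  p <- simulate_panel(cfg)
  expect_true(all(abs(p$truth$latent$latent_hdds - 4) < 1e-12))
})

test_that("attrition is monotone, permanent and switchable", {
  cfg <- structural_config(12)
  p <- simulate_panel(cfg)                       # attrition off in fixture
  expect_null(p$attrition)

  p1 <- apply_attrition(generator_config(
    seed = 12, districts_per_country = 2, towns_per_district = 3,
    villages_per_town = 3, households_per_village = 8,
    waves_per_country = 3, attrition_base_rate = 0), p)
  expect_equal(nrow(p1$households), nrow(p$households))
  expect_true(all(p1$attrition$retained == 1L))

  pa <- simulate_panel(structural_config(13, attrition = 0.15))
  att <- pa$attrition
  att <- att[order(att$household_id, att$wave), ]
  by_hh <- split(att$retained, att$household_id)
  expect_true(all(vapply(by_hh, function(r) all(diff(r) <= 0), TRUE)))

  p_all <- apply_attrition(generator_config(
    seed = 13, districts_per_country = 2, towns_per_district = 3,
    villages_per_town = 3, households_per_village = 8,
    waves_per_country = 3, attrition_base_rate = 1), p)
  expect_true(all(table(p_all$households$household_id) == 1L))
  expect_true(all(p_all$households$wave == 1L))
})

test_that("probe-scale panels sit near the calibrated descriptive anchors", {
  p <- simulate_panel(generator_config(
    seed = 30, districts_per_country = 3, towns_per_district = 4,
    villages_per_town = 8))
  sc <- score_panel(p)
  farm <- sc$fpd_species > 0L
  expect_lt(abs(mean(sc$fpd_species[farm]) - 5.55), 0.4)
  expect_lt(abs(mean(sc$hdds) - 5.66), 0.3)
  expect_lt(abs(100 * mean(sc$own_value_share, na.rm = TRUE) - 33), 3)
  hh1 <- p$households[p$households$is_farmer == 1L &
                      !duplicated(p$households$household_id), ]
  expect_gt(mean(hh1$landholding < 2), 0.72)
})
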