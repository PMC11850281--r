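test_that("unit-level diversity is the union over member farms", {
  p <- tiny_panel()
  # village V1 wave 1: h1 produces {cereals, legumes}, h2 {meat, milk}
  v <- aggregate_lpd(p, "village")
  r <- v[v$unit_id == "A-D1-T1-V1" & v$wave == 1L, ]
  expect_equal(r$lpd, 4L)
  expect_equal(r$n_farmers, 2L)
  # V2 has no sampled farms: empty unit
  r2 <- v[v$unit_id == "A-D1-T1-V2" & v$wave == 1L, ]
  expect_equal(r2$lpd, 0L)
  expect_equal(r2$n_farmers, 0L)
  expect_equal(r2$valid, 0L)
})

test_that("town aggregates equal the union recomputed from raw records", {
  p <- simulate_panel(structural_config(21))
  tw <- aggregate_lpd(p, "town")
  spg <- lapply(strsplit(p$taxonomy$species_map$groups, ";"),
                function(g) intersect(g[nzchar(g)], p$taxonomy$nutritious_groups))
  names(spg) <- p$taxonomy$species_map$code
  hh_town <- p$households$town_id[match(
    paste(p$production$household_id, p$production$wave),
    paste(p$households$household_id, p$households$wave))]
  set.seed(2)
  for (k in sample(nrow(tw), 20)) {
    sel <- hh_town == tw$unit_id[k] & p$production$wave == tw$wave[k]
    oracle <- length(unique(unlist(spg[p$production$species_code[sel]])))
    expect_equal(tw$lpd[k], oracle)
  }
  # permutation invariance over member farms
  p2 <- p
  p2$production <- p$production[rev(seq_len(nrow(p$production))), ]
  expect_equal(aggregate_lpd(p2, "town"), tw)
})

test_that("singleton-farm village-waves are excluded", {
  p <- simulate_panel(structural_config(22))
  v <- apply_village_exclusions(aggregate_lpd(p, "village"))
  expect_true(all(v$valid[v$n_farmers <= 1L] == 0L))
  expect_true(all(v$valid[v$n_farmers >= 2L] == 1L))
  expect_equal(attr(v, "n_excluded"),
               sum(v$n_farmers == 1L))  # zero-farm units were already invalid
  # the rule leaves town/district records untouched
  tw <- apply_village_exclusions(aggregate_lpd(p, "town"))
  expect_true(all(tw$valid[tw$n_farmers == 1L] == 1L))
})

test_that("joined households share their unit's diversity and counts add up", {
  p <- simulate_panel(structural_config(23))
  v <- apply_village_exclusions(aggregate_lpd(p, "village"))
  j <- join_lpd_to_households(p, v, "village")
  # two households of the same village-wave carry identical lpd
  hh <- merge(j, p$households[, c("household_id", "wave", "village_id")])
  one <- hh[hh$village_id == hh$village_id[1] & hh$wave == hh$wave[1], ]
  expect_true(length(unique(one$lpd)) == 1L)
  # accounting identity: joined rows = households in valid unit-waves
  valid_units <- paste(v$unit_id, v$wave)[v$valid == 1L]
  expected_n <- sum(paste(p$households$village_id, p$households$wave) %in%
                    valid_units)
  expect_equal(nrow(j), expected_n)
  expect_error(join_lpd_to_households(p, v, "town"), "aggregated at scale")
})

test_that("diversity is monotone across nested scales and dominates farms", {
  p <- simulate_panel(structural_config(24))
  sc <- score_panel(p)
  jv <- join_lpd_to_households(p, aggregate_lpd(p, "village"), "village")
  jt <- join_lpd_to_households(p, aggregate_lpd(p, "town"), "town")
  jd <- join_lpd_to_households(p, aggregate_lpd(p, "district"), "district")
  m <- merge(merge(jv, jt, by = c("household_id", "wave"),
                   suffixes = c("_v", "_t")),
             jd, by = c("household_id", "wave"))
  expect_true(all(m$lpd_v <= m$lpd_t))
  expect_true(all(m$lpd_t <= m$lpd))
  # a sampled farm's own group diversity never exceeds its village's
  mv <- merge(jv, sc, by = c("household_id", "wave"))
  expect_true(all(mv$fpd_groups <= mv$lpd))
})
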