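test_that("HDDS counts nutritious groups only, split by source", {
  cn <- data.frame(item_code = c("grain_staple", "pulses", "sugar"),
                   source = c("purchase", "own_production", "purchase"),
                   stringsAsFactors = FALSE)
  s <- compute_hdds(cn, tax)
  expect_equal(s$hdds, 2L)          # sugar excluded
  expect_equal(s$hdds_own, 1L)
  expect_equal(s$hdds_market, 1L)
  expect_equal(s$hdds_other, 0L)

  empty <- compute_hdds(cn[0, ], tax)
  expect_equal(unlist(empty), c(hdds = 0L, hdds_own = 0L, hdds_market = 0L,
                                hdds_other = 0L))
  cn$item_code[1] <- "mystery_item"
  expect_error(compute_hdds(cn, tax), "mystery_item")
})

test_that("HDDS matches a brute-force set-union oracle on random records", {
  set.seed(101)
  items <- tax$item_map$code
  srcs <- c("own_production", "purchase", "other")
  for (rep in 1:10) {
    cn <- data.frame(item_code = sample(items, 60, replace = TRUE),
                     source = sample(srcs, 60, replace = TRUE),
                     stringsAsFactors = FALSE)
    s <- compute_hdds(cn, tax)
    # oracle: literal set unions
    grp <- tax$item_map$group[match(cn$item_code, tax$item_map$code)]
    nutri <- grp %in% tax$nutritious_groups
    oracle <- function(sel) length(unique(grp[nutri & sel]))
    expect_equal(s$hdds, oracle(rep(TRUE, 60)))
    expect_equal(s$hdds_own, oracle(cn$source == "own_production"))
    expect_equal(s$hdds_market, oracle(cn$source == "purchase"))
    expect_equal(s$hdds_other, oracle(cn$source == "other"))
    # invariants: components bound the total
    expect_lte(max(s$hdds_own, s$hdds_market, s$hdds_other), s$hdds)
    expect_lte(s$hdds, s$hdds_own + s$hdds_market + s$hdds_other)
    # duplication and order invariance
    dup <- rbind(cn, cn[sample(60), ])
    expect_equal(compute_hdds(dup, tax)$hdds, s$hdds)
  }
})

test_that("FPD counts species and the union of produced food groups", {
  pr <- data.frame(species_code = c("maize", "sorghum", "cattle", "cotton"),
                   stringsAsFactors = FALSE)
  s <- compute_fpd(pr, tax)
  expect_equal(s$fpd_species, 4L)
  expect_equal(s$fpd_groups, 3L)    # cereals, meat, milk
  expect_equal(s$crop_groups, 1L)
  expect_equal(s$livestock_groups, 2L)
  expect_equal(s$cash_crop, 1L)
  # excluding cash-crop species from the count is switchable
  expect_equal(compute_fpd(pr, tax, include_cash_species = FALSE)$fpd_species,
               3L)
  expect_equal(unlist(compute_fpd(pr[0, , drop = FALSE], tax)),
               c(fpd_species = 0L, fpd_groups = 0L, crop_groups = 0L,
                 livestock_groups = 0L, cash_crop = 0L))
  expect_error(compute_fpd(data.frame(species_code = "unicorn"), tax),
               "unicorn")
})

test_that("FPD matches a brute-force union oracle and group-count regimes", {
  set.seed(102)
  all_sp <- tax$species_map$code
  gmap <- lapply(strsplit(tax$species_map$groups, ";"),
                 function(g) intersect(g[nzchar(g)], tax$nutritious_groups))
  names(gmap) <- all_sp
  for (rep in 1:10) {
    pr <- data.frame(species_code = sample(all_sp, 12), stringsAsFactors = FALSE)
    s <- compute_fpd(pr, tax)
    expect_equal(s$fpd_groups,
                 length(unique(unlist(gmap[pr$species_code]))))
  }
  # crops map to <= 1 group each, so group count <= species count
  crops <- c("maize", "beans", "tomato", "cassava", "banana")
  expect_lte(compute_fpd(data.frame(species_code = crops), tax)$fpd_groups,
             length(crops))
  # a single multi-group livestock species breaks that bound
  s <- compute_fpd(data.frame(species_code = "cattle"), tax)
  expect_gt(s$fpd_groups, s$fpd_species - 1L)
  expect_equal(s$fpd_groups, 2L)
})

test_that("subsistence share uses a strict threshold", {
  cn <- data.frame(source = c("own_production", "purchase"), value = c(60, 40))
  s <- compute_subsistence(cn)
  expect_equal(s$own_value_share, 0.6)
  expect_equal(s$subsistence, 1L)
  cn$value <- c(50, 50)
  s <- compute_subsistence(cn)                 # exactly half: not subsistence
  expect_equal(s$own_value_share, 0.5)
  expect_equal(s$subsistence, 0L)
  expect_true(is.na(compute_subsistence(cn[0, ])$own_value_share))
  zero <- data.frame(source = "purchase", value = 0)
  expect_true(is.na(compute_subsistence(zero)$own_value_share))
})

test_that("panel scoring agrees with per-household recomputation", {
  p <- simulate_panel(structural_config(11))
  sc <- score_panel(p)
  expect_equal(nrow(sc), nrow(p$households))
  # spot-check 25 random household-waves against the scalar functions
  set.seed(1)
  for (k in sample(nrow(sc), 25)) {
    hw <- sc[k, ]
    cn <- p$consumption[p$consumption$household_id == hw$household_id &
                        p$consumption$wave == hw$wave, ]
    pr <- p$production[p$production$household_id == hw$household_id &
                       p$production$wave == hw$wave, ]
    expect_equal(hw$hdds, compute_hdds(cn, tax)$hdds)
    expect_equal(hw$fpd_species, compute_fpd(pr, tax)$fpd_species)
    expect_equal(hw$fpd_groups, compute_fpd(pr, tax)$fpd_groups)
    sub <- compute_subsistence(cn)
    expect_equal(hw$own_value_share, sub$own_value_share)
  }
  # score invariants over the whole panel
  expect_true(all(sc$hdds <= 9L & sc$hdds >= 0L))
  expect_true(all(pmax(sc$hdds_own, sc$hdds_market, sc$hdds_other) <= sc$hdds))
  expect_true(all(sc$hdds <= sc$hdds_own + sc$hdds_market + sc$hdds_other))
  ok <- !is.na(sc$own_value_share)
  expect_true(all(sc$own_value_share[ok] >= 0 & sc$own_value_share[ok] <= 1))
  # non-farmers have no production but keep their consumption scores
  nf <- merge(sc, p$households[, c("household_id", "wave", "is_farmer")])
  expect_true(all(nf$fpd_species[nf$is_farmer == 0L] == 0L))
  expect_true(any(nf$hdds[nf$is_farmer == 0L] > 0L))
})
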