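#' Long-format household panel container
#'
#' A `panel_dataset` bundles the four interchange tables the analysis
#' consumes — household-wave observations, 7-day food consumption
#' records, farm production records and village geography — together
#' with a [food_taxonomy] and a per-country wave calendar. All
#' referential invariants are checked at construction: geography ids
#' nest strictly (village in town in district in country), every
#' consumption and production row matches an observed household-wave,
#' items and species resolve in the taxonomy, and keys are unique.
#'
#' @param households data.frame of household-wave observations. Required
#'   columns: `household_id, country, district_id, town_id, village_id,
#'   wave, head_sex, head_age, head_literate, landholding, phone,
#'   motorbike, electricity, offfarm_wage, self_employment, cash_crop,
#'   weather_shock, distance_urban, is_farmer`.
#' @param consumption data.frame: `household_id, wave, item_code,
#'   source, value` with `source` one of `own_production`, `purchase`,
#'   `other` and `value >= 0`.
#' @param production data.frame: `household_id, wave, species_code`.
#' @param geography data.frame: `village_id, town_id, district_id,
#'   country, distance_urban`.
#' @param taxonomy A [food_taxonomy].
#' @param wave_calendar named list, country -> integer vector of waves.
#'   Defaults to the waves observed per country.
#' @param truth optional generator truth (latent household effects and
#'   latent outcome index); kept for parameter-recovery checks.
#' @param attrition optional data.frame `household_id, wave, retained`
#'   recording scheduled waves and realised retention.
#' @return An object of class `panel_dataset`.
#' @export
panel_dataset <- function(households, consumption, production, geography,
                          taxonomy, wave_calendar = NULL, truth = NULL,
                          attrition = NULL) {
  stopifnot(inherits(taxonomy, "food_taxonomy"))
  households <- as.data.frame(households, stringsAsFactors = FALSE)
  consumption <- as.data.frame(consumption, stringsAsFactors = FALSE)
  production <- as.data.frame(production, stringsAsFactors = FALSE)
  geography <- as.data.frame(geography, stringsAsFactors = FALSE)

  hh_cols <- c("household_id", "country", "district_id", "town_id",
               "village_id", "wave", "head_sex", "head_age", "head_literate",
               "landholding", "phone", "motorbike", "electricity",
               "offfarm_wage", "self_employment", "cash_crop",
               "weather_shock", "distance_urban", "is_farmer")
  miss <- setdiff(hh_cols, names(households))
  if (length(miss))
    stop("households table missing columns: ", paste(miss, collapse = ", "))
  miss <- setdiff(c("household_id", "wave", "item_code", "source", "value"),
                  names(consumption))
  if (length(miss))
    stop("consumption table missing columns: ", paste(miss, collapse = ", "))
  miss <- setdiff(c("household_id", "wave", "species_code"),
                  names(production))
  if (length(miss))
    stop("production table missing columns: ", paste(miss, collapse = ", "))
  miss <- setdiff(c("village_id", "town_id", "district_id", "country",
                    "distance_urban"), names(geography))
  if (length(miss))
    stop("geography table missing columns: ", paste(miss, collapse = ", "))

  if (is.null(wave_calendar)) {
    wave_calendar <- lapply(split(households$wave, households$country),
                            function(w) sort(unique(as.integer(w))))
  }

  x <- structure(list(households = households, consumption = consumption,
                      production = production, geography = geography,
                      taxonomy = taxonomy, wave_calendar = wave_calendar,
                      truth = truth, attrition = attrition),
                 class = "panel_dataset")
  validate_panel(x)
  x
}

#' Validate a panel dataset
#'
#' Checks every declared invariant and stops with a descriptive error on
#' the first violation (orphan keys are listed). Called automatically by
#' [panel_dataset()] and [read_panel()].
#'
#' @param x A `panel_dataset`.
#' @return `x`, invisibly.
#' @export
validate_panel <- function(x) {
  hh <- x$households
  key <- paste(hh$household_id, hh$wave, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (household_id, wave) keys in households: ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = ", "))
  if (any(hh$landholding < 0, na.rm = TRUE)) stop("negative landholding")
  if (any(hh$distance_urban < 0, na.rm = TRUE)) stop("negative distance_urban")

  # strict geographic nesting: each lower unit maps to exactly one parent
  nest <- function(child, parent, what) {
    m <- unique(data.frame(c = child, p = parent, stringsAsFactors = FALSE))
    if (anyDuplicated(m$c))
      stop("broken geographic nesting: ", what, " maps to multiple parents: ",
           paste(utils::head(unique(m$c[duplicated(m$c)]), 5), collapse = ", "))
  }
  nest(hh$village_id, hh$town_id, "village")
  nest(hh$town_id, hh$district_id, "town")
  nest(hh$district_id, hh$country, "district")

  orphan <- setdiff(unique(hh$village_id), x$geography$village_id)
  if (length(orphan))
    stop("households reference villages absent from geography: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  gm <- match(hh$village_id, x$geography$village_id)
  bad <- hh$town_id != x$geography$town_id[gm] |
    hh$district_id != x$geography$district_id[gm] |
    hh$country != x$geography$country[gm]
  if (any(bad))
    stop("household geography disagrees with the geography table ",
         "(broken nesting) for villages: ",
         paste(utils::head(unique(hh$village_id[bad]), 5), collapse = ", "))

  check_ref <- function(tab, what) {
    if (!nrow(tab)) return(invisible())
    k <- paste(tab$household_id, tab$wave, sep = "\r")
    orphan <- setdiff(unique(k), key)
    if (length(orphan))
      stop(what, " rows reference unknown household-waves: ",
           paste(gsub("\r", "/", utils::head(orphan, 5)), collapse = ", "))
  }
  check_ref(x$consumption, "consumption")
  check_ref(x$production, "production")

  cn <- x$consumption
  if (nrow(cn)) {
    bad <- setdiff(unique(cn$source), c("own_production", "purchase", "other"))
    if (length(bad))
      stop("unknown consumption source: ", paste(bad, collapse = ", "))
    if (any(cn$value < 0, na.rm = TRUE)) stop("negative consumption value")
    bad <- setdiff(unique(cn$item_code), x$taxonomy$item_map$code)
    if (length(bad))
      stop("consumption items not in taxonomy: ", paste(bad, collapse = ", "))
  }
  pr <- x$production
  if (nrow(pr)) {
    bad <- setdiff(unique(pr$species_code), x$taxonomy$species_map$code)
    if (length(bad))
      stop("production species not in taxonomy: ", paste(bad, collapse = ", "))
    k <- paste(pr$household_id, pr$wave, pr$species_code, sep = "\r")
    if (anyDuplicated(k))
      stop("duplicate (household, wave, species) production rows")
  }
  bad <- setdiff(unique(hh$country), names(x$wave_calendar))
  if (length(bad))
    stop("countries missing from wave calendar: ", paste(bad, collapse = ", "))
  invisible(x)
}

panel_files <- c(households = "households.csv", consumption = "consumption.csv",
                 production = "production.csv", geography = "geography.csv",
                 taxonomy = "taxonomy.csv")

#' Read and write the panel interchange directory
#'
#' The interchange format is a directory of UTF-8 comma-separated files
#' with header rows: `households.csv`, `consumption.csv`,
#' `production.csv`, `geography.csv`, `taxonomy.csv`, and optionally
#' `truth.csv` and `attrition.csv` written by the synthetic generator.
#' `write_panel()` writes canonically sorted rows and fixed column
#' order, so outputs are diffable and `read_panel(write_panel(x))`
#' reproduces `x`.
#'
#' @param dir directory containing (or to receive) the CSV files.
#' @param taxonomy optional [food_taxonomy]; by default read from
#'   `taxonomy.csv` in `dir`.
#' @return `read_panel()` a validated `panel_dataset`; `write_panel()`
#'   the directory path, invisibly.
#' @export
read_panel <- function(dir, taxonomy = NULL) {
  for (f in panel_files[c("households", "consumption", "production",
                          "geography")]) {
    if (!file.exists(file.path(dir, f)))
      stop("missing interchange file: ", file.path(dir, f))
  }
  if (is.null(taxonomy)) taxonomy <- read_taxonomy(file.path(dir, "taxonomy.csv"))
  rd <- function(f, classes) {
    p <- file.path(dir, f)
    x <- tryCatch(utils::read.csv(p, stringsAsFactors = FALSE,
                                  colClasses = classes),
                  error = function(e) stop("cannot parse ", p, ": ",
                                           conditionMessage(e), call. = FALSE))
    x
  }
  hh <- rd("households.csv", NA)
  cn <- rd("consumption.csv", NA)
  pr <- rd("production.csv", NA)
  geo <- rd("geography.csv", NA)
  truth <- NULL
  if (file.exists(file.path(dir, "truth.csv"))) {
    tr <- rd("truth.csv", NA)
    truth <- list(
      households = unique(tr[, c("household_id", "c_i")]),
      latent = tr[, c("household_id", "wave", "latent_hdds")],
      params = NULL
    )
  }
  attr_tab <- if (file.exists(file.path(dir, "attrition.csv")))
    rd("attrition.csv", NA) else NULL
  panel_dataset(hh, cn, pr, geo, taxonomy, truth = truth,
                attrition = attr_tab)
}

#' @rdname read_panel
#' @param x A `panel_dataset`.
#' @export
write_panel <- function(x, dir) {
  stopifnot(inherits(x, "panel_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(tab, ord, f) {
    tab <- tab[do.call(order, tab[ord]), , drop = FALSE]
    utils::write.csv(tab, file.path(dir, f), row.names = FALSE, quote = FALSE)
  }
  hh_cols <- c("household_id", "country", "district_id", "town_id",
               "village_id", "wave", "head_sex", "head_age", "head_literate",
               "landholding", "phone", "motorbike", "electricity",
               "offfarm_wage", "self_employment", "cash_crop",
               "weather_shock", "distance_urban", "is_farmer")
  wr(x$households[hh_cols], c("household_id", "wave"), "households.csv")
  wr(x$consumption[c("household_id", "wave", "item_code", "source", "value")],
     c("household_id", "wave", "item_code", "source"), "consumption.csv")
  wr(x$production[c("household_id", "wave", "species_code")],
     c("household_id", "wave", "species_code"), "production.csv")
  wr(x$geography[c("village_id", "town_id", "district_id", "country",
                   "distance_urban")], "village_id", "geography.csv")
  write_taxonomy(x$taxonomy, file.path(dir, "taxonomy.csv"))
  if (!is.null(x$truth)) {
    tr <- merge(x$truth$latent, x$truth$households, by = "household_id")
    wr(tr[c("household_id", "wave", "c_i", "latent_hdds")],
       c("household_id", "wave"), "truth.csv")
  }
  if (!is.null(x$attrition))
    wr(x$attrition[c("household_id", "wave", "retained")],
       c("household_id", "wave"), "attrition.csv")
  invisible(dir)
}

#' Restrict a panel to an estimation sample
#'
#' `farmers_only` keeps household-waves with `is_farmer == 1`;
#' `balanced` keeps households observed in every wave of their
#' country's calendar; `all` is the identity. Consumption and
#' production rows of dropped observations are removed too.
#'
#' @param x A `panel_dataset`.
#' @param rule one of `"all"`, `"farmers_only"`, `"balanced"`.
#' @return A filtered `panel_dataset`.
#' @export
filter_sample <- function(x, rule = c("all", "farmers_only", "balanced")) {
  stopifnot(inherits(x, "panel_dataset"))
  rule <- match.arg(rule)
  hh <- x$households
  keep <- switch(rule,
    all = rep(TRUE, nrow(hh)),
    farmers_only = hh$is_farmer == 1L,
    balanced = {
      n_obs <- table(hh$household_id)
      n_cal <- vapply(x$wave_calendar, length, 1L)[hh$country]
      as.vector(n_obs[hh$household_id]) == n_cal
    })
  hh2 <- hh[keep, , drop = FALSE]
  key <- paste(hh2$household_id, hh2$wave, sep = "\r")
  sub <- function(tab)
    tab[paste(tab$household_id, tab$wave, sep = "\r") %in% key, , drop = FALSE]
  truth <- x$truth
  if (!is.null(truth)) {
    truth$households <- truth$households[
      truth$households$household_id %in% unique(hh2$household_id), ,
      drop = FALSE]
    truth$latent <- sub(truth$latent)
  }
  panel_dataset(hh2, sub(x$consumption), sub(x$production), x$geography,
                x$taxonomy, x$wave_calendar, truth = truth,
                attrition = x$attrition)
}

#' Trim consumption-value outliers
#'
#' Drops household-waves whose total consumption value falls outside
#' the given quantiles of their country-wave distribution. Surveys
#' often exclude implausible consumption totals; the 1st/99th
#' percentile window is a conventional, reproducible choice. Off by
#' default in the pipelines — synthetic data contain no recording
#' errors — and applied only when called explicitly.
#'
#' @param x a [panel_dataset].
#' @param lower,upper quantile bounds within country-wave.
#' @return the trimmed `panel_dataset`; attribute `n_trimmed` counts
#'   dropped household-waves.
#' @export
trim_outliers <- function(x, lower = 0.01, upper = 0.99) {
  stopifnot(inherits(x, "panel_dataset"), lower < upper)
  cn <- x$consumption
  hh <- x$households
  key <- paste(cn$household_id, cn$wave, sep = "\r")
  tot <- rowsum(cn$value, key)
  okey <- paste(hh$household_id, hh$wave, sep = "\r")
  total <- tot[match(okey, rownames(tot)), 1L]
  total[is.na(total)] <- 0
  grp <- paste(hh$country, hh$wave, sep = "\r")
  lo <- stats::ave(total, grp, FUN = function(v) stats::quantile(v, lower))
  hi <- stats::ave(total, grp, FUN = function(v) stats::quantile(v, upper))
  keep <- total >= lo & total <= hi
  hh2 <- hh[keep, , drop = FALSE]
  k2 <- okey[keep]
  sub <- function(tab)
    tab[paste(tab$household_id, tab$wave, sep = "\r") %in% k2, , drop = FALSE]
  out <- panel_dataset(hh2, sub(x$consumption), sub(x$production),
                       x$geography, x$taxonomy, x$wave_calendar,
                       truth = x$truth, attrition = x$attrition)
  attr(out, "n_trimmed") <- sum(!keep)
  out
}

#' @export
print.panel_dataset <- function(x, ...) {
  hh <- x$households
  cat("<panel_dataset>\n")
  cat(sprintf("  %d household-wave observations, %d households, %d countries\n",
              nrow(hh), length(unique(hh$household_id)),
              length(unique(hh$country))))
  cat(sprintf("  %d consumption rows, %d production rows, %d villages\n",
              nrow(x$consumption), nrow(x$production), nrow(x$geography)))
  if (!is.null(x$truth)) cat("  generator truth attached\n")
  invisible(x)
}
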