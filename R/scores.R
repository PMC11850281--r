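#' Household dietary diversity score for one household-wave
#'
#' Counts the distinct nutritious food groups (9 of the 12 standard
#' groups; sugar/sweets, oils/fats and spices/condiments/beverages are
#' excluded) consumed over the 7-day recall, in total and separately by
#' source (own production, market purchase, other).
#'
#' @param consumption data.frame of consumption records for a single
#'   household-wave (`item_code`, `source`; may be empty).
#' @param taxonomy a [food_taxonomy].
#' @return list with `hdds`, `hdds_own`, `hdds_market`, `hdds_other`.
#' @export
compute_hdds <- function(consumption, taxonomy) {
  if (!nrow(consumption))
    return(list(hdds = 0L, hdds_own = 0L, hdds_market = 0L, hdds_other = 0L))
  g <- taxonomy$item_map$group[match(consumption$item_code,
                                     taxonomy$item_map$code)]
  if (anyNA(g))
    stop("unresolvable item code(s): ",
         paste(unique(consumption$item_code[is.na(g)]), collapse = ", "))
  keep <- g %in% taxonomy$nutritious_groups
  g <- g[keep]; src <- consumption$source[keep]
  list(hdds = length(unique(g)),
       hdds_own = length(unique(g[src == "own_production"])),
       hdds_market = length(unique(g[src == "purchase"])),
       hdds_other = length(unique(g[src == "other"])))
}

#' Farm production diversity for one farm-wave
#'
#' Two diversity metrics: the number of distinct species produced
#' (crops and livestock, including non-food cash crops), and the number
#' of distinct nutritious food groups those species yield (union over
#' species; multi-product livestock such as cattle contribute both meat
#' and milk). Crop and livestock food-group counts are reported
#' separately, plus an indicator for any cash-crop species.
#'
#' @param production data.frame of production records for one
#'   household-wave (`species_code`; may be empty).
#' @param taxonomy a [food_taxonomy].
#' @param include_cash_species logical; count cash-crop species in the
#'   species metric (default TRUE; they never contribute food groups).
#' @return list with `fpd_species`, `fpd_groups`, `crop_groups`,
#'   `livestock_groups`, `cash_crop`.
#' @export
compute_fpd <- function(production, taxonomy, include_cash_species = TRUE) {
  if (!nrow(production))
    return(list(fpd_species = 0L, fpd_groups = 0L, crop_groups = 0L,
                livestock_groups = 0L, cash_crop = 0L))
  sp <- unique(production$species_code)
  m <- match(sp, taxonomy$species_map$code)
  if (anyNA(m))
    stop("unresolvable species code(s): ",
         paste(sp[is.na(m)], collapse = ", "))
  cash <- taxonomy$species_map$cash_crop[m] == 1L
  cls <- taxonomy$species_map$class[m]
  gl <- species_groups(taxonomy)[sp]
  list(fpd_species = if (include_cash_species) length(sp)
                     else sum(!cash),
       fpd_groups = length(unique(unlist(gl, use.names = FALSE))),
       crop_groups = length(unique(unlist(gl[cls == "crop"],
                                          use.names = FALSE))),
       livestock_groups = length(unique(unlist(gl[cls == "livestock"],
                                               use.names = FALSE))),
       cash_crop = as.integer(any(cash)))
}

#' Own-production share of consumption value
#'
#' The subsistence share is the monetary value of food consumed from
#' own production over the total value consumed from all sources. A
#' household is classed as a subsistence household when that share
#' strictly exceeds the threshold (more than 50% by default).
#'
#' @param consumption data.frame of records for one household-wave
#'   (`source`, `value`).
#' @param threshold subsistence cut-off on the share (strict).
#' @return list with `own_value_share` (NA when total value is zero)
#'   and `subsistence` (0/1, NA when the share is undefined).
#' @export
compute_subsistence <- function(consumption, threshold = 0.5) {
  total <- sum(consumption$value)
  if (!nrow(consumption) || total <= 0)
    return(list(own_value_share = NA_real_, subsistence = NA_integer_))
  share <- sum(consumption$value[consumption$source == "own_production"]) / total
  list(own_value_share = share,
       subsistence = as.integer(share > threshold))
}

#' Score every household-wave of a panel
#'
#' Vectorised application of [compute_hdds()], [compute_fpd()] and
#' [compute_subsistence()] to all observations, in deterministic
#' (household, wave) order. Household-waves with zero recorded
#' consumption value get `own_value_share = NA` and are excluded from
#' subsistence classification downstream.
#'
#' @param panel a [panel_dataset].
#' @param subsistence_threshold passed to [compute_subsistence()].
#' @param include_cash_species passed to [compute_fpd()].
#' @return data.frame with one row per household-wave: the identifiers,
#'   all diversity scores, `own_value_share` and `subsistence`.
#' @export
score_panel <- function(panel, subsistence_threshold = 0.5,
                        include_cash_species = TRUE) {
  stopifnot(inherits(panel, "panel_dataset"))
  tax <- panel$taxonomy
  hh <- panel$households
  ord <- order(hh$household_id, hh$wave)
  hh <- hh[ord, , drop = FALSE]
  n <- nrow(hh)
  okey <- paste(hh$household_id, hh$wave, sep = "\r")

  out <- data.frame(household_id = hh$household_id, wave = hh$wave,
                    stringsAsFactors = FALSE)

  # distinct (obs, group, source) consumption combinations
  cn <- panel$consumption
  if (nrow(cn)) {
    row <- match(paste(cn$household_id, cn$wave, sep = "\r"), okey)
    grp <- tax$item_map$group[match(cn$item_code, tax$item_map$code)]
    nutri <- grp %in% tax$nutritious_groups
    count_distinct <- function(sel) {
      k <- paste(row[sel], grp[sel], sep = "\r")
      tabulate(row[sel][!duplicated(k)], nbins = n)
    }
    out$hdds <- count_distinct(nutri)
    out$hdds_own <- count_distinct(nutri & cn$source == "own_production")
    out$hdds_market <- count_distinct(nutri & cn$source == "purchase")
    out$hdds_other <- count_distinct(nutri & cn$source == "other")
    total_v <- rowsum_vec(cn$value, row, n)
    own_v <- rowsum_vec(ifelse(cn$source == "own_production", cn$value, 0),
                        row, n)
    out$own_value_share <- ifelse(total_v > 0, own_v / total_v, NA_real_)
    out$subsistence <- ifelse(is.na(out$own_value_share), NA_integer_,
                              as.integer(out$own_value_share >
                                         subsistence_threshold))
  } else {
    out$hdds <- out$hdds_own <- out$hdds_market <- out$hdds_other <- 0L
    out$own_value_share <- NA_real_
    out$subsistence <- NA_integer_
  }

  # production metrics via distinct (obs, species) / (obs, group) pairs
  pr <- panel$production
  out$fpd_species <- out$fpd_groups <- out$crop_groups <-
    out$livestock_groups <- 0L
  out$cash_crop <- 0L
  if (nrow(pr)) {
    prow <- match(paste(pr$household_id, pr$wave, sep = "\r"), okey)
    sm <- tax$species_map
    mi <- match(pr$species_code, sm$code)
    cash <- sm$cash_crop[mi] == 1L
    counted <- if (include_cash_species) rep(TRUE, nrow(pr)) else !cash
    k <- paste(prow, pr$species_code, sep = "\r")
    dup <- duplicated(k)
    out$fpd_species <- tabulate(prow[counted & !dup], nbins = n)
    out$cash_crop <- as.integer(tabulate(prow[cash & !dup], nbins = n) > 0L)

    spg <- species_groups(tax)
    gl <- spg[pr$species_code[!dup]]
    gr_row <- rep.int(prow[!dup], lengths(gl))
    gr_cls <- rep.int(sm$class[mi][!dup], lengths(gl))
    gr <- unlist(gl, use.names = FALSE)
    dg <- function(sel) {
      kk <- paste(gr_row[sel], gr[sel], sep = "\r")
      tabulate(gr_row[sel][!duplicated(kk)], nbins = n)
    }
    all_sel <- rep(TRUE, length(gr))
    out$fpd_groups <- dg(all_sel)
    out$crop_groups <- dg(gr_cls == "crop")
    out$livestock_groups <- dg(gr_cls == "livestock")
  }
  rownames(out) <- NULL
  out
}

# grouped sum into a fixed-length vector
rowsum_vec <- function(v, g, n) {
  s <- rowsum(v, g)
  out <- numeric(n)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}
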