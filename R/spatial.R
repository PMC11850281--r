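#' Food-group production diversity at village, town or district scale
#'
#' For every unit-wave at the requested scale, counts the distinct
#' nutritious food groups produced by the sampled farm households
#' residing in the unit (the union over member farms), together with
#' the number of sampled farm households. Sampled farms are
#' household-waves with at least one production record.
#'
#' @param panel a [panel_dataset].
#' @param scale `"village"`, `"town"` or `"district"`.
#' @return data.frame `scale, unit_id, wave, lpd, n_farmers, valid`
#'   (valid is 1 unless the unit-wave has no sampled farms; village
#'   singleton exclusions are applied separately by
#'   [apply_village_exclusions()]).
#' @export
aggregate_lpd <- function(panel, scale = c("village", "town", "district")) {
  stopifnot(inherits(panel, "panel_dataset"))
  scale <- match.arg(scale)
  unit_col <- paste0(scale, "_id")
  hh <- panel$households
  pr <- panel$production
  tax <- panel$taxonomy

  hkey <- paste(hh$household_id, hh$wave, sep = "\r")
  unit <- hh[[unit_col]]

  # all scheduled unit-waves at this scale (units crossed with the
  # waves their country's households are observed in)
  uw <- unique(data.frame(unit_id = unit, wave = hh$wave,
                          stringsAsFactors = FALSE))
  uw <- uw[order(uw$unit_id, uw$wave), , drop = FALSE]
  ukey <- paste(uw$unit_id, uw$wave, sep = "\r")

  if (nrow(pr)) {
    prow <- match(paste(pr$household_id, pr$wave, sep = "\r"), hkey)
    p_unit <- unit[prow]
    p_uw <- match(paste(p_unit, pr$wave, sep = "\r"), ukey)

    # farm households per unit-wave
    fk <- paste(p_uw, pr$household_id, sep = "\r")
    n_farm <- tabulate(p_uw[!duplicated(fk)], nbins = nrow(uw))

    # union of nutritious groups over member farms
    spg <- species_groups(tax)
    sk <- paste(p_uw, pr$species_code, sep = "\r")
    keep <- !duplicated(sk)
    gl <- spg[pr$species_code[keep]]
    g_uw <- rep.int(p_uw[keep], lengths(gl))
    g <- unlist(gl, use.names = FALSE)
    gk <- paste(g_uw, g, sep = "\r")
    lpd <- tabulate(g_uw[!duplicated(gk)], nbins = nrow(uw))
  } else {
    n_farm <- integer(nrow(uw))
    lpd <- integer(nrow(uw))
  }
  data.frame(scale = scale, unit_id = uw$unit_id, wave = uw$wave,
             lpd = lpd, n_farmers = n_farm,
             valid = as.integer(n_farm > 0L), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Exclude uninformative village-wave units
#'
#' Village-waves with at most one sampled farm household are marked
#' invalid: with a single farm, village-level and farm-level production
#' diversity are identical, so such villages carry no distinct
#' village-scale signal. The rule only applies at village scale; town
#' and district records pass through unchanged. Exclusion counts are
#' reported as an attribute.
#'
#' @param records output of [aggregate_lpd()].
#' @return the records with `valid` updated; attribute `n_excluded`
#'   counts newly invalidated unit-waves.
#' @export
apply_village_exclusions <- function(records) {
  if (!nrow(records) || records$scale[1L] != "village") {
    attr(records, "n_excluded") <- 0L
    return(records)
  }
  newly <- records$valid == 1L & records$n_farmers <= 1L
  records$valid[records$n_farmers <= 1L] <- 0L
  attr(records, "n_excluded") <- sum(newly)
  records
}

#' Join unit-level production diversity onto household-waves
#'
#' Attaches the `lpd` and `n_farmers` of each household's unit at the
#' requested scale to the household-wave table. Households falling in
#' invalid unit-waves (no sampled farms, or singleton villages at
#' village scale) are dropped from that scale's estimation sample.
#'
#' @param panel a [panel_dataset].
#' @param records output of [aggregate_lpd()] (after
#'   [apply_village_exclusions()] for village scale).
#' @param scale the scale the records were aggregated at.
#' @return data.frame `household_id, wave, lpd, n_farmers` for
#'   households in valid units.
#' @export
join_lpd_to_households <- function(panel, records,
                                   scale = c("village", "town", "district")) {
  scale <- match.arg(scale)
  if (nrow(records) && any(records$scale != scale))
    stop("records were aggregated at scale '", records$scale[1L],
         "', not '", scale, "'")
  unit_col <- paste0(scale, "_id")
  hh <- panel$households
  rk <- paste(records$unit_id, records$wave, sep = "\r")
  m <- match(paste(hh[[unit_col]], hh$wave, sep = "\r"), rk)
  if (anyNA(m))
    stop("household-waves without a matching ", scale, "-wave unit")
  keep <- records$valid[m] == 1L
  data.frame(household_id = hh$household_id[keep], wave = hh$wave[keep],
             lpd = records$lpd[m][keep], n_farmers = records$n_farmers[m][keep],
             stringsAsFactors = FALSE, row.names = NULL)
}
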