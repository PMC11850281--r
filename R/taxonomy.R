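#' Food taxonomy: groups, species and consumption items
#'
#' A `food_taxonomy` holds the 12 food groups of the household dietary
#' diversity score (HDDS), the 9 nutritious groups retained for scoring,
#' a species registry mapping each crop or livestock species to zero or
#' more food groups, and an item registry mapping consumption items to a
#' single food group. Non-food cash crops (cotton, coffee, tea, tobacco)
#' are species that map to no food group; the three low-nutrient groups
#' (spices/condiments/beverages, sugar/sweets, oils/fats) are never
#' counted in HDDS or production food-group diversity.
#'
#' @param species data.frame with columns `code`, `class`
#'   ("crop"/"livestock"), `groups` (semicolon-separated group codes,
#'   possibly empty), `cash_crop` (0/1).
#' @param items data.frame with columns `code`, `group`.
#' @return An object of class `food_taxonomy` with elements `groups`
#'   (12 codes, ordered), `nutritious_groups` (9 codes), `species_map`,
#'   `item_map`.
#' @export
food_taxonomy <- function(species, items) {
  groups <- c("cereals", "legumes_nuts_seeds", "vegetables", "roots_tubers",
              "fruits", "eggs", "milk", "fish", "meat",
              "spices_condiments_beverages", "sugar_sweets", "oils_fats")
  excluded <- c("spices_condiments_beverages", "sugar_sweets", "oils_fats")
  nutritious <- setdiff(groups, excluded)
  stopifnot(length(groups) == 12L, length(nutritious) == 9L)

  species <- as.data.frame(species, stringsAsFactors = FALSE)
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  need_sp <- c("code", "class", "groups", "cash_crop")
  if (!all(need_sp %in% names(species)))
    stop("species table must have columns: ", paste(need_sp, collapse = ", "))
  if (!all(c("code", "group") %in% names(items)))
    stop("items table must have columns: code, group")
  if (anyDuplicated(species$code)) stop("duplicate species codes")
  if (anyDuplicated(items$code)) stop("duplicate item codes")
  if (!all(items$group %in% groups))
    stop("unknown food group in item map: ",
         paste(setdiff(items$group, groups), collapse = ", "))

  sp_groups <- strsplit(ifelse(is.na(species$groups), "", species$groups), ";",
                        fixed = TRUE)
  sp_groups <- lapply(sp_groups, function(g) g[nzchar(g)])
  bad <- setdiff(unlist(sp_groups), groups)
  if (length(bad))
    stop("unknown food group in species map: ", paste(bad, collapse = ", "))
  cash <- as.integer(species$cash_crop) == 1L
  if (any(cash & lengths(sp_groups) > 0L))
    stop("cash-crop species must map to zero food groups: ",
         paste(species$code[cash & lengths(sp_groups) > 0L], collapse = ", "))
  if (!all(species$class %in% c("crop", "livestock")))
    stop("species class must be 'crop' or 'livestock'")

  structure(list(
    groups = groups,
    nutritious_groups = nutritious,
    species_map = data.frame(code = species$code, class = species$class,
                             groups = vapply(sp_groups, paste, "", collapse = ";"),
                             cash_crop = as.integer(cash),
                             stringsAsFactors = FALSE),
    item_map = data.frame(code = items$code, group = items$group,
                          stringsAsFactors = FALSE)
  ), class = "food_taxonomy")
}

#' Default East/West African taxonomy
#'
#' A built-in registry of common crop and livestock species in the six
#' study countries (Ethiopia, Malawi, Niger, Nigeria, Tanzania, Uganda)
#' and one consumption item per food group and source context.
#' Livestock species map to every food group they yield (cattle to meat
#' and milk, chicken to meat and eggs); oil crops map to the excluded
#' oils/fats group; cash crops map to no group.
#'
#' @return A `food_taxonomy`.
#' @export
default_taxonomy <- function() {
  sp <- function(code, class, groups, cash = 0L)
    data.frame(code = code, class = class, groups = groups, cash_crop = cash,
               stringsAsFactors = FALSE)
  species <- rbind(
    sp(c("maize", "sorghum", "millet", "teff", "wheat", "rice", "barley"),
       "crop", "cereals"),
    sp(c("beans", "cowpea", "groundnut", "soybean", "pigeonpea", "chickpea",
         "sesame"), "crop", "legumes_nuts_seeds"),
    sp(c("tomato", "cabbage", "onion", "eggplant", "okra", "leafy_greens",
         "pepper"), "crop", "vegetables"),
    sp(c("cassava", "sweet_potato", "potato", "yam", "cocoyam"),
       "crop", "roots_tubers"),
    sp(c("banana", "mango", "avocado", "citrus", "papaya", "pineapple"),
       "crop", "fruits"),
    sp(c("oil_palm", "sunflower"), "crop", "oils_fats"),
    sp("sugarcane", "crop", "sugar_sweets"),
    sp("cattle", "livestock", "meat;milk"),
    sp("goat", "livestock", "meat;milk"),
    sp("camel", "livestock", "meat;milk"),
    sp("sheep", "livestock", "meat"),
    sp("pig", "livestock", "meat"),
    sp("chicken", "livestock", "meat;eggs"),
    sp("duck", "livestock", "meat;eggs"),
    sp("fish_pond", "livestock", "fish"),
    sp(c("cotton", "coffee", "tea", "tobacco"), "crop", "", cash = 1L)
  )
  items <- data.frame(
    code = c("grain_staple", "bread", "pulses", "nuts", "vegetables_fresh",
             "tubers", "fruit_fresh", "eggs_fresh", "milk_fresh", "fish_dried",
             "meat_fresh", "tea_spices", "sugar", "cooking_oil"),
    group = c("cereals", "cereals", "legumes_nuts_seeds", "legumes_nuts_seeds",
              "vegetables", "roots_tubers", "fruits", "eggs", "milk", "fish",
              "meat", "spices_condiments_beverages", "sugar_sweets",
              "oils_fats"),
    stringsAsFactors = FALSE
  )
  food_taxonomy(species, items)
}

#' Read or write a taxonomy CSV
#'
#' The taxonomy interchange CSV has columns
#' `code, kind(item|species), class(crop|livestock|item),
#' groups(semicolon-separated), cash_crop(0/1)`.
#'
#' @param path CSV file path.
#' @return `read_taxonomy()` a `food_taxonomy`; `write_taxonomy()` the
#'   path, invisibly.
#' @export
read_taxonomy <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("code", "kind", "class", "groups", "cash_crop")
  if (!all(need %in% names(x)))
    stop("taxonomy file ", path, " must have columns: ",
         paste(need, collapse = ", "))
  is_sp <- x$kind == "species"
  food_taxonomy(
    species = data.frame(code = x$code[is_sp], class = x$class[is_sp],
                         groups = x$groups[is_sp],
                         cash_crop = as.integer(x$cash_crop[is_sp]),
                         stringsAsFactors = FALSE),
    items = data.frame(code = x$code[!is_sp], group = x$groups[!is_sp],
                       stringsAsFactors = FALSE)
  )
}

#' @rdname read_taxonomy
#' @param taxonomy A `food_taxonomy`.
#' @export
write_taxonomy <- function(taxonomy, path) {
  stopifnot(inherits(taxonomy, "food_taxonomy"))
  sp <- taxonomy$species_map
  it <- taxonomy$item_map
  out <- rbind(
    data.frame(code = sp$code, kind = "species", class = sp$class,
               groups = sp$groups, cash_crop = sp$cash_crop,
               stringsAsFactors = FALSE),
    data.frame(code = it$code, kind = "item", class = "item",
               groups = it$group, cash_crop = 0L, stringsAsFactors = FALSE)
  )
  out <- out[order(out$kind, out$code), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# group sets per species code, as a named list of character vectors
species_groups <- function(taxonomy, nutritious_only = TRUE) {
  g <- strsplit(taxonomy$species_map$groups, ";", fixed = TRUE)
  g <- lapply(g, function(x) x[nzchar(x)])
  if (nutritious_only)
    g <- lapply(g, intersect, x = taxonomy$nutritious_groups)
  names(g) <- taxonomy$species_map$code
  g
}

#' @export
print.food_taxonomy <- function(x, ...) {
  cat("<food_taxonomy>\n")
  cat("  12 food groups; 9 nutritious (excludes",
      paste(setdiff(x$groups, x$nutritious_groups), collapse = ", "), ")\n")
  cat("  species:", nrow(x$species_map),
      sprintf("(%d crop, %d livestock, %d cash-crop)",
              sum(x$species_map$class == "crop"),
              sum(x$species_map$class == "livestock"),
              sum(x$species_map$cash_crop == 1L)), "\n")
  cat("  consumption items:", nrow(x$item_map), "\n")
  invisible(x)
}
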