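#' Default fuzzy-trait schema for Andean stream macroinvertebrate families
#'
#' The eight biological traits and their 41 categories used throughout the
#' package to fuzzy-code family-level communities: feeding habits (7
#' categories), respiration (4), body form (4), maximum body size (6), body
#' flexibility (3), locomotion (6), reproduction (8) and exoskeleton hardness
#' (3). Affinity scores against this schema are integers in \[0, 3\], where 0
#' means no affinity of a family for a category and 3 total affinity.
#'
#' @return A data frame with columns `trait` and `category`, one row per
#'   trait category (41 rows for the default schema), with `trait` a factor
#'   whose level order is the canonical trait order.
#' @seealso [gen_trait_matrix()], [normalize_traits()]
#' @examples
#' sch <- default_trait_schema()
#' table(sch$trait)
#' @export
default_trait_schema <- function() {
  path <- system.file("extdata", "trait_schema.csv", package = "hydromem",
                      mustWork = FALSE)
  if (nzchar(path) && file.exists(path)) {
    sch <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    sch <- .builtin_trait_schema()
  }
  sch$trait <- factor(sch$trait, levels = unique(sch$trait))
  validate_trait_schema(sch)
  sch
}

# Kept in code as well as in extdata so the schema survives partial installs.
.builtin_trait_schema <- function() {
  blocks <- list(
    "feeding habits" = c("collector-filterer", "collector-gatherer",
                         "piercer", "predator", "scraper", "shredder",
                         "parasite"),
    "respiration" = c("tegument", "gill", "plastron", "spiracle"),
    "body form" = c("streamlined", "flattened", "cylindrical", "spherical"),
    "maximum body size (mm)" = c("<2.5", "2.5-5", "5-10", "10-20", "20-40",
                                 "40-80"),
    "body flexibility (deg)" = c("none (<10)", "low (10-45)", "high (>45)"),
    "locomotion" = c("flier", "surface swimmer", "full water swimmer",
                     "crawler", "burrower", "temporarily attached"),
    "reproduction" = c("asexual", "clutches cemented", "clutches free",
                       "clutches in vegetation", "clutches terrestrial",
                       "isolated eggs clutches", "isolated eggs free",
                       "ovoviviparity"),
    "exoskeleton hardness" = c("none", "high", "moderate")
  )
  data.frame(
    trait = rep(names(blocks), lengths(blocks)),
    category = unlist(blocks, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Validate a trait schema
#'
#' Checks that category names are unique within each trait and that every
#' trait has at least one category.
#'
#' @param schema A data frame with columns `trait` and `category`.
#' @return The schema, invisibly, if valid; otherwise an error.
#' @export
validate_trait_schema <- function(schema) {
  stopifnot(is.data.frame(schema), all(c("trait", "category") %in% names(schema)))
  if (nrow(schema) == 0L) stop("trait schema is empty")
  by_trait <- split(schema$category, schema$trait)
  dup <- vapply(by_trait, function(x) anyDuplicated(x) > 0L, logical(1))
  if (any(dup)) {
    stop("duplicate categories within trait(s): ",
         paste(names(by_trait)[dup], collapse = ", "))
  }
  invisible(schema)
}

# Column labels used for trait matrices: "trait|category", unique by schema
# validation.
schema_labels <- function(schema) {
  paste(as.character(schema$trait), schema$category, sep = "|")
}
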