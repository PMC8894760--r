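## Controlled vocabularies ----------------------------------------------------

#' Controlled vocabularies for survey attributes
#'
#' Fixed sets of values recognised for the categorical attributes of a plant
#' material or formulation record. Plant-part and property values follow the
#' categories used in traditional-medicine compendia; regions follow the
#' three-way north/central/south stratification commonly used for Taiwan,
#' with `"unknown"` as the fallback.
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
part_levels <- c("whole_plant", "root_rhizome", "stem", "leaf", "flower",
                 "fruit_seed", "bark", "other")

#' @rdname vocabularies
#' @export
property_levels <- c("cold", "cool", "neutral", "warm", "hot", "unknown")

#' @rdname vocabularies
#' @export
flavor_levels <- c("sour", "bitter", "sweet", "spicy", "salty", "plain")

#' @rdname vocabularies
#' @export
region_levels <- c("north", "central", "south", "unknown")

## Constructors ---------------------------------------------------------------

#' Build a plant-material registry
#'
#' Validates and normalises a table of plant materials. One row is one
#' material: a specific part of a botanical species (so the stem and the leaf
#' of one species are two distinct materials with two distinct
#' `material_id`s, even though they share a `scientific_name`).
#'
#' @param df A data frame with columns `material_id`, `scientific_name`,
#'   `family`, and optionally `local_name`, `part_used`, `cultivated`, `wild`,
#'   `property`, `flavors`, `function_tags`, `pharmacology_tags`. The three
#'   tag/flavor columns may be character vectors with semicolon-separated
#'   values or list columns of character vectors.
#' @return A data frame of class `material_registry` with list columns for
#'   `flavors`, `function_tags` and `pharmacology_tags`.
#' @export
plant_materials <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("material_id", "scientific_name", "family")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("attribute table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$material_id <- as.character(df$material_id)
  if (anyNA(df$material_id) || any(!nzchar(df$material_id))) {
    stop("material_id must be non-empty for every material", call. = FALSE)
  }
  dup <- df$material_id[duplicated(df$material_id)]
  if (length(dup) > 0) {
    stop("duplicate material_id in attribute table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (is.null(df$local_name)) df$local_name <- NA_character_

  if (is.null(df$part_used)) df$part_used <- "other"
  df$part_used <- as.character(df$part_used)
  df$part_used[is.na(df$part_used) | !nzchar(df$part_used)] <- "other"
  bad_part <- setdiff(unique(df$part_used), part_levels)
  if (length(bad_part) > 0) {
    stop("unknown part_used value(s): ", paste(bad_part, collapse = ", "),
         "; expected one of ", paste(part_levels, collapse = ", "),
         call. = FALSE)
  }

  if (is.null(df$cultivated)) df$cultivated <- FALSE
  if (is.null(df$wild)) df$wild <- FALSE
  df$cultivated <- parse_flag(df$cultivated, "cultivated")
  df$wild <- parse_flag(df$wild, "wild")

  if (is.null(df$property)) df$property <- "unknown"
  df$property <- as.character(df$property)
  df$property[is.na(df$property) | !nzchar(df$property)] <- "unknown"
  bad_prop <- setdiff(unique(df$property), property_levels)
  if (length(bad_prop) > 0) {
    stop("unknown property value(s): ", paste(bad_prop, collapse = ", "),
         call. = FALSE)
  }

  df$flavors <- parse_tag_column(df$flavors, nrow(df))
  bad_flavor <- setdiff(unique(unlist(df$flavors)), flavor_levels)
  if (length(bad_flavor) > 0) {
    stop("unknown flavor value(s): ", paste(bad_flavor, collapse = ", "),
         call. = FALSE)
  }
  df$function_tags <- parse_tag_column(df$function_tags, nrow(df))
  df$pharmacology_tags <- parse_tag_column(df$pharmacology_tags, nrow(df))

  rownames(df) <- NULL
  class(df) <- c("material_registry", "data.frame")
  df
}

parse_flag <- function(x, what) {
  if (is.logical(x)) {
    x[is.na(x)] <- FALSE
    return(x)
  }
  x <- tolower(trimws(as.character(x)))
  out <- x %in% c("true", "t", "1", "yes", "y")
  ok <- x %in% c("true", "t", "1", "yes", "y", "false", "f", "0", "no", "n", "", "na")
  if (any(!ok)) {
    stop("cannot interpret ", what, " flag value(s): ",
         paste(unique(x[!ok]), collapse = ", "), call. = FALSE)
  }
  out
}

# Accepts either a list column of character vectors or a character column of
# semicolon-separated values; always returns a list column.
parse_tag_column <- function(x, n) {
  if (is.null(x)) return(I(rep(list(character(0)), n)))
  if (is.list(x)) {
    out <- lapply(x, function(v) {
      v <- trimws(as.character(v))
      sort(unique(v[nzchar(v)]))
    })
    return(I(out))
  }
  x <- as.character(x)
  out <- lapply(x, function(v) {
    if (is.na(v) || !nzchar(trimws(v))) return(character(0))
    parts <- trimws(strsplit(v, ";", fixed = TRUE)[[1]])
    sort(unique(parts[nzchar(parts)]))
  })
  I(out)
}

#' Assemble a validated survey dataset
#'
#' Combines a material registry and a list of store formulations into the
#' central container of the package. A formulation is the *set* of plant
#' materials one store combines into a single tea recipe; `N`, the number of
#' formulations, is the denominator of every use value.
#'
#' @param materials A `material_registry` (see [plant_materials()]) or a data
#'   frame coercible to one.
#' @param formulations A data frame with columns `store_id`, `region` and a
#'   list column `materials` of character vectors of material ids, or a plain
#'   long-form data frame with columns `store_id`, `region`, `material_id`
#'   (one row per occurrence).
#' @return An object of class `survey_dataset`: a list with elements
#'   `materials` (registry), `formulations` (data frame with list column
#'   `materials`) and `N`.
#' @export
survey_dataset <- function(materials, formulations) {
  if (!inherits(materials, "material_registry")) {
    materials <- plant_materials(materials)
  }
  formulations <- as.data.frame(formulations, stringsAsFactors = FALSE)
  if ("material_id" %in% names(formulations) &&
      !("materials" %in% names(formulations))) {
    formulations <- collapse_long_form(formulations)
  }
  required <- c("store_id", "region", "materials")
  missing_cols <- setdiff(required, names(formulations))
  if (length(missing_cols) > 0) {
    stop("formulation table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  formulations$store_id <- as.character(formulations$store_id)
  dup <- formulations$store_id[duplicated(formulations$store_id)]
  if (length(dup) > 0) {
    stop("duplicate store_id among formulations: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  formulations$region <- normalize_region(formulations$region)
  formulations$materials <- I(lapply(formulations$materials, function(m) {
    sort(unique(as.character(m)))
  }))

  sizes <- lengths(formulations$materials)
  if (any(sizes < 1)) {
    stop("formulation(s) with no materials: ",
         paste(formulations$store_id[sizes < 1], collapse = ", "),
         call. = FALSE)
  }
  used <- unique(unlist(formulations$materials))
  unknown <- setdiff(used, materials$material_id)
  if (length(unknown) > 0) {
    offenders <- formulations$store_id[vapply(
      formulations$materials, function(m) any(m %in% unknown), logical(1))]
    stop("formulation(s) ", paste(offenders, collapse = ", "),
         " reference material id(s) absent from the attribute table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  rownames(formulations) <- NULL
  structure(
    list(materials = materials,
         formulations = formulations,
         N = nrow(formulations)),
    class = "survey_dataset")
}

normalize_region <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | !nzchar(x)] <- "unknown"
  bad <- setdiff(unique(x), region_levels)
  if (length(bad) > 0) {
    warning("unrecognised region value(s) mapped to 'unknown': ",
            paste(bad, collapse = ", "), call. = FALSE)
    x[x %in% bad] <- "unknown"
  }
  x
}

# One row per (store, material) occurrence -> one row per store with a
# material set. Repeated occurrences collapse with a warning: field
# transcriptions commonly repeat rows.
collapse_long_form <- function(df) {
  required <- c("store_id", "region", "material_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("long-form formulation table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$store_id <- as.character(df$store_id)
  df$material_id <- as.character(df$material_id)
  key <- paste(df$store_id, df$material_id, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- unique(df$store_id[duplicated(key)])
    warning("duplicate (store_id, material_id) occurrence row(s) collapsed ",
            "for store(s): ", paste(dups, collapse = ", "), call. = FALSE)
  }
  stores <- unique(df$store_id)
  region <- vapply(stores, function(s) {
    r <- unique(df$region[df$store_id == s])
    if (length(r) > 1) {
      stop("store ", s, " is assigned multiple regions: ",
           paste(r, collapse = ", "), call. = FALSE)
    }
    as.character(r)
  }, character(1))
  mats <- lapply(stores, function(s) {
    sort(unique(df$material_id[df$store_id == s]))
  })
  data.frame(store_id = stores, region = unname(region),
             materials = I(mats), stringsAsFactors = FALSE)
}

## File I/O -------------------------------------------------------------------

# Sniffs tab vs comma from the header line.
detect_delim <- function(path) {
  header <- readLines(path, n = 1L, encoding = "UTF-8", warn = FALSE)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_table_auto <- function(path) {
  utils::read.table(path, sep = detect_delim(path), header = TRUE,
                    stringsAsFactors = FALSE, quote = "\"",
                    fileEncoding = "UTF-8", comment.char = "",
                    check.names = TRUE, colClasses = "character")
}

#' Read a formulation survey from delimited-text files
#'
#' The canonical on-disk form is a long-form occurrence table (one row per
#' store-by-material use) plus an attribute table keyed by `material_id`.
#' Delimiters (comma or tab) are auto-detected per file; text is read as
#' UTF-8 so local names may contain Han characters.
#'
#' @param formulations_file Path to the occurrence table with columns
#'   `store_id`, `region`, `material_id`. A wide per-store form with columns
#'   `store_id`, `region`, `materials` (semicolon-separated ids) is also
#'   accepted and normalised.
#' @param attributes_file Path to the material attribute table (see
#'   [plant_materials()] for columns; `flavors` and the tag columns hold
#'   semicolon-separated lists).
#' @return A validated [survey_dataset()].
#' @export
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' ds <- generate_survey(generator_config(n_stores = 6, n_species = 12,
#'                                        mean_size = 3), seed = 1)
#' write_survey(ds, file.path(dir, "forms.csv"), file.path(dir, "attrs.csv"))
#' ds2 <- read_survey(file.path(dir, "forms.csv"), file.path(dir, "attrs.csv"))
#' identical(material_frequencies(ds), material_frequencies(ds2))
read_survey <- function(formulations_file, attributes_file) {
  attrs <- read_table_auto(attributes_file)
  forms <- read_table_auto(formulations_file)
  if ("materials" %in% names(forms) && !("material_id" %in% names(forms))) {
    forms$materials <- I(lapply(strsplit(forms$materials, ";", fixed = TRUE),
                                trimws))
  }
  survey_dataset(plant_materials(attrs), forms)
}

#' Write a survey dataset to delimited-text files
#'
#' Serialises the dataset as a long-form occurrence CSV plus an attribute
#' CSV, the inverse of [read_survey()]: reading the written pair back yields
#' an identical dataset.
#'
#' @param dataset A `survey_dataset`.
#' @param formulations_file,attributes_file Output paths.
#' @return Invisibly, the two paths.
#' @export
write_survey <- function(dataset, formulations_file, attributes_file) {
  stopifnot(inherits(dataset, "survey_dataset"))
  f <- dataset$formulations
  long <- data.frame(
    store_id = rep(f$store_id, lengths(f$materials)),
    region = rep(f$region, lengths(f$materials)),
    material_id = unlist(f$materials),
    stringsAsFactors = FALSE)
  utils::write.csv(long, formulations_file, row.names = FALSE,
                   fileEncoding = "UTF-8")

  m <- dataset$materials
  flat <- data.frame(
    material_id = m$material_id,
    scientific_name = m$scientific_name,
    family = m$family,
    local_name = m$local_name,
    part_used = m$part_used,
    cultivated = m$cultivated,
    wild = m$wild,
    property = m$property,
    flavors = vapply(m$flavors, paste, character(1), collapse = ";"),
    function_tags = vapply(m$function_tags, paste, character(1), collapse = ";"),
    pharmacology_tags = vapply(m$pharmacology_tags, paste, character(1),
                               collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.csv(flat, attributes_file, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(c(formulations_file, attributes_file))
}

## Methods --------------------------------------------------------------------

#' @export
print.survey_dataset <- function(x, ...) {
  cat("Formulation survey:", x$N, "formulations,",
      nrow(x$materials), "plant materials\n")
  tab <- table(factor(x$formulations$region, levels = region_levels))
  tab <- tab[tab > 0]
  if (length(tab) > 0) {
    cat("Regions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.survey_dataset <- function(object, ...) {
  freq <- material_frequencies(object)
  cat("Formulation survey\n")
  cat("  formulations (N):      ", object$N, "\n")
  cat("  plant materials:       ", nrow(object$materials), "\n")
  cat("  distinct species:      ",
      length(unique(object$materials$scientific_name)), "\n")
  cat("  total occurrences:     ", freq$total_occurrences, "\n")
  cat("  mean formulation size: ",
      round(mean_formulation_size(object), 1), "\n")
  cat("  Shannon diversity (bits):",
      round(shannon_diversity(freq), 2), "\n")
  invisible(object)
}
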