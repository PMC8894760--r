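## Frequency, use value, diversity and attribute-distribution statistics.

#' Per-material frequency table
#'
#' Frequency of a material is the number of stores (formulations) whose
#' material set contains it — binary per store, regardless of quantity within
#' a recipe. Registry materials used nowhere are kept with count 0.
#'
#' @param dataset A `survey_dataset`.
#' @return An object of class `frequency_table`: a list with `counts` (named
#'   integer vector over all registry materials), `N` (formulation count) and
#'   `total_occurrences` (sum of formulation sizes).
#' @export
material_frequencies <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  ids <- dataset$materials$material_id
  counts <- integer(length(ids))
  names(counts) <- ids
  occ <- table(unlist(dataset$formulations$materials))
  counts[names(occ)] <- as.integer(occ)
  structure(
    list(counts = counts, N = dataset$N,
         total_occurrences = sum(counts)),
    class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, n = 10, ...) {
  cat("Frequency table:", length(x$counts), "materials, N =", x$N,
      "formulations,", x$total_occurrences, "occurrences\n")
  top <- sort_freq(x$counts)
  top <- top[seq_len(min(n, length(top)))]
  uv <- use_values(x)[names(top)]
  print(data.frame(material = names(top), frequency = unname(top),
                   UV = display_uv(unname(uv))), row.names = FALSE)
  invisible(x)
}

# count desc, ties by material id ascending
sort_freq <- function(counts) {
  counts[order(-counts, names(counts), method = "radix")]
}

#' Use values
#'
#' The use value of material *i* is `UV_i = U_i / N`: the number of stores
#' using it divided by the total number of stores surveyed. A standard
#' ethnobotanical importance index in `[0, 1]`.
#'
#' @param freq A `frequency_table`.
#' @return Named numeric vector of use values (unrounded; see
#'   [display_uv()] for the conventional 3-decimal presentation).
#' @export
#' @examples
#' # a material used in 10 of 32 formulations:
#' f <- structure(list(counts = c(ap = 10L), N = 32L, total_occurrences = 10L),
#'                class = "frequency_table")
#' use_values(f)          # 0.3125
#' display_uv(use_values(f))  # printed as 0.312
use_values <- function(freq) {
  stopifnot(inherits(freq, "frequency_table"))
  if (freq$N < 1) stop("use values need at least one formulation (N >= 1)",
                       call. = FALSE)
  freq$counts / freq$N
}

#' Presentation rounding for use values and percentages
#'
#' Internal statistics are kept at full precision; published tables
#' conventionally show use values at 3 decimals and percentages at 1 decimal
#' (or as integers), rounded to nearest with ties to even — so 10/32 = 0.3125
#' displays as 0.312, not 0.313.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 3 for UV, 1 for percentages).
#' @return Rounded numeric vector. `display_pct` first scales to percent.
#' @export
display_uv <- function(x, digits = 3) round(x, digits)

#' @rdname display_uv
#' @export
display_pct <- function(x, digits = 1) round(100 * x, digits)

#' Relative-abundance vector
#'
#' Converts counts to proportions `P_i` of total material occurrences,
#' dropping zero-count materials, as used by the Shannon index.
#'
#' @param freq A `frequency_table`.
#' @return Object of class `abundance_vector`: named numeric proportions
#'   summing to 1, all strictly positive.
#' @export
abundance_vector <- function(freq) {
  stopifnot(inherits(freq, "frequency_table"))
  counts <- freq$counts[freq$counts > 0]
  if (length(counts) == 0) {
    stop("cannot form an abundance vector: all counts are zero", call. = FALSE)
  }
  structure(counts / sum(counts), class = "abundance_vector")
}

#' Shannon diversity of the material inventory
#'
#' `H = -sum(P_i * log2(P_i))` where `P_i` is material *i*'s share of all
#' material occurrences (not of stores). For example, a material occurring in
#' 10 formulations out of 183 total occurrences contributes
#' `-(10/183) * log2(10/183)` (about 0.229 bits) to `H`. Log base 2 by
#' convention; `H` ranges from 0 (single material) to `log2(S)` (S materials,
#' uniform counts).
#'
#' @param freq A `frequency_table`, or an `abundance_vector`.
#' @param base Logarithm base, default 2 (bits).
#' @return Non-negative scalar.
#' @export
shannon_diversity <- function(freq, base = 2) {
  p <- if (inherits(freq, "abundance_vector")) unclass(freq)
       else unclass(abundance_vector(freq))
  -sum(p * log(p, base = base))
}

#' Mean number of materials per formulation
#'
#' @param dataset A `survey_dataset`.
#' @return Total material occurrences divided by N (e.g. 183 occurrences over
#'   32 formulations gives 5.71875, conventionally displayed as 5.7).
#' @export
mean_formulation_size <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  sum(lengths(dataset$formulations$materials)) / dataset$N
}

#' Botanical-family distribution
#'
#' Two complementary shares per family: the share of distinct botanical
#' species it contributes (species identified by `scientific_name`, so a stem
#' material and a leaf material of one species count once), and the share of
#' formulations containing at least one of its materials.
#'
#' @param dataset A `survey_dataset`.
#' @return Data frame with columns `family`, `n_species`, `species_share`,
#'   `n_formulations`, `formulation_share`, sorted by species share
#'   descending then family name.
#' @export
family_distribution <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  m <- dataset$materials
  species <- unique(m[, c("scientific_name", "family")])
  n_species_total <- length(unique(m$scientific_name))
  fam_species <- table(species$family)

  fams <- sort(unique(m$family))
  id_to_family <- stats::setNames(m$family, m$material_id)
  n_forms <- vapply(fams, function(f) {
    sum(vapply(dataset$formulations$materials,
               function(ids) any(id_to_family[ids] == f), logical(1)))
  }, integer(1))

  out <- data.frame(
    family = fams,
    n_species = as.integer(fam_species[fams]),
    species_share = as.numeric(fam_species[fams]) / n_species_total,
    n_formulations = as.integer(n_forms),
    formulation_share = as.numeric(n_forms) / dataset$N,
    stringsAsFactors = FALSE)
  out <- out[order(-out$species_share, out$family, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Plant-part distribution
#'
#' Share of materials per part used, over all registry materials. Shares sum
#' to 1; a missing part is recorded under `other` at registry construction.
#'
#' @param dataset A `survey_dataset`.
#' @return Named numeric vector over [part_levels].
#' @export
part_distribution <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  tab <- table(factor(dataset$materials$part_used, levels = part_levels))
  stats::setNames(as.numeric(tab) / nrow(dataset$materials), part_levels)
}

#' Cultivated/wild source distribution
#'
#' Shares of materials flagged as cultivated, as collectable in the wild, and
#' as both. The first two may sum above 1 because both flags can be set.
#'
#' @param dataset A `survey_dataset`.
#' @return List with `cultivated_share`, `wild_share`, `both_share`.
#' @export
source_distribution <- function(dataset) {
  m <- dataset$materials
  n <- nrow(m)
  list(cultivated_share = sum(m$cultivated) / n,
       wild_share = sum(m$wild) / n,
       both_share = sum(m$cultivated & m$wild) / n)
}

#' Property and flavor distribution with joint cross-tabulation
#'
#' Property (nature) shares are computed over materials whose property is
#' recorded (`property != "unknown"`); materials lacking a compendium record
#' are excluded from the denominator. Flavor shares use the same annotated
#' denominator, with a material counting once for each flavor it carries
#' (so flavor shares can sum above 1). The joint table gives the fraction of
#' annotated materials having a given property *and* a given flavor.
#'
#' @param dataset A `survey_dataset`.
#' @return List with `n_annotated`, `property_shares` (named vector over the
#'   five recorded properties), `flavor_shares` (named vector over
#'   [flavor_levels]) and `joint_shares` (property x flavor matrix).
#' @export
property_flavor_crosstab <- function(dataset) {
  m <- dataset$materials
  annotated <- m[m$property != "unknown", , drop = FALSE]
  n <- nrow(annotated)
  props <- setdiff(property_levels, "unknown")
  if (n == 0) {
    warning("no materials with a recorded property; shares are empty",
            call. = FALSE)
    return(list(n_annotated = 0L,
                property_shares = stats::setNames(numeric(0), character(0)),
                flavor_shares = stats::setNames(numeric(0), character(0)),
                joint_shares = matrix(numeric(0), 0, 0)))
  }
  prop_tab <- table(factor(annotated$property, levels = props))
  property_shares <- stats::setNames(as.numeric(prop_tab) / n, props)

  has_flavor <- vapply(flavor_levels, function(fl) {
    vapply(annotated$flavors, function(v) fl %in% v, logical(1))
  }, logical(n))
  if (n == 1) has_flavor <- matrix(has_flavor, nrow = 1,
                                   dimnames = list(NULL, flavor_levels))
  flavor_shares <- colSums(has_flavor) / n

  joint <- matrix(0, length(props), length(flavor_levels),
                  dimnames = list(props, flavor_levels))
  for (p in props) {
    sel <- annotated$property == p
    if (any(sel)) {
      joint[p, ] <- colSums(has_flavor[sel, , drop = FALSE]) / n
    }
  }
  list(n_annotated = n, property_shares = property_shares,
       flavor_shares = flavor_shares, joint_shares = joint)
}

#' Prevalence of traditional-function or pharmacology tags
#'
#' @param dataset A `survey_dataset`.
#' @param tag_field `"function_tags"` or `"pharmacology_tags"`.
#' @param denominator `"all"` (all registry materials, the default) or
#'   `"tagged"` (only materials carrying at least one tag in the field).
#' @return Named numeric vector, share of materials per tag, sorted
#'   decreasing then by tag name.
#' @export
tag_prevalence <- function(dataset,
                           tag_field = c("function_tags", "pharmacology_tags"),
                           denominator = c("all", "tagged")) {
  tag_field <- match.arg(tag_field)
  denominator <- match.arg(denominator)
  tags <- dataset$materials[[tag_field]]
  n <- if (denominator == "all") length(tags) else sum(lengths(tags) > 0)
  if (n == 0) return(stats::setNames(numeric(0), character(0)))
  tab <- table(unlist(lapply(tags, unique)))
  out <- as.numeric(tab) / n
  names(out) <- names(tab)
  out[order(-out, names(out), method = "radix")]
}
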