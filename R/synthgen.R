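## Seeded synthetic-survey generator: reproduces the statistical structure of
## a store-level herbal-tea formulation survey (long-tailed material
## popularity, zero-truncated Poisson formulation sizes, attribute marginals)
## so the full pipeline is testable without raw field data.

#' Generator configuration
#'
#' Defaults describe a survey of 32 stores and 73 plant materials (72
#' botanical species; one species contributes a stem and a leaf material)
#' with a mean of 5.7 materials per formulation, a Zipf-like material
#' popularity law whose default exponent puts the most popular material in
#' roughly 10 of 32 formulations, a north/central/south store mix
#' proportional to the 49/34/20 regional richness gradient, and attribute
#' marginals of roughly 46.5% cold property, 69% bitter flavor, 41% whole
#' plant and a 60/63/37 cultivated/wild/both source split.
#'
#' @param n_stores Number of stores (formulations), default 32.
#' @param n_species Number of plant materials, default 73.
#' @param mean_size Mean formulation size, default 5.7 (sizes follow a
#'   zero-truncated Poisson with this mean, capped at `n_species`).
#' @param popularity_exponent Zipf exponent `s` of the material-sampling
#'   weights `w_r = r^-s`; 0 gives uniform popularity. The default 0.45 is
#'   calibrated so the most popular material lands in about 10 of 32
#'   formulations at the default survey size.
#' @param region_mix Named probabilities over regions for store assignment.
#' @param property_probs Probabilities over the five recorded properties,
#'   conditional on the property being recorded.
#' @param p_property_unknown Probability a material has no property record
#'   (default 2/73, mirroring two unannotated materials out of 73).
#' @param flavor_probs Per-flavor independent inclusion probabilities; a
#'   material drawing no flavor is assigned `"plain"`.
#' @param part_probs Probabilities over [part_levels].
#' @param source_probs Probabilities over the four cultivated-by-wild cells,
#'   named `both`, `cultivated_only`, `wild_only`, `neither`.
#' @param n_families Number of botanical families to spread species over
#'   (default 33), themselves Zipf-weighted so one family dominates.
#' @param attribute_correlation Knob in `[0, 1]` coupling cold property and
#'   bitter flavor: with this probability a cold material is forced bitter
#'   (0 = fully independent attributes, the default).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_stores = 32,
                             n_species = 73,
                             mean_size = 5.7,
                             popularity_exponent = 0.45,
                             region_mix = c(north = 49, central = 34,
                                            south = 20),
                             property_probs = c(cold = 0.465, cool = 0.268,
                                                neutral = 0.14, warm = 0.09,
                                                hot = 0.037),
                             p_property_unknown = 2 / 73,
                             flavor_probs = c(sour = 0.08, bitter = 0.69,
                                              sweet = 0.27, spicy = 0.10,
                                              salty = 0.03, plain = 0.22),
                             part_probs = c(whole_plant = 0.411,
                                            root_rhizome = 0.206,
                                            leaf = 0.15, stem = 0.08,
                                            fruit_seed = 0.08, flower = 0.05,
                                            bark = 0.02, other = 0.003),
                             source_probs = c(both = 0.37,
                                              cultivated_only = 0.23,
                                              wild_only = 0.26,
                                              neither = 0.14),
                             n_families = 33,
                             attribute_correlation = 0) {
  if (n_stores < 1) stop("n_stores must be at least 1", call. = FALSE)
  if (n_species < 2) stop("n_species must be at least 2", call. = FALSE)
  if (mean_size >= n_species) {
    stop("mean_size must be smaller than n_species", call. = FALSE)
  }
  if (mean_size < 1) stop("mean_size must be at least 1 (formulations are ",
                          "non-empty)", call. = FALSE)
  stopifnot(all(names(region_mix) %in% region_levels),
            all(names(property_probs) %in% setdiff(property_levels, "unknown")),
            all(names(flavor_probs) %in% flavor_levels),
            all(names(part_probs) %in% part_levels),
            setequal(names(source_probs),
                     c("both", "cultivated_only", "wild_only", "neither")),
            attribute_correlation >= 0, attribute_correlation <= 1)
  structure(
    list(n_stores = n_stores, n_species = n_species, mean_size = mean_size,
         popularity_exponent = popularity_exponent,
         region_mix = region_mix / sum(region_mix),
         property_probs = property_probs / sum(property_probs),
         p_property_unknown = p_property_unknown,
         flavor_probs = flavor_probs,
         part_probs = part_probs / sum(part_probs),
         source_probs = source_probs / sum(source_probs),
         n_families = n_families,
         attribute_correlation = attribute_correlation),
    class = "generator_config")
}

# lambda of a zero-truncated Poisson with the requested mean:
# m = lambda / (1 - exp(-lambda))
truncated_poisson_lambda <- function(mean_size) {
  if (mean_size <= 1) return(1e-8)
  stats::uniroot(function(l) l / (1 - exp(-l)) - mean_size,
                 interval = c(1e-8, mean_size + 10), tol = 1e-10)$root
}

draw_truncated_poisson <- function(n, lambda, upper) {
  out <- stats::rpois(n, lambda)
  for (i in seq_len(200)) {
    bad <- out < 1
    if (!any(bad)) break
    out[bad] <- stats::rpois(sum(bad), lambda)
  }
  out[out < 1] <- 1
  pmin(out, upper)
}

sample_category <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

#' Generate a synthetic formulation survey
#'
#' Draws a complete, validated [survey_dataset()] from the configured
#' marginals: store regions from `region_mix`; formulation sizes from a
#' zero-truncated Poisson; each formulation's material set by weighted
#' sampling without replacement under Zipf popularity weights; and material
#' attributes (family, part, property, flavors, source flags, function tags)
#' from the configured distributions. Identical `(config, seed)` pairs yield
#' identical datasets.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; the generator restores the caller's RNG state
#'   on exit.
#' @return A `survey_dataset`.
#' @export
generate_survey <- function(config = generator_config(), seed) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  n_mat <- config$n_species
  ids <- sprintf("m%03d", seq_len(n_mat))

  # 72 distinct binomials for 73 materials: material n_mat reuses species 1
  # with a different part (stem vs leaf of one plant).
  n_binomials <- n_mat - 1
  genus <- sprintf("Genus%03d", seq_len(n_binomials))
  epithet <- sprintf("species%03d", seq_len(n_binomials))
  binomial <- paste(genus, epithet)
  species_of <- c(seq_len(n_binomials), 1L)

  fam_names <- c("Asteraceae", "Lamiaceae", "Acanthaceae", "Fabaceae",
                 "Rubiaceae",
                 sprintf("Family%02d", seq_len(max(0, config$n_families - 5))))
  fam_names <- fam_names[seq_len(config$n_families)]
  fam_w <- seq_along(fam_names)^-1
  family_of_species <- sample_category(n_binomials, stats::setNames(
    fam_w / sum(fam_w), fam_names))

  part <- sample_category(n_mat, config$part_probs)
  # the duplicated species must contribute two distinct parts
  part[n_mat] <- if (part[1] == "stem") "leaf" else "stem"

  rec <- stats::runif(n_mat) >= config$p_property_unknown
  property <- rep("unknown", n_mat)
  property[rec] <- sample_category(sum(rec), config$property_probs)

  flavors <- lapply(seq_len(n_mat), function(i) {
    draw <- names(config$flavor_probs)[
      stats::runif(length(config$flavor_probs)) < config$flavor_probs]
    if (property[i] == "cold" && config$attribute_correlation > 0 &&
        stats::runif(1) < config$attribute_correlation) {
      draw <- union(draw, "bitter")
    }
    if (length(draw) == 0) draw <- "plain"
    sort(draw)
  })

  src <- sample_category(n_mat, config$source_probs)
  cultivated <- src %in% c("both", "cultivated_only")
  wild <- src %in% c("both", "wild_only")

  fn_pool <- c("heat-clearing", "detoxification", "detumescence", "diuresis",
               "cough-relief", "liver-calming", "dampness-dispelling")
  fn_probs <- c(0.639, 0.548, 0.25, 0.25, 0.15, 0.12, 0.10)
  function_tags <- lapply(seq_len(n_mat), function(i) {
    sort(fn_pool[stats::runif(length(fn_pool)) < fn_probs])
  })

  materials <- plant_materials(data.frame(
    material_id = ids,
    scientific_name = binomial[species_of],
    family = family_of_species[species_of],
    local_name = sprintf("local-%03d", seq_len(n_mat)),
    part_used = part,
    cultivated = cultivated,
    wild = wild,
    property = property,
    flavors = I(flavors),
    function_tags = I(function_tags),
    pharmacology_tags = I(rep(list(character(0)), n_mat)),
    stringsAsFactors = FALSE))

  w <- seq_len(n_mat)^(-config$popularity_exponent)
  lambda <- truncated_poisson_lambda(config$mean_size)
  sizes <- draw_truncated_poisson(config$n_stores, lambda, n_mat)
  region <- sample_category(config$n_stores, config$region_mix)
  mats <- lapply(sizes, function(s) {
    sort(ids[sample.int(n_mat, s, prob = w)])
  })
  formulations <- data.frame(
    store_id = sprintf("s%03d", seq_len(config$n_stores)),
    region = region,
    materials = I(mats),
    stringsAsFactors = FALSE)

  survey_dataset(materials, formulations)
}

#' Plant an exact pair co-occurrence into a dataset
#'
#' Minimally edits the formulations so that the two given materials co-occur
#' in exactly `target_count` formulations, preserving all dataset invariants.
#' Excess co-occurrences are removed by dropping the second material from
#' (seed-chosen) formulations; deficits are filled by adding the missing
#' member(s) to formulations not yet containing both. Used to build recovery
#' fixtures for the core-network stage.
#'
#' @param dataset A `survey_dataset`.
#' @param pair Character vector of two distinct material ids present in the
#'   registry.
#' @param target_count Desired co-occurrence count, `0 <= target_count <= N`.
#' @param seed Integer seed controlling which formulations are edited.
#' @return A modified `survey_dataset`.
#' @export
plant_core_structure <- function(dataset, pair, target_count, seed = 1) {
  stopifnot(inherits(dataset, "survey_dataset"), length(pair) == 2)
  pair <- as.character(pair)
  if (pair[1] == pair[2]) stop("pair must name two distinct materials",
                               call. = FALSE)
  if (!all(pair %in% dataset$materials$material_id)) {
    stop("pair material(s) absent from the registry: ",
         paste(setdiff(pair, dataset$materials$material_id), collapse = ", "),
         call. = FALSE)
  }
  if (target_count < 0 || target_count > dataset$N) {
    stop("target_count must be between 0 and N = ", dataset$N, call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  mats <- dataset$formulations$materials
  has_both <- vapply(mats, function(m) all(pair %in% m), logical(1))
  current <- sum(has_both)

  pick <- function(x, k) x[sample.int(length(x), k)]  # avoids sample(n) pitfall
  if (current > target_count) {
    drop_from <- pick(which(has_both), current - target_count)
    for (i in drop_from) mats[[i]] <- setdiff(mats[[i]], pair[2])
  } else if (current < target_count) {
    add_to <- pick(which(!has_both), target_count - current)
    for (i in add_to) mats[[i]] <- sort(union(mats[[i]], pair))
  }
  f <- dataset$formulations
  f$materials <- I(mats)
  survey_dataset(dataset$materials, f)
}
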