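# Fixture builders and independent brute-force oracles used across tests.

# Minimal attribute table: sensible defaults, overridable per column.
make_attrs <- function(ids, scientific_name = NULL, family = "Asteraceae",
                       part_used = "whole_plant", cultivated = TRUE,
                       wild = FALSE, property = "cold", flavors = "bitter",
                       function_tags = "", local_name = NA_character_) {
  n <- length(ids)
  data.frame(
    material_id = ids,
    scientific_name = if (is.null(scientific_name))
      paste("Genus", ids) else scientific_name,
    family = rep_len(family, n),
    local_name = rep_len(local_name, n),
    part_used = rep_len(part_used, n),
    cultivated = rep_len(cultivated, n),
    wild = rep_len(wild, n),
    property = rep_len(property, n),
    flavors = rep_len(flavors, n),
    function_tags = rep_len(function_tags, n),
    stringsAsFactors = FALSE)
}

# Dataset from a named list of material-id vectors (names = store ids).
make_dataset <- function(sets, regions = "north", attrs = NULL) {
  ids <- sort(unique(unlist(sets)))
  if (is.null(attrs)) attrs <- make_attrs(ids)
  if (is.null(names(sets))) names(sets) <- paste0("s", seq_along(sets))
  survey_dataset(
    attrs,
    data.frame(store_id = names(sets),
               region = rep_len(regions, length(sets)),
               materials = I(unname(sets)),
               stringsAsFactors = FALSE))
}

# Oracle: pair counts by exhaustive double loop over the material universe.
oracle_pair_counts <- function(dataset) {
  ids <- sort(dataset$materials$material_id)
  out <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      cnt <- sum(vapply(dataset$formulations$materials,
                        function(m) ids[i] %in% m && ids[j] %in% m,
                        logical(1)))
      if (cnt > 0) out[[paste(ids[i], ids[j])]] <- cnt
    }
  }
  out
}

# Oracle: classify every union element by per-inventory membership.
oracle_venn_counts <- function(inventories) {
  universe <- sort(unique(unlist(inventories)))
  sigs <- vapply(universe, function(el) {
    paste(vapply(inventories, function(s) as.integer(el %in% s), integer(1)),
          collapse = "")
  }, character(1))
  table(sigs)
}

# A tiny deterministic survey used by several suites.
toy_survey <- function() {
  make_dataset(list(s1 = c("A", "B"), s2 = c("A", "C"), s3 = c("A")),
               regions = c("north", "south", "north"))
}
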