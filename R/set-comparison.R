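## Regional stratification and k-way inventory overlap (Venn) analysis.

#' Split a survey by region
#'
#' Each regional subset keeps only that region's formulations and the
#' materials they actually use, so downstream indices (species counts,
#' Shannon diversity) run per stratum. Regions with no formulations simply do
#' not appear.
#'
#' @param dataset A `survey_dataset`.
#' @param drop_unknown Drop the `"unknown"` stratum (default TRUE).
#' @return Named list of `survey_dataset`, in [region_levels] order.
#' @export
regional_subsets <- function(dataset, drop_unknown = TRUE) {
  stopifnot(inherits(dataset, "survey_dataset"))
  regions <- intersect(region_levels, unique(dataset$formulations$region))
  if (drop_unknown) regions <- setdiff(regions, "unknown")
  out <- lapply(regions, function(r) {
    f <- dataset$formulations[dataset$formulations$region == r, , drop = FALSE]
    used <- unique(unlist(f$materials))
    m <- dataset$materials[dataset$materials$material_id %in% used, ,
                           drop = FALSE]
    class(m) <- c("material_registry", "data.frame")
    survey_dataset(m, f)
  })
  stats::setNames(out, regions)
}

#' Materials common to every regional inventory
#'
#' @param subsets Named list of `survey_dataset` (from [regional_subsets()]).
#' @return Character vector of material ids used in every subset.
#' @export
shared_materials <- function(subsets) {
  if (length(subsets) < 2) {
    stop("need at least two inventories to intersect", call. = FALSE)
  }
  sets <- lapply(subsets, function(d) unique(unlist(d$formulations$materials)))
  sort(Reduce(intersect, sets))
}

#' k-way set-partition (Venn) analysis of inventories
#'
#' Classifies every element of the union of k inventories by its membership
#' signature — a k-character string of 0/1, one position per inventory in the
#' given order — and counts elements per signature. This is the tabular
#' content of a k-set Venn diagram.
#'
#' @param inventories Named list of 2 to 5 character vectors (sets of
#'   material keys; duplicates within a set are ignored).
#' @return Object of class `venn_partition`: list with `labels`, `counts`
#'   (named integer vector over all 2^k - 1 non-empty signatures, including
#'   zeros), `members` (list of element vectors per signature),
#'   `set_sizes`, `exclusive_counts`, `exclusive_shares` (denominator = that
#'   inventory's size) and `union_size`.
#' @export
#' @examples
#' venn_partition(list(bt = c("a", "b", "c"), qcc = c("b", "d")))
venn_partition <- function(inventories) {
  k <- length(inventories)
  if (k < 2 || k > 5) stop("between 2 and 5 inventories supported",
                           call. = FALSE)
  if (is.null(names(inventories)) || any(!nzchar(names(inventories)))) {
    names(inventories) <- paste0("set", seq_len(k))
  }
  inventories <- lapply(inventories, function(x) unique(as.character(x)))
  labels <- names(inventories)
  universe <- sort(unique(unlist(inventories)))

  membership <- vapply(inventories, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) {
    membership <- matrix(membership, nrow = 1)
  }
  sig <- apply(membership, 1, function(b) paste(as.integer(b), collapse = ""))

  all_sigs <- vapply(seq_len(2^k - 1), function(i) {
    paste(rev(as.integer(intToBits(i)[seq_len(k)])), collapse = "")
  }, character(1))
  # intToBits is little-endian; rev makes position 1 the first inventory
  all_sigs <- sort(all_sigs)
  counts <- stats::setNames(integer(length(all_sigs)), all_sigs)
  tab <- table(sig)
  counts[names(tab)] <- as.integer(tab)
  members <- stats::setNames(
    lapply(all_sigs, function(s) universe[sig == s]), all_sigs)

  only_bit <- vapply(seq_len(k), function(j) {
    b <- rep("0", k); b[j] <- "1"; paste(b, collapse = "")
  }, character(1))
  set_sizes <- vapply(inventories, length, integer(1))
  exclusive <- stats::setNames(counts[only_bit], labels)

  structure(
    list(labels = labels, counts = counts, members = members,
         set_sizes = set_sizes,
         exclusive_counts = exclusive,
         exclusive_shares = ifelse(set_sizes > 0, exclusive / set_sizes, 0),
         union_size = length(universe)),
    class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition of", length(x$labels), "inventories (",
      paste(x$labels, collapse = ", "), "), union size", x$union_size, "\n")
  print(data.frame(signature = names(x$counts), count = unname(x$counts)),
        row.names = FALSE)
  cat("Exclusive:",
      paste(sprintf("%s=%d (%s%%)", x$labels, x$exclusive_counts,
                    formatC(100 * x$exclusive_shares, format = "fg",
                            digits = 3)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Normalise a scientific name for cross-inventory matching
#'
#' External inventories (other herbal-tea traditions, regional compendia)
#' do not share material ids, so sets are matched on the binomial: authority
#' strings and parenthesised annotations (including part markers such as
#' "(stem)") are removed, the name is lower-cased, and the first two tokens —
#' genus and specific epithet — are kept.
#'
#' @param x Character vector of scientific names.
#' @return Character vector of normalised `"genus epithet"` keys.
#' @export
#' @examples
#' normalize_scientific_name("Ixeris chinensis (Thunb. ex Thunb.) Nakai")
#' normalize_scientific_name("Tithonia diversifolia (stem)")
normalize_scientific_name <- function(x) {
  x <- gsub("\\([^)]*\\)", " ", as.character(x))
  x <- tolower(trimws(gsub("[[:space:]]+", " ", x)))
  vapply(strsplit(x, " ", fixed = TRUE), function(tok) {
    paste(tok[seq_len(min(2, length(tok)))], collapse = " ")
  }, character(1))
}

#' Overlap of the top-k materials of two inventories
#'
#' Takes the k highest-use-value materials of each inventory and runs
#' [venn_partition()] on the two top-k sets. Ties at the UV cut are broken by
#' frequency (descending, when supplied) and then by name ascending, making
#' the top-k list deterministic.
#'
#' @param uv_a,uv_b Named numeric vectors of use values (names are the
#'   matching keys; apply [normalize_scientific_name()] first when comparing
#'   across surveys).
#' @param k Number of top materials per inventory (default 15).
#' @param freq_a,freq_b Optional named frequency vectors used as a secondary
#'   tie-break.
#' @param labels Length-2 character vector naming the inventories.
#' @return A `venn_partition` of the two top-k sets.
#' @export
top_k_overlap <- function(uv_a, uv_b, k = 15, freq_a = NULL, freq_b = NULL,
                          labels = c("a", "b")) {
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  venn_partition(stats::setNames(
    list(top_k_names(uv_a, k, freq_a), top_k_names(uv_b, k, freq_b)),
    labels))
}

top_k_names <- function(uv, k, freq = NULL) {
  if (length(uv) < k) {
    warning("inventory has only ", length(uv), " materials; using all",
            call. = FALSE)
    k <- length(uv)
  }
  tie <- if (is.null(freq)) rep(0, length(uv)) else -as.numeric(freq[names(uv)])
  ord <- order(-uv, tie, names(uv), method = "radix")
  names(uv)[ord][seq_len(k)]
}
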