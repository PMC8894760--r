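## Result serialization and the end-to-end analysis run.

#' Write a pipeline result to disk
#'
#' Dispatches on the result type: tables go to CSV, nested results
#' (`venn_partition`, `core_network`) to JSON, a `survey_dataset` to the
#' formulation/attribute file pair. Each format round-trips through the
#' corresponding reader.
#'
#' @param x A pipeline result.
#' @param path Output path. For a `survey_dataset`, the stem: files
#'   `<path>_formulations.csv` and `<path>_attributes.csv` are written.
#' @param ... Unused.
#' @return Invisibly, the path(s) written.
#' @export
write_report <- function(x, path, ...) UseMethod("write_report")

#' @export
write_report.default <- function(x, path, ...) {
  stop("no report writer for objects of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}

#' @export
write_report.frequency_table <- function(x, path, ...) {
  counts <- sort_freq(x$counts)
  uv <- counts / x$N
  out <- data.frame(material_id = names(counts),
                    frequency = unname(counts),
                    uv = unname(uv),
                    uv_display = display_uv(unname(uv)),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a frequency table written by [write_report()]
#'
#' @param path CSV path.
#' @param N Formulation count (recovered from the data when omitted, using
#'   `frequency / uv` of the most frequent material).
#' @return A `frequency_table`.
#' @export
read_frequency_table <- function(path, N = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (is.null(N)) {
    nz <- which(df$uv > 0)
    if (length(nz) == 0) stop("cannot recover N from an all-zero table; ",
                              "supply N", call. = FALSE)
    N <- as.integer(round(df$frequency[nz[1]] / df$uv[nz[1]]))
  }
  counts <- stats::setNames(as.integer(df$frequency), df$material_id)
  counts <- counts[order(names(counts), method = "radix")]
  structure(list(counts = counts, N = N, total_occurrences = sum(counts)),
            class = "frequency_table")
}

#' @export
write_report.venn_partition <- function(x, path, ...) {
  if (grepl("\\.json$", path)) {
    obj <- list(labels = as.list(x$labels),
                counts = as.list(x$counts),
                set_sizes = as.list(stats::setNames(as.integer(x$set_sizes),
                                                    x$labels)),
                union_size = x$union_size)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    out <- data.frame(signature = names(x$counts), count = unname(x$counts),
                      stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read a Venn partition from its JSON export
#'
#' @param path JSON path written by [write_report()].
#' @return A `venn_partition` (without per-signature member lists, which the
#'   JSON form does not carry).
#' @export
read_venn_partition <- function(path) {
  obj <- jsonlite::read_json(path)
  labels <- unlist(obj$labels)
  counts <- stats::setNames(vapply(obj$counts, as.integer, integer(1)),
                            names(obj$counts))
  k <- length(labels)
  only_bit <- vapply(seq_len(k), function(j) {
    b <- rep("0", k); b[j] <- "1"; paste(b, collapse = "")
  }, character(1))
  set_sizes <- stats::setNames(vapply(obj$set_sizes, as.integer, integer(1)),
                               names(obj$set_sizes))[labels]
  exclusive <- stats::setNames(counts[only_bit], labels)
  structure(
    list(labels = labels, counts = counts, members = NULL,
         set_sizes = set_sizes, exclusive_counts = exclusive,
         exclusive_shares = ifelse(set_sizes > 0, exclusive / set_sizes, 0),
         union_size = as.integer(obj$union_size)),
    class = "venn_partition")
}

#' @export
write_report.core_network <- function(x, path, ...) {
  export_network(x, path, format = "json")
}

#' @export
write_report.survey_dataset <- function(x, path, ...) {
  write_survey(x, paste0(path, "_formulations.csv"),
               paste0(path, "_attributes.csv"))
}

#' @export
write_report.pair_counts <- function(x, path, ...) {
  out <- data.frame(material_a = x$a, material_b = x$b, count = x$count,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
write_report.data.frame <- function(x, path, ...) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full survey analysis
#'
#' Executes every stage of the pipeline on one dataset and writes a report
#' bundle with fixed file names under `output_dir`: frequency/use-value
#' table, Shannon diversity overall and per region, family / part / source /
#' property-flavor / function tables, optional Venn JSONs for supplied
#' comparison inventories, pair counts, the thresholded core network
#' (GraphML, edge-list TSV and JSON), the core ranking, and a run log. On
#' any stage failure the partially written bundle is removed.
#'
#' @param dataset A `survey_dataset`, or a length-2 character vector of
#'   `(formulations_file, attributes_file)` paths.
#' @param output_dir Directory for the bundle (created if needed).
#' @param comparison_inventories Optional named list of character vectors of
#'   normalised scientific names to compare against the survey inventory via
#'   [venn_partition()].
#' @param threshold Core-network edge threshold (strict, default 4).
#' @param top_k Unused unless two inventories are compared by top-k use
#'   value; kept for CLI symmetry (default 15).
#' @param shannon_base Log base for diversity (default 2).
#' @return Invisibly, a list of computed results and file paths.
#' @export
run_full_analysis <- function(dataset, output_dir,
                              comparison_inventories = NULL,
                              threshold = 4, top_k = 15, shannon_base = 2) {
  if (is.character(dataset)) {
    stopifnot(length(dataset) == 2)
    dataset <- read_survey(dataset[1], dataset[2])
  }
  stopifnot(inherits(dataset, "survey_dataset"))
  created <- !dir.exists(output_dir)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  log_lines <- character(0)
  emit <- function(x, name, ...) {
    p <- file.path(output_dir, name)
    write_report(x, p, ...)
    written <<- c(written, p)
    p
  }
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  ok <- FALSE
  on.exit({
    if (!ok) {
      unlink(written)
      if (created) unlink(output_dir, recursive = TRUE)
    }
  })

  note("bittertea run: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
       " package ", as.character(utils::packageVersion("bittertea")))
  note("dataset: N=", dataset$N, " formulations, ",
       nrow(dataset$materials), " materials")

  freq <- material_frequencies(dataset)
  emit(freq, "frequency_uv.csv")
  note("frequencies: ", length(freq$counts), " materials, ",
       freq$total_occurrences, " occurrences -> frequency_uv.csv")

  subsets <- regional_subsets(dataset)
  sh <- data.frame(
    stratum = c("overall", names(subsets)),
    n_formulations = c(dataset$N,
                       vapply(subsets, function(d) d$N, integer(1))),
    n_materials = c(sum(freq$counts > 0),
                    vapply(subsets, function(d)
                      sum(material_frequencies(d)$counts > 0), integer(1))),
    shannon = c(shannon_diversity(freq, base = shannon_base),
                vapply(subsets, function(d)
                  shannon_diversity(material_frequencies(d),
                                    base = shannon_base), numeric(1))),
    stringsAsFactors = FALSE)
  sh$mean_formulation_size <- c(mean_formulation_size(dataset),
                                vapply(subsets, mean_formulation_size,
                                       numeric(1)))
  emit(sh, "shannon.csv")
  note("diversity: ", nrow(sh), " strata -> shannon.csv")
  if (length(subsets) >= 2) {
    shared <- shared_materials(subsets)
    emit(data.frame(material_id = shared, stringsAsFactors = FALSE),
         "shared_materials.csv")
    note("regional intersection: ", length(shared),
         " materials -> shared_materials.csv")
  }

  emit(family_distribution(dataset), "family_distribution.csv")
  pd <- part_distribution(dataset)
  emit(data.frame(part = names(pd), share = unname(pd),
                  pct = display_pct(unname(pd)), stringsAsFactors = FALSE),
       "part_distribution.csv")
  sd_ <- source_distribution(dataset)
  emit(data.frame(source = names(sd_), share = unlist(sd_, use.names = FALSE),
                  stringsAsFactors = FALSE), "source_distribution.csv")
  pf <- property_flavor_crosstab(dataset)
  emit(data.frame(property = names(pf$property_shares),
                  share = unname(pf$property_shares),
                  pct = display_pct(unname(pf$property_shares)),
                  stringsAsFactors = FALSE), "property_distribution.csv")
  emit(data.frame(flavor = names(pf$flavor_shares),
                  share = unname(pf$flavor_shares),
                  pct = display_pct(unname(pf$flavor_shares)),
                  stringsAsFactors = FALSE), "flavor_distribution.csv")
  tp <- tag_prevalence(dataset, "function_tags")
  emit(data.frame(tag = names(tp), share = unname(tp),
                  pct = display_pct(unname(tp)), stringsAsFactors = FALSE),
       "function_prevalence.csv")
  note("attribute tables: family/part/source/property/flavor/function written")

  if (!is.null(comparison_inventories)) {
    own <- unique(normalize_scientific_name(dataset$materials$scientific_name))
    for (nm in names(comparison_inventories)) {
      vp <- venn_partition(stats::setNames(
        list(own, normalize_scientific_name(comparison_inventories[[nm]])),
        c("survey", nm)))
      emit(vp, paste0("venn_", nm, ".json"))
      note("venn vs ", nm, ": union ", vp$union_size,
           " -> venn_", nm, ".json")
    }
  }

  pairs <- count_pairs(dataset)
  emit(pairs, "pair_counts.tsv")
  net <- build_core_network(pairs, use_values(freq), threshold = threshold)
  p <- file.path(output_dir, "core_network.graphml")
  export_network(net, p, "graphml"); written <- c(written, p)
  p <- file.path(output_dir, "core_edges.tsv")
  export_network(net, p, "edgelist"); written <- c(written, p)
  emit(net, "core_network.json")
  ranking <- rank_core_materials(net)
  emit(ranking, "core_ranking.csv")
  note("network: threshold>", threshold, ", ", length(net$nodes), " nodes, ",
       nrow(net$edges), " edges -> core_network.{graphml,json}, ",
       "core_edges.tsv, core_ranking.csv")

  log_path <- file.path(output_dir, "run_log.txt")
  writeLines(log_lines, log_path, useBytes = TRUE)
  written <- c(written, log_path)
  ok <- TRUE
  invisible(list(frequency = freq, shannon = sh, network = net,
                 ranking = ranking, files = written))
}
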