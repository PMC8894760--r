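## Drug-pair co-occurrence counting, thresholded core network, ranking.

#' Count drug-pair co-occurrences
#'
#' A drug pair is an unordered pair of materials appearing together in one
#' formulation; its count is the number of formulations containing both.
#' Every 2-subset of every formulation's material set contributes one
#' increment. Pair keys are canonicalised with the lexicographically smaller
#' id first; self-pairs cannot occur because formulations are sets.
#'
#' @param dataset A `survey_dataset`.
#' @return Object of class `pair_counts`: data frame with columns `a`, `b`
#'   (`a < b`), `count`, sorted by count descending then `a`, `b`; pairs that
#'   never co-occur are absent. Attribute `N` carries the formulation count.
#' @export
count_pairs <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (mats in dataset$formulations$materials) {
    m <- sort(mats)          # canonical order; sets are already deduplicated
    n <- length(m)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        key <- paste(m[i], m[j], sep = "\r")
        env[[key]] <- (if (is.null(env[[key]])) 0L else env[[key]]) + 1L
      }
    }
  }
  keys <- ls(env, sorted = TRUE)
  if (length(keys) == 0) {
    out <- data.frame(a = character(0), b = character(0), count = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    ab <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    out <- data.frame(a = ab[, 1], b = ab[, 2],
                      count = vapply(keys, function(k) env[[k]], integer(1)),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$a, out$b, method = "radix"), ]
  }
  rownames(out) <- NULL
  attr(out, "N") <- dataset$N
  class(out) <- c("pair_counts", "data.frame")
  out
}

#' Build the thresholded core co-occurrence network
#'
#' Keeps the drug pairs whose co-occurrence count is *strictly greater* than
#' the threshold (the conventional cut "more than four times" with the
#' default of 4), and the materials they involve. Nodes carry use values;
#' materials with no retained pair are excluded.
#'
#' @param pairs A `pair_counts` object (see [count_pairs()]).
#' @param uv Named numeric vector of use values covering every material that
#'   can become a node.
#' @param threshold Non-negative integer; an edge requires `count > threshold`
#'   (default 4).
#' @return Object of class `core_network`: list with `nodes` (named numeric,
#'   UV per retained material), `edges` (data frame `a`, `b`, `count`) and
#'   `threshold`.
#' @export
build_core_network <- function(pairs, uv, threshold = 4) {
  stopifnot(inherits(pairs, "data.frame"))
  if (threshold < 0) stop("threshold must be non-negative", call. = FALSE)
  edges <- pairs[pairs$count > threshold, c("a", "b", "count"), drop = FALSE]
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  edges <- edges[order(-edges$count, edges$a, edges$b, method = "radix"), ]
  rownames(edges) <- NULL
  node_ids <- sort(unique(c(edges$a, edges$b)))
  missing_uv <- node_ids[!(node_ids %in% names(uv)) | is.na(uv[node_ids])]
  if (length(missing_uv) > 0) {
    stop("no use value supplied for network material(s): ",
         paste(missing_uv, collapse = ", "), call. = FALSE)
  }
  structure(
    list(nodes = uv[node_ids], edges = edges,
         threshold = as.integer(threshold)),
    class = "core_network")
}

#' Rank core materials
#'
#' Scores each node of the core network and returns the full ranking; the
#' head of the list is read as the core medicinal materials. The default
#' score is weighted degree — the sum of co-occurrence counts on incident
#' edges — reflecting how strongly a material partners with others above
#' threshold. Ties break by node use value (descending), then name.
#'
#' @param net A `core_network`.
#' @param score `"wdegree"` (sum of incident edge counts, default),
#'   `"degree"` (number of incident edges) or `"eigenvector"` (eigenvector
#'   centrality of the count-weighted graph).
#' @return Data frame with columns `material`, `score`, `uv`, ordered best
#'   first; empty for an empty network.
#' @export
rank_core_materials <- function(net,
                                score = c("wdegree", "degree", "eigenvector")) {
  stopifnot(inherits(net, "core_network"))
  score <- match.arg(score)
  ids <- names(net$nodes)
  if (length(ids) == 0) {
    return(data.frame(material = character(0), score = numeric(0),
                      uv = numeric(0), stringsAsFactors = FALSE))
  }
  s <- switch(score,
    wdegree = {
      inc <- c(net$edges$a, net$edges$b)
      w <- rep(net$edges$count, 2)
      vapply(ids, function(m) sum(w[inc == m]), numeric(1))
    },
    degree = {
      inc <- c(net$edges$a, net$edges$b)
      vapply(ids, function(m) sum(inc == m), numeric(1))
    },
    eigenvector = {
      g <- as_igraph(net)
      ec <- igraph::eigen_centrality(g, weights = igraph::E(g)$count)$vector
      as.numeric(ec[ids])
    })
  out <- data.frame(material = ids, score = as.numeric(s),
                    uv = as.numeric(net$nodes[ids]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, -out$uv, out$material, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Convert a core network to an igraph graph
#'
#' @param net A `core_network`.
#' @return An undirected `igraph` graph with vertex attribute `uv` and edge
#'   attribute `count`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "core_network"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = names(net$nodes),
                            uv = as.numeric(net$nodes))
  if (nrow(net$edges) > 0) {
    g <- igraph::add_edges(g, rbind(net$edges$a, net$edges$b),
                           count = net$edges$count)
  }
  g
}

#' Export a core network to disk
#'
#' GraphML carries the node attribute `uv` and edge attribute `count`;
#' the edge-list TSV has columns `material_a`, `material_b`, `count`; JSON
#' serialises nodes, edges and threshold. Rows and keys are emitted in
#' sorted order so repeated exports of the same network are byte-identical.
#'
#' @param net A `core_network`.
#' @param path Output file path.
#' @param format `"graphml"`, `"edgelist"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(net, path, format = c("graphml", "edgelist", "json")) {
  stopifnot(inherits(net, "core_network"))
  format <- match.arg(format)
  edges <- net$edges[order(net$edges$a, net$edges$b, method = "radix"), ,
                     drop = FALSE]
  switch(format,
    graphml = igraph::write_graph(as_igraph(net), path, format = "graphml"),
    edgelist = {
      out <- data.frame(material_a = edges$a, material_b = edges$b,
                        count = edges$count, stringsAsFactors = FALSE)
      utils::write.table(out, path, sep = "\t", row.names = FALSE,
                         quote = FALSE, fileEncoding = "UTF-8")
    },
    json = {
      obj <- list(
        threshold = net$threshold,
        nodes = lapply(seq_along(net$nodes), function(i) {
          list(material = names(net$nodes)[i], uv = as.numeric(net$nodes[i]))
        }),
        edges = lapply(seq_len(nrow(edges)), function(i) {
          list(a = edges$a[i], b = edges$b[i], count = edges$count[i])
        }))
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    })
  invisible(path)
}

#' Read a core network back from its JSON export
#'
#' @param path Path written by `export_network(..., format = "json")`.
#' @return A `core_network`.
#' @export
read_core_network <- function(path) {
  obj <- jsonlite::read_json(path)
  nodes <- stats::setNames(
    vapply(obj$nodes, function(n) as.numeric(n$uv), numeric(1)),
    vapply(obj$nodes, function(n) as.character(n$material), character(1)))
  if (length(obj$edges) > 0) {
    edges <- data.frame(
      a = vapply(obj$edges, function(e) as.character(e$a), character(1)),
      b = vapply(obj$edges, function(e) as.character(e$b), character(1)),
      count = vapply(obj$edges, function(e) as.integer(e$count), integer(1)),
      stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(a = character(0), b = character(0),
                        count = integer(0), stringsAsFactors = FALSE)
  }
  edges <- edges[order(-edges$count, edges$a, edges$b, method = "radix"), ]
  rownames(edges) <- NULL
  structure(list(nodes = nodes[sort(names(nodes))], edges = edges,
                 threshold = as.integer(obj$threshold)),
            class = "core_network")
}

#' @export
print.core_network <- function(x, ...) {
  cat("Core co-occurrence network:", length(x$nodes), "materials,",
      nrow(x$edges), "drug pairs with count >", x$threshold, "\n")
  if (nrow(x$edges) > 0) print(utils::head(x$edges, 10), row.names = FALSE)
  invisible(x)
}

#' @export
summary.core_network <- function(object, ...) {
  print(object)
  r <- rank_core_materials(object)
  if (nrow(r) > 0) {
    cat("Top materials by weighted degree:\n")
    print(utils::head(r, 5), row.names = FALSE)
  }
  invisible(object)
}

#' Plot a core network
#'
#' Quick-look rendering in the conventional style: circle area proportional
#' to use value, edge width proportional to co-occurrence count.
#'
#' @param x A `core_network`.
#' @param ... Passed to `plot.igraph`.
#' @export
plot.core_network <- function(x, ...) {
  if (length(x$nodes) == 0) {
    stop("cannot plot an empty network", call. = FALSE)
  }
  g <- as_igraph(x)
  igraph::plot.igraph(
    g,
    vertex.size = 40 * sqrt(igraph::V(g)$uv / max(igraph::V(g)$uv)),
    edge.width = if (igraph::ecount(g) > 0)
      3 * igraph::E(g)$count / max(igraph::E(g)$count) else 1,
    ...)
  invisible(x)
}
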