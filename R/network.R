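# Directed disease-correlation network assembly, topology and export.
#
# Each disease is a node; a directed edge X -> Y records a statistically
# significant temporal correlation (earlier X, later Y). Edges carry the
# per-pair statistics of both analysis arms plus the quality-control
# p-values so the network is an auditable summary of the whole run.

EDGE_ATTRS <- c("coefficient", "hazard_ratio", "n", "cox_p_raw",
                "cox_p_adjusted", "zph_p", "ks_p",
                "wilcoxon_p_adjusted", "ttest_p_adjusted", "support")

#' Assemble the disease-correlation network from per-pair results
#'
#' @param cox data frame of Cox results with columns `from`, `to`,
#'   `coefficient`, `hazard_ratio`, `n`, `p_raw`, `p_adjusted` and
#'   optionally `zph_p`.
#' @param rsf optional data frame of RSF results with `from`, `to`,
#'   `wilcoxon_p_adjusted`, `ttest_p_adjusted`.
#' @param qc optional data frame with `from`, `to`, `ks_p`.
#' @param alpha significance threshold on adjusted p-values (default 0.05).
#' @param mode `"overlap"` keeps pairs significant in both arms (Cox
#'   adjusted p <= alpha and both RSF adjusted p <= alpha) — the
#'   higher-confidence display set; `"cox"` and `"rsf"` use one arm alone.
#' @param require_positive an edge asserts that X accelerates Y, so by
#'   default a pair must also show the positive direction (exposure
#'   hazard ratio > 1 for the Cox arm; exposed restricted mean survival
#'   below the comparison mean for the RSF arm). `FALSE` admits
#'   significant pairs of either direction.
#' @return An object of class `disease_network`: list with `nodes` (sorted
#'   labels of diseases incident to at least one edge) and `edges` (data
#'   frame with the per-edge attribute columns, including `support` =
#'   which arms flagged the pair).
#' @export
build_network <- function(cox, rsf = NULL, qc = NULL, alpha = 0.05,
                          mode = c("overlap", "cox", "rsf"),
                          require_positive = TRUE) {
  mode <- match.arg(mode)
  if (alpha <= 0 || alpha >= 1) dcn_stop("dcn_bad_input", "alpha must be in (0, 1)")
  need <- c("from", "to", "coefficient", "hazard_ratio", "n", "p_raw", "p_adjusted")
  if (!is.null(cox) && nrow(cox) > 0L && !all(need %in% names(cox)))
    dcn_stop("dcn_bad_input", "cox results lack required columns")
  if (mode %in% c("overlap", "rsf") && is.null(rsf))
    dcn_stop("dcn_bad_input", sprintf("mode '%s' requires RSF results", mode))

  e <- if (is.null(cox)) data.frame() else cox
  if (nrow(e) == 0L) return(new_disease_network(empty_edges()))
  e <- e[e$from != e$to, , drop = FALSE]
  if (anyDuplicated(paste(e$from, e$to, sep = "\r")))
    dcn_stop("dcn_bad_input", "duplicate ordered pair in cox results")

  key <- function(d) paste(d$from, d$to, sep = "\r")
  rsf_dir <- rep(TRUE, nrow(e))
  if (!is.null(rsf) && nrow(rsf) > 0L) {
    m <- match(key(e), key(rsf))
    e$wilcoxon_p_adjusted <- rsf$wilcoxon_p_adjusted[m]
    e$ttest_p_adjusted <- rsf$ttest_p_adjusted[m]
    if (all(c("mean_exposed", "mean_comparison") %in% names(rsf)))
      rsf_dir <- rsf$mean_exposed[m] < rsf$mean_comparison[m]
  } else {
    e$wilcoxon_p_adjusted <- NA_real_
    e$ttest_p_adjusted <- NA_real_
  }
  if (!is.null(qc) && nrow(qc) > 0L) {
    e$ks_p <- qc$ks_p[match(key(e), key(qc))]
  } else e$ks_p <- NA_real_

  cox_sig <- !is.na(e$p_adjusted) & e$p_adjusted <= alpha
  rsf_sig <- !is.na(e$wilcoxon_p_adjusted) & e$wilcoxon_p_adjusted <= alpha &
    !is.na(e$ttest_p_adjusted) & e$ttest_p_adjusted <= alpha
  if (require_positive) {
    cox_sig <- cox_sig & e$coefficient > 0
    rsf_sig <- rsf_sig & (is.na(rsf_dir) | rsf_dir)
  }
  keep <- switch(mode, overlap = cox_sig & rsf_sig, cox = cox_sig, rsf = rsf_sig)
  e <- e[keep, , drop = FALSE]
  e$support <- ifelse(cox_sig[keep] & rsf_sig[keep], "both",
                      ifelse(cox_sig[keep], "cox", "rsf"))
  edges <- data.frame(from = e$from, to = e$to, coefficient = e$coefficient,
                      hazard_ratio = e$hazard_ratio, n = e$n,
                      cox_p_raw = e$p_raw, cox_p_adjusted = e$p_adjusted,
                      zph_p = if ("zph_p" %in% names(e)) e$zph_p else NA_real_,
                      ks_p = e$ks_p,
                      wilcoxon_p_adjusted = e$wilcoxon_p_adjusted,
                      ttest_p_adjusted = e$ttest_p_adjusted,
                      support = e$support, stringsAsFactors = FALSE)
  new_disease_network(edges)
}

empty_edges <- function() {
  data.frame(from = character(0), to = character(0), coefficient = numeric(0),
             hazard_ratio = numeric(0), n = numeric(0), cox_p_raw = numeric(0),
             cox_p_adjusted = numeric(0), zph_p = numeric(0), ks_p = numeric(0),
             wilcoxon_p_adjusted = numeric(0), ttest_p_adjusted = numeric(0),
             support = character(0), stringsAsFactors = FALSE)
}

new_disease_network <- function(edges) {
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(edges$from, edges$to))), edges = edges),
            class = "disease_network")
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = data.frame(name = net$nodes))
}

#' Node degree table
#'
#' @param net a `disease_network`.
#' @return data frame with `disease`, `in_degree`, `out_degree`,
#'   `total_degree`, sorted by total degree descending then label. In-degree
#'   is the count of significant antecedent diseases (and drives node size
#'   in the conventional network rendering).
#' @export
degrees <- function(net) {
  stopifnot(inherits(net, "disease_network"))
  if (length(net$nodes) == 0L)
    return(data.frame(disease = character(0), in_degree = integer(0),
                      out_degree = integer(0), total_degree = integer(0)))
  g <- as_igraph(net)
  din <- igraph::degree(g, mode = "in")
  dout <- igraph::degree(g, mode = "out")
  out <- data.frame(disease = names(din), in_degree = as.integer(din),
                    out_degree = as.integer(dout),
                    total_degree = as.integer(din + dout),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$total_degree, out$disease), ]
  rownames(out) <- NULL
  out
}

#' Shortest disease trajectory between two nodes
#'
#' Minimum-hop path by breadth-first search. Edges are unweighted; ties are
#' broken deterministically by exploring neighbours in lexicographic order,
#' so the returned path is reproducible.
#'
#' @param net a `disease_network`.
#' @param from,to disease labels present in the network.
#' @param directed follow edge direction (default TRUE, trajectory
#'   semantics); `FALSE` treats edges as undirected.
#' @return character vector of node labels from `from` to `to` (length 1
#'   when `from == to`), or `NULL` when `to` is unreachable.
#' @export
shortest_path <- function(net, from, to, directed = TRUE) {
  stopifnot(inherits(net, "disease_network"))
  for (d in c(from, to)) {
    if (!d %in% net$nodes)
      dcn_stop("dcn_unknown_disease", sprintf("node not in network: %s", d))
  }
  if (identical(from, to)) return(from)
  adj <- adjacency_list(net, directed)
  prev <- stats::setNames(rep(NA_character_, length(net$nodes)), net$nodes)
  visited <- stats::setNames(logical(length(net$nodes)), net$nodes)
  visited[from] <- TRUE
  frontier <- from
  while (length(frontier) > 0L && !visited[to]) {
    nxt <- character(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (!visited[w]) {
          visited[w] <- TRUE
          prev[w] <- v
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  if (!visited[to]) return(NULL)
  path <- to
  while (path[1L] != from) path <- c(prev[[path[1L]]], path)
  path
}

adjacency_list <- function(net, directed = TRUE) {
  adj <- stats::setNames(vector("list", length(net$nodes)), net$nodes)
  for (v in net$nodes) adj[[v]] <- character(0)
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$from[i]; b <- net$edges$to[i]
    adj[[a]] <- c(adj[[a]], b)
    if (!directed) adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, function(x) sort(unique(x)))
}

#' Filter network edges on sample size, significance and effect size
#'
#' Keeps edges with `n >= min_n`, Cox adjusted p `<= max_p` and
#' `coefficient >= min_coeff`; nodes left without edges are dropped.
#' Filtering is idempotent and monotone: tightening any threshold never
#' adds edges.
#'
#' @param net a `disease_network`.
#' @param min_n minimum cohort size.
#' @param max_p maximum Cox BH-adjusted p-value.
#' @param min_coeff minimum exposure log-hazard-ratio.
#' @return the filtered `disease_network`.
#' @export
filter_network <- function(net, min_n = 0, max_p = 1, min_coeff = -Inf) {
  stopifnot(inherits(net, "disease_network"))
  e <- net$edges
  keep <- e$n >= min_n & e$cox_p_adjusted <= max_p & e$coefficient >= min_coeff
  keep[is.na(keep)] <- FALSE
  new_disease_network(e[keep, , drop = FALSE])
}

#' Export a disease network
#'
#' @param net a `disease_network`.
#' @param path output file path.
#' @param format `"csv-edgelist"` (one row per edge with all attributes;
#'   lossless), `"graphml"` (igraph writer; lossless round trip via
#'   [import_network()]), or `"cytoscape-json"` (the Cytoscape JS
#'   `elements` convention: `{nodes: [{data: {id}}], edges: [{data:
#'   {source, target, ...}}]}`, with node `in_degree` and edge
#'   `coefficient` exported as numeric attributes for size/thickness
#'   styling in the viewer).
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path,
                           format = c("csv-edgelist", "graphml", "cytoscape-json")) {
  stopifnot(inherits(net, "disease_network"))
  format <- match.arg(format)
  if (format == "csv-edgelist") {
    utils::write.csv(net$edges, path, row.names = FALSE)
  } else if (format == "graphml") {
    g <- as_igraph(net)
    deg <- degrees(net)
    igraph::V(g)$in_degree <- deg$in_degree[match(net$nodes, deg$disease)]
    igraph::write_graph(g, path, format = "graphml")
  } else {
    deg <- degrees(net)
    nodes <- lapply(net$nodes, function(v) {
      list(data = list(id = v,
                       in_degree = deg$in_degree[match(v, deg$disease)]))
    })
    edges <- lapply(seq_len(nrow(net$edges)), function(i) {
      d <- as.list(net$edges[i, , drop = FALSE])
      names(d)[names(d) == "from"] <- "source"
      names(d)[names(d) == "to"] <- "target"
      list(data = d)
    })
    jsonlite::write_json(list(elements = list(nodes = nodes, edges = edges)),
                         path, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  }
  invisible(path)
}

#' Re-import an exported disease network
#'
#' @param path file written by [export_network()].
#' @param format `"csv-edgelist"` or `"graphml"`.
#' @return a `disease_network`.
#' @export
import_network <- function(path, format = c("csv-edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "csv-edgelist") {
    e <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(from = "character", to = "character"))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    e <- igraph::as_data_frame(g, what = "edges")
    e <- e[, c("from", "to", intersect(EDGE_ATTRS, names(e)))]
  }
  for (cn in setdiff(intersect(EDGE_ATTRS, names(e)), "support")) {
    e[[cn]] <- as.numeric(e[[cn]])
    e[[cn]][is.nan(e[[cn]])] <- NA_real_
  }
  new_disease_network(e)
}

#' @export
print.disease_network <- function(x, ...) {
  cat(sprintf("<disease_network> %d nodes, %d directed edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges) > 0L) {
    tab <- table(x$edges$support)
    cat("  support:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
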