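mk_cox <- function(from, to, p_adj, coeff = 1, n = 1000) {
  data.frame(from = from, to = to, coefficient = coeff,
             hazard_ratio = exp(coeff), n = n, p_raw = p_adj / 2,
             p_adjusted = p_adj, zph_p = 0.5, stringsAsFactors = FALSE)
}

test_that("overlap mode keeps only pairs significant in both arms", {
  cox <- mk_cox(c("A", "A", "B", "C", "D"), c("B", "C", "C", "D", "E"),
                p_adj = c(0.01, 0.01, 0.2, 0.03, 0.04))
  rsf <- data.frame(from = cox$from, to = cox$to,
                    wilcoxon_p_adjusted = c(0.01, 0.2, 0.01, 0.02, 0.01),
                    ttest_p_adjusted = c(0.02, 0.01, 0.01, 0.03, 0.01))
  net <- build_network(cox, rsf, alpha = 0.05, mode = "overlap")
  expect_equal(nrow(net$edges), 3)  # A->B, C->D, D->E
  expect_setequal(paste(net$edges$from, net$edges$to), c("A B", "C D", "D E"))
  expect_true(all(net$edges$support == "both"))
  # overlap is a subset of each single-arm network
  ncox <- build_network(cox, rsf, alpha = 0.05, mode = "cox")
  nrsf <- build_network(cox, rsf, alpha = 0.05, mode = "rsf")
  key <- function(n) paste(n$edges$from, n$edges$to)
  expect_true(all(key(net) %in% key(ncox)))
  expect_true(all(key(net) %in% key(nrsf)))
  # single-arm filter agrees with a brute-force row filter
  expect_setequal(key(ncox), paste(cox$from, cox$to)[cox$p_adjusted <= 0.05])
})

test_that("empty results give an empty network and degrees handle it", {
  net <- build_network(data.frame(), mode = "cox")
  expect_length(net$nodes, 0)
  expect_equal(nrow(net$edges), 0)
  expect_equal(nrow(degrees(net)), 0)
})

test_that("degrees match brute-force adjacency counts and conserve the sum rule", {
  net <- random_network(12, 20, seed = 42)
  d <- degrees(net)
  # brute force from the edge list
  for (i in seq_len(nrow(d))) {
    v <- d$disease[i]
    expect_equal(d$in_degree[i], sum(net$edges$to == v))
    expect_equal(d$out_degree[i], sum(net$edges$from == v))
    expect_equal(d$total_degree[i], d$in_degree[i] + d$out_degree[i])
  }
  expect_equal(sum(d$in_degree), nrow(net$edges))
  expect_equal(sum(d$out_degree), nrow(net$edges))
  # single edge and complete-graph sanity cases
  n1 <- build_network(mk_cox("A", "B", 0.01), mode = "cox")
  d1 <- degrees(n1)
  expect_equal(d1$in_degree[d1$disease == "A"], 0L)
  expect_equal(d1$out_degree[d1$disease == "A"], 1L)
  expect_equal(d1$in_degree[d1$disease == "B"], 1L)
  expect_equal(d1$out_degree[d1$disease == "B"], 0L)
  k4 <- expand.grid(from = LETTERS[1:4], to = LETTERS[1:4], stringsAsFactors = FALSE)
  k4 <- k4[k4$from != k4$to, ]
  dk <- degrees(build_network(mk_cox(k4$from, k4$to, 0.01), mode = "cox"))
  expect_true(all(dk$in_degree == 3 & dk$out_degree == 3 & dk$total_degree == 6))
})

test_that("shortest paths agree with an independent BFS oracle", {
  net <- random_network(50, 180, seed = 7)
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = net$nodes)
  dmat <- igraph::distances(g, mode = "out")
  set.seed(8)
  for (q in 1:100) {
    a <- sample(net$nodes, 1); b <- sample(net$nodes, 1)
    p <- shortest_path(net, a, b)
    if (is.infinite(dmat[a, b])) {
      expect_null(p)
    } else {
      expect_equal(length(p) - 1, unname(dmat[a, b]))
      expect_equal(p[1], a); expect_equal(p[length(p)], b)
      # every hop is an edge
      if (length(p) > 1) {
        hops <- paste(p[-length(p)], p[-1])
        expect_true(all(hops %in% paste(net$edges$from, net$edges$to)))
      }
    }
  }
  expect_equal(shortest_path(net, net$nodes[1], net$nodes[1]), net$nodes[1])
  expect_error(shortest_path(net, "nope", net$nodes[1]), class = "dcn_unknown_disease")
})

test_that("a direct edge beats a two-hop detour and ties break lexicographically", {
  cox <- mk_cox(c("A", "B", "A"), c("B", "C", "C"), 0.01)
  net <- build_network(cox, mode = "cox")
  expect_equal(shortest_path(net, "A", "C"), c("A", "C"))
  # two equally short routes A->B->D and A->C->D: lexicographic tie-break via B
  cox2 <- mk_cox(c("A", "A", "B", "C"), c("B", "C", "D", "D"), 0.01)
  net2 <- build_network(cox2, mode = "cox")
  expect_equal(shortest_path(net2, "A", "D"), c("A", "B", "D"))
})

test_that("filtering is a brute-force row filter, idempotent and monotone", {
  net <- random_network(15, 30, seed = 3)
  f <- filter_network(net, min_n = 1000, max_p = 0.03, min_coeff = 0)
  e <- net$edges
  keep <- e$n >= 1000 & e$cox_p_adjusted <= 0.03 & e$coefficient >= 0
  expect_setequal(paste(f$edges$from, f$edges$to), paste(e$from, e$to)[keep])
  # isolated nodes are dropped
  expect_setequal(f$nodes, unique(c(f$edges$from, f$edges$to)))
  # idempotence
  f2 <- filter_network(f, min_n = 1000, max_p = 0.03, min_coeff = 0)
  expect_equal(f2$edges, f$edges)
  # identity at extreme thresholds; empty at max_p = 0
  expect_equal(filter_network(net, 0, 1, -Inf)$edges, net$edges)
  expect_equal(nrow(filter_network(net, 0, 0, -Inf)$edges), 0)
  # monotone: tightening never adds edges
  loose <- filter_network(net, 500, 0.04, -1)
  tight <- filter_network(net, 2000, 0.02, 0.5)
  expect_true(all(paste(tight$edges$from, tight$edges$to) %in%
                    paste(loose$edges$from, loose$edges$to)))
  expect_equal(sum(degrees(f)$in_degree), nrow(f$edges))
})

test_that("csv and graphml exports round-trip losslessly", {
  net <- random_network(10, 18, seed = 99)
  csv <- file.path(tempdir(), "net.csv")
  gml <- file.path(tempdir(), "net.graphml")
  export_network(net, csv, "csv-edgelist")
  export_network(net, gml, "graphml")
  back_csv <- import_network(csv, "csv-edgelist")
  expect_equal(back_csv$nodes, net$nodes)
  expect_equal(back_csv$edges, net$edges, tolerance = 1e-12)
  back_gml <- import_network(gml, "graphml")
  expect_equal(back_gml$nodes, net$nodes)
  cols <- names(net$edges)
  expect_equal(back_gml$edges[cols], net$edges[cols], tolerance = 1e-12)
})

test_that("cytoscape json follows the elements convention", {
  net <- random_network(6, 9, seed = 5)
  path <- file.path(tempdir(), "net.cyjs.json")
  export_network(net, path, "cytoscape-json")
  j <- jsonlite::read_json(path)
  expect_named(j, "elements")
  expect_named(j$elements, c("nodes", "edges"))
  ids <- vapply(j$elements$nodes, function(n) n$data$id, "")
  expect_setequal(ids, net$nodes)
  for (e in j$elements$edges) {
    expect_true(e$data$source %in% ids)
    expect_true(e$data$target %in% ids)
    expect_true(is.numeric(e$data$coefficient))
  }
  expect_error(export_network(net, path, "dot"))
})
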