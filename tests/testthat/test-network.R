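test_that("correlation_graph applies the |rho| and p thresholds", {
  set.seed(1)
  n <- 20
  base <- sort(runif(n))
  m <- rbind(t1 = round(1000 * base) + 1L,
             t2 = round(800 * base^1.2) + 1L,       # monotone with t1
             t3 = round(1000 * rev(base)) + 1L,     # anti-monotone
             matrix(rpois(5 * n, 50), 5,
                    dimnames = list(paste0("r", 1:5), NULL)))
  colnames(m) <- paste0("s", seq_len(n))
  tab <- otu_table(m)
  cg <- correlation_graph(tab)
  ed <- igraph::as_data_frame(cg$graph, what = "edges")
  # perfectly monotone pair retained with rho = 1
  e12 <- ed[(ed$from == "t1" & ed$to == "t2") |
              (ed$from == "t2" & ed$to == "t1"), ]
  expect_equal(nrow(e12), 1L)
  expect_equal(e12$rho, 1)
  expect_equal(e12$sign, "positive")
  # every retained edge satisfies both thresholds
  expect_true(all(abs(ed$rho) >= 0.6 & ed$p < 0.01))
  expect_equal(cg$n_positive + cg$n_negative, nrow(ed))
  # a strong-p but sub-threshold rho edge must be rejected: check by
  # recomputing the full rho matrix and confirming no kept pair is below 0.6
  r <- cor(apply(rel_abund(tab), 1, rank))   # samples x taxa -> taxa cor
  for (k in seq_len(nrow(ed)))
    expect_gte(abs(r[ed$from[k], ed$to[k]]), 0.6)
  expect_error(correlation_graph(make_table(matrix(1:14, 2, 7))), ">= 8")
  # a taxon constant in relative abundance is skipped with a warning
  # (equal sample depths so the constant row stays constant after closure)
  set.seed(2)
  m2 <- matrix(rpois(3 * 10, 30) + 1L, 3, 10)
  m2 <- rbind(m2, const = 7L, filler = max(colSums(m2)) + 50L - colSums(m2))
  rownames(m2)[1:3] <- paste0("v", 1:3)
  colnames(m2) <- paste0("s", 1:10)
  expect_warning(correlation_graph(otu_table(m2)), "constant")
  # taxon reordering leaves the edge set identical
  cg2 <- correlation_graph(otu_table(m[sample(nrow(m)), ]))
  canon <- function(e) {
    k <- data.frame(a = pmin(e$from, e$to), b = pmax(e$from, e$to),
                    rho = e$rho)
    k[order(k$a, k$b), ]
  }
  ed2 <- igraph::as_data_frame(cg2$graph, what = "edges")
  expect_equal(canon(ed), canon(ed2), ignore_attr = TRUE)
})

test_that("detect_modules finds planted and closed-form partitions", {
  # two disjoint 6-cliques: 2 modules, Q = 0.5
  g <- igraph::disjoint_union(igraph::make_full_graph(6),
                              igraph::make_full_graph(6))
  cg <- graph_fixture(g)
  mods <- detect_modules(cg, seed = 1)
  expect_equal(length(unique(mods$membership)), 2L)
  expect_equal(mods$Q, 0.5, tolerance = 1e-12)
  # complete graph: one module, Q = 0
  cgK <- graph_fixture(igraph::make_full_graph(8))
  modsK <- detect_modules(cgK, seed = 1)
  expect_equal(length(unique(modsK$membership)), 1L)
  expect_equal(modsK$Q, 0, tolerance = 1e-12)
  # planted 3-module recovery through the full pipeline
  tab <- simulate_modular_network_data(3, 10, 60, 0.9, seed = 7)
  cgp <- correlation_graph(tab)
  modp <- detect_modules(cgp, seed = 2)
  planted <- attr(tab, "module")[igraph::V(cgp$graph)$name]
  expect_gte(co_assignment_accuracy(planted, modp$membership[names(planted)]),
             0.9)
  # detected Q beats the trivial one-module partition (which is <= 0)
  triv <- stats::setNames(rep(1, igraph::vcount(cgp$graph)),
                          igraph::V(cgp$graph)$name)
  expect_gte(modp$Q, igraph::modularity(cgp$graph, triv))
  # rho_within = 0 yields near-empty graph
  tab0 <- simulate_modular_network_data(3, 10, 60, 0, seed = 8)
  cg0 <- correlation_graph(tab0)
  nv <- igraph::vcount(cg0$graph)
  expect_lt(2 * igraph::ecount(cg0$graph) / (nv * (nv - 1)), 0.01)
  expect_error(detect_modules(cg0, seed = 1), "no edges")
})

test_that("modularity Q matches the Newman oracle on random partitions", {
  set.seed(21)
  g <- igraph::sample_gnp(12, 0.35)
  igraph::V(g)$name <- paste0("n", 1:12)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  for (i in 1:10) {
    memb <- sample(1:3, 12, replace = TRUE)
    expect_equal(igraph::modularity(g, memb),
                 oracle_modularity(adj, memb), tolerance = 1e-12)
  }
})

test_that("topology reports closed-form metrics", {
  tri <- graph_fixture(igraph::make_full_graph(3))
  t1 <- topology(tri)
  expect_equal(t1$network$density, 1)
  expect_equal(t1$network$avg_clustering, 1)
  expect_equal(t1$network$avg_degree, 2)
  path <- graph_fixture(igraph::make_graph(~ A - B, B - C))
  t2 <- topology(path)
  expect_equal(t2$network$avg_path_length, 4 / 3, tolerance = 1e-12)
  star <- graph_fixture(igraph::make_star(6, mode = "undirected"))
  t3 <- topology(star)
  expect_equal(t3$network$avg_degree, 10 / 6, tolerance = 1e-12)
  expect_equal(sort(t3$nodes$degree, decreasing = TRUE)[1], 5)
})

test_that("zi_pi matches hand values and the brute-force oracle", {
  # node with 3 edges split 2/1 across two modules: Pi = 4/9
  g <- igraph::make_graph(~ x - a, x - b, x - c, a - b)
  cg <- graph_fixture(g)
  memb <- c(x = 1, a = 1, b = 1, c = 2)
  zp <- zi_pi(cg, memb)
  expect_equal(zp$Pi[zp$taxon == "x"], 1 - (4 / 9 + 1 / 9), tolerance = 1e-12)
  # all edges inside own module -> Pi = 0; even 2-way split -> Pi = 0.5
  expect_equal(zp$Pi[zp$taxon == "a"], 0)
  memb2 <- c(x = 1, a = 1, b = 2, c = 2)
  zp2 <- zi_pi(cg, memb2)
  expect_equal(zp2$Pi[zp2$taxon == "a"], 0.5)
  # oracle equivalence + the Zi standardization invariant on a random graph
  set.seed(5)
  gr <- igraph::sample_gnp(15, 0.3)
  igraph::V(gr)$name <- paste0("n", 1:15)
  cgr <- graph_fixture(gr)
  membr <- stats::setNames(sample(1:3, 15, replace = TRUE),
                           igraph::V(gr)$name)
  zpr <- zi_pi(cgr, membr)
  adj <- igraph::as_adjacency_matrix(gr, sparse = FALSE)
  orc <- oracle_zipi(adj, membr[rownames(adj)])
  expect_equal(zpr$Zi, orc$Zi, tolerance = 1e-12)
  expect_equal(zpr$Pi, orc$Pi, tolerance = 1e-12)
  for (m in unique(zpr$module)) {
    zs <- zpr$Zi[zpr$module == m]
    if (stats::sd(zs) > 0) {
      expect_equal(mean(zs), 0, tolerance = 1e-10)
      expect_equal(stats::sd(zs), 1, tolerance = 1e-10)
    }
  }
  expect_true(all(zpr$Pi >= 0 & zpr$Pi <= 1 - 1 / 3 + 1e-12))
  expect_error(zi_pi(cgr, membr[-1]), "unassigned")
})

test_that("classify_roles reproduces the exact threshold rules", {
  eps <- 1e-9
  zp <- data.frame(
    Zi = c(3.0, 3.0, 1.0, 1.0, 2.5, 2.5, 2.5 + eps, 2.5 + eps),
    Pi = c(0.70, 0.30, 0.70, 0.30, 0.62, 0.62 + eps, 0.62, 0.62 + eps))
  roles <- classify_roles(zp)$role
  expect_equal(as.character(roles),
               c("network_hub", "module_hub", "connector", "peripheral",
                 "peripheral",          # Zi = 2.5 is not > 2.5
                 "connector",           # Zi = 2.5, Pi > 0.62
                 "module_hub",          # Zi > 2.5, Pi = 0.62 is not > 0.62
                 "network_hub"))
  expect_error(classify_roles(data.frame(Zi = NA_real_, Pi = 0.1)), "finite")
})

test_that("fully separated modules yield no network hubs", {
  g <- igraph::disjoint_union(igraph::make_full_graph(6),
                              igraph::make_full_graph(6))
  cg <- graph_fixture(g)
  mods <- detect_modules(cg, seed = 1)
  zp <- classify_roles(zi_pi(cg, mods))
  expect_true(all(zp$Pi == 0))
  expect_false(any(zp$role == "network_hub"))
})

test_that("subnetworks induce per-group presence subgraphs", {
  m <- rbind(t1 = c(5L, 6L, 0L, 0L), t2 = c(4L, 5L, 0L, 0L),
             t3 = c(0L, 0L, 7L, 8L), t4 = c(0L, 0L, 6L, 7L),
             t5 = c(3L, 3L, 3L, 3L))
  colnames(m) <- paste0("s", 1:4)
  # build a graph by hand: edges inside each disjoint taxon set
  g <- igraph::make_graph(~ t1 - t2, t3 - t4, t1 - t5, t3 - t5)
  cg <- graph_fixture(g)
  tab <- otu_table(m)
  md <- data.frame(sample_id = paste0("s", 1:4),
                   site = rep(c("A", "B"), each = 2),
                   niche = "x", stringsAsFactors = FALSE)
  sub <- subnetworks(cg, tab, md, by = "site")
  expect_setequal(names(sub), c("A", "B"))
  expect_setequal(igraph::V(sub$A$graph$graph)$name, c("t1", "t2", "t5"))
  expect_setequal(igraph::V(sub$B$graph$graph)$name, c("t3", "t4", "t5"))
  # taxon absent from a group is excluded from its subgraph
  expect_false("t3" %in% igraph::V(sub$A$graph$graph)$name)
  # edge sets are disjoint for disjoint taxa (t5 shared but its edges differ)
  eA <- igraph::as_data_frame(sub$A$graph$graph, "edges")
  eB <- igraph::as_data_frame(sub$B$graph$graph, "edges")
  expect_length(intersect(paste(eA$from, eA$to), paste(eB$from, eB$to)), 0L)
  # single group covers all network taxa
  md1 <- md; md1$site <- "only"
  sub1 <- subnetworks(cg, tab, md1, by = "site")
  expect_setequal(igraph::V(sub1$only$graph$graph)$name,
                  igraph::V(g)$name)
  expect_error(subnetworks(cg, tab, md, by = "nope"), "no metadata column")
})

test_that("export_network writes edge, node and GraphML files", {
  tab <- simulate_modular_network_data(2, 6, 20, 0.9, seed = 3)
  cg <- correlation_graph(tab)
  mods <- detect_modules(cg, seed = 1)
  zp <- classify_roles(zi_pi(cg, mods))
  dir <- withr::local_tempdir()
  paths <- export_network(cg, zp, dir)
  expect_true(all(file.exists(paths)))
  ed <- utils::read.delim(paths[["edges"]])
  expect_true(all(c("source", "target", "rho", "p", "sign") %in% names(ed)))
  expect_equal(nrow(ed), igraph::ecount(cg$graph))
})
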