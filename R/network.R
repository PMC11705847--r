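#' Thresholded Spearman co-occurrence network
#'
#' All-pairs Spearman correlations (mid-rank ties) on per-sample relative
#' abundances; an undirected edge is kept when `|rho| >= rho_min` and the
#' two-sided p-value (t approximation) is `< p_max`.  Correlations are
#' computed across all samples of the analyzed set; build one network per
#' community set and induce sub-networks with [subnetworks].
#'
#' @param x an [otu_table] with at least 8 samples.
#' @param rho_min minimum absolute Spearman correlation (default 0.6).
#' @param p_max maximum p-value, exclusive (default 0.01).
#' @param min_prevalence minimum fraction of samples in which a taxon must
#'   occur to enter the correlation screen (default 0, i.e. no screen).
#' @return object of class `correlation_graph`: list with `graph` (an
#'   [igraph::igraph] whose vertices carry `abundance` and whose edges carry
#'   `rho`, `p`, `sign`), `n_positive`, `n_negative`, and the thresholds.
#' @export
correlation_graph <- function(x, rho_min = 0.6, p_max = 0.01,
                              min_prevalence = 0) {
  if (n_samples(x) < 8)
    stop("need >= 8 samples for meaningful Spearman p-values")
  p <- rel_abund(x)
  prev <- rowMeans(x$counts > 0)
  p <- p[prev >= min_prevalence, , drop = FALSE]
  constant <- apply(p, 1, function(v) length(unique(v)) == 1L)
  if (any(constant)) {
    warning(sum(constant), " constant taxon vector(s) skipped")
    p <- p[!constant, , drop = FALSE]
  }
  n <- ncol(p)
  rk <- t(apply(p, 1, rank))
  rho <- stats::cor(t(rk))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pval[abs(rho) >= 1 - 1e-12] <- 0
  keep <- abs(rho) >= rho_min & pval < p_max
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(from = rownames(p)[idx[, 1]],
                      to = rownames(p)[idx[, 2]],
                      rho = rho[idx], p = pval[idx],
                      sign = ifelse(rho[idx] > 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = rownames(p),
                          abundance = rowSums(x$counts)[rownames(p)],
                          stringsAsFactors = FALSE))
  structure(list(graph = g,
                 n_positive = sum(edges$sign == "positive"),
                 n_negative = sum(edges$sign == "negative"),
                 rho_min = rho_min, p_max = p_max),
            class = "correlation_graph")
}

#' @export
print.correlation_graph <- function(x, ...) {
  cat("correlation_graph: ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges (", x$n_positive, " positive, ",
      x$n_negative, " negative); |rho| >= ", x$rho_min, ", p < ", x$p_max,
      "\n", sep = "")
  invisible(x)
}

#' Detect network modules by modularity maximization
#'
#' Louvain-style greedy modularity maximization on the unsigned graph
#' (edge sign is an attribute, not a weight, unless `weighted = TRUE`,
#' which uses `|rho|`).  Deterministic for a fixed seed.
#'
#' @param cg a [correlation_graph].
#' @param seed integer seed.
#' @param weighted use `|rho|` edge weights (default `FALSE`).
#' @return list of class `module_partition`: `membership` (named integer
#'   vector) and `Q` (modularity of the partition, unweighted).
#' @export
detect_modules <- function(cg, seed = 1L, weighted = FALSE) {
  g <- cg$graph
  if (igraph::ecount(g) == 0) stop("graph has no edges")
  w <- if (weighted) abs(igraph::E(g)$rho) else NULL
  set.seed(as.integer(seed))
  cl <- igraph::cluster_louvain(g, weights = w)
  memb <- igraph::membership(cl)
  structure(list(membership = memb,
                 Q = igraph::modularity(g, memb)),
            class = "module_partition")
}

#' Network- and node-level topology
#'
#' Network level: node and edge counts, average degree (2E/N), density
#' (2E/(N(N-1))), average local clustering coefficient (isolates count 0),
#' average shortest path on the largest connected component, and the
#' positive-edge fraction.  Node level: degree, betweenness, local
#' clustering.
#'
#' @param cg a [correlation_graph].
#' @param modules optional [detect_modules] result; if given, modularity is
#'   included in the network-level metrics.
#' @return list of class `topology_result` with `network` (named list) and
#'   `nodes` (data.frame).
#' @export
topology <- function(cg, modules = NULL) {
  g <- cg$graph
  nv <- igraph::vcount(g)
  ne <- igraph::ecount(g)
  comp <- igraph::components(g)
  big <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  cc_local <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  net <- list(
    n_nodes = nv,
    n_edges = ne,
    avg_degree = 2 * ne / nv,
    density = if (nv > 1) 2 * ne / (nv * (nv - 1)) else 0,
    avg_clustering = mean(cc_local),
    avg_path_length = if (igraph::vcount(big) > 1)
      igraph::mean_distance(big, directed = FALSE) else NA_real_,
    positive_edge_fraction = if (ne > 0) cg$n_positive / ne else NA_real_)
  if (!is.null(modules)) net$modularity <- modules$Q
  nodes <- data.frame(
    taxon = igraph::V(g)$name,
    degree = igraph::degree(g),
    betweenness = igraph::betweenness(g, directed = FALSE),
    clustering = cc_local,
    stringsAsFactors = FALSE)
  structure(list(network = net, nodes = nodes), class = "topology_result")
}

#' Within-module degree (Zi) and participation coefficient (Pi)
#'
#' `Zi = (k_is - mean_s) / sd_s` where `k_is` is node i's number of edges
#' into its own module s and mean/sd are taken over that module's members
#' (sample sd); `Pi = 1 - sum_t (k_it / k_i)^2` over all modules t.
#' A module with zero spread gives `Zi = 0`; an isolated node gives
#' `Pi = 0`.
#'
#' @param cg a [correlation_graph].
#' @param modules a [detect_modules] result (or named membership vector)
#'   covering every node.
#' @return data.frame with columns `taxon`, `module`, `degree`, `Zi`, `Pi`.
#' @export
zi_pi <- function(cg, modules) {
  g <- cg$graph
  memb <- if (inherits(modules, "module_partition")) modules$membership
          else modules
  nodes <- igraph::V(g)$name
  if (!all(nodes %in% names(memb)))
    stop("unassigned node(s): ",
         paste(utils::head(setdiff(nodes, names(memb)), 5), collapse = ", "))
  memb <- memb[nodes]
  mods <- sort(unique(memb))
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  A <- A[nodes, nodes]
  # k_it: edges from node i into module t
  kit <- vapply(mods, function(m) rowSums(A[, memb == m, drop = FALSE]),
                numeric(length(nodes)))
  if (length(nodes) == 1L) kit <- matrix(kit, nrow = 1)
  k <- rowSums(kit)
  own <- match(memb, mods)
  kis <- kit[cbind(seq_along(nodes), own)]
  zi <- numeric(length(nodes))
  for (m in seq_along(mods)) {
    idx <- which(own == m)
    mu <- mean(kis[idx])
    s <- stats::sd(kis[idx])
    zi[idx] <- if (is.na(s) || s == 0) 0 else (kis[idx] - mu) / s
  }
  pi <- ifelse(k == 0, 0, 1 - rowSums((kit / pmax(k, 1))^2))
  data.frame(taxon = nodes, module = memb, degree = k, Zi = zi, Pi = pi,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify node roles from Zi and Pi
#'
#' Exact threshold rules: network hubs `Zi > 2.5 & Pi > 0.62`; module hubs
#' `Zi > 2.5 & Pi <= 0.62`; connectors `Zi <= 2.5 & Pi > 0.62`; peripherals
#' otherwise.  Boundary values (`Zi = 2.5`, `Pi = 0.62`) therefore fall to
#' the connector/peripheral side.
#'
#' @param zipi data.frame from [zi_pi], or a list/data.frame with `Zi` and
#'   `Pi` columns.
#' @return the input data.frame with a `role` factor column added (levels
#'   `peripheral`, `connector`, `module_hub`, `network_hub`).
#' @export
classify_roles <- function(zipi) {
  zi <- zipi$Zi
  pi <- zipi$Pi
  if (any(!is.finite(zi)) || any(!is.finite(pi)))
    stop("Zi and Pi must be finite")
  role <- ifelse(zi > 2.5,
                 ifelse(pi > 0.62, "network_hub", "module_hub"),
                 ifelse(pi > 0.62, "connector", "peripheral"))
  zipi$role <- factor(role, levels = c("peripheral", "connector",
                                       "module_hub", "network_hub"))
  zipi
}

#' Induced per-group sub-networks
#'
#' For each level of a metadata grouping, induce the subgraph on the taxa
#' present (count > 0) in at least one sample of that group and recompute
#' topology.  Edges are inherited, never re-thresholded.
#'
#' @param cg a [correlation_graph] built on the full table.
#' @param x the [otu_table] the graph was built from.
#' @param metadata data.frame with `sample_id` and the grouping column.
#' @param by name of the grouping column.
#' @return named list, one element per group: list with `graph` (a
#'   `correlation_graph`) and `topology`.
#' @export
subnetworks <- function(cg, x, metadata, by) {
  if (!by %in% names(metadata)) stop("no metadata column '", by, "'")
  metadata <- validate_metadata(x, metadata)
  out <- list()
  for (lev in unique(metadata[[by]])) {
    samp <- metadata$sample_id[metadata[[by]] == lev]
    present <- rownames(x$counts)[
      rowSums(x$counts[, samp, drop = FALSE] > 0) > 0]
    vids <- intersect(igraph::V(cg$graph)$name, present)
    if (length(vids) == 0) {
      warning("group '", lev, "' has no taxa in the network")
      out[[as.character(lev)]] <- NULL
      next
    }
    sub <- igraph::induced_subgraph(cg$graph, vids)
    ne <- igraph::ecount(sub)
    npos <- if (ne > 0) sum(igraph::E(sub)$sign == "positive") else 0L
    scg <- structure(list(graph = sub, n_positive = npos,
                          n_negative = ne - npos,
                          rho_min = cg$rho_min, p_max = cg$p_max),
                     class = "correlation_graph")
    out[[as.character(lev)]] <- list(graph = scg, topology = topology(scg))
  }
  out
}

#' Export a network for Gephi and tabular inspection
#'
#' Writes an edge-list TSV (`source`, `target`, `rho`, `p`, `sign`), a node
#' table TSV (`taxon`, `module`, `degree`, `Zi`, `Pi`, `role`), and a
#' GraphML file readable by Gephi.
#'
#' @param cg a [correlation_graph].
#' @param node_table data.frame from [classify_roles] (or [zi_pi]).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"network"`).
#' @return invisibly, the written paths.
#' @export
export_network <- function(cg, node_table, dir, prefix = "network") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ed <- igraph::as_data_frame(cg$graph, what = "edges")
  names(ed)[1:2] <- c("source", "target")
  edge_path <- file.path(dir, paste0(prefix, "_edges.tsv"))
  node_path <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  gml_path <- file.path(dir, paste0(prefix, ".graphml"))
  utils::write.table(ed, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(node_table, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- cg$graph
  if (!is.null(node_table$role)) {
    idx <- match(igraph::V(g)$name, node_table$taxon)
    igraph::V(g)$role <- as.character(node_table$role)[idx]
    igraph::V(g)$module <- node_table$module[idx]
  }
  igraph::write_graph(g, gml_path, format = "graphml")
  invisible(c(edges = edge_path, nodes = node_path, graphml = gml_path))
}
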