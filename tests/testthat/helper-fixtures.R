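# Small fixtures built in code at test time.

make_table <- function(m, taxa = NULL, samples = NULL) {
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(taxa, samples)
  otu_table(m)
}

random_table <- function(n_taxa, n_samples, seed = 1, lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples)
  m[1, ] <- m[1, ] + 1L   # guarantee no all-zero row
  make_table(m)
}

# correlation_graph wrapper around a hand-built igraph, for topology tests
graph_fixture <- function(g) {
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
  if (igraph::ecount(g) > 0) {
    if (is.null(igraph::E(g)$rho)) igraph::E(g)$rho <- 1
    if (is.null(igraph::E(g)$sign)) igraph::E(g)$sign <- "positive"
  }
  structure(list(graph = g,
                 n_positive = igraph::ecount(g), n_negative = 0,
                 rho_min = 0.6, p_max = 0.01),
            class = "correlation_graph")
}
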