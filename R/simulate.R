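#' Simulate a pure-birth (Yule) phylogeny
#'
#' Birth-only tree with exponential branch times, rescaled so every
#' root-to-tip path has length 1; tips are named `OTU_0001`, `OTU_0002`, ...
#' These trees supply the phylogenetic substrate for the null-model
#' machinery when no inferred tree is available.
#'
#' @param n_taxa number of tips (>= 3).
#' @param seed integer seed; the same seed yields an identical newick string.
#' @return an ultrametric [ape::phylo] with unit height.
#' @export
simulate_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 3) stop("n_taxa must be >= 3")
  set.seed(as.integer(seed))
  tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  h <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / h
  tr$tip.label <- sprintf("OTU_%04d", seq_len(n_taxa))
  tr
}

# Geometric-rank metacommunity: p_i proportional to decay^(i-1), normalized.
# Spans several orders of magnitude so occupancy runs from ~0 to 1.
.rank_abundances <- function(n_taxa, decay) {
  p <- decay^(seq_len(n_taxa) - 1)
  p / sum(p)
}

#' Simulate neutral Sloan-sampled communities
#'
#' The stationary form of the Sloan neutral model: metacommunity relative
#' abundances `p_i` follow a geometric rank curve; each sample's latent
#' composition is drawn component-wise from `Beta(Nm * p_i, Nm * (1 - p_i))`,
#' renormalized, and counts are drawn multinomially at `depth`.  Because this
#' is exactly the model [fit_ncm] fits, the fitted migration rate must
#' recover `m = Nm_true / depth`.
#'
#' @param n_taxa number of taxa.
#' @param n_samples number of local communities.
#' @param depth reads per sample.
#' @param Nm_true product of local community size and migration probability.
#' @param seed integer seed.
#' @param rank_decay geometric decay of the metacommunity rank curve
#'   (default 0.96).
#' @return list with `table` (an [otu_table]) and `meta_p` (the metacommunity
#'   relative abundances, named by taxon).
#' @export
simulate_neutral <- function(n_taxa, n_samples, depth, Nm_true, seed = 1L,
                             rank_decay = 0.96) {
  stopifnot(Nm_true > 0, n_taxa >= 2, n_samples >= 1, depth >= 1)
  set.seed(as.integer(seed))
  p <- .rank_abundances(n_taxa, rank_decay)
  if (any(p >= 1)) stop("degenerate metacommunity: some p_i >= 1")
  taxa <- sprintf("OTU_%04d", seq_len(n_taxa))
  counts <- matrix(0L, n_taxa, n_samples,
                   dimnames = list(taxa, sprintf("S%03d", seq_len(n_samples))))
  for (j in seq_len(n_samples)) {
    lat <- stats::rbeta(n_taxa, Nm_true * p, Nm_true * (1 - p))
    lat[!is.finite(lat)] <- 0
    if (sum(lat) <= 0) lat <- p
    counts[, j] <- stats::rmultinom(1, depth, lat / sum(lat))
  }
  list(table = suppressWarnings(otu_table(counts)),
       meta_p = stats::setNames(p, taxa))
}

#' Simulate selection along an environmental gradient
#'
#' Each taxon receives a niche optimum evolved on the tree by Brownian
#' motion (so optima are phylogenetically conserved), then linearly
#' standardized to mean-center of `env_range` and standard deviation a
#' quarter of its span.  Each sample sits at an environment value and the
#' expected abundance of taxon i in sample j is proportional to
#' `base_i * exp(-(env_j - opt_i)^2 / (2 * niche_sd^2))`, where `base_i` is
#' a geometric rank-abundance curve assigned to taxa in random order
#' (independent of the phylogeny) — real metacommunities are uneven, and
#' without this unevenness every taxon occurs in every sample and the
#' nearest-taxon null degenerates.  Each sample additionally applies a
#' lognormal abundance lottery (`sample_noise_sd`), so replicate samples
#' draw different members of the same niche-suitable, phylogenetically
#' clustered pool — the turnover that makes homogeneous selection visible
#' to nearest-taxon metrics.  Counts are multinomial at `depth`.
#' Samples at opposite ends of the gradient produce phylogenetically
#' divergent (beta-NTI > +2) pairs; replicates at one environment with
#' small `niche_sd` produce convergent (beta-NTI < -2) pairs; as
#' `niche_sd` grows the gradient washes out and pairs return to
#' `|beta-NTI| <= 2`.
#'
#' @param tree an [ape::phylo] whose tips name the taxa.
#' @param n_samples number of samples (ignored when `env` is given).
#' @param depth reads per sample.
#' @param niche_sd niche breadth (gradient units, > 0).
#' @param env_range interval of the gradient, default `c(-2, 2)`.
#' @param trait_rate Brownian-motion rate for the optima (default 1; the
#'   optima are re-standardized, so this only shapes relative placement).
#' @param seed integer seed.
#' @param env optional explicit per-sample environment values.
#' @param rank_decay geometric decay of the base rank-abundance curve
#'   (default 0.96).
#' @param sample_noise_sd standard deviation of the per-sample lognormal
#'   abundance lottery (default 1.5).
#' @return list with `table` (an [otu_table]), `metadata` (data.frame with
#'   `sample_id`, `site` = gradient half, `niche`, `env`) and `optima`.
#' @export
simulate_selection <- function(tree, n_samples, depth, niche_sd,
                               env_range = c(-2, 2), trait_rate = 1,
                               seed = 1L, env = NULL, rank_decay = 0.96,
                               sample_noise_sd = 1.5) {
  if (niche_sd <= 0) stop("niche_sd must be > 0")
  if (length(tree$tip.label) < 3) stop("tree must have >= 3 tips")
  set.seed(as.integer(seed))
  opt <- ape::rTraitCont(tree, model = "BM", sigma = sqrt(trait_rate))
  opt <- (opt - mean(opt)) / stats::sd(opt) *
    (diff(range(env_range)) / 4) + mean(env_range)
  if (is.null(env))
    env <- seq(env_range[1], env_range[2], length.out = n_samples)
  n_samples <- length(env)
  taxa <- tree$tip.label
  base <- sample(.rank_abundances(length(taxa), rank_decay))
  counts <- matrix(0L, length(taxa), n_samples,
                   dimnames = list(taxa, sprintf("S%03d", seq_len(n_samples))))
  for (j in seq_len(n_samples)) {
    w <- base * exp(-(env[j] - opt)^2 / (2 * niche_sd^2) +
                      sample_noise_sd * stats::rnorm(length(taxa)))
    if (sum(w) <= 0) w <- rep(1, length(w))
    counts[, j] <- stats::rmultinom(1, depth, w / sum(w))
  }
  md <- data.frame(sample_id = colnames(counts),
                   site = ifelse(env <= mean(env_range), "env_low", "env_high"),
                   niche = "simulated", env = env,
                   stringsAsFactors = FALSE)
  list(table = suppressWarnings(otu_table(counts)), metadata = md,
       optima = opt)
}

#' Simulate dispersal-limited, drifting communities
#'
#' Blocks of samples evolve independently by multiplicative log-normal drift
#' from a shared ancestral composition (no selection, no phylogenetic
#' signal).  Strong drift makes between-block pairs more dissimilar than the
#' Raup-Crick null expects (RC_bray -> +1, dispersal limitation) while
#' within-block pairs stay more similar than expected (RC_bray -> -1,
#' homogenizing dispersal / drift).
#'
#' @param n_taxa number of taxa.
#' @param n_blocks number of isolated blocks (>= 2).
#' @param samples_per_block samples in each block.
#' @param depth reads per sample.
#' @param drift_strength standard deviation of the per-block log-abundance
#'   perturbation (> 0).
#' @param seed integer seed.
#' @param rank_decay geometric decay of the ancestral rank curve.
#' @param within_sd per-sample log-abundance jitter inside a block
#'   (default 0.05).
#' @return list with `table` and `metadata` (`site` = block label).
#' @export
simulate_dispersal_limited <- function(n_taxa, n_blocks, samples_per_block,
                                       depth, drift_strength, seed = 1L,
                                       rank_decay = 0.96, within_sd = 0.05) {
  if (n_blocks < 2) stop("n_blocks must be >= 2")
  if (drift_strength <= 0) stop("drift_strength must be > 0")
  set.seed(as.integer(seed))
  p0 <- log(.rank_abundances(n_taxa, rank_decay))
  n_samples <- n_blocks * samples_per_block
  taxa <- sprintf("OTU_%04d", seq_len(n_taxa))
  counts <- matrix(0L, n_taxa, n_samples,
                   dimnames = list(taxa, sprintf("S%03d", seq_len(n_samples))))
  block <- rep(sprintf("B%02d", seq_len(n_blocks)), each = samples_per_block)
  j <- 0L
  for (b in seq_len(n_blocks)) {
    lp_block <- p0 + drift_strength * stats::rnorm(n_taxa)
    for (s in seq_len(samples_per_block)) {
      j <- j + 1L
      lp <- lp_block + within_sd * stats::rnorm(n_taxa)
      w <- exp(lp - max(lp))
      counts[, j] <- stats::rmultinom(1, depth, w / sum(w))
    }
  }
  md <- data.frame(sample_id = colnames(counts), site = block,
                   niche = "simulated", stringsAsFactors = FALSE)
  list(table = suppressWarnings(otu_table(counts)), metadata = md)
}

#' Simulate block-correlated abundances for network tests
#'
#' Planted-partition generator: taxa inside a module share a latent Gaussian
#' factor giving pairwise correlation about `rho_within`; taxa in different
#' modules are independent.  Latent values are exponentiated and sampled
#' multinomially, so the module structure survives as monotone (Spearman)
#' co-occurrence.
#'
#' @param n_modules number of planted modules.
#' @param taxa_per_module taxa per module.
#' @param n_samples number of samples (>= 10).
#' @param rho_within latent within-module correlation in (0, 1); 0 is
#'   accepted and yields independent taxa.
#' @param seed integer seed.
#' @param depth reads per sample (default 10000).
#' @param latent_scale multiplier on the latent values before
#'   exponentiation (default 1).
#' @return an [otu_table]; attribute `module` gives the planted assignment.
#' @export
simulate_modular_network_data <- function(n_modules, taxa_per_module,
                                          n_samples, rho_within, seed = 1L,
                                          depth = 10000, latent_scale = 1) {
  if (rho_within < 0 || rho_within >= 1)
    stop("rho_within must be in [0, 1)")
  if (n_samples < 10) stop("n_samples must be >= 10")
  set.seed(as.integer(seed))
  n_taxa <- n_modules * taxa_per_module
  module <- rep(seq_len(n_modules), each = taxa_per_module)
  taxa <- sprintf("OTU_%04d", seq_len(n_taxa))
  counts <- matrix(0L, n_taxa, n_samples,
                   dimnames = list(taxa, sprintf("S%03d", seq_len(n_samples))))
  for (j in seq_len(n_samples)) {
    f <- stats::rnorm(n_modules)
    z <- sqrt(rho_within) * f[module] +
      sqrt(1 - rho_within) * stats::rnorm(n_taxa)
    w <- exp(latent_scale * z)
    counts[, j] <- stats::rmultinom(1, depth, w / sum(w))
  }
  out <- suppressWarnings(otu_table(counts))
  attr(out, "module") <- stats::setNames(module, taxa)
  out
}
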