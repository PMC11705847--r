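# Fast beta-MNTD machinery.
#
# Given a weight matrix F (samples x taxa; relative abundances within each
# sample, or 1/richness for unweighted) and a taxon distance matrix d,
# beta-MNTD between communities k and l is
#   0.5 * [ sum_{i in k} f_ik * min_{j in l} d(i,j)
#         + sum_{j in l} f_jl * min_{i in k} d(j,i) ].
# MIND[i, l] = min distance from taxon i to any taxon present in sample l;
# then the matrix of "one-sided" sums is F %*% MIND and beta-MNTD is its
# symmetrization.  Taxa shared by both communities contribute 0 because
# d(i, i) = 0.
.bmntd_from <- function(Fw, pres, d) {
  S <- nrow(Fw)
  Tn <- ncol(Fw)
  MIND <- matrix(0, Tn, S)
  for (l in seq_len(S)) {
    idx <- which(pres[l, ])
    m <- d[, idx[1]]
    for (c in idx[-1]) m <- pmin.int(m, d[, c])
    MIND[, l] <- m
  }
  M1 <- Fw %*% MIND
  B <- (M1 + t(M1)) / 2
  dimnames(B) <- list(rownames(Fw), rownames(Fw))
  diag(B) <- 0
  B
}

.comm_weights <- function(x, weighted) {
  counts <- t(x$counts)              # samples x taxa
  pres <- counts > 0
  if (any(rowSums(pres) == 0)) stop("empty community")
  Fw <- if (weighted) counts / rowSums(counts) else pres / rowSums(pres)
  list(Fw = Fw, pres = pres)
}

#' Beta mean nearest taxon distance (beta-MNTD)
#'
#' Average phylogenetic distance between each taxon in one community and its
#' nearest relative in the other, weighted by relative abundance within each
#' community (or by 1/richness when `weighted = FALSE`), symmetrized over
#' the two directions.  Taxa shared by both communities contribute nearest
#' distance 0.
#'
#' @param x an [otu_table].
#' @param phylo_dist taxon distance matrix covering (a superset of) the
#'   table's taxa, e.g. from [cophenetic_dist].
#' @param weighted abundance-weighted (default) or presence-based.
#' @return square symmetric samples x samples matrix with zero diagonal.
#' @export
bmntd <- function(x, phylo_dist, weighted = TRUE) {
  taxa <- rownames(x$counts)
  missing <- setdiff(taxa, rownames(phylo_dist))
  if (length(missing))
    stop("taxa absent from the distance matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  d <- phylo_dist[taxa, taxa]
  cw <- .comm_weights(x, weighted)
  .bmntd_from(cw$Fw, cw$pres, d)
}

#' Beta nearest taxon index (beta-NTI)
#'
#' Standardized deviation of observed beta-MNTD from a null built by
#' shuffling taxon labels across the tips of the (pruned) tree:
#' `betaNTI = (bMNTD_obs - mean(bMNTD_null)) / sd(bMNTD_null)` per community
#' pair.  `|betaNTI| > 2` signals selection (+2 heterogeneous, -2
#' homogeneous).  A pair whose null has zero spread (e.g. a perfectly
#' symmetric star tree) is reported `NA` with a warning.
#'
#' @param x an [otu_table].
#' @param tree an [ape::phylo] containing the table's taxa as tips.
#' @param n_null number of tip-shuffle randomizations (default 999; >= 100
#'   recommended for a stable null sd).
#' @param seed integer seed.
#' @param weighted abundance-weighted beta-MNTD (default `TRUE`).
#' @return object of class `bnti_result`: `bnti`, `obs`, `null_mean`,
#'   `null_sd` (samples x samples matrices), `n_null`, `seed`.
#' @export
bnti <- function(x, tree, n_null = 999, seed = 1L, weighted = TRUE) {
  if (n_null < 2) stop("n_null must be >= 2")
  d <- cophenetic_dist(tree, rownames(x$counts))
  cw <- .comm_weights(x, weighted)
  obs <- .bmntd_from(cw$Fw, cw$pres, d)
  Tn <- nrow(d)
  set.seed(as.integer(seed))
  ssum <- ssq <- matrix(0, nrow(obs), ncol(obs))
  for (b in seq_len(n_null)) {
    perm <- sample.int(Tn)
    nb <- .bmntd_from(cw$Fw, cw$pres, d[perm, perm])
    ssum <- ssum + nb
    ssq <- ssq + nb^2
  }
  null_mean <- ssum / n_null
  null_var <- pmax((ssq - n_null * null_mean^2) / (n_null - 1), 0)
  null_sd <- sqrt(null_var)
  bn <- (obs - null_mean) / null_sd
  zero <- null_sd < 1e-12
  diag(zero) <- FALSE
  if (any(zero)) {
    warning(sum(zero) / 2, " pair(s) with zero-variance null; beta-NTI NA")
    bn[zero] <- NA_real_
  }
  diag(bn) <- 0
  dimnames(bn) <- dimnames(obs)
  structure(list(bnti = bn, obs = obs, null_mean = null_mean,
                 null_sd = null_sd, n_null = n_null, seed = seed),
            class = "bnti_result")
}

# One Raup-Crick null table: each community keeps its observed richness
# (taxa drawn without replacement with probability proportional to regional
# occupancy) and its observed total reads (one read per drawn taxon, the
# remainder multinomial on regional relative abundance over the drawn taxa).
.rc_null_table <- function(rich, totals, occ, pi_reg) {
  Tn <- length(occ)
  S <- length(rich)
  m <- matrix(0, S, Tn)
  for (s in seq_len(S)) {
    drawn <- sample.int(Tn, rich[s], prob = occ)
    fill <- if (totals[s] > rich[s])
      stats::rmultinom(1, totals[s] - rich[s], pi_reg[drawn])[, 1]
    else rep(0, rich[s])
    m[s, drawn] <- 1 + fill
  }
  m
}

#' Raup-Crick metric on Bray-Curtis dissimilarities (RC_bray)
#'
#' Compares observed Bray-Curtis dissimilarity against a null in which each
#' community is reassembled from the regional pool: observed richness drawn
#' with probability proportional to regional occupancy, abundance filled to
#' the observed total with probability proportional to regional relative
#' abundance.  `RC = ((#null < obs + 0.5 * #null = obs) / n_null - 0.5) * 2`,
#' bounded in `[-1, 1]`; values > +0.95 indicate dispersal limitation,
#' < -0.95 homogenizing dispersal.
#'
#' @param x an [otu_table] with >= 2 samples.
#' @param n_null randomizations (default 999).
#' @param seed integer seed.
#' @return object of class `rc_result`: `rc` (samples x samples matrix),
#'   `obs` (Bray-Curtis), `n_null`, `seed`.
#' @export
raup_crick_bray <- function(x, n_null = 999, seed = 1L) {
  if (n_samples(x) < 2) stop("need >= 2 samples")
  counts <- t(x$counts)                      # samples x taxa
  obs <- as.matrix(vegan::vegdist(counts, method = "bray"))
  rich <- rowSums(counts > 0)
  totals <- rowSums(counts)
  occ <- colSums(counts > 0)
  pi_reg <- colSums(counts) / sum(counts)
  set.seed(as.integer(seed))
  less <- ties <- matrix(0, nrow(obs), ncol(obs))
  tol <- 1e-10
  for (b in seq_len(n_null)) {
    nullbc <- as.matrix(vegan::vegdist(
      .rc_null_table(rich, totals, occ, pi_reg), method = "bray"))
    less <- less + (nullbc < obs - tol)
    ties <- ties + (abs(nullbc - obs) <= tol)
  }
  rc <- ((less + 0.5 * ties) / n_null - 0.5) * 2
  diag(rc) <- 0
  dimnames(rc) <- dimnames(obs)
  structure(list(rc = rc, obs = obs, n_null = n_null, seed = seed),
            class = "rc_result")
}

#' Classify assembly processes from beta-NTI and RC_bray
#'
#' Per community pair: `betaNTI > +2` is heterogeneous selection (HeS);
#' `betaNTI < -2` homogeneous selection (HoS); otherwise `RC > +0.95` is
#' dispersal limitation (DL), `RC < -0.95` homogenizing dispersal (HD) and
#' `|RC| <= 0.95` ecological drift (DR).  Boundary values (exactly +-2,
#' exactly +-0.95) fall to the non-selection / drift side, per the strict
#' inequalities.
#'
#' @param bnti beta-NTI matrix (or [bnti] result).
#' @param rc RC_bray matrix (or [raup_crick_bray] result) on the same
#'   samples.
#' @param groups optional per-sample labels; fractions are then also
#'   reported for within-group pairs of each group.
#' @return object of class `assembly_result`: `pairs` (data.frame with
#'   `sample_a`, `sample_b`, `bnti`, `rc`, `process`), `fractions` (named,
#'   sums to 1 over classified pairs), `by_group` (optional), `n_excluded`
#'   (pairs with missing beta-NTI).
#' @export
classify_processes <- function(bnti, rc, groups = NULL) {
  if (inherits(bnti, "bnti_result")) bnti <- bnti$bnti
  if (inherits(rc, "rc_result")) rc <- rc$rc
  if (!identical(dim(bnti), dim(rc)))
    stop("beta-NTI and RC matrices must align")
  ids <- rownames(bnti)
  n <- nrow(bnti)
  idx <- which(upper.tri(bnti), arr.ind = TRUE)
  b <- bnti[idx]
  r <- rc[idx]
  proc <- ifelse(b > 2, "HeS",
                 ifelse(b < -2, "HoS",
                        ifelse(r > 0.95, "DL",
                               ifelse(r < -0.95, "HD", "DR"))))
  proc[is.na(b)] <- NA
  levels5 <- c("HeS", "HoS", "DL", "HD", "DR")
  pairs <- data.frame(sample_a = ids[idx[, 1]], sample_b = ids[idx[, 2]],
                      bnti = b, rc = r,
                      process = factor(proc, levels = levels5),
                      stringsAsFactors = FALSE)
  frac <- function(pr) {
    tab <- table(factor(pr[!is.na(pr)], levels = levels5))
    if (sum(tab) == 0) tab * NA_real_ else tab / sum(tab)
  }
  by_group <- NULL
  if (!is.null(groups)) {
    groups <- stats::setNames(as.character(groups), ids)
    ga <- groups[pairs$sample_a]
    gb <- groups[pairs$sample_b]
    by_group <- lapply(stats::setNames(nm = unique(groups)), function(g)
      frac(pairs$process[ga == g & gb == g]))
  }
  structure(list(pairs = pairs, fractions = frac(pairs$process),
                 by_group = by_group,
                 n_excluded = sum(is.na(pairs$process))),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat("Assembly processes over", nrow(x$pairs), "community pairs",
      if (x$n_excluded) paste0("(", x$n_excluded, " excluded)"), "\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Phylogenetic normalized stochasticity ratio (pNST)
#'
#' Stochasticity ratio with beta-MNTD as the dissimilarity and the same
#' tip-shuffle null as [bnti].  Observed and null dissimilarities are first
#' scaled to [0, 1] by their global maximum; per pair, with `D` observed and
#' `E` the null mean, the normalized ratio is `D/E` when `D <= E`
#' (divergence below expectation = homogenizing selection side) and
#' `(1-D)/(1-E)` when `D > E`, clamped to [0, 1] — 1 means fully
#' stochastic (observed equals the null expectation), 0 fully
#' deterministic.  Group pNST is the mean over within-group pairs; two
#' groups are compared with the Wilcoxon rank-sum test on their per-pair
#' values.
#'
#' @param x an [otu_table].
#' @param tree an [ape::phylo] covering the table's taxa.
#' @param groups per-sample labels; each group needs >= 3 samples.
#' @param n_null randomizations (default 999).
#' @param seed integer seed.
#' @param weighted abundance-weighted beta-MNTD (default `TRUE`).
#' @return object of class `nst_result`: `pnst` (named per-group values in
#'   [0, 1]), `pairs` (per-pair ratios with group), `comparison` (Wilcoxon,
#'   when exactly 2 groups), `metric`, `variant`, `n_null`, `seed`.
#' @export
pnst <- function(x, tree, groups, n_null = 999, seed = 1L, weighted = TRUE) {
  groups <- as.factor(groups)
  if (length(groups) != n_samples(x)) stop("groups length must match samples")
  sizes <- table(groups)
  if (any(sizes < 3))
    stop("group(s) with < 3 samples: ",
         paste(names(sizes)[sizes < 3], collapse = ", "))
  d <- cophenetic_dist(tree, rownames(x$counts))
  cw <- .comm_weights(x, weighted)
  obs <- .bmntd_from(cw$Fw, cw$pres, d)
  Tn <- nrow(d)
  set.seed(as.integer(seed))
  ssum <- matrix(0, nrow(obs), ncol(obs))
  gmax <- max(obs)
  for (b in seq_len(n_null)) {
    perm <- sample.int(Tn)
    nb <- .bmntd_from(cw$Fw, cw$pres, d[perm, perm])
    ssum <- ssum + nb
    gmax <- max(gmax, max(nb))
  }
  if (gmax <= 0) stop("degenerate dissimilarities: all zero")
  Dn <- obs / gmax
  En <- (ssum / n_null) / gmax
  idx <- which(upper.tri(obs), arr.ind = TRUE)
  ids <- rownames(obs)
  st <- numeric(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    D <- Dn[idx[k, 1], idx[k, 2]]
    E <- En[idx[k, 1], idx[k, 2]]
    st[k] <- if (D <= E) {
      if (E <= 0) 1 else D / E
    } else {
      if (E >= 1) 1 else (1 - D) / (1 - E)
    }
  }
  st <- pmin(pmax(st, 0), 1)
  ga <- groups[match(ids[idx[, 1]], sample_ids(x))]
  gb <- groups[match(ids[idx[, 2]], sample_ids(x))]
  pairs <- data.frame(sample_a = ids[idx[, 1]], sample_b = ids[idx[, 2]],
                      st = st,
                      group = ifelse(as.character(ga) == as.character(gb),
                                     as.character(ga), NA),
                      stringsAsFactors = FALSE)
  pergroup <- vapply(levels(groups), function(g)
    mean(pairs$st[!is.na(pairs$group) & pairs$group == g]), numeric(1))
  comparison <- NULL
  if (nlevels(groups) == 2) {
    a <- pairs$st[!is.na(pairs$group) & pairs$group == levels(groups)[1]]
    b2 <- pairs$st[!is.na(pairs$group) & pairs$group == levels(groups)[2]]
    w <- suppressWarnings(stats::wilcox.test(a, b2, exact = FALSE))
    comparison <- list(statistic = unname(w$statistic), p_value = w$p.value)
  }
  structure(list(pnst = pergroup, pairs = pairs, comparison = comparison,
                 metric = "betaMNTD",
                 variant = "per-pair normalized (MST-type) ratio, max-scaled",
                 n_null = n_null, seed = seed),
            class = "nst_result")
}

#' @export
print.nst_result <- function(x, ...) {
  cat("pNST (", x$metric, ", ", x$n_null, " randomizations; ",
      x$variant, ")\n", sep = "")
  print(round(x$pnst, 4))
  if (!is.null(x$comparison))
    cat("Wilcoxon between groups: p =", format.pval(x$comparison$p_value),
        "\n")
  invisible(x)
}
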