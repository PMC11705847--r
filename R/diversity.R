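#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` over positive entries, natural log (the
#' convention of the vegan toolchain).
#'
#' @param counts non-negative numeric vector with at least one positive
#'   entry.
#' @return the Shannon index.
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  if (sum(counts) <= 0) stop("all-zero vector")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Per-sample alpha diversity
#'
#' @param x an [otu_table].
#' @return named numeric vector of Shannon indices, one per sample.
#' @export
alpha_diversity <- function(x) {
  apply(x$counts, 2, shannon)
}

#' Robust Aitchison (rclr) distance matrix
#'
#' Per sample, the robust centered log-ratio is taken over nonzero counts
#' only: `r_ik = log(x_ik) - mean(log(x_ik'))` over the sample's nonzero
#' taxa, with zeros treated as missing.  The distance between two samples is
#' the Euclidean distance of their rclr vectors over the taxa nonzero in
#' both, rescaled by `sqrt(n_taxa_total / n_shared)` to correct for varying
#' overlap size.  The result is scale-invariant: multiplying all counts of a
#' sample by a constant leaves every distance unchanged.
#'
#' This is deliberately the deterministic shared-support estimator, not the
#' matrix-completion (RPCA) one.
#'
#' @param x an [otu_table]; every sample must have at least 2 nonzero taxa.
#' @return square symmetric distance matrix; a pair of samples sharing fewer
#'   than 2 taxa gets `NA` with a warning.
#' @export
rclr_aitchison_dist <- function(x) {
  counts <- x$counts
  nz <- counts > 0
  if (any(colSums(nz) < 2))
    stop("every sample needs >= 2 nonzero taxa")
  lg <- log(counts)
  lg[!nz] <- NA_real_
  r <- sweep(lg, 2, colMeans(lg, na.rm = TRUE), "-")
  n <- ncol(counts)
  tot <- nrow(counts)
  d <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  undefined <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- nz[, i] & nz[, j]
      ns <- sum(shared)
      if (ns < 2L) {
        d[i, j] <- d[j, i] <- NA_real_
        undefined <- undefined + 1L
        next
      }
      diff <- r[shared, i] - r[shared, j]
      d[i, j] <- d[j, i] <- sqrt(sum(diff^2) * tot / ns)
    }
  }
  if (undefined > 0L)
    warning(undefined, " sample pair(s) share < 2 taxa; ",
            "distance undefined (NA)")
  d
}

#' Bray-Curtis dissimilarity matrix on relative abundances
#'
#' @param x an [otu_table].
#' @return square symmetric matrix in [0, 1].
#' @export
bray_curtis <- function(x) {
  as.matrix(vegan::vegdist(t(rel_abund(x)), method = "bray"))
}

#' Principal coordinates analysis (classical metric MDS)
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and scales eigenvectors by
#' the square root of their eigenvalues.  Negative eigenvalues are zeroed
#' and excluded from the variance denominator (recorded in the result).
#'
#' @param d square symmetric distance matrix.
#' @param k number of axes to return (>= 2).
#' @return list of class `pcoa_result`: `coordinates` (samples x k),
#'   `eigenvalues` (all, as computed), `proportion` (variance explained per
#'   returned axis, relative to the positive-eigenvalue total),
#'   `n_negative` (count of negative eigenvalues zeroed).
#' @export
pcoa <- function(d, k = 2) {
  stopifnot(k >= 2)
  d <- as.matrix(d)
  if (anyNA(d)) stop("distance matrix contains NA; drop undefined pairs first")
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (d^2) %*% J
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  pos <- e$values > sqrt(.Machine$double.eps) * max(abs(e$values))
  npos <- sum(pos)
  if (k > npos) {
    warning("only ", npos, " positive eigenvalues; returning ", npos, " axes")
    k <- npos
  }
  lam <- e$values[seq_len(k)]
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k, k)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(k))
  structure(list(coordinates = coords,
                 eigenvalues = e$values,
                 proportion = lam / sum(e$values[pos]),
                 n_negative = sum(e$values < 0)),
            class = "pcoa_result")
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Pseudo-F from Gower-centered distance sums of squares,
#' `F = (SS_between / (g - 1)) / (SS_within / (n - g))`, with a permutation
#' p-value `(1 + #(F_perm >= F_obs)) / (1 + n_perm)` under whole-sample
#' label permutation.
#'
#' @param d square symmetric distance matrix.
#' @param groups factor-like group labels, one per sample; every group needs
#'   at least 2 samples.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list of class `permanova_result` with `F`, `R2`, `p_value`,
#'   `n_permutations`, and the sums of squares.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  d <- as.matrix(d)
  if (anyNA(d)) stop("distance matrix contains NA")
  groups <- as.factor(groups)
  if (length(groups) != nrow(d)) stop("groups length must match samples")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need >= 2 groups")
  if (any(sizes < 2))
    stop("group(s) of size 1: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  D2 <- d^2
  n <- nrow(d)
  g <- nlevels(groups)
  ss_total <- sum(D2) / (2 * n)
  ss_within <- function(lab) {
    s <- 0
    for (lev in levels(groups)) {
      idx <- which(lab == lev)
      s <- s + sum(D2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  f_stat <- function(lab) {
    ssw <- ss_within(lab)
    ((ss_total - ssw) / (g - 1)) / (ssw / (n - g))
  }
  f_obs <- f_stat(groups)
  set.seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (f_stat(groups[sample.int(n)]) >= f_obs) exceed <- exceed + 1L
  }
  ssw_obs <- ss_within(groups)
  structure(list(F = f_obs,
                 R2 = (ss_total - ssw_obs) / ss_total,
                 p_value = (1 + exceed) / (1 + n_perm),
                 n_permutations = n_perm,
                 SS_total = ss_total, SS_between = ss_total - ssw_obs,
                 SS_within = ssw_obs),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA: pseudo-F = ", signif(x$F, 5),
      ", R2 = ", signif(x$R2, 4),
      ", p = ", format(x$p_value),
      " (", x$n_permutations, " permutations)\n", sep = "")
  invisible(x)
}

# Per-pair Bray-Curtis decomposition: contribution of each taxon to the
# dissimilarity between two relative-abundance profiles.  Sums to BC exactly.
.simper_pair <- function(p_i, p_j) {
  abs(p_i - p_j) / sum(p_i + p_j)
}

#' SIMPER: per-taxon contributions to between-group dissimilarity
#'
#' For each between-group sample pair, taxon k contributes
#' `|p_ik - p_jk| / sum_k(p_ik + p_jk)` of the pair's Bray-Curtis
#' dissimilarity (computed on relative abundances).  Contributions are
#' averaged over all between-group pairs and reported with percentage and
#' cumulative percentage, sorted descending.
#'
#' @param x an [otu_table].
#' @param groups labels, exactly 2 distinct values among the used samples.
#' @return data.frame of class `simper_result` with columns `taxon`,
#'   `mean_contrib`, `pct`, `cum_pct`; attribute `mean_dissimilarity` holds
#'   the average between-group Bray-Curtis.
#' @export
simper <- function(x, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("simper compares exactly 2 groups")
  if (length(groups) != n_samples(x)) stop("groups length must match samples")
  p <- rel_abund(x)
  ia <- which(groups == levels(groups)[1])
  ib <- which(groups == levels(groups)[2])
  acc <- numeric(nrow(p))
  npair <- 0L
  for (i in ia) for (j in ib) {
    acc <- acc + .simper_pair(p[, i], p[, j])
    npair <- npair + 1L
  }
  mean_contrib <- acc / npair
  ord <- order(mean_contrib, decreasing = TRUE)
  out <- data.frame(taxon = rownames(p)[ord],
                    mean_contrib = mean_contrib[ord],
                    pct = 100 * mean_contrib[ord] / sum(mean_contrib),
                    stringsAsFactors = FALSE)
  out$cum_pct <- cumsum(out$pct)
  attr(out, "mean_dissimilarity") <- sum(mean_contrib)
  class(out) <- c("simper_result", "data.frame")
  out
}

#' Levins niche breadth per taxon
#'
#' `B_j = 1 / sum_i(P_ij^2)` where `P_ij` is the proportion of taxon j's
#' total count found in sample i.  B ranges from 1 (found in a single
#' sample; habitat specialist) to the number of samples (spread evenly;
#' generalist).
#'
#' @param x an [otu_table].
#' @param groups optional sample labels; if given, the attribute
#'   `group_means` reports, per group, the mean breadth of the taxa present
#'   in that group's samples (the community-level niche-width comparison).
#' @return named numeric vector of breadths.
#' @export
levins_breadth <- function(x, groups = NULL) {
  P <- x$counts / rowSums(x$counts)
  B <- 1 / rowSums(P^2)
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    gm <- vapply(levels(groups), function(lev) {
      idx <- which(groups == lev)
      present <- rowSums(x$counts[, idx, drop = FALSE]) > 0
      mean(B[present])
    }, numeric(1))
    attr(B, "group_means") <- gm
  }
  B
}

.stars <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
                                   ifelse(p <= 0.05, "*", "ns")))
}

# Dunn's post hoc z-statistics on the joint mid-ranks, with tie correction.
.dunn_test <- function(values, groups, p_adjust = "bonferroni") {
  groups <- as.factor(groups)
  N <- length(values)
  rk <- rank(values)
  tie <- table(rk)
  tiecorr <- sum(tie^3 - tie) / (12 * (N - 1))
  v <- N * (N + 1) / 12 - tiecorr
  levs <- levels(groups)
  mean_rk <- tapply(rk, groups, mean)
  n_g <- tapply(rk, groups, length)
  pairs <- utils::combn(levs, 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    z[k] <- (mean_rk[[a]] - mean_rk[[b]]) /
      sqrt(v * (1 / n_g[[a]] + 1 / n_g[[b]]))
    p_raw[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  p_adj <- stats::p.adjust(p_raw, method = p_adjust)
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p_unadj = p_raw, p_adj = p_adj, stars = .stars(p_adj),
             stringsAsFactors = FALSE)
}

#' Nonparametric group comparison of a per-sample statistic
#'
#' Two groups: two-sided Wilcoxon rank-sum test.  Three or more groups:
#' Kruskal-Wallis test plus all pairwise Dunn post hoc z-tests with
#' multiplicity-adjusted p-values (Bonferroni by default).  Significance
#' stars follow the usual figure-legend convention
#' (`*` p <= 0.05, `**` p <= 0.01, `***` p <= 0.001).
#'
#' @param values numeric vector, one value per sample.
#' @param groups group labels.
#' @param design `"auto"` picks by the number of groups; `"two_group"` and
#'   `"multi_group"` enforce the expected design.
#' @param p_adjust adjustment method for Dunn's pairwise p-values
#'   (`"bonferroni"` default, `"BH"` available).
#' @return list of class `group_compare_result`: for two groups `statistic`,
#'   `p_value`, `stars`; for multi-group additionally `H` and `pairwise`
#'   (the Dunn table).
#' @export
group_compare <- function(values, groups,
                          design = c("auto", "two_group", "multi_group"),
                          p_adjust = "bonferroni") {
  design <- match.arg(design)
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("group(s) with < 2 observations: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  k <- nlevels(groups)
  if (design == "two_group" && k != 2) stop("two_group design needs 2 groups")
  if (design == "multi_group" && k < 3) stop("multi_group design needs >= 3")
  if (k == 2) {
    w <- suppressWarnings(
      stats::wilcox.test(values ~ groups, exact = FALSE, correct = TRUE))
    out <- list(design = "two_group", statistic = unname(w$statistic),
                p_value = w$p.value, stars = .stars(w$p.value))
  } else {
    kw <- stats::kruskal.test(values, groups)
    out <- list(design = "multi_group", H = unname(kw$statistic),
                p_value = kw$p.value, stars = .stars(kw$p.value),
                pairwise = .dunn_test(values, groups, p_adjust))
  }
  class(out) <- "group_compare_result"
  out
}

#' @export
print.group_compare_result <- function(x, ...) {
  if (x$design == "two_group") {
    cat("Wilcoxon rank-sum: W = ", x$statistic, ", p = ",
        format.pval(x$p_value), " ", x$stars, "\n", sep = "")
  } else {
    cat("Kruskal-Wallis: H = ", signif(x$H, 5), ", p = ",
        format.pval(x$p_value), " ", x$stars, "\n", sep = "")
    cat("Dunn post hoc (", nrow(x$pairwise), " pairs):\n", sep = "")
    print(x$pairwise, digits = 4)
  }
  invisible(x)
}
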