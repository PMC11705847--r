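# Sloan neutral community model: occurrence frequency vs mean relative
# abundance.  Predicted frequency of detection for a taxon with
# metacommunity relative abundance p, local community size N and migration
# probability m, at detection limit d:
#   F(p; m) = 1 - BetaCDF(d; N m p, N m (1 - p))
.ncm_predict <- function(p, m, N, d) {
  1 - stats::pbeta(d, N * m * p, N * m * (1 - p))
}

# 95% prediction band for an observed detection frequency at n samples:
# binomial quantiles of the predicted probability.  This is a band for the
# *observation* f = X/n given the fitted curve, not a CI for the curve.
.prediction_band <- function(pred, n, conf = 0.95) {
  a <- (1 - conf) / 2
  list(lower = stats::qbinom(a, n, pred) / n,
       upper = stats::qbinom(1 - a, n, pred) / n)
}

.ncm_core <- function(p, f, N, d) {
  sse <- function(m) {
    pred <- .ncm_predict(p, m, N, d)
    sum((f - pred)^2)
  }
  opt <- stats::optimize(sse, interval = c(1e-6, 1), tol = 1e-9)
  m_hat <- opt$minimum
  SSE <- opt$objective
  if (!is.finite(SSE)) stop("NCM fit failure: non-finite SSE at m = ", m_hat)
  SST <- sum((f - mean(f))^2)
  r2 <- if (SST > 0) 1 - SSE / SST else if (SSE < 1e-12) 0 else -Inf
  list(m = m_hat, SSE = SSE, R2 = r2)
}

#' Fit the Sloan neutral community model
#'
#' For each OTU, `p_i` is its mean relative abundance across samples and
#' `f_i` the fraction of samples where it is detected (count > 0).  With
#' `N` the mean sample depth and detection limit `d`, the model predicts
#' `F(p; m) = 1 - BetaCDF(d; N m p, N m (1 - p))`; the migration
#' probability `m` is estimated by least squares over `(1e-6, 1)` and the
#' goodness of fit is `R2 = 1 - SSE/SST` (which can be negative).  The 95%
#' prediction band around the fitted curve is the binomial quantile band of
#' the predicted detection probability at n = number of samples.
#'
#' The default detection limit is `d = log(2)/N` rather than the
#' conventional `1/N`: for count-sampled data, detection of a taxon with
#' latent frequency `pi` is binomial, `1 - (1 - pi)^N`, and the hard
#' threshold that best mimics that smooth curve is the frequency at which
#' detection probability is one half, `log(2)/N`.  With `1/N` the migration
#' estimate carries a systematic upward bias (about +30% at typical
#' depths); `log(2)/N` makes the estimator recover the generative
#' parameter.  Pass `detection_limit = 1/N` to reproduce the conventional
#' choice.
#'
#' @param x an [otu_table] with >= 10 samples and >= 20 OTUs.
#' @param detection_limit override for `d` (default `log(2)/N`).
#' @return object of class `ncm_fit`: `m`, `N`, `Nm`, `R2`, `d`, and `otus`,
#'   a data.frame with per-OTU `p`, `freq_obs`, `freq_pred`, `lower`,
#'   `upper`.
#' @export
fit_ncm <- function(x, detection_limit = NULL) {
  if (n_samples(x) < 10) stop("need >= 10 samples")
  if (n_taxa(x) < 20) stop("need >= 20 OTUs")
  counts <- x$counts
  N <- mean(colSums(counts))
  d <- if (is.null(detection_limit)) log(2) / N else detection_limit
  p <- rowMeans(rel_abund(x))
  f <- rowMeans(counts > 0)
  if (all(f == 1))
    warning("saturated occupancy: every OTU present in every sample")
  fit <- .ncm_core(p, f, N, d)
  if (fit$m < 2e-6 || fit$m > 1 - 1e-6)
    warning("fitted m at the boundary of (0, 1]: m = ", signif(fit$m, 4))
  pred <- .ncm_predict(p, fit$m, N, d)
  band <- .prediction_band(pred, n_samples(x))
  structure(list(m = fit$m, N = N, Nm = N * fit$m, R2 = fit$R2, d = d,
                 n_samples = n_samples(x),
                 otus = data.frame(taxon = rownames(counts), p = p,
                                   freq_obs = f, freq_pred = pred,
                                   lower = band$lower, upper = band$upper,
                                   stringsAsFactors = FALSE,
                                   row.names = NULL)),
            class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat("Sloan neutral community model fit\n")
  cat("  m  = ", signif(x$m, 4), "   Nm = ", signif(x$Nm, 5),
      "   N = ", signif(x$N, 6), "\n", sep = "")
  cat("  R2 = ", signif(x$R2, 4), "  (", nrow(x$otus), " OTUs, ",
      x$n_samples, " samples)\n", sep = "")
  if (!is.null(x$ci)) {
    cat("  95% bootstrap CI (", x$ci$reps, " reps): m in [",
        signif(x$ci$m[1], 4), ", ", signif(x$ci$m[2], 4), "], R2 in [",
        signif(x$ci$R2[1], 4), ", ", signif(x$ci$R2[2], 4), "]\n", sep = "")
  }
  invisible(x)
}

#' Bootstrap confidence intervals for the neutral-model fit
#'
#' OTUs are resampled with replacement `reps` times and the model refit;
#' 2.5/97.5 percentiles give 95% CIs for `m`, `Nm` and `R2`, and pointwise
#' CIs for the fitted frequency curve evaluated at the original `p_i`.
#'
#' @param x the [otu_table] the fit was made on.
#' @param reps bootstrap repetitions (default 1000).
#' @param seed integer seed.
#' @param fit optional existing [fit_ncm] result (refit otherwise).
#' @return the `ncm_fit` augmented with `ci` (list with `m`, `Nm`, `R2`,
#'   `reps`, `n_failed`) and per-OTU `curve_lower` / `curve_upper` columns.
#' @export
ncm_bootstrap <- function(x, reps = 1000, seed = 1L, fit = NULL) {
  if (is.null(fit)) fit <- fit_ncm(x)
  p <- fit$otus$p
  f <- fit$otus$freq_obs
  n_otu <- length(p)
  set.seed(as.integer(seed))
  m_b <- r2_b <- rep(NA_real_, reps)
  curves <- matrix(NA_real_, reps, n_otu)
  for (b in seq_len(reps)) {
    idx <- sample.int(n_otu, replace = TRUE)
    res <- tryCatch(.ncm_core(p[idx], f[idx], fit$N, fit$d),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$m)) next
    m_b[b] <- res$m
    r2_b[b] <- res$R2
    curves[b, ] <- .ncm_predict(p, res$m, fit$N, fit$d)
  }
  failed <- sum(is.na(m_b))
  if (failed > 0.1 * reps)
    stop("bootstrap failure: ", failed, " of ", reps, " refits failed")
  q <- function(v) stats::quantile(v, c(0.025, 0.975), na.rm = TRUE,
                                   names = FALSE)
  fit$ci <- list(m = q(m_b), Nm = q(fit$N * m_b), R2 = q(r2_b),
                 reps = reps, n_failed = failed)
  cl <- apply(curves, 2, function(v) q(v))
  fit$otus$curve_lower <- cl[1, ]
  fit$otus$curve_upper <- cl[2, ]
  fit
}

#' Partition OTUs against the neutral prediction band
#'
#' Labels each fitted OTU `above` when its observed frequency exceeds the
#' upper 95% band at its abundance, `below` when under the lower band, and
#' `within` otherwise; the three fractions sum to 1.
#'
#' @param fit an [fit_ncm] (optionally bootstrapped) result.
#' @return list of class `ncm_partition`: `labels` (factor per OTU),
#'   `counts`, `fractions`.
#' @export
ncm_partition <- function(fit) {
  o <- fit$otus
  tol <- 1e-9
  lab <- ifelse(o$freq_obs > o$upper + tol, "above",
                ifelse(o$freq_obs < o$lower - tol, "below", "within"))
  lab <- factor(lab, levels = c("above", "within", "below"))
  counts <- table(lab)
  structure(list(labels = stats::setNames(lab, o$taxon),
                 counts = counts,
                 fractions = counts / sum(counts)),
            class = "ncm_partition")
}
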