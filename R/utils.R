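# internal helpers

# Cluster-grouped sandwich covariance for a fitted glm (dispersion fixed
# at 1, as for binomial models).  A^{-1} B A^{-1} with A the Fisher
# information and B the outer product of cluster-summed scores; no
# small-sample correction (none is assumed by the 2-df Q statistic).
glm_cluster_vcov <- function(fit, cluster) {
  X <- stats::model.matrix(fit)
  mu <- stats::fitted(fit)
  eta <- fit$linear.predictors
  fam <- stats::family(fit)
  sc <- X * ((fit$y - mu) * fam$mu.eta(eta) / fam$variance(mu))
  cluster <- as.character(cluster)
  if (anyNA(cluster)) stop("cluster labels must be non-missing")
  meat <- crossprod(rowsum(sc, cluster))
  bread <- stats::summary.glm(fit)$cov.unscaled
  bread %*% meat %*% bread
}

chisq_p <- function(stat, df) stats::pchisq(stat, df, lower.tail = FALSE)

# replicate-indexed RNG streams: a deterministic vector of sub-seeds
replicate_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
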