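# Small fixtures shared across test files; everything is generated in
# code, seeded, and sized for speed.

tiny_config <- function(J = 10L, n_j = 10L, model = "random_intercept",
                        seed = 1L) {
  dgp_config(n_clusters = J, cluster_size = n_j, model = model,
             seed = seed)
}

tiny_dataset <- function(J = 10L, n_j = 10L,
                         model = "random_intercept", seed = 1L) {
  generate_dataset(tiny_config(J, n_j, model, seed))
}

# one-way ANOVA estimate of a variable's intraclass correlation
anova_icc <- function(v, cluster_id) {
  k <- mean(table(cluster_id))
  a <- stats::anova(stats::aov(v ~ factor(cluster_id)))
  msb <- a$`Mean Sq`[1]
  msw <- a$`Mean Sq`[2]
  (msb - msw) / (msb + (k - 1) * msw)
}

# hand-built lmm_fit for pooling tests
fake_fit <- function(estimates, ses, terms = paste0("b", seq_along(estimates)),
                     n = 100L) {
  structure(list(coefficients = data.frame(term = terms,
                                           estimate = estimates,
                                           se = ses),
                 converged = TRUE, n = n, n_clusters = 5L,
                 model = "random_intercept"),
            class = "lmm_fit")
}

# likelihood-ratio test p-value for dependence of a missingness
# indicator on the reference variable's bin index
mar_dependence_p <- function(miss_ind, ref, n_bins = 25L) {
  rng <- range(ref)
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(ref, brk, rightmost.closed = TRUE, all.inside = TRUE)
  full <- stats::glm(miss_ind ~ factor(bin), family = stats::binomial())
  null <- stats::glm(miss_ind ~ 1, family = stats::binomial())
  stats::anova(null, full, test = "LRT")$`Pr(>Chi)`[2]
}

# override only the tree count so a method's own pmm_k survives the merge
fast_forest_opts <- list(forest = list(n_trees = 50L))
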