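# Shared fixtures built in code.

# canonical rebinding model: the published R/T partitioning for Hb 1 without
# ATP at 25 C, pH 7.4, 1 atm CO, with the documented geminate assumptions
hb1_model <- function(CO_atm = 1) {
  CO_M <- co_concentration(CO_atm, 298.15)
  hb_rebinding_model(
    geminate = data.frame(amplitude = c(0.04, 0.04),
                          tau_s = c(1e-7, 1e-6), beta = c(0.8, 0.8)),
    A_R = 0.92 * 0.84, k_R = 9.4e5 * CO_M,
    A_T = 0.92 * 0.16, k_T = 2.4e5 * CO_M)
}

# brute-force unmixing oracle: exhaustive grid search over coefficient space
# with the offset profiled out analytically for each candidate, refined once
# around the coarse optimum. Independent of the NNLS path used by unmix().
grid_search_unmix <- function(spectrum, basis, coarse = 0.05, fine = 2e-3,
                              upper = 1.5) {
  B <- vapply(basis$references, function(s) s$absorbances,
              numeric(length(basis$grid)))
  y <- spectrum$absorbances
  Bc <- sweep(B, 2, colMeans(B))
  yc <- y - mean(y)
  k <- ncol(B)
  search <- function(lo, hi, step) {
    axes <- lapply(seq_len(k), function(i)
      seq(max(lo[i], 0), min(hi[i], upper), by = step))
    Cc <- as.matrix(expand.grid(axes))
    E <- matrix(yc, nrow = length(yc), ncol = nrow(Cc)) - Bc %*% t(Cc)
    rss <- colSums(E^2)
    Cc[which.min(rss), ]
  }
  c1 <- search(rep(0, k), rep(upper, k), coarse)
  c2 <- search(c1 - coarse, c1 + coarse, fine)
  offset <- mean(y) - sum(colMeans(B) * c2)
  list(coefficients = setNames(as.numeric(c2), names(basis$references)),
       offset = offset)
}

# deterministic parameter draws for property-style tests
random_rebinding_models <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    hb_rebinding_model(
      geminate = data.frame(amplitude = runif(2, 0.01, 0.1),
                            tau_s = 10^runif(2, -8, -5),
                            beta = runif(2, 0.4, 1)),
      A_R = runif(1, 0.2, 0.9), k_R = 10^runif(1, 3, 5),
      A_T = runif(1, 0.05, 0.4), k_T = 10^runif(1, 0.5, 2.5))
  })
}
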