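# simulate from the latent model: scores drawn, indicators = loading *
# latent + noise, endogenous score = g1 * C1 + g2 * C2 + residual
simulate_latent_data <- function(n, g1 = 0.6, g2 = 0.3, loading = 0.95,
                                 rho_exo = 0.3, seed = 1) {
  set.seed(seed)
  c1 <- rnorm(n)
  c2 <- rho_exo * c1 + sqrt(1 - rho_exo^2) * rnorm(n)
  var_structural <- g1^2 + g2^2 + 2 * g1 * g2 * rho_exo
  d <- g1 * c1 + g2 * c2 + rnorm(n, sd = sqrt(max(0.05, 1 - var_structural)))
  ind <- function(lat, k) sapply(seq_len(k), function(i)
    loading * lat + sqrt(1 - loading^2) * rnorm(n))
  X <- cbind(ind(d, 2), ind(c1, 2), ind(c2, 2))
  colnames(X) <- c("d1", "d2", "x1", "x2", "y1", "y2")
  as.data.frame(X)
}

latent_spec <- function() {
  pls_spec(blocks = list(D = c("d1", "d2"), C1 = c("x1", "x2"),
                         C2 = c("y1", "y2")),
           paths = data.frame(from = c("C1", "C2"), to = c("D", "D")))
}
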