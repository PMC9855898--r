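# shared fixture builders (all data generated in code)

# two-class Gaussian matrix: p_info columns shifted by `effect` (in
# within-class sd units) between classes, the rest pure noise
two_class_matrix <- function(n1, n2, p, p_info = 0, effect = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm((n1 + n2) * p), n1 + n2, p)
  labels <- rep(c("A", "B"), c(n1, n2))
  if (p_info > 0)
    X[labels == "A", seq_len(p_info)] <-
      X[labels == "A", seq_len(p_info)] + effect
  list(X = X, labels = labels)
}

# tiny spectra_set on an ascending-input grid
toy_spectra <- function(n = 3, wn = c(1050, 1100, 1150, 1200, 1250),
                        seed = 1) {
  set.seed(seed)
  spectra_set(wn, matrix(rnorm(n * length(wn)), n),
              sample_ids = paste0("S", seq_len(n)))
}

# the ten discriminating band centers of the default generator
selected_centers <- function() {
  bl <- default_band_library()
  bl$center[bl$informative]
}

# data generated exactly from an A-component latent model (+ noise),
# returned with the latent dimension
latent_matrix <- function(n, p, A, noise_sd = 0, seed = 1) {
  set.seed(seed)
  T_ <- matrix(rnorm(n * A), n, A) %*% diag(seq(A, 1), A)
  P <- qr.Q(qr(matrix(rnorm(p * A), p, A)))
  T_ %*% t(P) + matrix(rnorm(n * p, 0, noise_sd), n, p)
}
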