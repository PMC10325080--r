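# Fixtures are built in code; nothing is read from disk except what a
# test itself writes to tempdir().

# complete cross-over grid with deterministic (seeded) responses
make_grid_df <- function(I = 2, H = 2, K = 4, J = 2, t = seq_len(K) - 1,
                         seed = 42) {
  set.seed(seed)
  df <- expand.grid(time = t,
                    treatment = LETTERS[seq_len(H)],
                    subject = sprintf("s%02d", seq_len(I)),
                    stringsAsFactors = FALSE)[, 3:1]
  for (j in seq_len(J))
    df[[sprintf("met%02d", j)]] <- rnorm(nrow(df), mean = 10)
  df
}

make_ld <- function(...) {
  long_dataset(make_grid_df(...), "subject", "treatment", "time")
}

# small, fast simulation spec: I subjects, quadratic model, modest noise
small_spec <- function(I = 8, J = 3, sigma_eps = 0.3,
                       D_scale = 1) {
  sdv <- c(0.5, 0.05, 0.01, 0.03, 0.005) * D_scale
  corr <- matrix(0.2, 5, 5); diag(corr) <- 1
  beta <- cbind(rep(5, J),
                seq(0.2, 0.6, length.out = J),
                seq(-0.05, 0.02, length.out = J),
                seq(-0.2, 0.2, length.out = J),
                seq(0.02, -0.02, length.out = J))
  simulation_spec(I = I, H = 2, K = 6, J = J, t = 0:5,
                  beta_tilde = beta, D_tilde = outer(sdv, sdv) * corr,
                  sigma_eps = sigma_eps)
}

quad_basis <- function() time_basis("polynomial", 2)
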