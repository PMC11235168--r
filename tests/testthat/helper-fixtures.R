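# randomized but valid dual-equilibration measurements built from known
# truth via the forward model
random_measurements <- function(n, noise_sd = 0) {
  true_ne <- stats::runif(n, -250, 50)
  true_xe <- stats::runif(n, 0, 0.95)
  tibble::tibble(
    sample_id = sprintf("r%05d", seq_len(n)),
    true_ne = true_ne, true_xe = true_xe,
    delta_e1 = forward_equilibrate(true_ne, true_xe, -160) +
      stats::rnorm(n, 0, noise_sd),
    delta_e2 = forward_equilibrate(true_ne, true_xe, -428) +
      stats::rnorm(n, 0, noise_sd),
    delta_w1 = -160, delta_w2 = -428, alpha_ew = 1.082)
}

# independent oracle for the carbon-bound hydrogen count: build the
# molecular graph of an unbranched saturated alkane explicitly (carbons in
# a chain, valence 4) and count the hydrogens needed to saturate it
alkane_h_by_graph <- function(n_carbons) {
  degree <- rep(2, n_carbons)
  degree[c(1, n_carbons)] <- 1
  if (n_carbons == 1) degree <- 0
  sum(4 - degree)
}
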