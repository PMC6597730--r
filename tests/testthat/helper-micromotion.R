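# Independent O(N^2) pairwise MSD oracle: explicit double loop over all
# (start, start + lag) pairs. Defines the semantics the fast estimator must
# reproduce bit for bit.
msd_brute <- function(x, y, dt, k_max) {
  n <- length(x)
  msd <- numeric(k_max)
  for (k in seq_len(k_max)) {
    sq <- numeric(n - k)
    for (s in seq_len(n - k)) {
      dx <- x[s + k] - x[s]
      dy <- y[s + k] - y[s]
      sq[s] <- dx * dx + dy * dy
    }
    msd[k] <- mean(sq)
  }
  tibble::tibble(
    lag_s = seq_len(k_max) * dt,
    msd_um2 = msd,
    n_pairs = n - seq_len(k_max)
  )
}

# reference sphere: 1.00 um radius at 24 C in a water-like solvent
ref_thermal <- function() thermal_params()

ref_motion <- function() {
  tp <- ref_thermal()
  d_r <- rotational_diffusion(tp)
  list(
    D_t = translational_diffusion(tp),
    D_r = d_r,
    tau_r = rotational_time(d_r)
  )
}
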