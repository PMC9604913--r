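# Shared helpers: the analytic fixture battery and a per-pixel loop
# comparison of the vectorized SIFT image against the reference descriptor.

fixture_battery <- function() analytic_fixtures()

# Max elementwise difference between compute_sift_image() and looping
# descriptor_at() over every pixel of img.
sift_loop_gap <- function(img, cfg = dense_sift_config()) {
  S <- compute_sift_image(img, cfg)
  mx <- 0
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      mx <- max(mx, max(abs(S[r, c, ] - descriptor_at(img, r, c, cfg))))
    }
  }
  mx
}

# 3-standard-error binomial band around p for n draws.
binom_band <- function(p, n, k = 3) {
  se <- sqrt(p * (1 - p) / n)
  c(p - k * se, p + k * se)
}
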