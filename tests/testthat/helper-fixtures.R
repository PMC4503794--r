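# Shared fixtures: small phantom, canonical voxel, Rician noise helper.

tiny_phantom <- function(shape = c(16L, 16L, 8L), snr = 100) {
  build_phantom(phantom_spec(shape = shape, snr = snr))
}

canonical_voxel <- function() {
  two_pool_params(m0 = 1000, f = 0.12, kf = 3.0, t1f = 1.05, t2f = 0.07)
}

add_rician <- function(s, sigma) {
  sqrt((s + rnorm(length(s), 0, sigma))^2 + rnorm(length(s), 0, sigma)^2)
}

bssfp_rows <- function() {
  p <- default_protocol()
  p[p$kind == "bssfp", ]
}

spgr_rows <- function() {
  p <- default_protocol()
  p[p$kind == "spgr", ]
}
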