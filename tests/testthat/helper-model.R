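# Shared fitted curve (deterministic); fitted once per test run.
.curve_cache <- new.env(parent = emptyenv())
default_curve <- function() {
  if (is.null(.curve_cache$curve)) .curve_cache$curve <- fit_access_curve()
  .curve_cache$curve
}

# Independent fixed-point solver for the consanguinity adjustment: iterate
# to convergence instead of a fixed iteration count.
converged_adjusted_imr <- function(imr, alpha, curve, model, tol = 1e-9,
                                   max_iter = 1000) {
  a <- access_from_imr(imr, curve)
  imr_k <- imr
  for (k in seq_len(max_iter)) {
    prev <- imr_k
    c_imr <- consanguinity_imr(alpha, a, model)
    imr_k <- max(imr - c_imr, model$imr_floor)
    a <- access_from_imr(imr_k, curve)
    if (abs(imr_k - prev) < tol) break
  }
  imr_k
}
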