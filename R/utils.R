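# Shared numeric helpers.

# Round half away from zero (printed tables round 92.14 -> 92, 75.5 -> 76);
# base round() is banker's rounding and would give 75.5 -> 76 but 76.5 -> 76.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  out <- sign(x) * floor(abs(x) * p + 0.5) / p
  out[is.na(x)] <- NA_real_
  out
}

# Inverse-CDF truncated normal; guarantees draws inside (lower, upper).
rtrunc_norm <- function(n, mean, sd, lower = 0, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12), mean, sd)
}

is_positive_label <- function(labels) startsWith(as.character(labels), "Y")

`%||%` <- function(a, b) if (is.null(a)) b else a
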