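# Shared constants and small numeric helpers.

# The 20 standard amino acids (one-letter codes).
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Kyte-Doolittle hydropathy scale. The ambiguity letter X is scored 0
# (neutral) so that unknown residues neither create nor destroy an
# h-region on their own.
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
              Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
              L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
              S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -0.3,
              X = 0)

#' Wilson score confidence interval for a binomial proportion
#'
#' Chosen over the Wald interval for its behaviour at small counts and at
#' proportions near 0 or 1 (the regime of false-positive calibration).
#'
#' @param k Number of successes.
#' @param n Number of trials (must be >= 1).
#' @param conf Confidence level, default 0.95.
#' @return Named numeric vector with elements `low` and `high`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = max(0, centre - half), high = min(1, centre + half))
}

# Deterministic 31-bit rolling hash of a character scalar; used to echo a
# config fingerprint into output file headers.
.string_hash <- function(x) {
  h <- 0
  for (code in utf8ToInt(x)) h <- (h * 31 + code) %% 2147483647
  sprintf("%08x", h)
}

# Canonical one-line rendering of a config list for hashing/echoing.
.config_string <- function(config) {
  flat <- vapply(names(config), function(nm) {
    val <- config[[nm]]
    paste0(nm, "=", paste(format(val), collapse = ","))
  }, character(1))
  paste(flat[order(names(config))], collapse = ";")
}
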