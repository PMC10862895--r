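#' Format a replica statistic in `mean±sem` style
#'
#' Renders a mean and standard error the way replica-aggregated occupancies
#' are conventionally reported, e.g. `"97.4±1.4%"`.
#'
#' @param mean,sem numeric scalars.
#' @param digits decimal places kept (default 1).
#' @param percent if `TRUE` (default) values are fractions and are rendered
#'   as percentages with a trailing `%`.
#' @return a character scalar.
#' @examples
#' format_mean_sem(0.974, 0.014)     # "97.4±1.4%"
#' format_mean_sem(97, 1, percent = FALSE)
#' @export
format_mean_sem <- function(mean, sem, digits = 1, percent = TRUE) {
  scale <- if (percent) 100 else 1
  suffix <- if (percent) "%" else ""
  sprintf("%.*f±%.*f%s", digits, mean * scale, digits, sem * scale, suffix)
}

# 32-bit FNV-1a over a string; provenance fingerprint only, not cryptographic.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor the byte into the low 8 bits (h can exceed .Machine$integer.max,
    # so bitwXor on the whole word is unavailable)
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b %% 256))
    # 32-bit multiply by 16777619 without overflow: split into 16-bit halves
    lo <- h %% 65536
    hi <- (h %/% 65536) %% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Squared Euclidean distances from one point to rows of a matrix.
dist_to <- function(p, m) {
  sqrt(colSums((t(m) - p)^2))
}

# Draw a derived seed for sub-stream `k` from a base seed, staying < 2^31.
derive_seed <- function(seed, k) {
  (as.integer(seed) + 1009L * as.integer(k)) %% 2147483647L
}
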