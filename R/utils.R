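#' @keywords internal
"_PACKAGE"

# Round half away from zero, matching how three-decimal F1 scores are
# conventionally printed (base round() uses banker's rounding).
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# FNV-1a 32-bit hash of a string, kept below 2^31 so it is a valid R integer.
# Used to derive named substream seeds and to fingerprint configurations.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte only touches the low 8 bits; keeps h a double in [0, 2^32)
    h <- (h - h %% 256) + bitwXor(h %% 256, b %% 256)
    # 32-bit modular multiply by the FNV prime 16777619; the product is
    # split so every intermediate stays below 2^53 (exact in doubles)
    h1 <- floor(h / 65536)
    h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  as.integer(h %% 2147483647L)
}

# Seed for a named random substream under one root seed. Streams are keyed by
# name so e.g. adding metabolites to one matrix never perturbs another stream.
substream_seed <- function(root_seed, ...) {
  key <- paste(c(format(root_seed), ...), collapse = "/")
  fnv1a32(key)
}

with_substream <- function(root_seed, ..., expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(root_seed, ...))
  expr
}

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("bovipreg_config_error", "error")))
}

stop_data <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("bovipreg_data_error", "error")))
}

# "k/n" strings as printed in the discovery and validation tables
format_counts <- function(k, n) sprintf("%d/%d", as.integer(k), as.integer(n))

config_hash <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  sprintf("%08x", fnv1a32(as.character(js)))
}
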