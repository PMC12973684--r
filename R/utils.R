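# Internal helpers: validation errors, scalar checks, config hashing.

fail_validation <- function(...) {
  stop(structure(
    class = c("prdi_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

fail_io <- function(...) {
  stop(structure(
    class = c("prdi_io_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

is_num_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is_num_scalar(x))
    fail_validation(name, " must be a single finite number")
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi)
    fail_validation(name, " = ", format(x), " is outside the allowed range")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 32-bit FNV-1a over the UTF-8 bytes of a string; multiplication is split into
# 16-bit halves so the arithmetic stays exact in doubles.
fnv1a32 <- function(txt) {
  bytes <- as.integer(charToRaw(enc2utf8(paste(txt, collapse = "\n"))))
  h <- 2166136261
  two32 <- 2^32
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h1 <- floor(h / 65536)
    h0 <- h - h1 * 65536
    # 16777619 = 0x01000193
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% two32
  }
  hi <- floor(h / 65536)
  sprintf("%04x%04x", as.integer(hi), as.integer(h - hi * 65536))
}

# bitwXor for values up to 2^32-1 (base bitwXor is limited to 32-bit signed ints)
bitwXor_dbl <- function(a, b) {
  hi_a <- floor(a / 2^16); lo_a <- a - hi_a * 2^16
  hi_b <- floor(b / 2^16); lo_b <- b - hi_b * 2^16
  bitwXor(as.integer(hi_a), as.integer(hi_b)) * 2^16 +
    bitwXor(as.integer(lo_a), as.integer(lo_b))
}

config_hash <- function(config) {
  fnv1a32(as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)))
}
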