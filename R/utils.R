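#' @importFrom rlang abort warn inform %||% .data .env :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Round half away from zero at `digits` decimals; matches how occurrence
# rates are printed (0.310585... -> 0.31, 1.216444... -> 1.22).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Foreground share of the background population
#'
#' Percentage of the background population captured by the foreground
#' case series, rounded half-up to two decimals (the precision at which
#' such shares are reported to safety analysts).
#'
#' @param fg_size Foreground patient count (non-negative integer).
#' @param bg_size Background patient count; must be positive, otherwise
#'   the share is undefined and `NA_real_` is returned.
#' @return A single percentage value (e.g. `0.31` for 108 / 34773).
#' @examples
#' proportion(108, 34773)
#' proportion(423, 34773)
#' @export
proportion <- function(fg_size, bg_size) {
  stopifnot(fg_size >= 0)
  if (is.na(bg_size) || bg_size <= 0) {
    return(NA_real_)
  }
  round_half_up(100 * fg_size / bg_size, 2)
}

# 32-bit FNV-1a over a UTF-8 string, in double arithmetic (kept exact:
# the low byte is xored directly, the modular product is split 16/16).
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    hi16 <- h %/% 65536
    lo16 <- h %% 65536
    h <- (((hi16 * 16777619) %% 65536) * 65536 + lo16 * 16777619) %% 4294967296
  }
  h
}

# Deterministic sub-seed (< 2^31) for a named RNG stream, so that draws
# for one concern (demographics, exposures, ...) do not perturb others.
stream_seed <- function(seed, name) {
  as.integer((as.double(seed) * 48271 + fnv1a32(name)) %% 2147483647)
}

# Stable content hash of arbitrary R inputs via md5 of a canonical dump.
content_hash <- function(...) {
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp), add = TRUE)
  obj <- list(...)
  con <- file(tmp, "wb")
  serialize(obj, con, version = 2, xdr = TRUE)
  close(con)
  unname(tools::md5sum(tmp))
}

scheme_key <- function(scheme_id, code) paste0(scheme_id, "\x01", code)

split_key <- function(key) {
  parts <- strsplit(key, "\x01", fixed = TRUE)
  tibble(
    scheme_id = vapply(parts, `[[`, "", 1L),
    code = vapply(parts, `[[`, "", 2L)
  )
}

utils::globalVariables(".")
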