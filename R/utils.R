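#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a base seed and integer keys
#'
#' Mixes the base seed with any number of integer keys through a small
#' multiplicative-congruential scheme so that every subject, series and
#' permutation stream gets its own deterministic seed below 2^31.
#'
#' @param seed base integer seed
#' @param ... integer keys (subject index, modality code, ...)
#' @return a single integer in [0, 2^31 - 2]
#' @export
derive_seed <- function(seed, ...) {
  keys <- c(seed, unlist(list(...)))
  s <- 0
  for (k in keys) {
    # 69069 * 2^31 < 2^53, so the double-precision product is exact
    s <- (s * 69069 + (as.numeric(k) %% 2147483647)) %% 2147483647
  }
  as.integer(s)
}

stop_ischemri <- function(msg, class) {
  stop(structure(class = c(class, "ischemri_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_that <- function(cond, msg, class = "ischemri_invalid") {
  if (!isTRUE(cond)) stop_ischemri(msg, class)
  invisible(TRUE)
}

## Mirror a slab array (or mask) across the midline sagittal plane (x-flip).
mirror_x <- function(a) {
  d <- dim(a)
  a[d[1]:1, , , drop = FALSE]
}

## Ensure an array is nx x ny x nz (promote a matrix to a single slice).
as_volume <- function(a) {
  if (is.null(dim(a))) stop_ischemri("expected an array", "ischemri_invalid")
  if (length(dim(a)) == 2) dim(a) <- c(dim(a), 1L)
  a
}

## Extract frame k of a 4D series array without dropping thin dimensions.
frame_volume <- function(data, k) {
  d <- dim(data)
  array(data[, , , k], dim = d[1:3])
}

## FNV-1a hash over a serialized object; used for provenance fingerprints.
object_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  # drop the serialization header (R version specific)
  bytes <- bytes[-seq_len(14)]
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

fmt_num <- function(x, digits = 3) formatC(x, format = "fg", digits = digits)
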