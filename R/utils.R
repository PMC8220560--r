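# Internal helpers shared across modules.

AA_CODE <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

BETA_MIN <- -29L
BETA_MAX <- 237L

#' Label a beta-chain residue position
#'
#' The DRB1 beta chain is numbered 1..237 for the mature chain and -29..-1
#' for the signal peptide.  Labels are the conventional "\u03b271" style.
#'
#' @param index Integer vector of positions in -29..237 (0 is not a valid
#'   position).
#' @return Character vector of labels, e.g. "beta71" rendered as the Greek letter.
#' @export
position_label <- function(index) {
  index <- as.integer(index)
  check_positions(index)
  paste0("\u03b2", index)
}

check_positions <- function(index) {
  if (any(is.na(index)) || any(index < BETA_MIN) || any(index > BETA_MAX) ||
      any(index == 0L)) {
    stop("residue positions must be integers in ", BETA_MIN, "..", BETA_MAX,
         " (excluding 0)", call. = FALSE)
  }
  invisible(index)
}

# Evaluate `expr` with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG afterwards.  All generators in the package funnel through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a stream-specific 31-bit sub-seed from a master seed.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 16807) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Apply a scalar function over a character vector, evaluating it once per
# unique value (mappers and name parsing are called on long columns).
map_chr <- function(x, f) {
  ux <- unique(x)
  vals <- vapply(ux, f, character(1), USE.NAMES = FALSE)
  vals[match(x, ux)]
}
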