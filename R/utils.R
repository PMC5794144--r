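#' @keywords internal
"_PACKAGE"

# Round half away from zero. base::round() rounds half to even, which would
# turn the expected frame counts into off-by-one values (e.g. 23.5 -> 24 here).
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Derive a reproducible substream seed from a master seed and a label
#'
#' All randomness in the package flows from one master integer seed. Each
#' stochastic stage (weather, ground truth, pixel noise, splits, forests)
#' draws from its own named substream so that, for example, rendering a subset
#' of frames is bit-identical to slicing a full render. The derived seed is
#' kept below 2^31 - 1 so it is always a valid R integer.
#'
#' @param seed master integer seed.
#' @param ... labels (characters or integers) naming the substream.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    bytes <- if (is.character(p)) utf8ToInt(p) else as.integer(p)
    for (b in bytes) {
      h <- (h * 131 + as.double(b) + 17) %% 2147483647
    }
  }
  as.integer(h)
}

# Evaluate `expr` under a seeded RNG without disturbing the caller's RNG state.
with_substream <- function(seed, ..., expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, ...))
  expr
}

stop_domain <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop_domain(fmt, ...)
  invisible(TRUE)
}
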