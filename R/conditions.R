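#' @keywords internal
"_PACKAGE"

# Typed conditions used across the package. Every validation failure signals a
# classed error so callers (and the test-suite) can distinguish malformed files
# from scientific degeneracies without string matching.

sa_stop <- function(class, msg, ..., call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "swayagree_error", "error", "condition"),
    list(message = msg, call = call, ...)
  )
  stop(cond)
}

sa_format_error    <- function(msg, ...) sa_stop("sa_format_error", msg, ...)
sa_validation_error <- function(msg, ...) sa_stop("sa_validation_error", msg, ...)
sa_io_error        <- function(msg, ...) sa_stop("sa_io_error", msg, ...)
sa_pairing_error   <- function(msg, ...) sa_stop("sa_pairing_error", msg, ...)
sa_low_load_error  <- function(msg, ...) sa_stop("sa_low_load_error", msg, ...)
sa_too_short_error <- function(msg, ...) sa_stop("sa_too_short_error", msg, ...)
sa_degenerate_error <- function(msg, ...) sa_stop("sa_degenerate_error", msg, ...)

# Run code with a temporarily seeded RNG, restoring the caller's RNG state so
# simulation helpers are pure functions of their seed argument.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
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
  force(code)
}

# Stable integer sub-seed from a key tuple (subject, device, trial indices).
# Pure integer arithmetic in double precision (exact below 2^53), reduced mod
# 2^31 - 1 so the result is a valid 32-bit seed. Adding subjects/devices never
# perturbs the seed of an existing (subject, device, trial) cell.
derive_seed <- function(master, ...) {
  key <- c(...)
  h <- as.double(master) %% 2147483647
  for (k in key) {
    h <- (h * 48271 + as.double(k) * 8191 + 7919) %% 2147483647
  }
  as.integer(h)
}

#' Canonical names of the nine stabilometric parameters
#'
#' Fixed column/reporting order used everywhere in the package: total sway
#' path (`dot`), 95% prediction ellipse area (`area`), per-axis dispersion
#' (`rms_ap`, `rms_ml`), per-axis amplitude (`adcp_ap`, `adcp_ml`), per-axis
#' mean velocity (`mv_ap`, `mv_ml`) and total mean velocity (`tmv`).
#'
#' @return Character vector of length nine.
#' @export
metric_names <- function() {
  c("dot", "area", "rms_ap", "rms_ml", "adcp_ap", "adcp_ml",
    "mv_ap", "mv_ml", "tmv")
}
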