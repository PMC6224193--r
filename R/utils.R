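# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop("`seed` must be a single finite number", call. = FALSE)
    }
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(code)
}

#' Derive a reproducible sub-seed from a master seed and a stage label
#'
#' A single master seed is the only source of randomness in multi-stage runs;
#' each stage (connectivity wiring, input realization, parameter draws, ...)
#' receives its own substream seed derived deterministically from the master
#' seed and a stable text label. The result always lies in `[1, 2^31 - 20]` so
#' it is a valid R integer seed.
#'
#' @param master Integer master seed.
#' @param stage Character label naming the stage.
#' @return A single integer seed.
#' @examples
#' derive_seed(42, "connectivity")
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  stopifnot(is.character(stage), length(stage) == 1L)
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes) * 2654435761) %% 2147483629
  as.integer((abs(as.numeric(master)) * 48271 + h) %% 2147483629 + 1)
}

# Trapezoidal integral of y sampled at uniform spacing dx.
trapz_uniform <- function(y, dx) {
  n <- length(y)
  if (n < 2L) return(0)
  dx * (sum(y) - (y[1L] + y[n]) / 2)
}

# Lognormal sample with arithmetic mean `mean` and coefficient of variation
# `cv`; cv = 0 degenerates to the constant `mean`.
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

stop_l4ei <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "l4ei_error")))
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_l4ei("l4ei_invalid_spec", sprintf("`%s` must be a positive finite scalar", name))
  }
  invisible(x)
}
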