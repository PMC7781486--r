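# Internal helpers shared across modules.

# Deterministic child-seed derivation. Keeps everything reproducible from one
# master seed while giving distinct streams to (run, input, circuit, ...)
# combinations. All arithmetic stays below 2^53 so doubles are exact; the
# result is a valid 32-bit R seed.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master %% 2147483647L)
  for (k in idx) {
    s <- (s * 69069 + as.double(k) * 7919 + 1) %% 2147483647
  }
  s <- as.integer(s)
  if (s <= 0L) s <- s + 2147483646L
  s
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Timestamped message to stderr, filtered by a package-level log level.
blade_log <- function(msg, level = c("info", "debug", "warn"), verbose = TRUE) {
  level <- match.arg(level)
  if (isTRUE(verbose)) {
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    toupper(level), msg))
  }
  invisible(NULL)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
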