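# Internal helpers: seeded sub-streams, validation, small numerics.

#' Derive a reproducible sub-stream seed from a root seed and a label
#'
#' Each synthetic table is drawn from its own stream keyed by
#' `(seed, label)`, so adding a generator never shifts the draws of another.
#' The hash is a simple 31-multiplier rolling hash over the label bytes,
#' folded into the root seed modulo 2^31 - 1.
#'
#' @param seed integer root seed.
#' @param label character stream label (e.g. a table name).
#' @return an integer seed, always in [0, 2^31 - 2].
#' @keywords internal
stream_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(label) == 1L)
  m <- 2147483647 # 2^31 - 1, keeps everything in exact double range
  h <- as.double(abs(as.integer(seed))) %% m
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% m
  as.integer(h)
}

# Evaluate `expr` under a seeded RNG stream, restoring the caller's RNG state.
with_stream <- function(seed, label, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(stream_seed(seed, label))
  expr
}

# stop() with a consistent condition class so tests can assert on it
abort_reefpress <- function(msg, class = "reefpress_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

validation_error <- function(msg) abort_reefpress(msg, "reefpress_validation_error")
config_error <- function(msg) abort_reefpress(msg, "reefpress_config_error")

# assert columns exist in a data.frame
need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L)
    validation_error(sprintf("%s is missing required column(s): %s",
                             what, paste(miss, collapse = ", ")))
  invisible(df)
}

# lognormal meanlog/sdlog from arithmetic mean and CV
lnorm_pars <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# negative binomial draw with Poisson limit at k = Inf
rcounts <- function(n, mean, k) {
  if (n == 0L) return(integer(0))
  if (mean <= 0) return(integer(n))
  if (is.infinite(k)) as.integer(stats::rpois(n, mean))
  else as.integer(stats::rnbinom(n, size = k, mu = mean))
}
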