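# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_preserved_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                      lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  low_ok <- if (lower_open) x > lower else x >= lower
  high_ok <- if (upper_open) x < upper else x <= upper
  if (!low_ok || !high_ok) {
    stop(sprintf("'%s' = %g is outside its allowed range %s%g, %g%s", name, x,
                 if (lower_open) "(" else "[", lower, upper,
                 if (upper_open) ")" else "]"), call. = FALSE)
  }
  invisible(x)
}

# Wald 95% CI on the OR scale from a single log-OR and its variance.
single_study_ci <- function(log_or, var_log_or) {
  half <- 1.96 * sqrt(var_log_or)
  c(exp(log_or - half), exp(log_or + half))
}

# Significance convention used throughout: 95% CI excludes OR = 1.
ci_excludes_null <- function(ci_low, ci_high) {
  is.finite(ci_low) & is.finite(ci_high) & (ci_low > 1 | ci_high < 1)
}

# md5 of an arbitrary R object, via its serialization to a temp file.
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}
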