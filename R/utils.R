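# Internal helpers: classed conditions, argument checks, formatting.

sm_stop <- function(message, class) {
  stop(structure(
    class = c(class, "spinemult_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

assert_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    sm_stop(sprintf("`%s` must be a single positive finite number", name),
            "spinemult_domain_error")
  }
  invisible(x)
}

match_sex <- function(sex) {
  if (!is.character(sex) || length(sex) != 1L || !sex %in% c("male", "female")) {
    sm_stop('`sex` must be "male" or "female"', "spinemult_domain_error")
  }
  sex
}

# Run `code` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

fmt_cm <- function(x) sprintf("%.2f", x)
fmt_mult <- function(x) sprintf("%.3f", x)
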