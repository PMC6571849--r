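# internal helpers

stop_lasso <- function(msg, class, ...) {
  rlang::abort(msg, class = c(paste0("lassocapture_", class), "lassocapture_error"), ...)
}

check_number <- function(x, name, positive = TRUE, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_lasso(sprintf("`%s` must be a single finite number", name), "invalid_argument")
  }
  if (positive && !(x > 0 || (allow_zero && x == 0))) {
    stop_lasso(sprintf("`%s` must be %s", name, if (allow_zero) "non-negative" else "positive"),
               "invalid_argument")
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop_lasso(sprintf("`%s` must be an integer >= %d", name, min), "invalid_argument")
  }
  as.integer(x)
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
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
  force(code)
}

table_hash <- function(x) {
  rlang::hash(round(unclass(as.numeric(x)), 12))
}
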