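# internal helpers

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
# Keeps all generator functions deterministic without clobbering the session.
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_input <- function(...) {
  stop(structure(class = c("abrcog_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_param <- function(...) {
  stop(structure(class = c("abrcog_param_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mean/variance of the mixture-of-uniforms age distribution implied by params
age_moments <- function(group_sizes, age_ranges) {
  w <- group_sizes / sum(group_sizes)
  m <- vapply(age_ranges, function(r) mean(r), numeric(1))
  v <- vapply(age_ranges, function(r) diff(r)^2 / 12, numeric(1))
  mu <- sum(w * m)
  list(mean = mu, var = sum(w * (v + m^2)) - mu^2)
}
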