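# internal helpers shared across modules

# Derive a reproducible substream seed from a global seed and a stage label.
# Keeps every derived seed in [0, 2^31 - 2] so it is a valid R integer.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  v <- as.numeric(utf8ToInt(label))
  h <- sum(v * seq_along(v) * 2654435) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

# run expr with a local RNG state seeded from (seed, label)
with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, label))
  force(expr)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a whole number >= %s.", name, min),
          class = "pgsmed_config_error")
  }
  as.integer(x)
}

check_prob <- function(x, name, open = TRUE) {
  lo_ok <- if (open) x > 0 else x >= 0
  hi_ok <- if (open) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || !hi_ok) {
    abort(sprintf("`%s` must be a probability in %s0, 1%s.", name,
                  if (open) "(" else "[", if (open) ")" else "]"),
          class = "pgsmed_config_error")
  }
  as.numeric(x)
}

# stderr logging with per-stage record counts, silenced via option
log_info <- function(...) {
  if (isTRUE(getOption("pgsmed.quiet", FALSE))) return(invisible(NULL))
  inform(paste0(...), class = "pgsmed_log")
}

`%||%` <- rlang::`%||%`
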