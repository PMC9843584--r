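# Internal helpers: error signalling and reproducible RNG handling.

abort_ntaug <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("ntaug_", class), "ntaug_error"), ...)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so package functions never perturb user randomness.
#'
#' @param seed Non-negative integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, !is.na(seed))
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
  set.seed(as.integer(seed))
  expr
}

# Independent RNG stream: an environment carrying its own .Random.seed,
# swapped in for the duration of `expr`.  Lets stochastic augmentation draw
# from a stream separate from the training loop's, so disabling augmentation
# leaves the training trajectory untouched.
new_rng_stream <- function(seed) {
  st <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed))
  st$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  st
}

stream_eval <- function(stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

# sample() without the length-1 surprise (sample(5) permutes 1:5).
sample_exact <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size = size, replace = replace, prob = prob)]
}

AA_LETTERS <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
NT_LETTERS <- c("A", "C", "G", "T")
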