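#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators never disturb the
#' caller's random number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Derive a stage seed from a master seed and a label
#'
#' Stable string hash so that each pipeline stage and each data combination
#' gets its own reproducible stream; adding a combination never perturbs the
#' randomness of the others. Result is always in `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param ... character labels (stage name, combination id, ...).
#' @return A single integer seed.
#' @export
#' @examples
#' stableSeed(1, "network")
#' stableSeed(1, "folds", "comboA")
stableSeed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  tag <- paste(c(...), collapse = "/")
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- abs(as.numeric(master)) %% m
  for (code in utf8ToInt(tag)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared argument checkers -------------------------------------------------

assertFlagIn <- function(x, choices, what) {
  if (!is.character(x) || length(x) != 1 || !x %in% choices) {
    stop(sprintf("'%s' must be one of: %s", what,
                 paste(choices, collapse = ", ")), call. = FALSE)
  }
  x
}

assertCount <- function(x, what, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("'%s' must be an integer >= %s", what, min), call. = FALSE)
  }
  as.integer(x)
}
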