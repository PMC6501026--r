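# Internal helpers: seeded streams, argument checks, shared formatting.

#' @keywords internal
#' @noRd
.stream_seed <- function(seed, stream) {
  # Deterministic 32-bit sub-seed for a named generator stream.  Every source
  # of randomness in the package derives its seed this way from one global
  # seed, so a single integer reproduces the whole cohort.
  ch <- utf8ToInt(stream)
  h <- sum(ch * seq_along(ch)) %% 104729L
  as.integer((abs(as.numeric(seed)) * 48271 + h * 9973) %% 2147483647)
}

#' @noRd
.with_seed <- function(seed, code) {
  # Evaluate `code` under `set.seed(seed)` and restore the caller's RNG state.
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
  })
  set.seed(seed)
  force(code)
}

#' @noRd
.check_binary_matrix <- function(x, name = "mutations") {
  if (!is.matrix(x)) stop(sprintf("'%s' must be a matrix", name), call. = FALSE)
  if (!all(x %in% c(0, 1))) {
    stop(sprintf("'%s' must be binary (0/1)", name), call. = FALSE)
  }
  invisible(x)
}

#' @noRd
.check_same_samples <- function(a, b, what_a, what_b) {
  ia <- rownames(a) %||% colnames(a)
  ib <- rownames(b) %||% colnames(b)
  if (!identical(ia, ib)) {
    only_a <- setdiff(ia, ib)
    only_b <- setdiff(ib, ia)
    stop(sprintf(
      "sample identifiers of %s and %s differ (only in %s: %s; only in %s: %s)",
      what_a, what_b,
      what_a, paste(utils::head(only_a, 5), collapse = ", "),
      what_b, paste(utils::head(only_b, 5), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.logit <- function(p) log(p / (1 - p))

#' @noRd
.plogis2 <- function(x) 1 / (1 + exp(-x))
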