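#' @importFrom stats var sd cor dist lowess p.adjust pt rgamma rlnorm rnorm
#'   rpois rbinom runif prcomp cutree as.dist hclust quantile setNames
#' @importFrom utils head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible integer seed from a base seed and string labels
#'
#' All per-pair and per-split randomness in the package flows from one
#' top-level seed through this hash, so results do not depend on the order
#' in which pairs are visited or on the number of workers.
#'
#' @param seed integer base seed.
#' @param ... character labels mixed into the hash (sorted by the caller
#'   when symmetry is required).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @keywords internal
hash_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  m <- 2147483647  # 2^31 - 1, keeps everything a valid R integer
  h <- as.numeric(seed) %% m
  for (s in unlist(list(...))) {
    for (code in utf8ToInt(as.character(s))) {
      h <- (h * 31 + code) %% m
    }
  }
  as.integer(h)
}

# Run `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stop_cider <- function(class, ...) {
  stop(errorCondition(paste0(...), class = c(class, "cider_error")))
}

warn_cider <- function(class, ...) {
  warning(warningCondition(paste0(...), class = c(class, "cider_warning")))
}
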