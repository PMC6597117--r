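#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from a single master seed which is
#' split into named substreams, so that independent stages (schedule
#' generation, proportion noise, exploration-time draws, optimizer starts)
#' never share or disturb each other's random state.
#'
#' The derivation is a small multiplicative hash over the master seed and the
#' key strings, reduced modulo 2^31 - 2 so the result is always a valid
#' positive integer seed.
#'
#' @param master integer master seed.
#' @param ... character or numeric keys naming the substream
#'   (e.g. animal id, condition, stage name).
#' @return a positive integer seed.
#' @examples
#' substream_seed(1, "rat01", "overlapping")
#' @export
substream_seed <- function(master, ...) {
  keys <- paste(vapply(list(...), function(x) paste(format(x), collapse = "|"),
                       character(1)), collapse = "::")
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(keys)) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h %% 2147483645L + 1L)
}

# Evaluate expr with a local RNG state seeded at `seed`; the caller's RNG
# state is restored afterwards, so no stage reads or leaks global RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
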