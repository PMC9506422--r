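#' Derive a stage-specific seed from a master seed
#'
#' One master seed drives the whole pipeline; each stage gets its own
#' deterministic sub-seed so stages can be re-run individually and still
#' reproduce. The stage name is hashed onto the integer range with a small
#' polynomial rolling hash (no external digest dependency), and the result is
#' kept below 2^31 so it is always a valid R integer.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(length(master) == 1, is.finite(master))
  h <- as.double(master %% 2147483647)
  for (code in utf8ToInt(as.character(stage))) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# row sd ignoring NA, sample (n-1) convention
row_sds <- function(x) matrixStats::rowSds(x, na.rm = TRUE)
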