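#' Deterministic stage-level substream seeds
#'
#' One master seed drives a run; each stochastic stage draws from its own
#' substream whose seed is a stable hash of (stage, iteration, lineage).
#' Changing, say, the number of designs per complex therefore does not
#' perturb the docking draws. The hash is a Lehmer-style modular chain
#' kept below 2^31.
#'
#' @param master master seed (integer).
#' @param stage stage label, e.g. `"dock"`.
#' @param iteration,lineage integer stream coordinates.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(master, stage, iteration = 0L, lineage = 0L) {
  p <- 2147483647
  h <- (as.numeric(master) %% p) + 1
  bytes <- utf8ToInt(paste(stage, iteration, lineage, sep = "/"))
  for (b in bytes) h <- (h * 69621 + b + 1) %% p
  as.integer(h %% (p - 2) + 1)
}

# evaluate code under a seed, then restore the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
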