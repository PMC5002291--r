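# Evaluate expr with a locally set RNG state, restoring the caller's state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive n reproducible child seeds (< 2^31) from one master seed.
deriveSeeds <- function(masterSeed, n) {
  withSeed(masterSeed, sample.int(.Machine$integer.max - 1L, n))
}

#' Convert simulator cycle counts to equivalent months of walking
#'
#' Knee wear simulators report test duration in millions of gait cycles
#' (Mc); retrieval cohorts report time in host in months. The customary
#' equivalence is that one million cycles of level walking represents
#' twelve months of in vivo use, so a standard five-million-cycle test
#' corresponds to sixty months in host.
#'
#' @param millionCycles test duration in millions of cycles.
#' @param monthsPerMc months of in vivo use represented by one million
#'   cycles (default 12).
#' @return equivalent duration in months.
#' @examples
#' cyclesToMonths(5)  # 60
#' @export
cyclesToMonths <- function(millionCycles, monthsPerMc = 12) {
  stopifnot(is.numeric(millionCycles), millionCycles >= 0, monthsPerMc > 0)
  millionCycles * monthsPerMc
}
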