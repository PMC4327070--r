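#' Physical constants
#'
#' Fixed CODATA 2018 values used throughout the surface-density chain.
#' These are not user-configurable: every 10^3-scale unit error in this
#' problem traces back to a constant or a unit, so both are pinned.
#'
#' @return Named list with `N_A` (Avogadro number, 1/mol) and `eps0`
#'   (vacuum permittivity, F/m).
#' @export
#' @examples
#' wgm_constants()$N_A
wgm_constants <- function() {
  list(
    N_A  = 6.02214076e23,   # 1/mol, exact (SI 2019)
    eps0 = 8.8541878128e-12 # F/m
  )
}

# run code with a local RNG seed, restoring global state afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
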