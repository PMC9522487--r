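#' Disease-stage parameter presets for the Leslie-Gower model
#'
#' The three clinically motivated parameter sets of the model: an early
#' prognosis (mild conversion of cell types, weak predation), acute
#' leukemia (strong interspecific coupling) and chronic leukemia (all
#' rates equal). Values are packaged exactly as stated, with no unit
#' conversion; densities are in model units of \eqn{10^9} cells/liter.
#'
#' @param stage `"early"`, `"acute"` or `"chronic"`.
#' @return a [leslie_params()] object (with the default `k = 100`,
#'   `c = 1`, which do not enter the equilibrium or stability analysis).
#' @examples
#' stage_scenario("early")
#' @export
stage_scenario <- function(stage = c("early", "acute", "chronic")) {
  stage <- match.arg(stage)
  preset <- switch(stage,
    early   = list(r1 = 0.5, c1 = 1.42e-6, b = 0.1,  r2 = 0.6,  c2 = 0.5),
    acute   = list(r1 = 0.7, c1 = 0.7,     b = 0.25, r2 = 0.75, c2 = 0.4),
    chronic = list(r1 = 0.6, c1 = 0.6,     b = 0.6,  r2 = 0.6,  c2 = 0.6)
  )
  leslie_params(r1 = preset$r1, r2 = preset$r2, c1 = preset$c1,
                c2 = preset$c2, b = preset$b)
}

#' Post-chemotherapy cell counts used by the transplantation game
#'
#' The residual counts after high-dose chemotherapy that parameterise the
#' HSC transplantation analysis: natural-killer (NK) cells, remaining
#' healthy leukocytes, peripheral CD34+ stem cells infused and the CD34+
#' cell number (both per kg of recipient body weight), and the two
#' residual c.leu counts. The NK value of 2.08e-7 cells is stored
#' verbatim despite being dimensionally implausible (a fractional cell).
#'
#' @return object of class `transplant_counts`: a named list with
#'   `nk`, `leu`, `cd34_infused`, `cd34_number`, `cleu_major`,
#'   `cleu_minor`.
#' @export
transplant_counts <- function() {
  structure(list(nk = 2.08e-7,
                 leu = 5.00e8,
                 cd34_infused = 9.19e6,
                 cd34_number = 3.47e4,
                 cleu_major = 4.31e-1,
                 cleu_minor = 1.42e-6),
            class = "transplant_counts")
}

#' Initial coalition frequencies from transplant cell counts
#'
#' Maps absolute post-chemotherapy counts to an initial point on the
#' frequency simplex under one of the two coalition groupings:
#' `"leu_vs_hsc_cleu"` puts leu (with NK cells) alone as the favourable
#' group against the (HSC, c.leu) coalition; `"hsc_leu_vs_cleu"` puts the
#' (HSC, leu, NK) coalition against residual c.leu.
#'
#' @param counts a [transplant_counts()] object (or compatible list).
#' @param grouping `"leu_vs_hsc_cleu"` or `"hsc_leu_vs_cleu"`.
#' @return numeric `c(favourable, unfavourable)` frequencies summing to 1.
#' @examples
#' initial_frequency_state(transplant_counts(), "leu_vs_hsc_cleu")
#' @export
initial_frequency_state <- function(counts,
                                    grouping = c("leu_vs_hsc_cleu",
                                                 "hsc_leu_vs_cleu")) {
  grouping <- match.arg(grouping)
  hsc <- counts$cd34_infused + counts$cd34_number
  cleu <- counts$cleu_major + counts$cleu_minor
  if (grouping == "leu_vs_hsc_cleu") {
    fav <- counts$leu + counts$nk
    unf <- hsc + cleu
  } else {
    fav <- counts$leu + counts$nk + hsc
    unf <- cleu
  }
  total <- fav + unf
  if (total <= 0) {
    stop("all cell counts are zero; frequencies are undefined",
         call. = FALSE)
  }
  c(favourable = fav / total, unfavourable = unf / total)
}

#' Seeded random clinical scenario
#'
#' Draws a clinically plausible Leslie-Gower scenario around a disease
#' stage preset: each rate of [stage_scenario()] is perturbed by an
#' independent Uniform(0.9, 1.1) factor; the initial leu density is drawn
#' uniformly from the diagnostic range 30-200 (in units of \eqn{10^9}
#' cells/liter), with the initial c.leu density a Uniform(0.1, 1) fraction
#' of it; the observation horizon is a whole number of days between 40
#' and 80. The draw is fully determined by `seed` and leaves the global
#' RNG state untouched.
#'
#' @param stage disease stage passed to [stage_scenario()].
#' @param seed integer RNG seed.
#' @return list with `stage`, `params` ([leslie_params()]),
#'   `initial_state` (`c(i, l)`), `horizon` (days) and `seed`.
#' @examples
#' random_scenario("early", seed = 42)
#' @export
random_scenario <- function(stage = c("early", "acute", "chronic"), seed) {
  stage <- match.arg(stage)
  if (missing(seed) || !is.finite(seed)) {
    stop("`seed` must be supplied as an integer", call. = FALSE)
  }
  base <- stage_scenario(stage)
  draw <- with_local_seed(as.integer(seed), function() {
    fac <- runif(5, 0.9, 1.1)
    i0 <- runif(1, 30, 200)
    frac <- runif(1, 0.1, 1.0)
    horizon <- sample(40:80, 1)
    list(fac = fac, i0 = i0, frac = frac, horizon = horizon)
  })
  params <- leslie_params(r1 = base$r1 * draw$fac[1],
                          c1 = base$c1 * draw$fac[2],
                          b  = base$b  * draw$fac[3],
                          r2 = base$r2 * draw$fac[4],
                          c2 = base$c2 * draw$fac[5],
                          k = base$k, c = base$c)
  list(stage = stage,
       params = params,
       initial_state = c(i = draw$i0, l = draw$frac * draw$i0),
       horizon = draw$horizon,
       seed = as.integer(seed))
}

# Run `expr_fn` under a private RNG stream, restoring any pre-existing
# global state afterwards.
with_local_seed <- function(seed, expr_fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr_fn()
}
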