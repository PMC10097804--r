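#' Construct a codon model specification
#'
#' @param name one of `"M0"`, `"TWO_RATIO"`, `"M1a"`, `"M2a"`, `"MA_NULL"`,
#'   `"MA_ALT"` (see [CodonModelSpec-class] for the class structures).
#' @param fixed named list of parameters to hold fixed (any of `kappa`,
#'   `omega`, `omegaBg`, `omegaFg`, `omega0`, `omega2`, `p0`, `p1`). For
#'   `MA_NULL`, `omega2 = 1` is always implied. A spec with all parameters
#'   fixed doubles as a simulation truth.
#' @return a [CodonModelSpec-class].
#' @examples
#' codonModelSpec("M0")
#' codonModelSpec("MA_ALT", fixed = list(omega2 = 4))
#' @export
codonModelSpec <- function(name, fixed = list()) {
  name <- match.arg(name, .MODEL_NAMES)
  if (name == "MA_NULL") fixed$omega2 <- 1
  new("CodonModelSpec", name = name, fixed = fixed)
}

#' @rdname codonSelect-accessors
#' @export
setMethod("modelName", "CodonModelSpec", function(x) x@name)

setMethod("show", "CodonModelSpec", function(object) {
  cat("CodonModelSpec:", object@name)
  if (length(object@fixed))
    cat(" [fixed:", paste(names(object@fixed), unlist(object@fixed),
                          sep = "=", collapse = ", "), "]")
  cat("\n")
})

## parameter names that are free for each model (before applying user fixes)
.modelParamNames <- function(name) {
  switch(name,
    M0        = c("kappa", "omega"),
    TWO_RATIO = c("kappa", "omegaBg", "omegaFg"),
    M1a       = c("kappa", "omega0", "p0"),
    M2a       = c("kappa", "omega0", "omega2", "p0", "p1"),
    MA_NULL   = c("kappa", "omega0", "p0", "p1"),
    MA_ALT    = c("kappa", "omega0", "omega2", "p0", "p1"))
}

## natural-scale box bounds for each parameter
.PARAM_BOUNDS <- list(
  kappa   = c(1e-2, 100),
  omega   = c(1e-4, 999),
  omegaBg = c(1e-4, 999),
  omegaFg = c(1e-4, 999),
  omega0  = c(1e-4, 1),
  omega2  = c(1, 999),
  p0      = c(1e-6, 1 - 1e-6),
  p1      = c(1e-6, 1 - 1e-6)
)

## Site-class structure implied by a model at given parameter values.
## Returns a list with vectors prop, omegaBg, omegaFg (one entry per class).
.classStructure <- function(name, par) {
  switch(name,
    M0 = list(prop = 1,
              omegaBg = par$omega, omegaFg = par$omega),
    TWO_RATIO = list(prop = 1,
                     omegaBg = par$omegaBg, omegaFg = par$omegaFg),
    M1a = list(prop = c(par$p0, 1 - par$p0),
               omegaBg = c(par$omega0, 1),
               omegaFg = c(par$omega0, 1)),
    M2a = {
      p2 <- 1 - par$p0 - par$p1
      list(prop = c(par$p0, par$p1, p2),
           omegaBg = c(par$omega0, 1, par$omega2),
           omegaFg = c(par$omega0, 1, par$omega2))
    },
    MA_NULL = ,
    MA_ALT = {
      w2 <- if (name == "MA_NULL") 1 else par$omega2
      prest <- 1 - par$p0 - par$p1
      p2a <- prest * par$p0 / (par$p0 + par$p1)
      p2b <- prest * par$p1 / (par$p0 + par$p1)
      list(prop = c(par$p0, par$p1, p2a, p2b),
           omegaBg = c(par$omega0, 1, par$omega0, 1),
           omegaFg = c(par$omega0, 1, w2, w2))
    })
}

## default starting values; `jitter` perturbs omegas across restarts
.initParams <- function(name, restart = 1L, fixed = list()) {
  omegaStarts <- c(0.1, 0.5, 1.5)
  w <- omegaStarts[((restart - 1L) %% length(omegaStarts)) + 1L]
  par <- list(kappa = 2, omega = w, omegaBg = w, omegaFg = w,
              omega0 = min(w, 0.9), omega2 = max(1.5, w),
              p0 = 0.7, p1 = 0.2)
  par[.modelParamNames(name)] <- par[.modelParamNames(name)]
  par[names(fixed)] <- fixed
  par
}
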