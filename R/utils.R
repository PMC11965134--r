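## Internal helpers shared across modules.

## Run `expr` under a given seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Derive a reproducible child seed below 2^31 from a base seed and an index.
.childSeed <- function(seed, index) {
    as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 9973) %%
               2147483647)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Coerce a 2D slice (or bare vector from a degenerate NIfTI) to a 3D array
## by appending singleton dimensions; NIfTI readers drop trailing ones.
.as3DArray <- function(x) {
    d <- dim(x)
    if (is.null(d)) d <- length(x)
    if (length(d) > 3L) stop("expected at most 3 dimensions")
    array(x, dim = c(d, rep(1L, 3L - length(d))))
}

#' Convert b-values between s/mm^2 and ms/um^2
#'
#' The package stores b internally in ms/um^2 so that exponents D*b with
#' diffusivities in um^2/ms are dimensionless: 1 ms/um^2 = 1000 s/mm^2.
#'
#' @param b numeric vector of b-values
#' @return the converted vector
#' @export
bFromSmm2 <- function(b) b / 1000

#' @rdname bFromSmm2
#' @export
bToSmm2 <- function(b) b * 1000
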