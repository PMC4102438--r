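#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{expr} with the global RNG seeded at \code{seed} and restores the
#' caller's RNG state afterwards, so seeded generators do not perturb user
#' code. A \code{NULL} seed evaluates \code{expr} with the current stream.
#'
#' @param seed integer seed or \code{NULL}.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
    if (is.null(seed)) {
        return(eval.parent(substitute(expr)))
    }
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) {
            assign(".Random.seed", old, envir = globalenv())
        } else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE)) {
            rm(".Random.seed", envir = globalenv())
        }
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}

## one-sided / two-sided bootstrap p with add-one continuity so p is never 0
bootP <- function(stat, boot, side = c("greater", "two.sided")) {
    side <- match.arg(side)
    b <- length(boot)
    if (side == "greater") {
        (sum(boot <= 0) + 1) / (b + 1)
    } else {
        lo <- (sum(boot <= 0) + 1) / (b + 1)
        hi <- (sum(boot >= 0) + 1) / (b + 1)
        min(1, 2 * min(lo, hi))
    }
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
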