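#' @import methods
#' @importFrom stats approx optimize cor.test lm coef step as.formula
#'   wilcox.test fisher.test binom.test quantile rbinom rpois runif rexp
#'   setNames pnorm sd terms extractAIC rmultinom
#' @importFrom utils read.table write.table head tail
NULL

## ---------------------------------------------------------------------------
## GeneticMap: ordered physical positions with cumulative genetic distance.
## The universal currency of the pipeline: every rate, profile and comparison
## is derived from one of these.  Cumulative distance is stored in cM; the
## origin need not be zero (maps clipped out of a larger map keep their
## offset).
## ---------------------------------------------------------------------------

#' GeneticMap: cumulative genetic distance along physical coordinates
#'
#' Ordered physical marker positions (bp, 0-based) with the cumulative
#' genetic distance (cM) at each position. Genetic distance between
#' positions is obtained by linear interpolation of the cumulative curve,
#' i.e. rate is piecewise constant between markers. Queries outside the
#' mapped span extrapolate at zero rate, reflecting that no rate can be
#' estimated beyond marker coverage.
#'
#' @slot positions numeric, strictly increasing physical positions (bp).
#' @slot cumulative numeric, non-decreasing cumulative distance (cM),
#'   same length as \code{positions}.
#' @slot sexLabel one of \code{"male"}, \code{"female"}, \code{"sex-averaged"}.
#' @slot sourceLabel free-text provenance (population, study, simulation).
#' @export
setClass("GeneticMap",
    representation(positions = "numeric", cumulative = "numeric",
                   sexLabel = "character", sourceLabel = "character"),
    prototype(sexLabel = "sex-averaged", sourceLabel = ""))

setValidity("GeneticMap", function(object) {
    p <- object@positions
    d <- object@cumulative
    if (length(p) != length(d))
        return("positions and cumulative must have equal length")
    if (length(p) < 1L)
        return("a map needs at least one marker")
    if (length(p) > 1L) {
        bad <- which(diff(p) <= 0)
        if (length(bad))
            return(sprintf("positions not strictly increasing at row %d",
                           bad[1L] + 1L))
        bad <- which(diff(d) < 0)
        if (length(bad))
            return(sprintf("cumulative distance decreases at row %d",
                           bad[1L] + 1L))
    }
    if (!object@sexLabel %in% c("male", "female", "sex-averaged"))
        return("sexLabel must be male, female or sex-averaged")
    TRUE
})

#' Construct a GeneticMap
#'
#' @param positions strictly increasing physical positions (bp).
#' @param cumulative non-decreasing cumulative genetic distance.
#' @param unit unit of \code{cumulative}: \code{"cM"} (default) or
#'   \code{"Morgans"} (converted to cM on construction).
#' @param sexLabel \code{"male"}, \code{"female"} or \code{"sex-averaged"}.
#' @param sourceLabel free-text provenance label.
#' @return a \linkS4class{GeneticMap}.
#' @examples
#' m <- GeneticMap(c(0, 1e6, 2.7e6), c(0, 20, 50), sexLabel = "male")
#' mapLength(m)
#' @export
GeneticMap <- function(positions, cumulative, unit = c("cM", "Morgans"),
                       sexLabel = "sex-averaged", sourceLabel = "") {
    unit <- match.arg(unit)
    if (unit == "Morgans") cumulative <- cumulative * 100
    new("GeneticMap", positions = as.numeric(positions),
        cumulative = as.numeric(cumulative), sexLabel = sexLabel,
        sourceLabel = sourceLabel)
}

#' @rdname GeneticMap
#' @param x,object a \code{GeneticMap}.
#' @export
mapPositions <- function(x) x@positions

#' @rdname GeneticMap
#' @export
mapCumulative <- function(x) x@cumulative

#' @rdname GeneticMap
#' @export
mapSpan <- function(x) range(x@positions)

#' Total genetic length of a map (cM)
#' @param x a \code{GeneticMap}.
#' @export
mapLength <- function(x) {
    d <- x@cumulative
    d[length(d)] - d[1L]
}

#' @rdname GeneticMap
#' @export
sexLabel <- function(x) x@sexLabel

setMethod("show", "GeneticMap", function(object) {
    cat(sprintf(
        "GeneticMap (%s%s): %d markers, %.0f-%.0f bp, %.4g cM\n",
        object@sexLabel,
        if (nzchar(object@sourceLabel))
            paste0(", ", object@sourceLabel) else "",
        length(object@positions), min(object@positions),
        max(object@positions), mapLength(object)))
})

## ---------------------------------------------------------------------------
## RateTrack: windowed cM/Mb rates
## ---------------------------------------------------------------------------

#' RateTrack: recombination rate per genomic window
#'
#' Sorted, non-overlapping half-open windows \code{[start, end)} with a
#' recombination rate in cM/Mb each. \code{NA} marks windows where no rate
#' could be estimated (outside marker coverage) -- deliberately distinct
#' from a zero rate.
#'
#' @slot start,end numeric window bounds (bp, half-open).
#' @slot rate numeric, cM/Mb, \code{NA} allowed.
#' @export
setClass("RateTrack",
    representation(start = "numeric", end = "numeric", rate = "numeric"))

setValidity("RateTrack", function(object) {
    s <- object@start; e <- object@end; r <- object@rate
    if (length(s) != length(e) || length(s) != length(r))
        return("start, end, rate must have equal length")
    if (any(e <= s)) return("windows must satisfy start < end")
    if (length(s) > 1L && any(s[-1L] < s[-length(s)]))
        return("windows must be sorted by start")
    if (any(!is.na(r) & r < 0)) return("rates must be non-negative")
    TRUE
})

#' @rdname RateTrack-class
#' @param start,end,rate parallel numeric vectors.
#' @export
RateTrack <- function(start, end, rate) {
    new("RateTrack", start = as.numeric(start), end = as.numeric(end),
        rate = as.numeric(rate))
}

setMethod("show", "RateTrack", function(object) {
    cat(sprintf("RateTrack: %d windows, %.0f-%.0f bp, mean %.3g cM/Mb\n",
                length(object@start), min(object@start), max(object@end),
                mean(object@rate, na.rm = TRUE)))
})

#' Convert a RateTrack to a data.frame
#' @param x a \code{RateTrack}.
#' @export
trackAsDataFrame <- function(x) {
    data.frame(start = x@start, end = x@end, rate = x@rate)
}

## ---------------------------------------------------------------------------
## Map arithmetic
## ---------------------------------------------------------------------------

#' Genetic distance spanned by a physical interval
#'
#' Linearly interpolates the cumulative curve inside marker gaps; positions
#' outside the mapped span contribute zero distance (constant
#' extrapolation). Vectorised over \code{a}, \code{b}.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param a,b interval bounds in bp, \code{a <= b}.
#' @return genetic distance in cM (non-negative, additive over abutting
#'   intervals).
#' @examples
#' m <- GeneticMap(c(0, 100), c(0, 1))
#' intervalCM(m, 0, 50)   # 0.5
#' @export
intervalCM <- function(map, a, b) {
    if (any(a > b)) stopf("intervalCM requires a <= b")
    cumAt(map, b) - cumAt(map, a)
}

## cumulative cM at arbitrary positions, constant beyond the span
cumAt <- function(map, at) {
    p <- map@positions
    d <- map@cumulative
    if (length(p) == 1L) return(rep(d, length(at)))
    approx(p, d, xout = pmin(pmax(at, p[1L]), p[length(p)]),
           ties = "ordered")$y
}

#' Mean recombination rate over a region
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param start,end region bounds in bp (half-open); must overlap the map
#'   span and have positive length.
#' @return mean rate in cM/Mb.
#' @export
meanRate <- function(map, start, end) {
    if (end <= start) stopf("meanRate: zero-length region")
    sp <- mapSpan(map)
    if (end <= sp[1L] || start >= sp[2L])
        stopf("meanRate: region [%.0f, %.0f) does not overlap the map span",
              start, end)
    intervalCM(map, start, end) / (end - start) * 1e6
}

#' Windowed rate track from a map
#'
#' Slides a window of \code{windowBp} at \code{stepBp} steps across the map
#' span (sliding-window smoothing of rates, e.g. 250 kb windows at 10 kb
#' steps for broad-scale trends). Windows extending beyond the mapped span
#' are reported with rate \code{NA}.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param windowBp window length (bp), \code{windowBp >= stepBp > 0}.
#' @param stepBp step between window starts (bp).
#' @param from,to optional bounds for the tiling; default the map span.
#' @return a \linkS4class{RateTrack}.
#' @export
rateTrack <- function(map, windowBp, stepBp = windowBp, from = NULL,
                      to = NULL) {
    if (stepBp <= 0 || windowBp < stepBp)
        stopf("rateTrack requires windowBp >= stepBp > 0")
    sp <- mapSpan(map)
    if (is.null(from)) from <- sp[1L]
    if (is.null(to)) to <- sp[2L]
    starts <- seq(from, to - windowBp, by = stepBp)
    if (!length(starts)) stopf("rateTrack: span shorter than one window")
    ends <- starts + windowBp
    rate <- intervalCM(map, starts, ends) / windowBp * 1e6
    rate[starts < sp[1L] | ends > sp[2L]] <- NA_real_
    RateTrack(starts, ends, rate)
}

## ---------------------------------------------------------------------------
## I/O: the 2-3 column cumulative-distance dialect
## ---------------------------------------------------------------------------

#' Read a genetic map from cumulative-distance text
#'
#' Whitespace-delimited text: column 1 the physical position, columns 2+
#' cumulative genetic distance (one column per sex where two are present).
#' Lines starting with \code{#} are ignored. Distances are stored internally
#' in cM; files in Morgans are converted on input.
#'
#' @param path file path.
#' @param unit distance unit in the file: \code{"Morgans"} or \code{"cM"}.
#' @param column which cumulative column to read (2-based file column is
#'   \code{column + 1}); default 1, i.e. file column 2.
#' @param sexLabel,sourceLabel labels for the resulting map.
#' @return a \linkS4class{GeneticMap}.
#' @export
readGeneticMap <- function(path, unit = c("Morgans", "cM"), column = 1L,
                           sexLabel = "sex-averaged", sourceLabel = path) {
    unit <- match.arg(unit)
    tab <- read.table(path, header = FALSE, comment.char = "#")
    if (ncol(tab) < column + 1L)
        stopf("map file %s has no cumulative column %d", path, column)
    pos <- tab[[1L]]
    cum <- tab[[column + 1L]]
    if (length(pos) > 1L) {
        bad <- which(diff(pos) <= 0)
        if (length(bad))
            stopf("non-monotone positions in %s at row %d", path, bad[1L] + 1L)
        bad <- which(diff(cum) < 0)
        if (length(bad))
            stopf("decreasing cumulative distance in %s at row %d", path,
                  bad[1L] + 1L)
    }
    GeneticMap(pos, cum, unit = unit, sexLabel = sexLabel,
               sourceLabel = sourceLabel)
}

#' Write a genetic map in the cumulative-distance dialect
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param path output file.
#' @param unit unit to write: \code{"Morgans"} or \code{"cM"}.
#' @export
writeGeneticMap <- function(map, path, unit = c("Morgans", "cM")) {
    unit <- match.arg(unit)
    d <- map@cumulative
    if (unit == "Morgans") d <- d / 100
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# genetic map: sex=%s unit=%s", map@sexLabel, unit),
               con)
    write.table(
        data.frame(pos = format(map@positions, digits = 17,
                                scientific = FALSE, trim = TRUE),
                   cum = format(d, digits = 17, scientific = FALSE,
                                trim = TRUE)),
        con, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
    invisible(path)
}

#' Write a RateTrack as BED-like text
#'
#' Three tab-separated columns: start, end, rate (cM/Mb); \code{NA} written
#' as \code{.} in BED spirit.
#'
#' @param track a \linkS4class{RateTrack}.
#' @param path output file.
#' @export
writeRateTrack <- function(track, path) {
    rate <- ifelse(is.na(track@rate), ".",
                   format(track@rate, digits = 10, scientific = FALSE,
                          trim = TRUE))
    write.table(
        data.frame(format(track@start, digits = 17, scientific = FALSE,
                          trim = TRUE),
                   format(track@end, digits = 17, scientific = FALSE,
                          trim = TRUE), rate),
        path, quote = FALSE, row.names = FALSE, col.names = FALSE,
        sep = "\t")
    invisible(path)
}

#' Linear blend of two genetic maps
#'
#' Returns the map whose cumulative distance is
#' \code{alpha * A + (1 - alpha) * B} on the union of the two marker
#' grids, as used when modelling an admixed population's recombination as
#' a weighted average of two source-population maps.
#'
#' @param mapA,mapB \linkS4class{GeneticMap}s.
#' @param alpha weight on \code{mapA}, in [0, 1].
#' @return a \linkS4class{GeneticMap}.
#' @export
blendMaps <- function(mapA, mapB, alpha) {
    pos <- sort(unique(c(mapA@positions, mapB@positions)))
    GeneticMap(pos, alpha * cumAt(mapA, pos) + (1 - alpha) * cumAt(mapB, pos),
               sourceLabel = sprintf("blend %.3f", alpha))
}
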