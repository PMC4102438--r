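## ---------------------------------------------------------------------------
## Statistics comparing two maps, or a map against observed crossovers:
## rank correlation at scale, anchor-centred rate profiles with bootstrap
## significance, two-map mixture-weight likelihood fits, mean-squared-
## difference bootstrap, and regional rate contrasts.  All pedigree-derived
## significance resamples parents (fathers), not events.
## ---------------------------------------------------------------------------

#' MixtureWeightFit: weight of map A in the best blend of two maps
#'
#' @slot alpha weight on map A in \code{alpha * A + (1 - alpha) * B}.
#' @slot se bootstrap standard error.
#' @slot pVsHalf bootstrap p-value against an equal 0.5/0.5 blend.
#' @slot nBoot number of bootstrap replicates.
#' @slot degenerate \code{TRUE} when the two maps have identical per-bin
#'   masses, leaving the likelihood constant in alpha.
#' @slot logLik maximised log-likelihood.
#' @export
setClass("MixtureWeightFit",
    representation(alpha = "numeric", se = "numeric", pVsHalf = "numeric",
                   nBoot = "numeric", degenerate = "logical",
                   logLik = "numeric"))

setMethod("show", "MixtureWeightFit", function(object) {
    if (object@degenerate) {
        cat("MixtureWeightFit: degenerate (identical per-bin masses)\n")
    } else {
        cat(sprintf(
            "MixtureWeightFit: alpha = %.3f (s.e. %.3f), p vs 0.5 = %.3g\n",
            object@alpha, object@se, object@pVsHalf))
    }
})

#' ProfileResult: mean rate around a set of anchors
#'
#' @slot offsets bp offsets relative to the anchor midpoint (symmetric
#'   about zero).
#' @slot meanRate mean windowed rate (cM/Mb) at each offset.
#' @slot nAnchors number of anchors averaged.
#' @slot backgroundRate region-wide mean rate (cM/Mb).
#' @slot pElevation bootstrap p for central elevation (NA when not
#'   computed).
#' @export
setClass("ProfileResult",
    representation(offsets = "numeric", meanRate = "numeric",
                   nAnchors = "numeric", backgroundRate = "numeric",
                   pElevation = "numeric"))

setMethod("show", "ProfileResult", function(object) {
    mid <- which.min(abs(object@offsets))
    cat(sprintf(
        "ProfileResult: %d anchors, centre %.3g vs background %.3g cM/Mb%s\n",
        object@nAnchors, object@meanRate[mid], object@backgroundRate,
        if (is.na(object@pElevation)) "" else
            sprintf(" (p = %.3g)", object@pElevation)))
})

## shared physical span of two maps
sharedSpan <- function(mapA, mapB) {
    a <- mapSpan(mapA); b <- mapSpan(mapB)
    lo <- max(a[1L], b[1L]); hi <- min(a[2L], b[2L])
    if (hi <= lo) stopf("maps do not overlap")
    c(lo, hi)
}

#' Spearman rank correlation of two maps at a physical scale
#'
#' Tiles the shared span with non-overlapping windows of \code{scaleBp},
#' computes each map's windowed rate, and correlates the ranks. Windows
#' with a missing rate in either map are dropped. The p-value is exact for
#' nine or fewer windows, else the large-sample approximation.
#'
#' @param mapA,mapB \linkS4class{GeneticMap}s with overlapping spans.
#' @param scaleBp window size (e.g. 50000 for the 50 kb scale).
#' @return list with \code{rho}, \code{p} and \code{n} (windows used).
#' @export
spearmanAtScale <- function(mapA, mapB, scaleBp) {
    sp <- sharedSpan(mapA, mapB)
    rA <- rateTrack(mapA, scaleBp, scaleBp, from = sp[1L], to = sp[2L])
    rB <- rateTrack(mapB, scaleBp, scaleBp, from = sp[1L], to = sp[2L])
    keep <- !is.na(rA@rate) & !is.na(rB@rate)
    n <- sum(keep)
    if (n < 3L) stopf("need at least 3 complete windows, got %d", n)
    ct <- suppressWarnings(cor.test(rA@rate[keep], rB@rate[keep],
                                    method = "spearman", exact = n <= 9L))
    list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

## windowed rates at anchor + offset grid; rows anchors, cols offsets
profileMatrix <- function(map, anchors, offsets, avgWindowBp) {
    sp <- mapSpan(map)
    ctr <- outer(anchors, offsets, "+")
    lo <- ctr - avgWindowBp / 2
    hi <- ctr + avgWindowBp / 2
    r <- (cumAt(map, hi) - cumAt(map, lo)) / avgWindowBp * 1e6
    r[lo < sp[1L] | hi > sp[2L]] <- NA_real_
    matrix(r, nrow = length(anchors))
}

#' Mean rate profile around anchor points
#'
#' For each offset on a symmetric grid, averages over anchors the windowed
#' rate centred at anchor + offset (anchors are event midpoints when built
#' from crossovers). Window placements leaving the mapped span are treated
#' as missing for that anchor-offset cell.
#'
#' @param map \linkS4class{GeneticMap} supplying rates.
#' @param anchors anchor positions (bp), inside the map span.
#' @param halfWidthBp profile half-width (bp).
#' @param avgWindowBp averaging window (e.g. 2000 for 2 kb averaging).
#' @param stepBp offset grid step (e.g. 100 for 100 bp intervals).
#' @return a \linkS4class{ProfileResult}.
#' @export
profileAroundPoints <- function(map, anchors, halfWidthBp, avgWindowBp,
                                stepBp) {
    if (!length(anchors)) stopf("at least one anchor required")
    sp <- mapSpan(map)
    if (any(anchors < sp[1L] | anchors > sp[2L]))
        stopf("anchors must lie inside the map span")
    offsets <- seq(-halfWidthBp, halfWidthBp, by = stepBp)
    pm <- profileMatrix(map, anchors, offsets, avgWindowBp)
    new("ProfileResult", offsets = offsets,
        meanRate = colMeans(pm, na.rm = TRUE),
        nAnchors = length(anchors),
        backgroundRate = meanRate(map, sp[1L], sp[2L]),
        pElevation = NA_real_)
}

#' Bootstrap test for rate elevation at anchors
#'
#' Statistic: mean windowed rate centred on the anchors minus the
#' region-wide mean rate. Anchors are resampled with replacement; the
#' one-sided p for elevation is the fraction of bootstrap statistics at or
#' below zero (add-one corrected).
#'
#' @param map \linkS4class{GeneticMap}.
#' @param anchors anchor positions (>= 2).
#' @param avgWindowBp averaging window around each anchor.
#' @param nBoot bootstrap iterations (the published analysis used 5000).
#' @param seed integer seed.
#' @return list with \code{statistic} (cM/Mb), \code{p}, \code{boot}.
#' @export
bootstrapPeakTest <- function(map, anchors, avgWindowBp = 5000,
                              nBoot = 5000, seed = NULL) {
    if (length(anchors) < 2L) stopf("need at least 2 anchors")
    sp <- mapSpan(map)
    vals <- profileMatrix(map, anchors, 0, avgWindowBp)[, 1L]
    bg <- meanRate(map, sp[1L], sp[2L])
    stat <- mean(vals, na.rm = TRUE) - bg
    boot <- withSeed(seed, {
        vapply(seq_len(nBoot), function(b) {
            mean(vals[sample.int(length(vals), replace = TRUE)],
                 na.rm = TRUE) - bg
        }, numeric(1))
    })
    list(statistic = stat, p = (sum(boot <= 0) + 1) / (nBoot + 1),
         boot = boot)
}

## per-event weights over bins: event mass spread uniformly over its
## physical interval; zero-length events assign to their containing bin
eventBinWeights <- function(events, binStart, binEnd) {
    W <- matrix(0, nrow = nrow(events), ncol = length(binStart))
    for (e in seq_len(nrow(events))) {
        s <- events$start[e]; t <- events$end[e]
        if (t <= s) {
            b <- findInterval(s, binStart)
            if (b >= 1L && b <= length(binStart)) W[e, b] <- 1
            next
        }
        ov <- pmax(0, pmin(t, binEnd) - pmax(s, binStart))
        if (sum(ov) > 0) W[e, ] <- ov / (t - s)
    }
    W
}

#' Maximum-likelihood mixture weight of two maps given crossover events
#'
#' Bins the shared span (10 kb by default); the blend
#' \code{alpha * A + (1 - alpha) * B} assigns each bin a crossover
#' probability proportional to its blended genetic mass. Each event spreads
#' its mass uniformly (by physical length) over the bins its interval
#' covers; \code{alpha} maximises the summed event log-likelihood by 1-D
#' search on [0, 1]. Standard error and the p-value against 0.5 come from
#' bootstrap over parents (fathers), not events.
#'
#' @param events event data.frame (columns parent, start, end).
#' @param mapA,mapB candidate \linkS4class{GeneticMap}s covering the span.
#' @param binBp bin width (default 10000).
#' @param nBoot bootstrap replicates over parents.
#' @param seed integer seed.
#' @return a \linkS4class{MixtureWeightFit}.
#' @export
fitMixtureWeight <- function(events, mapA, mapB, binBp = 10000,
                             nBoot = 200, seed = NULL) {
    if (nrow(events) < 10L) stopf("need at least 10 events")
    sp <- sharedSpan(mapA, mapB)
    binStart <- seq(sp[1L], sp[2L] - binBp, by = binBp)
    binEnd <- binStart + binBp
    mA <- intervalCM(mapA, binStart, binEnd)
    mB <- intervalCM(mapB, binStart, binEnd)
    pA <- mA / sum(mA)
    pB <- mB / sum(mB)
    degenerate <- max(abs(pA - pB)) < 1e-12
    W <- eventBinWeights(events, binStart, binEnd)
    fit1 <- function(rows) {
        Wr <- W[rows, , drop = FALSE]
        negll <- function(a) {
            p <- a * mA + (1 - a) * mB
            p <- p / sum(p)
            -sum(log(pmax(Wr %*% p, 1e-300)))
        }
        optimize(negll, c(0, 1))
    }
    if (degenerate) {
        return(new("MixtureWeightFit", alpha = NA_real_, se = NA_real_,
                   pVsHalf = NA_real_, nBoot = 0, degenerate = TRUE,
                   logLik = -fit1(seq_len(nrow(W)))$objective))
    }
    opt <- fit1(seq_len(nrow(W)))
    if (nBoot <= 0)
        return(new("MixtureWeightFit", alpha = opt$minimum, se = NA_real_,
                   pVsHalf = NA_real_, nBoot = 0, degenerate = FALSE,
                   logLik = -opt$objective))
    byParent <- split(seq_len(nrow(events)), events$parent)
    boot <- withSeed(seed, {
        vapply(seq_len(nBoot), function(b) {
            rows <- unlist(byParent[sample.int(length(byParent),
                                               replace = TRUE)])
            fit1(rows)$minimum
        }, numeric(1))
    })
    pHalf <- min(1, 2 * min((sum(boot <= 0.5) + 1) / (nBoot + 1),
                            (sum(boot >= 0.5) + 1) / (nBoot + 1)))
    new("MixtureWeightFit", alpha = opt$minimum, se = sd(boot),
        pVsHalf = pHalf, nBoot = nBoot, degenerate = FALSE,
        logLik = -opt$objective)
}

## rate track (cM/Mb) implied by a set of events over fixed windows
eventsRate <- function(events, binStart, binEnd, nMeioses) {
    W <- eventBinWeights(events, binStart, binEnd)
    mass <- colSums(W * events$mass)
    mass / nMeioses * 100 / ((binEnd - binStart) / 1e6)
}

#' Mean-squared-difference bootstrap: which candidate map is closer?
#'
#' Resamples parents (fathers) with replacement, builds a windowed rate
#' track from their events, and computes the mean squared difference (MSD)
#' against each candidate map. Returns the fraction of bootstraps in which
#' map A is closer than map B (ties split evenly, so swapping A and B maps
#' the fraction f to 1 - f exactly) and the implied one-sided p for A being
#' closer.
#'
#' @param events event data.frame (columns parent, start, end, mass).
#' @param mapA,mapB candidate \linkS4class{GeneticMap}s.
#' @param scaleBp comparison window size.
#' @param nBoot bootstrap replicates.
#' @param nMeioses meioses the events came from (scales the pedigree rate);
#'   defaults to the number of distinct parents.
#' @param seed integer seed.
#' @return list with \code{fraction}, \code{p}, \code{msdA}, \code{msdB}.
#' @export
msdBootstrap <- function(events, mapA, mapB, scaleBp = 10000, nBoot = 200,
                         nMeioses = NULL, seed = NULL) {
    if (nrow(events) < 10L) stopf("need at least 10 events")
    sp <- sharedSpan(mapA, mapB)
    binStart <- seq(sp[1L], sp[2L] - scaleBp, by = scaleBp)
    binEnd <- binStart + scaleBp
    rA <- intervalCM(mapA, binStart, binEnd) / scaleBp * 1e6
    rB <- intervalCM(mapB, binStart, binEnd) / scaleBp * 1e6
    byParent <- split(seq_len(nrow(events)), events$parent)
    if (is.null(nMeioses)) nMeioses <- length(byParent)
    msdA0 <- msdB0 <- numeric(nBoot)
    res <- withSeed(seed, {
        for (b in seq_len(nBoot)) {
            rows <- unlist(byParent[sample.int(length(byParent),
                                               replace = TRUE)])
            rP <- eventsRate(events[rows, , drop = FALSE], binStart, binEnd,
                             nMeioses)
            msdA0[b] <- mean((rP - rA)^2)
            msdB0[b] <- mean((rP - rB)^2)
        }
        list(msdA = msdA0, msdB = msdB0)
    })
    f <- mean((res$msdA < res$msdB) + 0.5 * (res$msdA == res$msdB))
    list(fraction = f, p = 1 - f, msdA = res$msdA, msdB = res$msdB)
}

#' Compare crossover rates between two regions
#'
#' Per-region rate is summed event mass in the region divided by (meioses x
#' region length), in cM/Mb. Significance of the difference comes from
#' bootstrap over parents.
#'
#' @param events event data.frame (columns parent, start, end, mass).
#' @param nMeioses number of meioses of the relevant sex.
#' @param regionA,regionB numeric length-2 bp intervals, disjoint, inside
#'   \code{coverage}.
#' @param coverage numeric length-2 marker-coverage span.
#' @param nBoot bootstrap replicates.
#' @param seed integer seed.
#' @return list with \code{rateA}, \code{rateB}, \code{diff}, \code{p}.
#' @export
regionRateDifference <- function(events, nMeioses, regionA, regionB,
                                 coverage, nBoot = 200, seed = NULL) {
    regs <- list(regionA, regionB)
    for (r in regs)
        if (r[1L] < coverage[1L] || r[2L] > coverage[2L])
            stopf("region [%.0f, %.0f) outside marker coverage", r[1L],
                  r[2L])
    if (max(regionA[1L], regionB[1L]) < min(regionA[2L], regionB[2L]))
        stopf("regions must be disjoint")
    regionMass <- function(ev, r) {
        if (!nrow(ev)) return(0)
        len <- pmax(ev$end - ev$start, 1e-9)
        ov <- pmax(0, pmin(ev$end, r[2L]) - pmax(ev$start, r[1L]))
        ## zero-length events: in or out
        pt <- ev$end <= ev$start
        frac <- ifelse(pt, as.numeric(ev$start >= r[1L] & ev$start < r[2L]),
                       ov / len)
        sum(ev$mass * frac)
    }
    rate <- function(ev, r)
        regionMass(ev, r) / nMeioses * 100 / ((r[2L] - r[1L]) / 1e6)
    rateA <- rate(events, regionA)
    rateB <- rate(events, regionB)
    byParent <- split(seq_len(nrow(events)), events$parent)
    boot <- withSeed(seed, {
        vapply(seq_len(nBoot), function(b) {
            rows <- unlist(byParent[sample.int(length(byParent),
                                               replace = TRUE)])
            ev <- events[rows, , drop = FALSE]
            rate(ev, regionA) - rate(ev, regionB)
        }, numeric(1))
    })
    list(rateA = rateA, rateB = rateB, diff = rateA - rateB,
         p = bootP(rateA - rateB, boot, "two.sided"))
}

#' Write a rate profile as tabular text
#'
#' Three tab-separated columns: offset (bp), mean rate (cM/Mb), number of
#' anchors averaged.
#'
#' @param profile a \linkS4class{ProfileResult}.
#' @param path output file.
#' @export
writeProfile <- function(profile, path) {
    write.table(data.frame(offset = profile@offsets,
                           meanRate = profile@meanRate,
                           n = profile@nAnchors),
                path, quote = FALSE, row.names = FALSE, col.names = FALSE,
                sep = "\t")
    invisible(path)
}
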