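## ---------------------------------------------------------------------------
## GC-biased gene conversion statistics on polarized variants: six-class
## classification with CpG flagging, binned allele-frequency spectra,
## extreme-bin and quantile-quantile comparisons, the near-fixation bias
## ratio, the U-shaped mixture estimate of extremely active motifs, and an
## AFS-percentile recombination-map estimate.
##
## A variant is a site with ancestral allele assigned from the outgroup
## (chimpanzee) state and a derived-allele frequency strictly inside (0,1).
## CpG-context sites are excluded from all statistics by default because
## methyl-C deamination dominates their mutation process.
## ---------------------------------------------------------------------------

#' AFSpectrum: binned derived-allele-frequency spectrum
#'
#' @slot binEdges bin boundaries partitioning (0, 1).
#' @slot counts sites per bin.
#' @slot classLabel the variant class(es) counted.
#' @export
setClass("AFSpectrum",
    representation(binEdges = "numeric", counts = "numeric",
                   classLabel = "character"))

setValidity("AFSpectrum", function(object) {
    if (length(object@counts) + 1L != length(object@binEdges))
        return("need one more bin edge than counts")
    if (any(object@counts < 0)) return("counts must be non-negative")
    if (is.unsorted(object@binEdges, strictly = TRUE))
        return("bin edges must be strictly increasing")
    TRUE
})

setMethod("show", "AFSpectrum", function(object) {
    cat(sprintf("AFSpectrum (%s): %d sites in %d bins\n",
                paste(object@classLabel, collapse = "+"),
                sum(object@counts), length(object@counts)))
})

#' @rdname AFSpectrum-class
#' @param x an \code{AFSpectrum}.
#' @export
spectrumCounts <- function(x) x@counts

#' BiasEstimate: near-fixation count ratio AT->GC : GC->AT
#'
#' @slot ratio count ratio (possibly \code{Inf} when no GC->AT site is in
#'   the band).
#' @slot pValue binomial test of the in-band split against 0.5.
#' @slot band the derived-allele-frequency band used.
#' @slot nGC,nAT in-band counts of GC-gaining and GC-losing sites.
#' @export
setClass("BiasEstimate",
    representation(ratio = "numeric", pValue = "numeric", band = "numeric",
                   nGC = "numeric", nAT = "numeric"))

setMethod("show", "BiasEstimate", function(object) {
    cat(sprintf(
        "BiasEstimate: %.3g (%d GC-gaining vs %d GC-losing in [%.2f, %.2f)), p = %.3g\n",
        object@ratio, object@nGC, object@nAT, object@band[1L],
        object@band[2L], object@pValue))
})

#' UMixtureFit: weight of the U-shaped component in a spectrum
#'
#' @slot lambda weight on the symmetric U component.
#' @slot ci bootstrap confidence interval (2.5/97.5 percentiles).
#' @slot logLik maximised binned multinomial log-likelihood.
#' @slot nBoot bootstrap replicates.
#' @export
setClass("UMixtureFit",
    representation(lambda = "numeric", ci = "numeric", logLik = "numeric",
                   nBoot = "numeric"))

setMethod("show", "UMixtureFit", function(object) {
    cat(sprintf("UMixtureFit: lambda = %.3f [%.3f, %.3f]\n", object@lambda,
                object@ci[1L], object@ci[2L]))
})

## the two pooled strong/weak class groups
gcGainClasses <- c("AT.GC.ts", "AT.GC.tv")
gcLossClasses <- c("GC.AT.ts", "GC.AT.tv")

#' Classify polarized variants into the six mutation classes
#'
#' Classes: AT->GC transitions and transversions (GC-gaining), GC->AT
#' transitions and transversions (GC-losing), and the GC-conservative
#' A<->T and C<->G transversions. A site is CpG-flagged iff the ancestral
#' or derived base forms a CpG dinucleotide with its flanking context
#' (equivalent on either strand, since CpG is its own reverse complement).
#'
#' @param anc,der ancestral and derived bases (vectors over A/C/G/T).
#' @param left,right flanking bases.
#' @return data.frame with columns \code{mclass} (see
#'   \code{\link{afsClasses}}) and \code{cpg}.
#' @export
classifyVariants <- function(anc, der, left, right) {
    anc <- toupper(anc); der <- toupper(der)
    left <- toupper(left); right <- toupper(right)
    ok <- c("A", "C", "G", "T")
    if (!all(c(anc, der, left, right) %in% ok))
        stopf("bases must be A, C, G or T")
    if (any(anc == der)) stopf("ancestral and derived alleles must differ")
    key <- paste0(anc, der)
    lut <- c(AG = "AT.GC.ts", TC = "AT.GC.ts", AC = "AT.GC.tv",
             TG = "AT.GC.tv", GA = "GC.AT.ts", CT = "GC.AT.ts",
             GT = "GC.AT.tv", CA = "GC.AT.tv", AT = "A.T", TA = "A.T",
             CG = "C.G", GC = "C.G")
    cpg <- (anc == "C" & right == "G") | (anc == "G" & left == "C") |
           (der == "C" & right == "G") | (der == "G" & left == "C")
    data.frame(mclass = unname(lut[key]), cpg = cpg,
               stringsAsFactors = FALSE)
}

## apply the standard site filters used by every AFS statistic
filterVariants <- function(variants, classes = NULL, mafMin = 0.01,
                           excludeCpG = TRUE) {
    keep <- variants$daf > 0 & variants$daf < 1 &
        pmin(variants$daf, 1 - variants$daf) >= mafMin
    if (excludeCpG) keep <- keep & !variants$cpg
    if (!is.null(classes)) keep <- keep & variants$mclass %in% classes
    variants[keep, , drop = FALSE]
}

#' Binned derived-allele-frequency spectrum for a variant class
#'
#' @param variants data.frame with columns daf, mclass, cpg (as produced
#'   by \code{\link{simAfsVariants}} or assembled from
#'   \code{\link{classifyVariants}}).
#' @param classes class label(s) to pool (see \code{\link{afsClasses}}).
#' @param binWidth frequency bin width (default 0.10, matching the
#'   published >90\%/<10\% tails).
#' @param mafMin minor-allele-frequency inclusion cutoff.
#' @param excludeCpG drop CpG-flagged sites (default).
#' @return an \linkS4class{AFSpectrum}.
#' @export
buildSpectrum <- function(variants, classes, binWidth = 0.10,
                          mafMin = 0.01, excludeCpG = TRUE) {
    if (!all(classes %in% afsClasses))
        stopf("unknown variant class: %s",
              paste(setdiff(classes, afsClasses), collapse = ", "))
    v <- filterVariants(variants, classes, mafMin, excludeCpG)
    edges <- seq(0, 1, by = binWidth)
    if (edges[length(edges)] < 1) edges <- c(edges, 1)
    cnt <- as.numeric(table(cut(v$daf, edges, right = FALSE,
                                include.lowest = FALSE)))
    new("AFSpectrum", binEdges = edges, counts = cnt,
        classLabel = classes)
}

#' Compare the extreme bins of two spectra
#'
#' \code{delta} is the difference in the fraction of sites falling in the
#' chosen tail bin; significance comes from a two-sided exact test on the
#' 2x2 table (in-tail vs not, spectrum A vs B).
#'
#' @param specA,specB \linkS4class{AFSpectrum}s on identical bins.
#' @param tail \code{"top"} (highest bin) or \code{"bottom"}.
#' @return list with \code{delta}, \code{p}, \code{fracA}, \code{fracB}.
#' @export
compareExtremeBins <- function(specA, specB, tail = c("top", "bottom")) {
    tail <- match.arg(tail)
    if (!identical(specA@binEdges, specB@binEdges))
        stopf("spectra must share bin edges")
    tA <- sum(specA@counts); tB <- sum(specB@counts)
    if (tA == 0 || tB == 0) stopf("empty spectrum")
    b <- if (tail == "top") length(specA@counts) else 1L
    inA <- specA@counts[b]; inB <- specB@counts[b]
    ft <- fisher.test(matrix(c(inA, tA - inA, inB, tB - inB), nrow = 2L))
    list(delta = inA / tA - inB / tB, p = ft$p.value, fracA = inA / tA,
         fracB = inB / tB)
}

#' Quantile-quantile comparison of two frequency samples
#'
#' Matched quantiles of two derived-allele-frequency samples, plus a
#' rank-based two-sample location test (Wilcoxon) for a shift.
#'
#' @param dafA,dafB numeric frequency samples (x- and y-axis).
#' @param probs quantile grid.
#' @return list with \code{quantiles} (data.frame prob, x, y) and
#'   \code{pShift}.
#' @export
qqCompare <- function(dafA, dafB, probs = seq(0.01, 0.99, by = 0.01)) {
    if (!length(dafA) || !length(dafB)) stopf("empty frequency sample")
    list(quantiles = data.frame(prob = probs,
                                x = quantile(dafA, probs, names = FALSE),
                                y = quantile(dafB, probs, names = FALSE)),
         pShift = suppressWarnings(wilcox.test(dafA, dafB)$p.value))
}

#' Fixation-bias estimate from near-fixation counts
#'
#' Counts GC-gaining (AT->GC, transitions and transversions pooled) and
#' GC-losing (GC->AT) segregating sites with derived-allele frequency in
#' the band and returns their ratio; equal fixation pressure gives 1. The
#' p-value is a two-sided binomial test of the in-band split against 0.5
#' (one-sided when the denominator is empty and the ratio infinite).
#'
#' @param variants variant data.frame (daf, mclass, cpg).
#' @param band frequency band, default [0.95, 1).
#' @param mafMin,excludeCpG site filters (see \code{\link{buildSpectrum}}).
#' @return a \linkS4class{BiasEstimate}.
#' @export
fixationBias <- function(variants, band = c(0.95, 1.0), mafMin = 0.01,
                         excludeCpG = TRUE) {
    v <- filterVariants(variants, c(gcGainClasses, gcLossClasses), mafMin,
                        excludeCpG)
    inBand <- v$daf >= band[1L] & v$daf < band[2L]
    nGC <- sum(inBand & v$mclass %in% gcGainClasses)
    nAT <- sum(inBand & v$mclass %in% gcLossClasses)
    if (nGC + nAT == 0L) stopf("no sites in the frequency band")
    if (nAT == 0L) {
        p <- binom.test(nGC, nGC, p = 0.5,
                        alternative = "greater")$p.value
        return(new("BiasEstimate", ratio = Inf, pValue = p, band = band,
                   nGC = nGC, nAT = nAT))
    }
    p <- binom.test(nGC, nGC + nAT, p = 0.5)$p.value
    new("BiasEstimate", ratio = nGC / nAT, pValue = p, band = band,
        nGC = nGC, nAT = nAT)
}

#' Fit the U-shaped mixture weight of a target spectrum
#'
#' Models the target spectrum as \code{lambda * U + (1 - lambda) *
#' background}, where U places equal mass 0.5/0.5 on the lowest and highest
#' frequency bins (derived alleles either newly arisen or nearly fixed) and
#' the background is the region-wide spectrum. \code{lambda} maximises the
#' binned multinomial log-likelihood; the confidence interval comes from
#' bootstrap resampling of target sites.
#'
#' @param target,background \linkS4class{AFSpectrum}s on identical bins;
#'   the background must be non-degenerate.
#' @param nBoot bootstrap replicates.
#' @param seed integer seed.
#' @return a \linkS4class{UMixtureFit}.
#' @export
fitUMixture <- function(target, background, nBoot = 200, seed = NULL) {
    if (!identical(target@binEdges, background@binEdges))
        stopf("spectra must share bin edges")
    nT <- sum(target@counts)
    if (nT == 0 || sum(background@counts) == 0)
        stopf("empty spectrum")
    bg <- background@counts / sum(background@counts)
    nb <- length(bg)
    U <- numeric(nb); U[c(1L, nb)] <- 0.5
    if (any(target@counts > 0 & bg == 0 & U == 0))
        stopf("target occupies bins with no background or U support")
    fit1 <- function(cnt) {
        negll <- function(l) {
            p <- l * U + (1 - l) * bg
            -sum(cnt[cnt > 0] * log(pmax(p[cnt > 0], 1e-300)))
        }
        ## profile on a grid then polish: the likelihood can touch the
        ## boundary at 0 or 1
        grid <- seq(0, 1, by = 0.01)
        ll <- vapply(grid, negll, numeric(1))
        g0 <- grid[which.min(ll)]
        o <- optimize(negll, c(max(0, g0 - 0.02), min(1, g0 + 0.02)))
        if (negll(g0) < o$objective) list(minimum = g0,
                                          objective = negll(g0)) else o
    }
    opt <- fit1(target@counts)
    ci <- c(NA_real_, NA_real_)
    if (nBoot > 0) {
        boot <- withSeed(seed, {
            pT <- target@counts / nT
            vapply(seq_len(nBoot), function(b)
                fit1(as.numeric(rmultinom(1L, nT, pT)))$minimum,
                numeric(1))
        })
        ci <- unname(quantile(boot, c(0.025, 0.975)))
    }
    new("UMixtureFit", lambda = opt$minimum, ci = ci,
        logLik = -opt$objective, nBoot = nBoot)
}

#' Allele-frequency spectra by distance band around anchors
#'
#' For each radius r, takes variants within r bp of any anchor and builds
#' GC-gaining and GC-losing spectra; shift tests against the whole region
#' use the rank-based \code{\link{qqCompare}} p-value on the raw
#' frequencies.
#'
#' @param variants variant data.frame (pos, daf, mclass, cpg).
#' @param anchors an \linkS4class{AnchorSet} or numeric anchor positions.
#' @param radii distance bands in bp (default 25 and 500).
#' @param mafMin,excludeCpG site filters.
#' @return list per radius (named by radius) with \code{n}, spectra for
#'   the GC-gaining and GC-losing groups, and \code{pGainVsWhole} /
#'   \code{pLossVsWhole}; bands with no variants are omitted with a
#'   warning.
#' @export
nearAnchorAFS <- function(variants, anchors, radii = c(25, 500),
                          mafMin = 0.01, excludeCpG = TRUE) {
    apos <- if (is(anchors, "AnchorSet")) anchors@positions else
        sort(as.numeric(anchors))
    if (!length(apos)) stopf("no anchors supplied")
    v <- filterVariants(variants, c(gcGainClasses, gcLossClasses), mafMin,
                        excludeCpG)
    ## distance to nearest anchor
    idx <- findInterval(v$pos, apos)
    dLeft <- ifelse(idx >= 1L, v$pos - apos[pmax(idx, 1L)], Inf)
    dRight <- ifelse(idx < length(apos), apos[pmin(idx + 1L,
        length(apos))] - v$pos, Inf)
    dist <- pmin(dLeft, dRight)
    wholeGain <- v$daf[v$mclass %in% gcGainClasses]
    wholeLoss <- v$daf[v$mclass %in% gcLossClasses]
    out <- list()
    for (r in radii) {
        sel <- dist <= r
        if (!any(sel)) {
            warning(sprintf("no variants within %g bp of an anchor; band omitted", r))
            next
        }
        vb <- v[sel, , drop = FALSE]
        bandGain <- vb$daf[vb$mclass %in% gcGainClasses]
        bandLoss <- vb$daf[vb$mclass %in% gcLossClasses]
        out[[as.character(r)]] <- list(
            radius = r, n = nrow(vb),
            gainSpectrum = buildSpectrum(vb, gcGainClasses, mafMin = 0,
                                         excludeCpG = FALSE),
            lossSpectrum = buildSpectrum(vb, gcLossClasses, mafMin = 0,
                                         excludeCpG = FALSE),
            pGainVsWhole = if (length(bandGain) && length(wholeGain))
                qqCompare(wholeGain, bandGain)$pShift else NA_real_,
            pLossVsWhole = if (length(bandLoss) && length(wholeLoss))
                qqCompare(wholeLoss, bandLoss)$pShift else NA_real_)
    }
    out
}

#' Estimate a recombination map from AFS percentiles
#'
#' Per window, the predictor is the 70th percentile of the derived-allele
#' frequency of GC-gaining (AT->GC) variants; a straight-line fit of the
#' reference-map window rates on this predictor yields fitted rates, which
#' are then smoothed (250 kb windows at 10 kb steps by default).
#'
#' @param variants variant data.frame (pos, daf, mclass, cpg).
#' @param windowBp predictor window size.
#' @param stepBp predictor window step.
#' @param referenceMap \linkS4class{GeneticMap} supplying the response.
#' @param minVariants minimum qualifying variants per window (default 10).
#' @param prob percentile used as predictor (default 0.7).
#' @param smoothBp,smoothStepBp smoothing of the output track.
#' @return list with \code{track} (\linkS4class{RateTrack} of smoothed
#'   fitted rates), \code{fit} (the lm), and \code{windows} (per-window
#'   predictor/response table).
#' @export
estimateMapFromAFS <- function(variants, windowBp, stepBp, referenceMap,
                               minVariants = 10, prob = 0.7,
                               smoothBp = 250000, smoothStepBp = 10000) {
    sp <- mapSpan(referenceMap)
    v <- filterVariants(variants, gcGainClasses)
    starts <- seq(sp[1L], sp[2L] - windowBp, by = stepBp)
    ends <- starts + windowBp
    pred <- resp <- rep(NA_real_, length(starts))
    for (i in seq_along(starts)) {
        daf <- v$daf[v$pos >= starts[i] & v$pos < ends[i]]
        if (length(daf) >= minVariants) {
            pred[i] <- quantile(daf, prob, names = FALSE)
            resp[i] <- meanRate(referenceMap, starts[i], ends[i])
        }
    }
    ok <- !is.na(pred)
    if (sum(ok) < 20L)
        stopf("need >= 20 windows with >= %d qualifying variants",
              minVariants)
    win <- data.frame(start = starts[ok], end = ends[ok],
                      predictor = pred[ok], rate = resp[ok])
    if (sd(win$predictor) < 1e-12) {
        warning("degenerate (constant) predictor; returning a flat map")
        fitted <- rep(mean(win$rate), nrow(win))
        fit <- NULL
    } else {
        fit <- lm(rate ~ predictor, data = win)
        fitted <- pmax(fit$fitted.values, 0)
    }
    win$fitted <- fitted
    ## smooth fitted window rates to the output grid
    ctr <- (win$start + win$end) / 2
    sStart <- seq(sp[1L], sp[2L] - smoothBp, by = smoothStepBp)
    sEnd <- sStart + smoothBp
    sm <- vapply(seq_along(sStart), function(i) {
        inWin <- ctr >= sStart[i] & ctr < sEnd[i]
        if (any(inWin)) mean(win$fitted[inWin]) else NA_real_
    }, numeric(1))
    list(track = RateTrack(sStart, sEnd, sm), fit = fit, windows = win)
}

## ---------------------------------------------------------------------------
## Variant I/O
## ---------------------------------------------------------------------------

#' Read polarized variants from tabular text
#'
#' Whitespace-delimited columns: position, ancestral base, derived base,
#' derived-allele frequency, left flank, right flank (lines starting with
#' \code{#} ignored). Classification and CpG flagging are applied on
#' ingest.
#'
#' @param path file path.
#' @return variant data.frame (pos, anc, der, left, right, daf, mclass,
#'   cpg) as consumed by the spectrum and bias functions.
#' @export
readPolarizedVariants <- function(path) {
    tab <- read.table(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 6L)
        stopf("expected 6 columns: pos anc der daf left right")
    cl <- classifyVariants(tab[[2L]], tab[[3L]], tab[[5L]], tab[[6L]])
    data.frame(pos = tab[[1L]], anc = toupper(tab[[2L]]),
               der = toupper(tab[[3L]]), left = toupper(tab[[5L]]),
               right = toupper(tab[[6L]]), daf = tab[[4L]],
               mclass = cl$mclass, cpg = cl$cpg,
               stringsAsFactors = FALSE)
}

#' Write polarized variants as tabular text
#'
#' @param variants variant data.frame.
#' @param path output file.
#' @export
writePolarizedVariants <- function(variants, path) {
    write.table(variants[, c("pos", "anc", "der", "daf", "left", "right")],
                path, quote = FALSE, row.names = FALSE, col.names = FALSE,
                sep = "\t")
    invisible(path)
}

#' Read polarized variants from a VCF with an ancestral-allele tag
#'
#' Biallelic SNVs with an \code{AA} INFO tag are polarized against the
#' ancestral allele: when AA equals the ALT allele, REF is derived and
#' the derived-allele frequency is \code{1 - AF}. Flanking context is
#' looked up in \code{reference}. Requires the \pkg{vcfR} package.
#'
#' @param path VCF file (uncompressed or gzipped).
#' @param reference a \code{DNAString} (or character string) holding the
#'   reference sequence of the region, 1-based at \code{POS}.
#' @param afTag INFO tag holding the ALT allele frequency (default
#'   \code{"AF"}).
#' @return variant data.frame as from \code{\link{readPolarizedVariants}};
#'   sites with AA matching neither allele are dropped. Positions are
#'   converted to the package's 0-based convention.
#' @export
readPolarizedVcf <- function(path, reference, afTag = "AF") {
    if (!requireNamespace("vcfR", quietly = TRUE))
        stopf("readPolarizedVcf requires the vcfR package")
    refChars <- if (is(reference, "DNAString"))
        strsplit(as.character(reference), "")[[1L]] else
        strsplit(toupper(reference), "")[[1L]]
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    pos <- as.numeric(fix$POS)
    ref <- toupper(fix$REF)
    alt <- toupper(fix$ALT)
    aa <- toupper(vcfR::extract.info(v, "AA"))
    af <- suppressWarnings(as.numeric(vcfR::extract.info(v, afTag)))
    bases <- c("A", "C", "G", "T")
    keep <- ref %in% bases & alt %in% bases & aa %in% bases &
        (aa == ref | aa == alt) & !is.na(af) & pos > 1 &
        pos < length(refChars)
    if (!any(keep))
        stopf("no polarizable biallelic SNVs with AA/%s in %s", afTag,
              path)
    pos <- pos[keep]; ref <- ref[keep]; alt <- alt[keep]
    aa <- aa[keep]; af <- af[keep]
    anc <- aa
    der <- ifelse(aa == ref, alt, ref)
    daf <- ifelse(aa == ref, af, 1 - af)
    left <- refChars[pos - 1L]
    right <- refChars[pos + 1L]
    cl <- classifyVariants(anc, der, left, right)
    data.frame(pos = pos - 1L, anc = anc, der = der, left = left,
               right = right, daf = daf, mclass = cl$mclass,
               cpg = cl$cpg, stringsAsFactors = FALSE)
}
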