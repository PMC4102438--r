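## ---------------------------------------------------------------------------
## Human-chimpanzee substitution analysis: 2-kb window construction with
## validity/divergence filters, six-class substitution counting with CpG
## exclusion in either species, per-class OLS regression on recombination
## rate, hotspot/coldspot excess estimation and stepwise-AIC rate
## prediction.
##
## Substitution direction cannot be polarized without a usable outgroup, so
## classes are keyed (chimp state -> human state); see
## \code{\link{substClasses}}.
## ---------------------------------------------------------------------------

#' RegressionResult: recombination-rate effect on a substitution class
#'
#' @slot effect substitution-rate change per 10 cM/Mb.
#' @slot se standard error of the effect.
#' @slot p two-sided p-value.
#' @slot covariates covariates included in the model.
#' @slot targetClass the dependent substitution class.
#' @export
setClass("RegressionResult",
    representation(effect = "numeric", se = "numeric", p = "numeric",
                   covariates = "character", targetClass = "character"))

setMethod("show", "RegressionResult", function(object) {
    cat(sprintf(
        "RegressionResult (%s): %.4g%% per 10 cM/Mb (s.e. %.2g%%), p = %.3g\n",
        object@targetClass, 100 * object@effect, 100 * object@se,
        object@p))
})

#' ExcessEstimate: substitution-rate excess of a rate stratum
#'
#' @slot excess per-base rate difference versus intermediate windows.
#' @slot bootDist bootstrap draws of the excess.
#' @slot p two-sided bootstrap p for a nonzero excess.
#' @export
setClass("ExcessEstimate",
    representation(excess = "numeric", bootDist = "numeric", p = "numeric"))

setMethod("show", "ExcessEstimate", function(object) {
    cat(sprintf("ExcessEstimate: %+.3g%% per base (p = %.3g)\n",
                100 * object@excess, object@p))
})

subPairClass <- local({
    lut <- c(AG = "ATGCts", TC = "ATGCts", GA = "GCATts", CT = "GCATts",
             GC = "GCCG", CG = "GCCG", GT = "GCTA", CA = "GCTA",
             AC = "ATCG", TG = "ATCG", AT = "ATTA", TA = "ATTA")
    function(chimp, human) unname(lut[paste0(chimp, human)])
})

#' Count substitution classes in an aligned sequence pair
#'
#' Each mismatching position is assigned to one of the six classes keyed
#' (chimp state -> human state); mismatches in a CpG dinucleotide context
#' in either species are excluded (methyl-C deamination), and positions
#' with a non-ACGT base at a mismatch are skipped.
#'
#' @param human,chimp equal-length character vectors of aligned bases
#'   (single characters; gaps or ambiguity codes allowed and treated as
#'   invalid).
#' @param valid optional logical vector of positions usable at all
#'   (e.g. unmasked); defaults to both bases being ACGT.
#' @return list with \code{counts} (named per \code{\link{substClasses}}),
#'   \code{cpgExcluded}, \code{matches}, \code{skipped} and
#'   \code{validBases}.
#' @export
countSubstitutionClasses <- function(human, chimp, valid = NULL) {
    if (length(human) != length(chimp))
        stopf("aligned sequences must have equal length")
    ok <- c("A", "C", "G", "T")
    isB <- function(x) x %in% ok
    baseOk <- isB(human) & isB(chimp)
    if (is.null(valid)) valid <- baseOk
    valid <- valid & baseOk
    mism <- valid & human != chimp
    ## CpG context in either species: focal C followed by G, or focal G
    ## preceded by C, on the species' own sequence
    n <- length(human)
    nxt <- c(human[-1L], "N"); prv <- c("N", human[-n])
    cpgH <- (human == "C" & nxt == "G") | (human == "G" & prv == "C")
    nxtC <- c(chimp[-1L], "N"); prvC <- c("N", chimp[-n])
    cpgC <- (chimp == "C" & nxtC == "G") | (chimp == "G" & prvC == "C")
    cpg <- cpgH | cpgC
    counted <- mism & !cpg
    cls <- subPairClass(chimp[counted], human[counted])
    counts <- setNames(numeric(length(substClasses)), substClasses)
    if (length(cls)) {
        tab <- table(cls)
        counts[names(tab)] <- as.numeric(tab)
    }
    list(counts = counts, cpgExcluded = sum(mism & cpg),
         matches = sum(valid & human == chimp),
         skipped = sum(!baseOk & if (is.null(valid)) TRUE else valid),
         validBases = sum(valid))
}

#' Build and filter aligned 2-kb windows
#'
#' Divides the alignment into a fixed grid of \code{windowBp} windows and
#' keeps windows with at least \code{minValid} aligned, unmasked, gap-free
#' bases and total divergence at most \code{maxDivergence}; windows outside
#' the map span are dropped. Each kept window carries its six class counts
#' (CpG-context mismatches excluded), GC and CpG content of the human
#' sequence, and the mean recombination rate from the supplied map.
#'
#' @param human,chimp aligned sequences: equal-length single character
#'   strings, \code{DNAString}s, or character vectors of bases. Gaps and
#'   masked bases should be non-ACGT characters (e.g. \code{-}, \code{N}).
#' @param map \linkS4class{GeneticMap} for window rates.
#' @param mask optional logical vector, \code{TRUE} = masked out.
#' @param offset genomic coordinate of alignment position 1.
#' @param windowBp window size (default 2000).
#' @param minValid minimum usable bases per window (default 1000).
#' @param maxDivergence maximum mismatch fraction (default 0.05).
#' @return data.frame of windows: start, end, validBases, six class count
#'   columns, cpgExcluded, gcFrac, cpgFrac, rate.
#' @export
alignmentWindows <- function(human, chimp, map, mask = NULL, offset = 0,
                             windowBp = 2000, minValid = 1000,
                             maxDivergence = 0.05) {
    toChars <- function(x) {
        if (is(x, "DNAString")) x <- as.character(x)
        if (length(x) == 1L && nchar(x) > 1L)
            x <- strsplit(x, "")[[1L]]
        toupper(x)
    }
    h <- toChars(human); c0 <- toChars(chimp)
    if (length(h) != length(c0))
        stopf("human and chimp sequences must align position by position")
    usable <- if (is.null(mask)) rep(TRUE, length(h)) else !mask
    sp <- mapSpan(map)
    nWin <- floor(length(h) / windowBp)
    out <- list()
    for (w in seq_len(nWin)) {
        i0 <- (w - 1L) * windowBp + 1L
        idx <- i0:(i0 + windowBp - 1L)
        start <- offset + i0 - 1L
        end <- start + windowBp
        if (start < sp[1L] || end > sp[2L]) next
        cc <- countSubstitutionClasses(h[idx], c0[idx], usable[idx])
        if (cc$validBases < minValid) next
        div <- (sum(cc$counts) + cc$cpgExcluded) / cc$validBases
        if (div > maxDivergence) next
        hv <- h[idx][usable[idx] & h[idx] %in% c("A", "C", "G", "T")]
        gc <- mean(hv %in% c("G", "C"))
        nxt <- c(h[idx][-1L], "N")
        cpgN <- sum(h[idx] == "C" & nxt == "G")
        row <- data.frame(start = start, end = end,
                          validBases = cc$validBases)
        for (cl in substClasses) row[[cl]] <- cc$counts[[cl]]
        row$cpgExcluded <- cc$cpgExcluded
        row$gcFrac <- gc
        row$cpgFrac <- cpgN / max(length(hv), 1L)
        row$rate <- meanRate(map, start, end)
        out[[length(out) + 1L]] <- row
    }
    if (!length(out)) stopf("no windows pass the filters")
    do.call(rbind, out)
}

## per-base class rates as a data.frame, plus rate/10 and content columns
windowDesign <- function(windows) {
    d <- data.frame(rate10 = windows$rate / 10, gcFrac = windows$gcFrac,
                    cpgFrac = windows$cpgFrac)
    for (cl in substClasses)
        d[[cl]] <- windows[[cl]] / windows$validBases
    d
}

#' OLS regression of a substitution class on recombination rate
#'
#' Models the per-base rate of the target class on human recombination
#' rate (per 10 cM/Mb), GC content, CpG content and the per-base rates of
#' the five other classes, mirroring the published design that controls
#' for locus-specific mutation-rate variation. Reports the recombination
#' coefficient.
#'
#' @param windows window data.frame from \code{\link{alignmentWindows}} or
#'   \code{\link{simAlignment}}.
#' @param targetClass one of \code{\link{substClasses}}.
#' @return a \linkS4class{RegressionResult}.
#' @export
classRateRegression <- function(windows, targetClass) {
    if (!targetClass %in% substClasses)
        stopf("unknown substitution class %s", targetClass)
    if (nrow(windows) < 20L) stopf("need at least 20 windows")
    d <- windowDesign(windows)
    covars <- c("rate10", "gcFrac", "cpgFrac",
                setdiff(substClasses, targetClass))
    d$y <- windows[[targetClass]] / windows$validBases
    X <- as.matrix(cbind(1, d[covars]))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        drop <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
        stopf("design matrix rank deficient; collinear columns: %s",
              paste(drop, collapse = ", "))
    }
    fit <- lm(as.formula(paste("y ~", paste(covars, collapse = " + "))),
              data = d)
    sm <- summary(fit)$coefficients
    new("RegressionResult", effect = sm["rate10", 1L],
        se = sm["rate10", 2L], p = sm["rate10", 4L],
        covariates = covars, targetClass = targetClass)
}

#' GC-transition excess in the hottest and coldest windows
#'
#' Splits windows at the q and 1-q quantiles of recombination rate and
#' estimates, for the chosen lineage-proxy class, the per-base
#' substitution-rate excess of the hot and cold strata relative to windows
#' with intermediate rates. \code{side = "human_GC"} counts chimp-AT /
#' human-GC transitions (GC gain on the human side); \code{"chimp_GC"}
#' counts chimp-GC / human-AT transitions. Bootstrap over windows supplies
#' per-stratum p-values and the hot-vs-cold difference p.
#'
#' @param windows window data.frame.
#' @param side \code{"human_GC"} or \code{"chimp_GC"}.
#' @param q rate quantile defining the strata (default 0.15).
#' @param nBoot bootstrap replicates.
#' @param seed integer seed.
#' @return list with \code{hot}, \code{cold}
#'   (\linkS4class{ExcessEstimate}s) and \code{pHotVsCold}.
#' @export
hotspotExcess <- function(windows, side = c("human_GC", "chimp_GC"),
                          q = 0.15, nBoot = 200, seed = NULL) {
    side <- match.arg(side)
    if (nrow(windows) < 20L) stopf("need at least 20 windows")
    cl <- if (side == "human_GC") "ATGCts" else "GCATts"
    qs <- quantile(windows$rate, c(q, 1 - q), names = FALSE)
    stratum <- ifelse(windows$rate > qs[2L], "hot",
                      ifelse(windows$rate < qs[1L], "cold", "mid"))
    for (s in c("hot", "cold", "mid"))
        if (sum(stratum == s) < 3L)
            stopf("stratum '%s' has fewer than 3 windows", s)
    perBase <- function(rows)
        sum(windows[[cl]][rows]) / sum(windows$validBases[rows])
    idx <- split(seq_len(nrow(windows)), stratum)
    exHot <- perBase(idx$hot) - perBase(idx$mid)
    exCold <- perBase(idx$cold) - perBase(idx$mid)
    boot <- withSeed(seed, {
        t(vapply(seq_len(nBoot), function(b) {
            rs <- lapply(idx, function(i) sample(i, replace = TRUE))
            c(perBase(rs$hot) - perBase(rs$mid),
              perBase(rs$cold) - perBase(rs$mid))
        }, numeric(2)))
    })
    mk <- function(ex, bd)
        new("ExcessEstimate", excess = ex, bootDist = bd,
            p = bootP(ex, bd, "two.sided"))
    list(hot = mk(exHot, boot[, 1L]), cold = mk(exCold, boot[, 2L]),
         pHotVsCold = bootP(exHot - exCold, boot[, 1L] - boot[, 2L],
                            "two.sided"))
}

#' Stepwise-AIC linear model predicting recombination rate
#'
#' Bidirectional stepwise selection from the intercept-only model over the
#' eight candidates (GC content, CpG content and the six per-base class
#' rates), using AIC = n log(RSS/n) + 2k. Reports the selected covariates
#' and the fraction of rate variance explained.
#'
#' @param windows window data.frame.
#' @return list with \code{selected} (character), \code{fit} (the lm),
#'   \code{r2} and \code{aic}.
#' @export
stepwiseRatePredict <- function(windows) {
    if (nrow(windows) < 20L) stopf("need at least 20 windows")
    d <- windowDesign(windows)
    d$rate <- windows$rate
    cand <- c("gcFrac", "cpgFrac", substClasses)
    fit0 <- lm(rate ~ 1, data = d)
    upper <- as.formula(paste("~", paste(cand, collapse = " + ")))
    fit <- step(fit0, scope = list(lower = ~1, upper = upper),
                direction = "both", trace = 0)
    list(selected = attr(terms(fit), "term.labels"), fit = fit,
         r2 = summary(fit)$r.squared,
         aic = extractAIC(fit)[2L])
}
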