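## ---------------------------------------------------------------------------
## Crossover detection in nuclear families: a Lander-Green HMM over
## inheritance vectors, accommodating per-genotype error and ungenotyped
## founders.
##
## Hidden state: the inheritance vector v of 2n bits for n children --
## paternal bit (which of the father's two haplotype slots child c received)
## then maternal bit per child.  Founder ordered genotypes are summed out
## marker by marker under Hardy-Weinberg; because founder haplotypes are in
## linkage equilibrium this per-marker sum is exactly the sum over founder
## phases.  Transitions flip each meiosis bit independently with the
## Haldane probability theta = (1 - exp(-2d))/2 from the sex-appropriate
## prior map distance d (Morgans).  Emission at a marker multiplies, over
## genotyped individuals, the probability of the observed genotype given
## the true one (misread with probability epsilon, uniformly over the two
## wrong genotypes; missing observations contribute 1).
##
## X-linked markers appended beyond the pseudoautosomal boundary put the
## father's dummy (Y-side) haplotype in slot 2: sons' paternal bits are
## pinned to the dummy and daughters' to the real X, and paternal
## transitions between X-linked markers carry theta = 0.
## ---------------------------------------------------------------------------

#' CrossoverPosterior: per-meiosis, per-interval recombination posteriors
#'
#' @slot prob numeric matrix, one row per meiosis, one column per
#'   inter-marker interval; entries in [0, 1] (NA when the family
#'   likelihood is zero).
#' @slot meiosis data.frame describing each row: family, parent role,
#'   child index, sex of the transmitting parent.
#' @slot positions marker positions the intervals are built on.
#' @slot logLik family log-likelihood under the HMM.
#' @export
setClass("CrossoverPosterior",
    representation(prob = "matrix", meiosis = "data.frame",
                   positions = "numeric", logLik = "numeric"))

setValidity("CrossoverPosterior", function(object) {
    if (ncol(object@prob) != length(object@positions) - 1L)
        return("prob needs one column per inter-marker interval")
    if (nrow(object@prob) != nrow(object@meiosis))
        return("one meiosis row per prob row required")
    p <- object@prob
    if (any(!is.na(p) & (p < -1e-9 | p > 1 + 1e-9)))
        return("posterior entries must lie in [0, 1]")
    TRUE
})

setMethod("show", "CrossoverPosterior", function(object) {
    cat(sprintf(
        "CrossoverPosterior: %d meioses x %d intervals, logLik %.4f\n",
        nrow(object@prob), ncol(object@prob), object@logLik))
})

#' Expected crossovers per meiosis
#'
#' Row sums of the posterior matrix: the expected number of crossovers in
#' each meiosis given the data.
#' @param post a \linkS4class{CrossoverPosterior}.
#' @export
expectedCrossovers <- function(post) rowSums(post@prob)

## observation likelihood table: P(obs | true g) for g = 0,1,2, per marker.
## Returns 3 x L matrix; missing obs contribute 1.
obsLikTable <- function(obs, L, eps) {
    tab <- matrix(1, nrow = 3L, ncol = L)
    if (is.null(obs) || !length(obs)) return(tab)
    seen <- which(!is.na(obs))
    for (m in seen) {
        tab[, m] <- eps / 2
        tab[obs[m] + 1L, m] <- 1 - eps
    }
    tab
}

#' Crossover posteriors for one family
#'
#' Runs the forward-backward algorithm over inheritance vectors and returns
#' the per-interval posterior probability of recombination for every
#' meiosis, plus the family log-likelihood. A Mendelian-impossible family
#' at \code{epsilon = 0} yields \code{logLik = -Inf} and \code{NA}
#' posteriors rather than an error.
#'
#' @param family a \linkS4class{Family} (at least one genotyped parent).
#' @param panel the \linkS4class{MarkerPanel} the genotypes are on.
#' @param priorMapMale,priorMapFemale \linkS4class{GeneticMap}s supplying
#'   prior inter-marker distances for paternal and maternal transitions.
#' @param epsilon per-genotype error probability in [0, 0.5).
#' @return a \linkS4class{CrossoverPosterior}.
#' @export
familyPosteriors <- function(family, panel, priorMapMale, priorMapFemale,
                             epsilon = 0.002) {
    if (epsilon < 0 || epsilon >= 0.5)
        stopf("epsilon must lie in [0, 0.5)")
    if (length(family@father) == 0L && length(family@mother) == 0L)
        stopf("family %s has no genotyped parent", family@id)
    L <- nMarkers(panel)
    if (ncol(family@children) != L)
        stopf("family genotypes cover %d markers but panel has %d",
              ncol(family@children), L)
    n <- nChildren(family)
    nb <- 2L * n
    V <- 2L^nb

    ## per-state bit layout: paternal bits 1..n, maternal bits n+1..2n
    states <- 0:(V - 1L)
    bits <- vapply(seq_len(nb),
                   function(j) bitwAnd(states, 2L^(j - 1L)) > 0L,
                   logical(V))
    if (V == 1L) bits <- matrix(bits, nrow = 1L)
    xorIdx <- lapply(seq_len(nb),
                     function(j) bitwXor(states, 2L^(j - 1L)) + 1L)

    ## per-child emission index into the 4 combos (pat slot, mat slot)
    comboIdx <- lapply(seq_len(n), function(c)
        1L + bits[, c] + 2L * bits[, n + c])

    fLik <- obsLikTable(family@father, L, epsilon)
    mLik <- obsLikTable(family@mother, L, epsilon)
    cLik <- lapply(seq_len(n),
                   function(c) obsLikTable(family@children[c, ], L, epsilon))
    isMale <- family@childSex == "M"

    E <- matrix(0, nrow = V, ncol = L)
    for (m in seq_len(L)) {
        q <- panel@freqB[m]
        pA <- c(1 - q, q)                 # P(allele = 0), P(allele = 1)
        if (!panel@xLinked[m]) {
            for (f1 in 0:1) for (f2 in 0:1) for (m1 in 0:1) for (m2 in 0:1) {
                w <- pA[f1 + 1L] * pA[f2 + 1L] * pA[m1 + 1L] * pA[m2 + 1L] *
                    fLik[f1 + f2 + 1L, m] * mLik[m1 + m2 + 1L, m]
                if (w == 0) next
                contrib <- rep(w, V)
                fa <- c(f1, f2); ma <- c(m1, m2)
                for (c in seq_len(n)) {
                    ## genotype for the 4 (pat, mat) slot combos
                    g4 <- c(fa[1L] + ma[1L], fa[2L] + ma[1L],
                            fa[1L] + ma[2L], fa[2L] + ma[2L])
                    contrib <- contrib * cLik[[c]][g4 + 1L, m][comboIdx[[c]]]
                }
                E[, m] <- E[, m] + contrib
            }
        } else {
            ## father hemizygous: slot 1 = real X allele f1, slot 2 = dummy
            ## (allele 0); his coded genotype is f1.  Sons must draw the
            ## dummy slot, daughters the X slot.
            for (f1 in 0:1) for (m1 in 0:1) for (m2 in 0:1) {
                w <- pA[f1 + 1L] * pA[m1 + 1L] * pA[m2 + 1L] *
                    fLik[f1 + 1L, m] * mLik[m1 + m2 + 1L, m]
                if (w == 0) next
                contrib <- rep(w, V)
                ma <- c(m1, m2)
                for (c in seq_len(n)) {
                    if (isMale[c]) {
                        ## paternal slot 2 (dummy, allele 0) required
                        g4 <- c(NA, 0 + ma[1L], NA, 0 + ma[2L])
                        t4 <- c(0, cLik[[c]][g4[2L] + 1L, m],
                                0, cLik[[c]][g4[4L] + 1L, m])
                    } else {
                        g4 <- c(f1 + ma[1L], NA, f1 + ma[2L], NA)
                        t4 <- c(cLik[[c]][g4[1L] + 1L, m], 0,
                                cLik[[c]][g4[3L] + 1L, m], 0)
                    }
                    contrib <- contrib * t4[comboIdx[[c]]]
                }
                E[, m] <- E[, m] + contrib
            }
        }
    }

    ## per-interval flip probabilities, per meiosis
    theta <- matrix(0, nrow = max(L - 1L, 0L), ncol = nb)
    if (L > 1L) {
        a <- panel@positions[-L]
        b <- panel@positions[-1L]
        dM <- intervalCM(priorMapMale, a, b) / 100
        dF <- intervalCM(priorMapFemale, a, b) / 100
        thM <- 0.5 * (1 - exp(-2 * dM))
        thF <- 0.5 * (1 - exp(-2 * dF))
        ## no recombination on the dummy haplotype: paternal theta = 0
        ## between X-linked markers
        thM[panel@xLinked[-L] & panel@xLinked[-1L]] <- 0
        theta[, seq_len(n)] <- thM
        theta[, n + seq_len(n)] <- thF
    }

    mixBit <- function(x, j, th) {
        if (th == 0) x else (1 - th) * x + th * x[xorIdx[[j]]]
    }
    meiosis <- data.frame(
        family = family@id,
        parent = rep(c("father", "mother"), each = n),
        child = rep(seq_len(n), 2L),
        sex = rep(c("male", "female"), each = n),
        stringsAsFactors = FALSE)

    failed <- function() {
        new("CrossoverPosterior",
            prob = matrix(NA_real_, nrow = nb, ncol = max(L - 1L, 0L)),
            meiosis = meiosis, positions = panel@positions, logLik = -Inf)
    }

    ## forward pass with per-step normalisation
    alphas <- vector("list", L)
    logc <- numeric(L)
    a <- E[, 1L] / V
    s <- sum(a)
    if (s <= 0) return(failed())
    alphas[[1L]] <- a / s
    logc[1L] <- log(s)
    if (L > 1L) {
        for (i in seq_len(L - 1L)) {
            a <- alphas[[i]]
            for (j in seq_len(nb)) a <- mixBit(a, j, theta[i, j])
            a <- a * E[, i + 1L]
            s <- sum(a)
            if (s <= 0) return(failed())
            alphas[[i + 1L]] <- a / s
            logc[i + 1L] <- log(s)
        }
    }
    loglik <- sum(logc)

    prob <- matrix(NA_real_, nrow = nb, ncol = max(L - 1L, 0L))
    if (L > 1L) {
        ## backward pass; B[i] = beta_{i+1} * E[, i+1], normalised
        beta <- rep(1, V)
        Bs <- vector("list", L - 1L)
        for (i in (L - 1L):1L) {
            Bi <- beta * E[, i + 1L]
            Bs[[i]] <- Bi / sum(Bi)
            b <- Bs[[i]]
            for (j in seq_len(nb)) b <- mixBit(b, j, theta[i, j])
            beta <- b
        }
        for (i in seq_len(L - 1L)) {
            A <- alphas[[i]]
            B <- Bs[[i]]
            for (j in seq_len(nb)) {
                th <- theta[i, j]
                if (th == 0) { prob[j, i] <- 0; next }
                D <- A
                for (k in seq_len(nb)) if (k != j)
                    D <- mixBit(D, k, theta[i, k])
                num <- th * sum(D[xorIdx[[j]]] * B)
                den <- sum(((1 - th) * D + th * D[xorIdx[[j]]]) * B)
                prob[j, i] <- if (den > 0) num / den else NA_real_
            }
        }
    }
    new("CrossoverPosterior", prob = prob, meiosis = meiosis,
        positions = panel@positions, logLik = loglik)
}

## ---------------------------------------------------------------------------
## Event post-processing and sex-specific map construction
## ---------------------------------------------------------------------------

#' Call individual crossover events from posteriors
#'
#' Scans the posterior along the chromosome, per meiosis. Each maximal
#' contiguous run of intervals with positive posterior whose total mass
#' reaches \code{eventThreshold} yields \code{round(mass)} events (at least
#' one), split at event-count quantiles of the run's cumulative mass. Each
#' event is reported on the smallest contiguous marker span containing at
#' least \code{massQuantile} of its mass (ties broken leftmost).
#'
#' @param post a \linkS4class{CrossoverPosterior}.
#' @param eventThreshold minimum run mass for an event (default 0.5).
#' @param massQuantile fraction of event mass the reported interval must
#'   contain (default 0.95).
#' @return data.frame with columns family, parent, child, sex, start, end,
#'   mass (possibly zero rows).
#' @export
callEvents <- function(post, eventThreshold = 0.5, massQuantile = 0.95) {
    pos <- post@positions
    out <- list()
    for (r in seq_len(nrow(post@prob))) {
        p <- post@prob[r, ]
        if (anyNA(p)) next
        on <- p > 1e-9
        if (!any(on)) next
        runs <- rle(on)
        stops <- cumsum(runs$lengths)
        starts <- stops - runs$lengths + 1L
        for (k in which(runs$values)) {
            idx <- starts[k]:stops[k]
            M <- sum(p[idx])
            if (M < eventThreshold) next
            nev <- max(1L, round(M))
            cm <- cumsum(p[idx])
            assign <- pmin(nev, ceiling(cm / (M / nev) - 1e-12))
            for (ev in seq_len(nev)) {
                sub <- idx[assign == ev]
                if (!length(sub)) next
                mass <- sum(p[sub])
                need <- massQuantile * mass
                ## smallest contiguous sub-span holding >= need
                best <- NULL
                bestLen <- Inf
                lo <- 1L
                acc <- 0
                psub <- p[sub]
                hi <- 0L
                while (hi < length(sub) || acc >= need) {
                    if (acc >= need) {
                        len <- pos[sub[hi] + 1L] - pos[sub[lo]]
                        if (len < bestLen) {
                            bestLen <- len
                            best <- c(sub[lo], sub[hi])
                        }
                        acc <- acc - psub[lo]
                        lo <- lo + 1L
                        if (lo > hi) break
                    } else {
                        hi <- hi + 1L
                        acc <- acc + psub[hi]
                    }
                }
                if (is.null(best)) best <- c(sub[1L], sub[length(sub)])
                out[[length(out) + 1L]] <- data.frame(
                    family = post@meiosis$family[r],
                    parent = paste0(post@meiosis$family[r], "_",
                                    post@meiosis$parent[r]),
                    child = post@meiosis$child[r],
                    sex = post@meiosis$sex[r],
                    start = pos[best[1L]], end = pos[best[2L] + 1L],
                    mass = mass, stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(out))
        return(data.frame(family = character(0), parent = character(0),
                          child = integer(0), sex = character(0),
                          start = numeric(0), end = numeric(0),
                          mass = numeric(0)))
    do.call(rbind, out)
}

#' Build sex-specific maps from crossover posteriors
#'
#' Adds the posterior probability of crossover in each inter-marker
#' interval over all parents of a sex and divides by the number of meioses
#' of that sex; the per-interval quotients, taken as Morgans, are
#' accumulated into a cumulative map.
#'
#' @param posteriors list of \linkS4class{CrossoverPosterior} over one
#'   shared panel.
#' @return list with elements \code{male} and \code{female}
#'   (\linkS4class{GeneticMap} or \code{NULL} with a warning when a sex has
#'   no meioses) and \code{nMeioses} (named counts).
#' @export
buildSexMaps <- function(posteriors) {
    stopifnot(length(posteriors) >= 1L)
    pos <- posteriors[[1L]]@positions
    for (p in posteriors)
        if (!identical(p@positions, pos))
            stopf("all families must share one marker panel")
    nI <- length(pos) - 1L
    res <- list(male = NULL, female = NULL)
    counts <- c(male = 0, female = 0)
    sums <- list(male = numeric(nI), female = numeric(nI))
    for (p in posteriors) {
        for (sx in c("male", "female")) {
            rows <- which(p@meiosis$sex == sx)
            if (!length(rows)) next
            pr <- p@prob[rows, , drop = FALSE]
            ok <- !apply(pr, 1L, anyNA)
            counts[sx] <- counts[sx] + sum(ok)
            if (any(ok))
                sums[[sx]] <- sums[[sx]] + colSums(pr[ok, , drop = FALSE])
        }
    }
    for (sx in c("male", "female")) {
        if (counts[sx] == 0) {
            warning(sprintf("no %s meioses; %s map omitted", sx, sx))
            next
        }
        inc <- sums[[sx]] / counts[sx] * 100   # Morgans -> cM
        res[[sx]] <- GeneticMap(pos, c(0, cumsum(inc)), sexLabel = sx,
                                sourceLabel = "pedigree posterior")
    }
    res$nMeioses <- counts
    res
}

#' Crossover events per meiosis
#'
#' @param events event data.frame from \code{\link{callEvents}}.
#' @param nMeioses number of meioses the events were called from.
#' @param coverage optional numeric length-2 span; also reports the rate
#'   restricted to events with both endpoints inside it.
#' @return list with \code{rate} and \code{rateCovered}.
#' @export
eventsPerMeiosis <- function(events, nMeioses, coverage = NULL) {
    if (nMeioses <= 0) stopf("nMeioses must be positive")
    rate <- nrow(events) / nMeioses
    rc <- rate
    if (!is.null(coverage) && nrow(events))
        rc <- sum(events$start >= coverage[1L] &
                  events$end <= coverage[2L]) / nMeioses
    list(rate = rate, rateCovered = rc)
}
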