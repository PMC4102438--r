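## ---------------------------------------------------------------------------
## Seeded generators for every input the pipeline consumes.  Defaults follow
## the study design they emulate: ~2.7 Mb region, male map dominated by an
## obligatory crossover (50 cM), female map ~5 cM, families of 2-3 children
## with one parent usually ungenotyped, per-genotype error 0.002.
## ---------------------------------------------------------------------------

#' The six substitution classes, keyed chimp state -> human state
#'
#' Order: AT->GC transitions, GC->AT transitions, GC->CG, GC->TA, AT->CG,
#' AT->TA transversions.
#' @export
substClasses <- c("ATGCts", "GCATts", "GCCG", "GCTA", "ATCG", "ATTA")

#' The six polarized-variant classes (ancestral -> derived)
#' @export
afsClasses <- c("AT.GC.ts", "AT.GC.tv", "GC.AT.ts", "GC.AT.tv", "A.T", "C.G")

## inverse-CDF sample of physical positions proportional to map density
sampleFromMapDensity <- function(map, n) {
    cum <- map@cumulative
    pos <- map@positions
    if (cum[length(cum)] - cum[1L] <= 0)
        return(runif(n, pos[1L], pos[length(pos)]))
    u <- runif(n, cum[1L], cum[length(cum)])
    approx(cum, pos, xout = u, ties = "ordered")$y
}

#' Simulate a hotspot-plus-background genetic map
#'
#' Cumulative map = uniform background plus point-like hotspot masses spread
#' over short (1-2 kb) segments at uniform positions, mimicking the
#' clustering of recombination into narrow hotspots.
#'
#' @param lengthBp region length (bp).
#' @param backgroundCM total background genetic length (cM).
#' @param nHotspots number of hotspots.
#' @param hotspotMassDist function(n) drawing hotspot masses in cM.
#' @param sexLabel label for the map.
#' @param seed integer seed (\code{NULL} to use the current stream).
#' @return list with \code{map} (\linkS4class{GeneticMap}) and
#'   \code{hotspots} (data.frame of start, end, massCM).
#' @export
simMap <- function(lengthBp = 2.7e6, backgroundCM = 10, nHotspots = 30,
                   hotspotMassDist = function(n) rexp(n, rate = 1),
                   sexLabel = "sex-averaged", seed = NULL) {
    withSeed(seed, {
        width <- if (nHotspots > 0) runif(nHotspots, 1000, 2000) else
            numeric(0)
        hstart <- if (nHotspots > 0)
            runif(nHotspots, 0, lengthBp - max(width, 0)) else numeric(0)
        mass <- if (nHotspots > 0) hotspotMassDist(nHotspots) else numeric(0)
        brk <- sort(unique(c(0, lengthBp, hstart, hstart + width)))
        cum <- backgroundCM * brk / lengthBp
        for (h in seq_len(nHotspots)) {
            frac <- pmin(pmax((brk - hstart[h]) / width[h], 0), 1)
            cum <- cum + mass[h] * frac
        }
        list(map = GeneticMap(brk, cum, sexLabel = sexLabel,
                              sourceLabel = "simulated"),
             hotspots = data.frame(start = hstart, end = hstart + width,
                                   massCM = mass))
    })
}

## crossover positions of one transmitted gamete
gameteCrossovers <- function(map, obligatory, extraRate) {
    if (obligatory) {
        ## one chiasma per bivalent, in the transmitted gamete w.p. 1/2
        xo <- if (runif(1) < 0.5) sampleFromMapDensity(map, 1L) else
            numeric(0)
        nx <- rpois(1L, extraRate)
        if (nx > 0) xo <- c(xo, sampleFromMapDensity(map, nx))
        sort(xo)
    } else {
        k <- rpois(1L, mapLength(map) / 100)
        sort(sampleFromMapDensity(map, k))
    }
}

corruptGenotypes <- function(g, epsilon) {
    if (epsilon <= 0) return(g)
    hit <- which(!is.na(g) & runif(length(g)) < epsilon)
    for (i in hit) g[i] <- sample(setdiff(0:2, g[i]), 1L)
    g
}

#' Simulate pedigree genotypes from known sex-specific maps
#'
#' Female meioses place crossovers by a Poisson process with intensity given
#' by the female map. Male meioses under \code{obligatoryMale} carry exactly
#' one chiasma positioned proportional to male-map density, present in the
#' transmitted gamete with probability 1/2 (plus rare Poisson extras).
#' Genotypes are drawn under Hardy-Weinberg from \code{mafDist}, corrupted
#' per genotype with probability \code{epsilon}, and one parent is hidden
#' with probability \code{parentMissingProb}.
#'
#' @param nFamilies number of families.
#' @param maleMap,femaleMap generating \linkS4class{GeneticMap}s.
#' @param childrenDist function(n) drawing the number of children (>= 2).
#' @param panelSize number of markers.
#' @param mafDist function(n) drawing "B"-allele frequencies in (0, 1).
#' @param epsilon per-genotype error probability.
#' @param parentMissingProb probability one parent is ungenotyped.
#' @param obligatoryMale use the obligatory-crossover male model.
#' @param extraMaleRate Poisson rate of additional male crossovers.
#' @param seed integer seed.
#' @return list with \code{families} (list of \linkS4class{Family}),
#'   \code{panel} (\linkS4class{MarkerPanel}) and \code{truth} (per-meiosis
#'   crossover positions and counts plus the generating maps).
#' @export
simPedigrees <- function(nFamilies, maleMap, femaleMap,
                         childrenDist = function(n) sample(2:3, n,
                             replace = TRUE),
                         panelSize = 50,
                         mafDist = function(n) runif(n, 0.2, 0.8),
                         epsilon = 0.002, parentMissingProb = 0.86,
                         obligatoryMale = TRUE, extraMaleRate = 0.002,
                         seed = NULL) {
    withSeed(seed, {
        span <- range(c(mapSpan(maleMap), mapSpan(femaleMap)))
        pos <- sort(runif(panelSize, span[1L], span[2L]))
        while (anyDuplicated(pos))
            pos <- sort(c(pos[!duplicated(pos)],
                          runif(sum(duplicated(pos)), span[1L], span[2L])))
        panel <- MarkerPanel(pos, mafDist(panelSize))
        nKids <- childrenDist(nFamilies)
        fams <- vector("list", nFamilies)
        truth <- list()
        haplos <- list()
        for (f in seq_len(nFamilies)) {
            id <- sprintf("fam%04d", f)
            fhap <- matrix(rbinom(2L * panelSize, 1L, rep(panel@freqB,
                each = 2L)), nrow = 2L)
            mhap <- matrix(rbinom(2L * panelSize, 1L, rep(panel@freqB,
                each = 2L)), nrow = 2L)
            n <- nKids[f]
            kids <- matrix(0, nrow = n, ncol = panelSize)
            sexes <- sample(c("M", "F"), n, replace = TRUE)
            for (c in seq_len(n)) {
                for (side in c("pat", "mat")) {
                    map <- if (side == "pat") maleMap else femaleMap
                    hap <- if (side == "pat") fhap else mhap
                    xo <- gameteCrossovers(map,
                        obligatory = (side == "pat") && obligatoryMale,
                        extraRate = if (side == "pat") extraMaleRate else 0)
                    slot0 <- rbinom(1L, 1L, 0.5)
                    nBelow <- findInterval(pos, xo)
                    slot <- (slot0 + nBelow) %% 2L + 1L
                    allele <- hap[cbind(slot, seq_len(panelSize))]
                    kids[c, ] <- kids[c, ] + allele
                    truth[[length(truth) + 1L]] <- data.frame(
                        family = id, child = c,
                        sex = if (side == "pat") "male" else "female",
                        nCrossovers = length(xo),
                        positions = I(list(xo)))
                }
            }
            father <- colSums(fhap)
            mother <- colSums(mhap)
            if (runif(1) < parentMissingProb) {
                if (runif(1) < 0.5) father <- NULL else mother <- NULL
            }
            corrupt <- function(g) if (is.null(g)) NULL else
                corruptGenotypes(g, epsilon)
            kidsErr <- t(apply(kids, 1L, corruptGenotypes, epsilon))
            fams[[f]] <- Family(id, corrupt(father), corrupt(mother),
                                kidsErr, sexes)
            haplos[[id]] <- list(father = fhap, mother = mhap)
        }
        list(families = fams, panel = panel,
             truth = list(meioses = do.call(rbind, truth),
                          haplotypes = haplos,
                          maleMap = maleMap, femaleMap = femaleMap))
    })
}

## stationary density of derived-allele frequency under conversion bias B:
## f(x) propto (1 - exp(-B(1-x))) / (x(1-x)), with the 1/x neutral limit.
biasedAfsDensity <- function(x, B) {
    if (abs(B) < 1e-8) 1 / x else (1 - exp(-B * (1 - x))) / (x * (1 - x))
}

sampleBiasedAfs <- function(n, B, delta = 5e-5) {
    grid <- seq(delta, 1 - delta, length.out = 4096L)
    f <- biasedAfsDensity(grid, B)
    cdf <- cumsum((f[-1L] + f[-length(f)]) / 2 * diff(grid))
    cdf <- c(0, cdf) / cdf[length(cdf) - 0L]
    approx(cdf, grid, xout = runif(n), ties = "ordered")$y
}

## draw bases and flanks for a variant of a given class; CpG-forming flank
## forced with probability cpgRate where the focal bases allow it
classBases <- function(class) {
    pairs <- switch(class,
        AT.GC.ts = list(c("A", "G"), c("T", "C")),
        AT.GC.tv = list(c("A", "C"), c("T", "G")),
        GC.AT.ts = list(c("G", "A"), c("C", "T")),
        GC.AT.tv = list(c("G", "T"), c("C", "A")),
        A.T = list(c("A", "T"), c("T", "A")),
        C.G = list(c("C", "G"), c("G", "C")),
        stopf("unknown variant class %s", class))
    pairs[[sample.int(2L, 1L)]]
}

#' Simulate polarized variants with class-specific conversion bias
#'
#' Population frequencies are drawn from a stationary density proportional
#' to \code{(1 - exp(-B(1-x)))/(x(1-x))} with class-specific scaled bias B
#' (the neutral 1/x spectrum as B -> 0); observed derived-allele frequencies
#' come from binomial sampling of \code{nChromosomes}, conditioned on the
#' site segregating in the sample.
#'
#' @param nSites number of segregating sites to emit.
#' @param classMix named probabilities over \code{\link{afsClasses}}.
#' @param biasB named per-class bias B (0 = neutral).
#' @param nChromosomes sample size (chromosomes).
#' @param lengthBp region length for uniform positions.
#' @param cpgRate probability a variant is placed in a CpG context where its
#'   bases allow one.
#' @param delta frequency truncation of the stationary density.
#' @param seed integer seed.
#' @return list with \code{variants} (data.frame pos, anc, der, left, right,
#'   daf, mclass, cpg) and \code{truth} (true population frequencies and
#'   biases).
#' @export
simAfsVariants <- function(nSites, classMix = setNames(rep(1 / 6, 6),
                           afsClasses),
                           biasB = setNames(rep(0, 6), afsClasses),
                           nChromosomes = 200L, lengthBp = 2.7e6,
                           cpgRate = 0, delta = 5e-5, seed = NULL) {
    withSeed(seed, {
        cls <- sample(names(classMix), nSites, replace = TRUE,
                      prob = classMix)
        x <- numeric(nSites)
        k <- integer(nSites)
        for (cl in unique(cls)) {
            i <- which(cls == cl)
            x[i] <- sampleBiasedAfs(length(i), biasB[[cl]], delta)
            k[i] <- rbinom(length(i), nChromosomes, x[i])
            ## condition on segregating in the sample: rejection-sample the
            ## (frequency, count) pair jointly
            while (any(bad <- k[i] == 0L | k[i] == nChromosomes)) {
                j <- i[bad]
                x[j] <- sampleBiasedAfs(length(j), biasB[[cl]], delta)
                k[j] <- rbinom(length(j), nChromosomes, x[j])
            }
        }
        anc <- der <- left <- right <- character(nSites)
        for (i in seq_len(nSites)) {
            b <- classBases(cls[i])
            anc[i] <- b[1L]; der[i] <- b[2L]
            left[i] <- sample(c("A", "T"), 1L)
            right[i] <- sample(c("A", "T"), 1L)
            if (cpgRate > 0 && runif(1) < cpgRate) {
                if (any(c(anc[i], der[i]) == "C")) right[i] <- "G"
                else if (any(c(anc[i], der[i]) == "G")) left[i] <- "C"
            }
        }
        cg <- (anc == "C" & right == "G") | (anc == "G" & left == "C") |
              (der == "C" & right == "G") | (der == "G" & left == "C")
        variants <- data.frame(
            pos = round(sort(runif(nSites, 0, lengthBp))),
            anc = anc, der = der, left = left, right = right,
            daf = k / nChromosomes, mclass = cls, cpg = cg,
            stringsAsFactors = FALSE)
        list(variants = variants,
             truth = list(x = x, biasB = biasB, classMix = classMix,
                          nChromosomes = nChromosomes))
    })
}

#' Simulate aligned 2-kb windows with rate-dependent GC gain
#'
#' Per-window substitution counts are binomial draws; the chimp-AT/human-GC
#' transition probability increases linearly with the supplied
#' recombination rate (\code{humanGcEffectPer10} per 10 cM/Mb); all other
#' classes are rate-independent.
#'
#' @param nWindows number of 2-kb windows.
#' @param rates per-window recombination rate (cM/Mb), recycled.
#' @param baseRates named per-base substitution probabilities per class.
#' @param humanGcEffectPer10 added per-base probability of the ATGCts class
#'   per 10 cM/Mb of rate.
#' @param windowBp window width.
#' @param seed integer seed.
#' @return list with \code{windows} (data.frame start, end, validBases, six
#'   class counts, gcFrac, cpgFrac, rate) and \code{truth}.
#' @export
simAlignment <- function(nWindows, rates,
                         baseRates = setNames(c(0.0042, 0.0038, 0.0031,
                             0.0017, 0.0014, 0.0010), substClasses),
                         humanGcEffectPer10 = 0.0011, windowBp = 2000,
                         seed = NULL) {
    stopifnot(all(baseRates >= 0 & baseRates <= 0.02))
    withSeed(seed, {
        rate <- rep_len(rates, nWindows)
        valid <- round(runif(nWindows, 1500, windowBp))
        win <- data.frame(start = (seq_len(nWindows) - 1L) * windowBp,
                          end = seq_len(nWindows) * windowBp,
                          validBases = valid)
        for (cl in substClasses) {
            p <- rep(baseRates[[cl]], nWindows)
            if (cl == "ATGCts") p <- p + humanGcEffectPer10 * rate / 10
            win[[cl]] <- rbinom(nWindows, valid, pmin(p, 1))
        }
        win$gcFrac <- runif(nWindows, 0.35, 0.55)
        win$cpgFrac <- runif(nWindows, 0.005, 0.03)
        win$rate <- rate
        list(windows = win,
             truth = list(effect = humanGcEffectPer10,
                          baseRates = baseRates))
    })
}

#' Simulate crossover events from a map
#'
#' Event midpoints are drawn proportional to map density and wrapped in
#' resolution intervals centred on the midpoint (clipped to the map span).
#'
#' @param map generating \linkS4class{GeneticMap}.
#' @param nEvents number of events.
#' @param resolutionDist function(n) drawing interval lengths (bp).
#' @param sex sex label attached to the events.
#' @param seed integer seed.
#' @return event data.frame (parent, sex, start, end, mass, midpoint).
#' @export
simEventsFromMap <- function(map, nEvents,
                             resolutionDist = function(n) runif(n, 13000,
                                 45000),
                             sex = "male", seed = NULL) {
    stopifnot(nEvents >= 1)
    withSeed(seed, {
        mid <- sampleFromMapDensity(map, nEvents)
        len <- resolutionDist(nEvents)
        sp <- mapSpan(map)
        start <- pmax(mid - len / 2, sp[1L])
        end <- pmin(mid + len / 2, sp[2L])
        end <- pmax(end, start)   # zero-width allowed at the span edge
        data.frame(parent = sprintf("p%04d", seq_len(nEvents)), sex = sex,
                   start = start, end = end, mass = 1, midpoint = mid,
                   stringsAsFactors = FALSE)
    })
}
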