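test_that("all 12 ordered base pairs classify per the six-way scheme", {
    cases <- data.frame(
        anc = c("A", "T", "A", "T", "G", "C", "G", "C", "A", "T", "C", "G"),
        der = c("G", "C", "C", "G", "A", "T", "T", "A", "T", "A", "G", "C"),
        want = c("AT.GC.ts", "AT.GC.ts", "AT.GC.tv", "AT.GC.tv",
                 "GC.AT.ts", "GC.AT.ts", "GC.AT.tv", "GC.AT.tv",
                 "A.T", "A.T", "C.G", "C.G"))
    got <- classifyVariants(cases$anc, cases$der, rep("T", 12), rep("T", 12))
    expect_equal(got$mclass, cases$want)
    expect_false(any(got$cpg))

    ## CpG contexts: C with right G, G with left C, on ancestral or derived
    expect_true(classifyVariants("A", "G", "T", "T")$cpg == FALSE)
    expect_true(classifyVariants("C", "T", "A", "G")$cpg)    # deamination
    expect_true(classifyVariants("T", "G", "C", "A")$cpg)    # derived G after C
    expect_true(classifyVariants("G", "A", "C", "T")$cpg)
    expect_error(classifyVariants("A", "A", "T", "T"), "differ")
    expect_error(classifyVariants("A", "N", "T", "T"), "bases")
})

test_that("classification conserves counts across classes and CpG pool", {
    sim <- simAfsVariants(3000, cpgRate = 0.3, seed = 111)
    v <- sim$variants
    cl <- classifyVariants(v$anc, v$der, v$left, v$right)
    expect_equal(cl$mclass, v$mclass)
    expect_equal(cl$cpg, v$cpg)
    ## every variant lands in exactly one class
    expect_equal(sum(table(cl$mclass)), nrow(v))
    spectraN <- sum(vapply(afsClasses, function(cls)
        sum(spectrumCounts(buildSpectrum(v, cls, mafMin = 0))),
        numeric(1)))
    expect_equal(spectraN, sum(!v$cpg))
})

test_that("statistics are invariant under strand-complementing everything", {
    sim <- simAfsVariants(4000, biasB = setNames(c(2, 2, 0, 0, 0, 0),
                                                 afsClasses),
                          cpgRate = 0.15, seed = 112)
    v <- sim$variants
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ## complementing swaps left/right flanks (reverse strand reading)
    v2 <- data.frame(pos = v$pos, anc = comp[v$anc], der = comp[v$der],
                     left = comp[v$right], right = comp[v$left],
                     daf = v$daf, stringsAsFactors = FALSE)
    cl2 <- classifyVariants(v2$anc, v2$der, v2$left, v2$right)
    v2$mclass <- cl2$mclass; v2$cpg <- cl2$cpg
    expect_equal(v2$cpg, v$cpg)
    b1 <- fixationBias(v)
    b2 <- fixationBias(v2)
    expect_equal(b1@ratio, b2@ratio)
    expect_equal(b1@pValue, b2@pValue)
    s1 <- buildSpectrum(v, "AT.GC.ts")
    s2 <- buildSpectrum(v2, "AT.GC.ts")
    expect_equal(spectrumCounts(s1), spectrumCounts(s2))
})

test_that("neutral spectra follow the 1/x sampling density", {
    sim <- simAfsVariants(10000, classMix = setNames(c(1, 0, 0, 0, 0, 0),
                                                     afsClasses),
                          nChromosomes = 100, seed = 113)
    sfs <- buildSpectrum(sim$variants, "AT.GC.ts", mafMin = 0)
    ## expected bin mass from the density-integration oracle
    edges <- sfs@binEdges
    pBin <- vapply(seq_len(length(edges) - 1L), function(i)
        oracleBandProb(0, edges[i], edges[i + 1L], 100), numeric(1))
    ## top edge: include daf = 1 - 1/n < 1 sites (band is half-open)
    n <- sum(spectrumCounts(sfs))
    expected <- n * pBin / sum(pBin)
    chi <- sum((spectrumCounts(sfs) - expected)^2 / pmax(expected, 1))
    expect_lt(chi, qchisq(0.999, df = length(pBin) - 1))
})

test_that("conversion bias enriches the top of the spectrum", {
    sim <- simAfsVariants(8000, biasB = setNames(c(3, 3, 0, 0, 0, 0),
                                                 afsClasses),
                          seed = 114)
    gain <- buildSpectrum(sim$variants, c("AT.GC.ts", "AT.GC.tv"))
    loss <- buildSpectrum(sim$variants, c("GC.AT.ts", "GC.AT.tv"))
    topGain <- spectrumCounts(gain)[10] / sum(spectrumCounts(gain))
    topLoss <- spectrumCounts(loss)[10] / sum(spectrumCounts(loss))
    expect_gt(topGain, topLoss)
    cmp <- compareExtremeBins(gain, loss, "top")
    expect_gt(cmp$delta, 0)
    expect_lt(cmp$p, 0.001)
    ## bottom tail goes the other way
    cmpB <- compareExtremeBins(gain, loss, "bottom")
    expect_lt(cmpB$delta, 0)
})

test_that("compareExtremeBins handles identity and tiny counts exactly", {
    s <- new("AFSpectrum", binEdges = seq(0, 1, 0.1),
             counts = c(5, 3, 2, 1, 1, 1, 1, 2, 3, 6), classLabel = "x")
    same <- compareExtremeBins(s, s, "top")
    expect_equal(same$delta, 0)
    expect_equal(same$p, 1)
    tiny <- new("AFSpectrum", binEdges = seq(0, 1, 0.1),
                counts = c(1, 0, 0, 0, 0, 0, 0, 0, 0, 2), classLabel = "y")
    out <- compareExtremeBins(tiny, s, "top")
    expect_true(is.finite(out$p))
    expect_error(compareExtremeBins(s, new("AFSpectrum",
        binEdges = seq(0, 1, 0.1), counts = rep(0, 10), classLabel = "z")),
        "empty")
})

test_that("qq comparison sits on the diagonal for identical samples and shifts under bias", {
    set.seed(115)
    x <- runif(500)
    qq <- qqCompare(x, x)
    expect_equal(qq$quantiles$x, qq$quantiles$y)
    sim <- simAfsVariants(5000, biasB = setNames(c(2.5, 2.5, 0, 0, 0, 0),
                                                 afsClasses), seed = 116)
    v <- sim$variants
    gain <- v$daf[v$mclass %in% c("AT.GC.ts", "AT.GC.tv")]
    loss <- v$daf[v$mclass %in% c("GC.AT.ts", "GC.AT.tv")]
    qq2 <- qqCompare(loss, gain)
    expect_gt(mean(qq2$quantiles$y >= qq2$quantiles$x), 0.9)
    expect_lt(qq2$pShift, 0.01)
})

test_that("fixation bias is calibrated at B = 0 and matches the band oracle", {
    sim0 <- simAfsVariants(20000, nChromosomes = 100, seed = 117)
    b0 <- fixationBias(sim0$variants)
    se0 <- b0@ratio * sqrt(1 / b0@nGC + 1 / b0@nAT)
    expect_lt(abs(b0@ratio - 1), 2 * se0)

    ## equal in-band counts give ratio exactly 1, p = 1
    vEq <- data.frame(pos = 1:4, anc = c("A", "A", "G", "G"),
                      der = c("G", "G", "A", "A"), left = "T", right = "T",
                      daf = rep(0.96, 4),
                      mclass = c("AT.GC.ts", "AT.GC.ts", "GC.AT.ts",
                                 "GC.AT.ts"), cpg = FALSE)
    bEq <- fixationBias(vEq, mafMin = 0)
    expect_equal(bEq@ratio, 1)
    expect_equal(bEq@pValue, 1)
})

test_that("U-mixture recovery hits the endpoints and the planted weight", {
    bg <- new("AFSpectrum", binEdges = seq(0, 1, 0.1),
              counts = c(400, 200, 120, 90, 70, 60, 55, 50, 45, 40),
              classLabel = "bg")
    expect_equal(fitUMixture(bg, bg, nBoot = 0)@lambda, 0,
                 tolerance = 1e-6)
    pureU <- new("AFSpectrum", binEdges = seq(0, 1, 0.1),
                 counts = c(500, 0, 0, 0, 0, 0, 0, 0, 0, 500),
                 classLabel = "u")
    expect_equal(fitUMixture(pureU, bg, nBoot = 0)@lambda, 1,
                 tolerance = 1e-6)
    ## planted 0.3 mixture at n = 1000 with a bootstrap interval
    set.seed(118)
    p <- 0.3 * c(0.5, rep(0, 8), 0.5) +
        0.7 * spectrumCounts(bg) / sum(spectrumCounts(bg))
    tgt <- new("AFSpectrum", binEdges = seq(0, 1, 0.1),
               counts = as.numeric(rmultinom(1, 1000, p)),
               classLabel = "t")
    fit <- fitUMixture(tgt, bg, nBoot = 100, seed = 119)
    expect_lt(abs(fit@lambda - 0.3), 0.05)
    expect_true(fit@ci[1] <= fit@lambda && fit@lambda <= fit@ci[2])
})

test_that("near-anchor spectra detect locally planted bias", {
    set.seed(120)
    anchors <- sort(runif(40, 1e5, 2.6e6))
    near <- simAfsVariants(1500, biasB = setNames(c(6, 6, 0, 0, 0, 0),
                                                  afsClasses), seed = 121)
    far <- simAfsVariants(6000, seed = 122)
    ## place biased variants within 25 bp of anchors, the rest at random
    near$variants$pos <- round(sample(anchors, 1500, TRUE) +
                               runif(1500, -25, 25))
    out <- nearAnchorAFS(rbind(near$variants, far$variants), anchors,
                         radii = c(25, 500))
    expect_named(out, c("25", "500"))
    expect_lt(out[["25"]]$pGainVsWhole, 0.05)
    ## an empty band is omitted with a warning
    expect_warning(
        res <- nearAnchorAFS(far$variants[far$variants$pos > 2.7e6 + 1e5, ,
                                          drop = FALSE],
                             anchors, radii = c(25)),
        "omitted")
    expect_length(res, 0)
})

test_that("AFS-percentile map estimation tracks the reference at broad scale", {
    ## AT->GC daf percentiles proportional to the local rate of a
    ## hotspot-bearing reference map, with uniform within-window noise
    set.seed(123)
    refMap <- simMap(2e6, backgroundCM = 15, nHotspots = 25,
                     hotspotMassDist = function(n) rexp(n, 1 / 1.2),
                     seed = 124)$map
    rt <- rateTrack(refMap, 50000, 50000)
    vlist <- lapply(seq_along(rt@start), function(i) {
        n <- 120
        daf <- runif(n, 0, min(1, rt@rate[i] / 60))
        data.frame(pos = round(runif(n, rt@start[i], rt@end[i] - 1)),
                   anc = "A", der = "G", left = "T", right = "T",
                   daf = pmin(pmax(daf, 0.02), 0.98),
                   mclass = "AT.GC.ts", cpg = FALSE,
                   stringsAsFactors = FALSE)
    })
    v <- do.call(rbind, vlist)
    est <- estimateMapFromAFS(v, 50000, 50000, refMap)
    expect_s4_class(est$track, "RateTrack")
    expect_gte(nrow(est$windows), 20)
    ## at the smoothed 250 kb scale the estimate tracks the truth
    truth <- rateTrack(refMap, 250000, 10000)
    keep <- !is.na(est$track@rate) & !is.na(truth@rate)
    expect_gt(cor(est$track@rate[keep], truth@rate[keep]), 0.8)
    ## constant daf: flat output with a warning
    vFlat <- v
    vFlat$daf <- 0.5
    expect_warning(f <- estimateMapFromAFS(vFlat, 50000, 50000, refMap),
                   "degenerate")
    expect_equal(sd(f$windows$fitted), 0)
})

test_that("polarized-variant text and VCF ingestion classify on the fly", {
    sim <- simAfsVariants(300, cpgRate = 0.2, seed = 130)
    tf <- withr::local_tempfile()
    writePolarizedVariants(sim$variants, tf)
    back <- readPolarizedVariants(tf)
    expect_equal(back$mclass, sim$variants$mclass)
    expect_equal(back$cpg, sim$variants$cpg)
    expect_equal(back$daf, sim$variants$daf)

    skip_if_not_installed("vcfR")
    ## tiny handwritten VCF against a known reference: site 1 has AA=REF
    ## (derived = ALT, daf = AF), site 2 has AA=ALT (derived = REF,
    ## daf = 1 - AF); site 3 is not polarizable and is dropped
    ref <- "TTACGTTAGT"
    vf <- withr::local_tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##INFO=<ID=AA,Number=1,Type=String,Description=\"anc\">",
        "##INFO=<ID=AF,Number=1,Type=Float,Description=\"freq\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
        "par\t3\t.\tA\tG\t.\t.\tAA=A;AF=0.25",
        "par\t6\t.\tT\tC\t.\t.\tAA=C;AF=0.90",
        "par\t8\t.\tA\tG\t.\t.\tAA=T;AF=0.50"), vf)
    v <- readPolarizedVcf(vf, ref)
    expect_equal(nrow(v), 2)
    expect_equal(v$pos, c(2, 5))          # 0-based
    expect_equal(v$anc, c("A", "C"))
    expect_equal(v$der, c("G", "T"))
    expect_equal(v$daf, c(0.25, 0.10))
    expect_equal(v$mclass, c("AT.GC.ts", "GC.AT.ts"))
    ## site 1 flanks A..G? reference around pos 3 is T,A,C -> left T,
    ## right C, no CpG; site 2 (pos 6) has left G? check CpG flag directly
    expect_equal(v$left, c("T", "G"))
    expect_equal(v$right, c("C", "T"))
    expect_false(any(v$cpg))
})
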