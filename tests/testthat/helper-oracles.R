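## Independent oracles used across the suite.  These deliberately avoid the
## package's own code paths: the HMM oracle enumerates inheritance-vector
## paths outright, the motif oracle slides a window base by base, and the
## AFS oracle integrates the stationary density on a grid.

## -- brute-force pedigree likelihood/posterior by path enumeration ---------
oracleFamily <- function(family, panel, mapM, mapF, eps) {
    L <- nMarkers(panel)
    n <- nrow(family@children)
    nb <- 2L * n
    V <- 2L^nb
    bit <- function(v, j) bitwAnd(v, 2L^(j - 1L)) > 0L
    olik <- function(obs, g)
        if (is.na(obs)) 1 else if (obs == g) 1 - eps else eps / 2
    emis <- function(v, m) {
        q <- panel@freqB[m]
        pA <- c(1 - q, q)
        tot <- 0
        for (f1 in 0:1) for (f2 in 0:1) for (m1 in 0:1) for (m2 in 0:1) {
            w <- pA[f1 + 1] * pA[f2 + 1] * pA[m1 + 1] * pA[m2 + 1]
            if (length(family@father))
                w <- w * olik(family@father[m], f1 + f2)
            if (length(family@mother))
                w <- w * olik(family@mother[m], m1 + m2)
            for (c in seq_len(n)) {
                fa <- if (bit(v, c)) f2 else f1
                ma <- if (bit(v, n + c)) m2 else m1
                w <- w * olik(family@children[c, m], fa + ma)
            }
            tot <- tot + w
        }
        tot
    }
    pos <- panel@positions
    thM <- 0.5 * (1 - exp(-2 * intervalCM(mapM, pos[-L], pos[-1]) / 100))
    thF <- 0.5 * (1 - exp(-2 * intervalCM(mapF, pos[-L], pos[-1]) / 100))
    th <- cbind(matrix(rep(thM, n), ncol = n),
                matrix(rep(thF, n), ncol = n))
    Etab <- matrix(0, V, L)
    for (v in 0:(V - 1)) for (m in 1:L) Etab[v + 1, m] <- emis(v, m)
    P <- as.matrix(expand.grid(rep(list(0:(V - 1)), L)))
    w <- rep(1 / V, nrow(P))
    for (m in 1:L) w <- w * Etab[P[, m] + 1L, m]
    if (L > 1) for (i in 1:(L - 1)) for (j in 1:nb) {
        fl <- bitwAnd(bitwXor(P[, i], P[, i + 1]), 2L^(j - 1L)) > 0L
        w <- w * ifelse(fl, th[i, j], 1 - th[i, j])
    }
    tot <- sum(w)
    post <- matrix(0, nb, max(L - 1, 0))
    if (L > 1) for (i in 1:(L - 1)) for (j in 1:nb) {
        fl <- bitwAnd(bitwXor(P[, i], P[, i + 1]), 2L^(j - 1L)) > 0L
        post[j, i] <- sum(w[fl]) / tot
    }
    list(logLik = log(tot), post = post)
}

## -- naive sliding-window degenerate-motif scan ----------------------------
## N in the sequence never matches; midpoints in 0-based forward coords.
oracleMotifScan <- function(seqChar, motif, bothStrands = TRUE) {
    revcomp <- function(s) chartr("ACGTn", "TGCAn",
                                  paste(rev(strsplit(s, "")[[1]]),
                                        collapse = ""))
    scan1 <- function(sq, mot) {
        s <- strsplit(sq, "")[[1]]
        m <- strsplit(mot, "")[[1]]
        w <- length(m)
        nWin <- length(s) - w + 1L
        if (nWin < 1L) return(integer(0))
        ok <- rep(TRUE, nWin)
        for (j in seq_len(w)) {
            sj <- s[j:(j + nWin - 1L)]
            ok <- ok & if (m[j] == "n") sj %in% c("A", "C", "G", "T") else
                sj == m[j]
        }
        which(ok)
    }
    st <- scan1(seqChar, motif)
    if (bothStrands) st <- c(st, scan1(seqChar, revcomp(motif)))
    sort(unique(st - 1 + (nchar(motif) - 1) / 2))
}

## -- stationary-density band integral under binomial sampling --------------
## P(daf in [lo, hi) | site segregates in a sample of nChrom) for bias B.
oracleBandProb <- function(B, lo, hi, nChrom, delta = 5e-5,
                           gridN = 2000L) {
    x <- seq(delta, 1 - delta, length.out = gridN)
    f <- if (abs(B) < 1e-8) 1 / x else
        (1 - exp(-B * (1 - x))) / (x * (1 - x))
    k <- 0:nChrom
    inBand <- (k / nChrom) >= lo & (k / nChrom) < hi & k > 0 & k < nChrom
    seg <- k > 0 & k < nChrom
    pBand <- vapply(x, function(xx)
        sum(dbinom(k[inBand], nChrom, xx)), numeric(1))
    pSeg <- vapply(x, function(xx)
        sum(dbinom(k[seg], nChrom, xx)), numeric(1))
    trap <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))
    trap(f * pBand) / trap(f * pSeg)
}

## -- small deterministic maps ----------------------------------------------
linearMap <- function(lengthBp = 1e6, cm = 10, sex = "sex-averaged")
    GeneticMap(c(0, lengthBp), c(0, cm), sexLabel = sex)

twoSegmentMap <- function()
    GeneticMap(c(0, 5e5, 1e6), c(0, 2, 10))
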