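priorM <- GeneticMap(c(0, 3e5), c(0, 15), sexLabel = "male")
priorF <- GeneticMap(c(0, 3e5), c(0, 3), sexLabel = "female")

test_that("families with no genotyped parent are rejected", {
    expect_error(Family("f", NULL, NULL, matrix(1, 2, 3), c("M", "F")),
                 "at least one parent")
    expect_error(Family("f", c(0, 1, 2), NULL, matrix(1, 1, 3), "M"),
                 "two children")
})

test_that("uninformative (all-homozygous) data return the prior thetas", {
    pos <- c(0, 1e5, 2e5, 3e5)
    panel <- MarkerPanel(pos, c(0.5, 0.4, 0.6, 0.3))
    fam <- Family("h", rep(2, 4), rep(2, 4), matrix(2, 2, 4), c("M", "F"))
    thM <- 0.5 * (1 - exp(-2 * intervalCM(priorM, pos[-4], pos[-1]) / 100))
    thF <- 0.5 * (1 - exp(-2 * intervalCM(priorF, pos[-4], pos[-1]) / 100))
    p0 <- familyPosteriors(fam, panel, priorM, priorF, epsilon = 0)
    expect_equal(p0@prob[1, ], thM, tolerance = 1e-12)
    expect_equal(p0@prob[3, ], thF, tolerance = 1e-12)
    p1 <- familyPosteriors(fam, panel, priorM, priorF, epsilon = 0.01)
    expect_equal(p1@prob[1, ], thM, tolerance = 1e-4)
})

test_that("a fully informative recombinant child is localised exactly", {
    ## father AB at three markers, mother AA.  Children 1-2 inherited the
    ## paternal B haplotype throughout; child 3 switches to A at marker 3:
    ## a crossover in interval 2 of child 3's paternal meiosis.  (Two
    ## children alone cannot attribute the crossover - founder-phase
    ## symmetry splits it 0.5/0.5 - so a third child breaks the tie.)
    pos <- c(0, 1e5, 2e5)
    panel <- MarkerPanel(pos, rep(0.5, 3))
    tightM <- GeneticMap(c(0, 3e5), c(0, 1.5), sexLabel = "male")
    fam <- Family("r", father = c(1, 1, 1), mother = c(0, 0, 0),
                  children = rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 0)),
                  childSex = c("M", "F", "F"))
    post <- familyPosteriors(fam, panel, tightM, priorF, epsilon = 0)
    want <- oracleFamily(fam, panel, tightM, priorF, 0)
    expect_equal(post@logLik, want$logLik, tolerance = 1e-9)
    expect_equal(unname(post@prob), unname(want$post), tolerance = 1e-9)
    ## child 3's paternal meiosis carries the crossover in interval 2;
    ## the residual mass on children 1-2 is the double-flip alternative,
    ## suppressed by one power of theta (~0.005 here)
    expect_gt(post@prob[3, 2], 0.98)
    expect_lt(max(post@prob[1:2, ]), 0.02)
    expect_lt(max(post@prob[, 1]), 0.02)
})

test_that("genotyping error is preferred over a double crossover", {
    ## tight prior map: a double crossover is (theta^2)-improbable
    tightM <- GeneticMap(c(0, 4e5), c(0, 0.4), sexLabel = "male")
    pos <- seq(0, 4e5, 1e5)
    panel <- MarkerPanel(pos, rep(0.5, 5))
    ## child2 discordant at the middle marker only: double crossover or a
    ## single misread genotype
    fam <- Family("e", father = rep(1, 5), mother = rep(0, 5),
                  children = rbind(rep(1, 5), c(1, 1, 0, 1, 1)),
                  childSex = c("F", "F"))
    post <- familyPosteriors(fam, panel, tightM, priorF, epsilon = 0.01)
    want <- oracleFamily(fam, panel, tightM, priorF, 0.01)
    expect_equal(post@logLik, want$logLik, tolerance = 1e-9)
    expect_equal(unname(post@prob), unname(want$post), tolerance = 1e-9)
    ## little posterior crossover mass anywhere
    expect_lt(max(post@prob[1:2, ]), 0.2)
})

test_that("posteriors match exhaustive enumeration on random families", {
    set.seed(20)
    for (rep in 1:8) {
        n <- sample(2:3, 1)
        L <- if (n == 3) 3 else sample(4:5, 1)
        pos <- sort(sample(seq(0, 3e5, 1e4), L))
        panel <- MarkerPanel(pos, runif(L, 0.2, 0.8))
        father <- if (runif(1) < 0.35) NULL else sample(0:2, L, TRUE)
        mother <- if (is.null(father)) sample(0:2, L, TRUE) else
            if (runif(1) < 0.35) NULL else sample(0:2, L, TRUE)
        kids <- matrix(sample(c(0:2, NA), n * L, TRUE,
                              prob = c(.3, .3, .3, .1)), nrow = n)
        fam <- Family(paste0("f", rep), father, mother, kids,
                      sample(c("M", "F"), n, TRUE))
        eps <- sample(c(0.002, 0.01, 0.05), 1)
        got <- familyPosteriors(fam, panel, priorM, priorF, eps)
        want <- oracleFamily(fam, panel, priorM, priorF, eps)
        expect_equal(got@logLik, want$logLik, tolerance = 1e-9)
        expect_equal(unname(got@prob), unname(want$post), tolerance = 1e-8)
    }
})

test_that("posteriors are invariant under allele relabelling at a marker", {
    set.seed(21)
    pos <- c(0, 1e5, 2e5, 3e5)
    panel <- MarkerPanel(pos, c(0.3, 0.6, 0.4, 0.7))
    fam <- Family("s", sample(0:2, 4, TRUE), sample(0:2, 4, TRUE),
                  matrix(sample(0:2, 8, TRUE), 2), c("M", "M"))
    p1 <- familyPosteriors(fam, panel, priorM, priorF, 0.01)
    ## swap alleles at marker 2: genotypes g -> 2 - g, freq q -> 1 - q
    panel2 <- MarkerPanel(pos, replace(panel@freqB, 2, 1 - panel@freqB[2]))
    flip <- function(g) replace(g, 2, 2 - g[2])
    fam2 <- Family("s", flip(fam@father), flip(fam@mother),
                   t(apply(fam@children, 1, flip)), fam@childSex)
    p2 <- familyPosteriors(fam2, panel2, priorM, priorF, 0.01)
    expect_equal(p1@prob, p2@prob, tolerance = 1e-12)
    expect_equal(p1@logLik, p2@logLik, tolerance = 1e-12)
})

test_that("Mendelian-impossible data at epsilon 0 yield -Inf, not an error", {
    pos <- c(0, 1e5)
    panel <- MarkerPanel(pos, c(0.5, 0.5))
    fam <- Family("m", father = c(2, 2), mother = c(2, 2),
                  children = rbind(c(0, 0), c(2, 2)), c("M", "F"))
    post <- familyPosteriors(fam, panel, priorM, priorF, epsilon = 0)
    expect_identical(post@logLik, -Inf)
    expect_true(all(is.na(post@prob)))
})

test_that("posterior row sums equal expected crossover counts on average", {
    sim <- simMap(3e5, backgroundCM = 30, nHotspots = 3, seed = 31,
                  sexLabel = "male")
    fem <- GeneticMap(c(0, 3e5), c(0, 2), sexLabel = "female")
    ped <- simPedigrees(80, sim$map, fem, panelSize = 25, epsilon = 0,
                        parentMissingProb = 0, obligatoryMale = FALSE,
                        seed = 32)
    posts <- lapply(ped$families, familyPosteriors, panel = ped$panel,
                    priorMapMale = sim$map, priorMapFemale = fem,
                    epsilon = 1e-4)
    exp_male <- unlist(lapply(posts, function(p)
        expectedCrossovers(p)[p@meiosis$sex == "male"]))
    truthM <- ped$truth$meioses[ped$truth$meioses$sex == "male", ]
    ## compare mean expected to mean simulated crossover count
    se <- sd(truthM$nCrossovers) / sqrt(nrow(truthM))
    expect_lt(abs(mean(exp_male) - mean(truthM$nCrossovers)), 3 * se + 0.03)
})

test_that("X-boundary augmentation pins paternal bits and finds boundary crossovers", {
    pos <- c(0, 1e5, 2e5)
    panel <- MarkerPanel(pos, rep(0.5, 3))
    ## father AB throughout the PAR; all three children carry his B
    ## haplotype.  The two sons' paternal side must join the dummy (Y)
    ## chromosome beyond the boundary while the daughter's joins the real
    ## X, so the shared B haplotype can connect to both only through a
    ## crossover between the last PAR marker and the boundary - in the
    ## daughter's meiosis, since the alternative needs one in each son.
    fam <- Family("x", father = c(1, 1, 1), mother = c(0, 0, 0),
                  children = rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1)),
                  childSex = c("M", "M", "F"))
    ## no X markers supplied: unchanged
    un <- augmentParBoundary(fam, panel)
    expect_identical(un$family, fam)
    expect_identical(un$panel, panel)

    ## X markers (hemizygous coding: dummy counts as allele A).  Father's
    ## X allele is B at both markers; sons show only the maternal A.
    xPanel <- MarkerPanel(c(4e5, 4.5e5), c(0.5, 0.5))
    xFam <- Family("x", father = c(1, 1), mother = c(0, 0),
                   children = rbind(c(0, 0), c(0, 0), c(1, 1)),
                   childSex = c("M", "M", "F"))
    aug <- augmentParBoundary(fam, panel, xFam, xPanel)
    expect_equal(nMarkers(aug$panel), 5)
    expect_identical(aug$panel@xLinked, c(FALSE, FALSE, FALSE, TRUE, TRUE))
    expect_error(augmentParBoundary(fam, panel, xFam,
                                    MarkerPanel(c(1.5e5, 4e5), c(0.5, 0.5))),
                 "beyond the pseudoautosomal span")

    mapM <- GeneticMap(c(0, 4.5e5), c(0, 9), sexLabel = "male")
    mapF <- GeneticMap(c(0, 4.5e5), c(0, 4), sexLabel = "female")
    ## without augmentation the crossover is undetectable
    p0 <- familyPosteriors(fam, panel, mapM, mapF, 0.001)
    expect_lt(max(p0@prob[1:3, ]), 0.05)
    ## with augmentation the daughter's boundary crossover appears
    p1 <- familyPosteriors(aug$family, aug$panel, mapM, mapF, 0.001)
    boundaryInt <- 3L
    expect_gt(p1@prob[3, boundaryInt], 0.9)
    expect_lt(max(p1@prob[1:2, boundaryInt]), 0.1)
    ## intervals between X-linked markers carry paternal theta 0
    expect_equal(unname(p1@prob[1:3, 4]), c(0, 0, 0))
    ## the unaugmented family still agrees with path enumeration
    want <- oracleFamily(fam, panel, mapM, mapF, 0.001)
    expect_equal(p0@logLik, want$logLik, tolerance = 1e-9)
})

test_that("event calling follows the mass-scan rule", {
    pos <- seq(0, 5e5, 1e5)
    mkPost <- function(rows) {
        new("CrossoverPosterior", prob = rows,
            meiosis = data.frame(family = "f", parent = "father",
                                 child = seq_len(nrow(rows)), sex = "male"),
            positions = pos, logLik = 0)
    }
    ## all-zero posterior: no events
    expect_equal(nrow(callEvents(mkPost(matrix(0, 1, 5)))), 0)
    ## all mass in one interval: one event there with mass 1
    ev <- callEvents(mkPost(matrix(c(0, 1, 0, 0, 0), 1)))
    expect_equal(nrow(ev), 1)
    expect_equal(c(ev$start, ev$end, ev$mass), c(1e5, 2e5, 1))
    ## (0.2, 0.3, 0.15) run: one event over the three intervals, mass 0.65
    ev2 <- callEvents(mkPost(matrix(c(0, 0.2, 0.3, 0.15, 0), 1)))
    expect_equal(nrow(ev2), 1)
    expect_equal(ev2$mass, 0.65)
    expect_equal(c(ev2$start, ev2$end), c(1e5, 4e5))
    ## sub-threshold run: no event
    expect_equal(nrow(callEvents(mkPost(matrix(c(0, 0.2, 0.2, 0, 0), 1)))),
                 0)
    ## two separated unit masses: two events
    ev3 <- callEvents(mkPost(matrix(c(1, 0, 0, 0, 1), 1)))
    expect_equal(nrow(ev3), 2)
})

test_that("every crossover is recovered when markers are fully informative", {
    ## fully informative paternal markers: father heterozygous everywhere
    ## (haplotype 1 all B, haplotype 2 all A), mother homozygous AA, so a
    ## child's paternal haplotype is read off directly and a template
    ## switch is visible at the exact inter-marker interval.
    set.seed(44)
    pos <- seq(0, 5e5, length.out = 21)
    panel <- MarkerPanel(pos, rep(0.5, 21))
    mapM <- GeneticMap(c(0, 5e5), c(0, 50), sexLabel = "male")
    mapF <- GeneticMap(c(0, 5e5), c(0, 0), sexLabel = "female")
    nrec <- 0; nfound <- 0
    for (f in 1:20) {
        kids <- matrix(0, 3, 21)
        xos <- vector("list", 3)
        for (c in 1:3) {
            xo <- if (runif(1) < 0.5) runif(1, 1, 5e5 - 1) else numeric(0)
            xos[[c]] <- xo
            slot0 <- rbinom(1, 1, 0.5)
            slot <- (slot0 + findInterval(pos, xo)) %% 2
            kids[c, ] <- ifelse(slot == 0, 1, 0)   # B on haplotype 1
        }
        fam <- Family(paste0("i", f), father = rep(1, 21),
                      mother = rep(0, 21), kids, rep("F", 3))
        post <- familyPosteriors(fam, panel, mapM, mapF, epsilon = 0)
        ev <- callEvents(post)
        for (c in 1:3) {
            xo <- xos[[c]]
            if (length(xo) != 1) next
            nrec <- nrec + 1
            hit <- ev[ev$child == c & ev$sex == "male", , drop = FALSE]
            iv <- findInterval(xo, pos)
            if (nrow(hit) >= 1 &&
                any(hit$start <= pos[iv] & pos[iv + 1] <= hit$end))
                nfound <- nfound + 1
        }
    }
    expect_gt(nrec, 15)
    expect_equal(nfound, nrec)
})

test_that("false-positive events are rare on a zero-length generating map", {
    flat <- GeneticMap(c(0, 5e5), c(0, 0), sexLabel = "male")
    fem <- GeneticMap(c(0, 5e5), c(0, 0), sexLabel = "female")
    ped <- simPedigrees(120, flat, fem, panelSize = 20, epsilon = 0.01,
                        parentMissingProb = 0, obligatoryMale = FALSE,
                        seed = 43)
    prior <- GeneticMap(c(0, 5e5), c(0, 50), sexLabel = "male")
    priorF2 <- GeneticMap(c(0, 5e5), c(0, 5), sexLabel = "female")
    nEv <- 0; nMei <- 0
    for (f in ped$families) {
        post <- familyPosteriors(f, ped$panel, prior, priorF2, 0.01)
        nEv <- nEv + nrow(callEvents(post))
        nMei <- nMei + 2 * nChildren(f)
    }
    expect_gt(nMei, 400)
    expect_lt(nEv / nMei, 0.05)
})

test_that("eventsPerMeiosis counts and coverage restriction work", {
    expect_equal(eventsPerMeiosis(data.frame(start = numeric(0),
                                             end = numeric(0)), 10)$rate, 0)
    ev <- data.frame(start = c(0, 100, 900), end = c(50, 200, 1100))
    r <- eventsPerMeiosis(ev, 10, coverage = c(0, 1000))
    expect_equal(r$rate, 0.3)
    expect_equal(r$rateCovered, 0.2)
    expect_error(eventsPerMeiosis(ev, 0), "positive")
})
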