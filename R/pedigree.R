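## ---------------------------------------------------------------------------
## Pedigree data model: marker panels and nuclear families.
##
## Genotypes are coded 0/1/2 = copies of the "B" allele, NA = missing.
## Hemizygous genotypes at X-linked markers (fathers, sons) are coded with
## the dummy chromosome counting as allele "A": a son carrying X allele B is
## coded 1.  The crossover HMM relies on this convention.
## ---------------------------------------------------------------------------

#' MarkerPanel: the marker grid families are genotyped on
#'
#' @slot positions strictly increasing physical positions (bp).
#' @slot freqB population frequency of the "B" allele per marker, in (0, 1);
#'   used to marginalise ungenotyped founders under Hardy-Weinberg.
#' @slot xLinked logical per marker; \code{TRUE} marks markers proximal to
#'   the pseudoautosomal boundary added by \code{\link{augmentParBoundary}},
#'   where fathers and sons are hemizygous.
#' @export
setClass("MarkerPanel",
    representation(positions = "numeric", freqB = "numeric",
                   xLinked = "logical"))

setValidity("MarkerPanel", function(object) {
    p <- object@positions
    if (length(p) != length(object@freqB) ||
        length(p) != length(object@xLinked))
        return("positions, freqB and xLinked must have equal length")
    if (length(p) > 1L && any(diff(p) <= 0))
        return("marker positions must be strictly increasing")
    if (any(object@freqB <= 0 | object@freqB >= 1))
        return("freqB must lie strictly inside (0, 1)")
    TRUE
})

#' @rdname MarkerPanel-class
#' @param positions,freqB,xLinked see slots.
#' @export
MarkerPanel <- function(positions, freqB, xLinked = rep(FALSE,
                        length(positions))) {
    new("MarkerPanel", positions = as.numeric(positions),
        freqB = as.numeric(freqB), xLinked = as.logical(xLinked))
}

#' @rdname MarkerPanel-class
#' @param x a \code{MarkerPanel}.
#' @export
nMarkers <- function(x) length(x@positions)

setMethod("show", "MarkerPanel", function(object) {
    cat(sprintf("MarkerPanel: %d markers (%d X-linked), %.0f-%.0f bp\n",
                nMarkers(object), sum(object@xLinked),
                min(object@positions), max(object@positions)))
})

#' Family: genotypes of a nuclear family over a marker panel
#'
#' At least two children and at least one genotyped parent are required;
#' families with no genotyped parent carry no phase information for the
#' crossover HMM and are rejected outright.
#'
#' @slot id family identifier.
#' @slot father,mother numeric genotype vectors (0/1/2/NA), or length zero
#'   when that parent is wholly ungenotyped.
#' @slot children numeric matrix, one row per child.
#' @slot childSex character, \code{"M"}/\code{"F"} per child (needed for
#'   hemizygosity at X-linked markers).
#' @export
setClass("Family",
    representation(id = "character", father = "numeric", mother = "numeric",
                   children = "matrix", childSex = "character"))

setValidity("Family", function(object) {
    L <- ncol(object@children)
    n <- nrow(object@children)
    if (n < 2L) return("a family needs at least two children")
    if (length(object@father) == 0L && length(object@mother) == 0L)
        return("at least one parent must be genotyped")
    for (g in list(object@father, object@mother))
        if (length(g) && length(g) != L)
            return("parent genotypes must cover the same markers as children")
    if (length(object@childSex) != n)
        return("childSex must have one entry per child")
    if (!all(object@childSex %in% c("M", "F")))
        return("childSex entries must be 'M' or 'F'")
    gt <- c(object@father, object@mother, object@children)
    if (!all(is.na(gt) | gt %in% 0:2))
        return("genotypes must be 0, 1, 2 or NA")
    TRUE
})

#' @rdname Family-class
#' @param id,father,mother,children,childSex see slots. Pass \code{NULL}
#'   for an ungenotyped parent.
#' @export
Family <- function(id, father, mother, children, childSex) {
    new("Family", id = as.character(id),
        father = if (is.null(father)) numeric(0) else as.numeric(father),
        mother = if (is.null(mother)) numeric(0) else as.numeric(mother),
        children = matrix(as.numeric(children), nrow = nrow(children)),
        childSex = as.character(childSex))
}

#' @rdname Family-class
#' @param x a \code{Family}.
#' @export
nChildren <- function(x) nrow(x@children)

setMethod("show", "Family", function(object) {
    cat(sprintf("Family %s: %d children (%s), father %s, mother %s\n",
                object@id, nChildren(object),
                paste(object@childSex, collapse = ""),
                if (length(object@father)) "genotyped" else "missing",
                if (length(object@mother)) "genotyped" else "missing"))
})

#' Append X-linked markers beyond the pseudoautosomal boundary
#'
#' Adds markers proximal to the pseudoautosomal boundary at which fathers
#' and sons are hemizygous: they are modelled with one real X haplotype and
#' one dummy chromosome with a fixed allele and no recombination. Because a
#' son must inherit the dummy (Y-side) haplotype and a daughter the real X,
#' the paternal inheritance bit is pinned at these markers, which makes
#' crossovers between the last pseudoautosomal marker and the boundary
#' detectable.
#'
#' @param family a \linkS4class{Family} over \code{panel}.
#' @param panel the pseudoautosomal \linkS4class{MarkerPanel}.
#' @param xFamily a \linkS4class{Family} holding the same individuals'
#'   genotypes over \code{xPanel} (hemizygous genotypes coded with the dummy
#'   counting as allele "A"), or \code{NULL} to leave the family unchanged.
#' @param xPanel \linkS4class{MarkerPanel} of X-linked markers; all
#'   positions must exceed the pseudoautosomal span.
#' @return \code{list(family =, panel =)} with markers appended and flagged
#'   \code{xLinked}.
#' @export
augmentParBoundary <- function(family, panel, xFamily = NULL, xPanel = NULL) {
    if (is.null(xFamily) || is.null(xPanel))
        return(list(family = family, panel = panel))
    if (min(xPanel@positions) <= max(panel@positions))
        stopf("X-linked markers must lie beyond the pseudoautosomal span")
    if (nChildren(xFamily) != nChildren(family) ||
        !identical(xFamily@childSex, family@childSex))
        stopf("xFamily must describe the same children as family")
    joinParent <- function(g, xg, L, xL) {
        if (!length(g) && !length(xg)) return(numeric(0))
        c(if (length(g)) g else rep(NA_real_, L),
          if (length(xg)) xg else rep(NA_real_, xL))
    }
    L <- nMarkers(panel); xL <- nMarkers(xPanel)
    fam <- Family(family@id,
                  joinParent(family@father, xFamily@father, L, xL),
                  joinParent(family@mother, xFamily@mother, L, xL),
                  cbind(family@children, xFamily@children),
                  family@childSex)
    pan <- MarkerPanel(c(panel@positions, xPanel@positions),
                       c(panel@freqB, xPanel@freqB),
                       c(panel@xLinked, rep(TRUE, xL)))
    list(family = fam, panel = pan)
}

## ---------------------------------------------------------------------------
## Tabular genotype I/O: one row per individual
## family_id individual_id role(sex-coded) sex genotypes(0/1/2/NA)...
## ---------------------------------------------------------------------------

#' Write families as tabular genotype text
#'
#' One row per individual: family id, individual id, role
#' (\code{father}/\code{mother}/\code{child}), sex, then one genotype column
#' per marker (0/1/2, \code{NA} for missing).
#'
#' @param families list of \linkS4class{Family}.
#' @param path output file.
#' @export
writeFamilies <- function(families, path) {
    rows <- lapply(families, function(f) {
        out <- list()
        if (length(f@father))
            out <- c(out, list(c(f@id, paste0(f@id, "_F"), "father", "M",
                                 f@father)))
        if (length(f@mother))
            out <- c(out, list(c(f@id, paste0(f@id, "_M"), "mother", "F",
                                 f@mother)))
        for (i in seq_len(nChildren(f)))
            out <- c(out, list(c(f@id, paste0(f@id, "_C", i), "child",
                                 f@childSex[i], f@children[i, ])))
        do.call(rbind, out)
    })
    tab <- as.data.frame(do.call(rbind, rows))
    write.table(tab, path, quote = FALSE, row.names = FALSE,
                col.names = FALSE, sep = "\t")
    invisible(path)
}

#' Read families from tabular genotype text
#'
#' @param path file written in the \code{\link{writeFamilies}} layout.
#' @return list of \linkS4class{Family}.
#' @export
readFamilies <- function(path) {
    tab <- read.table(path, header = FALSE, sep = "\t",
                      na.strings = "NA", stringsAsFactors = FALSE)
    gcols <- seq(5L, ncol(tab))
    lapply(split(tab, factor(tab[[1L]], levels = unique(tab[[1L]]))),
           function(d) {
        getg <- function(role) {
            r <- d[d[[3L]] == role, gcols, drop = FALSE]
            if (!nrow(r)) NULL else as.numeric(r[1L, ])
        }
        kids <- d[d[[3L]] == "child", , drop = FALSE]
        Family(d[1L, 1L], getg("father"), getg("mother"),
               as.matrix(kids[, gcols, drop = FALSE]), kids[[4L]])
    })
}

#' Write crossover events in the two-column interval dialect
#'
#' Two tab-separated columns, start and end bp of each event, as in the
#' published per-sex crossover lists.
#'
#' @param events event data.frame from \code{\link{callEvents}}.
#' @param path output file.
#' @param sex optional filter (\code{"male"}/\code{"female"}).
#' @export
writeEvents <- function(events, path, sex = NULL) {
    if (!is.null(sex)) events <- events[events$sex == sex, , drop = FALSE]
    write.table(
        data.frame(format(events$start, digits = 17, scientific = FALSE,
                          trim = TRUE),
                   format(events$end, digits = 17, scientific = FALSE,
                          trim = TRUE)),
        path, quote = FALSE, row.names = FALSE, col.names = FALSE,
        sep = "\t")
    invisible(path)
}

#' Read crossover events from two-column interval text
#'
#' @param path file with start/end columns (extra columns ignored).
#' @param sex sex label to attach.
#' @return event data.frame with columns start, end, parent, sex, mass.
#' @export
readEvents <- function(path, sex = "male") {
    tab <- read.table(path, header = FALSE)
    data.frame(parent = paste0("p", seq_len(nrow(tab))), sex = sex,
               start = tab[[1L]], end = tab[[2L]], mass = 1)
}
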