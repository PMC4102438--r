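## ---------------------------------------------------------------------------
## Anchor sets: degenerate-motif scanning, thinning and filtering rules
## that produce the anchor positions rate profiles and near-anchor AFS
## statistics are centred on.  Coordinates are 0-based throughout; the
## reported position of a match is its midpoint in forward-strand
## coordinates.
## ---------------------------------------------------------------------------

#' AnchorSet: sorted anchor positions with optional strengths
#'
#' @slot positions sorted bp midpoints.
#' @slot provenance one of \code{"motif"}, \code{"peak"},
#'   \code{"event-midpoint"} or free text.
#' @slot strength optional per-anchor score (e.g. peak p-value), length 0
#'   or one per position.
#' @export
setClass("AnchorSet",
    representation(positions = "numeric", provenance = "character",
                   strength = "numeric"),
    prototype(provenance = "motif", strength = numeric(0)))

setValidity("AnchorSet", function(object) {
    p <- object@positions
    if (is.unsorted(p)) return("positions must be sorted")
    if (length(object@strength) &&
        length(object@strength) != length(p))
        return("strength must align 1:1 with positions")
    TRUE
})

#' @rdname AnchorSet-class
#' @param positions,provenance,strength see slots.
#' @export
AnchorSet <- function(positions, provenance = "motif",
                      strength = numeric(0)) {
    o <- order(positions)
    new("AnchorSet", positions = as.numeric(positions)[o],
        provenance = provenance,
        strength = if (length(strength)) as.numeric(strength)[o] else
            numeric(0))
}

#' @rdname AnchorSet-class
#' @param x an \code{AnchorSet}.
#' @export
anchorPositions <- function(x) x@positions

setMethod("show", "AnchorSet", function(object) {
    cat(sprintf("AnchorSet (%s): %d anchors%s\n", object@provenance,
                length(object@positions),
                if (length(object@positions))
                    sprintf(", %.0f-%.0f bp", min(object@positions),
                            max(object@positions)) else ""))
})

setMethod("length", "AnchorSet", function(x) length(x@positions))

subsetAnchors <- function(x, keep) {
    new("AnchorSet", positions = x@positions[keep],
        provenance = x@provenance,
        strength = if (length(x@strength)) x@strength[keep] else numeric(0))
}

#' Scan a sequence for a degenerate motif
#'
#' Finds exact matches to a motif over \code{{A,C,G,T,n}} where \code{n}
#' matches any base (the canonical PRDM9 target is the 13-bp
#' \code{CCnCCnTnnCCnC}). An \code{N} in the sequence never matches, even
#' at degenerate motif positions. Reverse-complement matches are included
#' by default; reported positions are match midpoints in forward-strand
#' coordinates (0-based), deduplicated.
#'
#' @param sequence a \code{DNAString} or single character string.
#' @param motif motif over \code{A,C,G,T,n}.
#' @param bothStrands scan the reverse complement too (the motif is not
#'   palindromic, so this matters).
#' @return an \linkS4class{AnchorSet} with provenance \code{"motif"}.
#' @export
scanDegenerateMotif <- function(sequence, motif = "CCnCCnTnnCCnC",
                                bothStrands = TRUE) {
    subject <- if (is(sequence, "DNAString")) sequence else
        Biostrings::DNAString(sequence)
    if (nchar(motif) > length(subject))
        return(AnchorSet(numeric(0), "motif"))
    pat <- Biostrings::DNAString(chartr("n", "N", toupper(motif)))
    w <- length(pat)
    hasN <- Biostrings::start(Biostrings::matchPattern("N", subject))
    scan1 <- function(p) {
        m <- Biostrings::matchPattern(p, subject, fixed = "subject")
        st <- Biostrings::start(m)
        if (length(hasN) && length(st)) {
            ## drop matches overlapping any N in the sequence
            bad <- vapply(st, function(s)
                any(hasN >= s & hasN < s + w), logical(1))
            st <- st[!bad]
        }
        st
    }
    starts <- scan1(pat)
    if (bothStrands)
        starts <- c(starts, scan1(Biostrings::reverseComplement(pat)))
    mids <- sort(unique(starts - 1 + (w - 1) / 2))
    AnchorSet(mids, "motif")
}

#' Keep anchors in SNP-dense surroundings
#'
#' An anchor is retained iff the SNP count in the centred window strictly
#' exceeds \code{windowBp * minPerBp} (the published rule: more than one
#' SNP per 2 kb in the surrounding 50 kb).
#'
#' @param anchors an \linkS4class{AnchorSet}.
#' @param snpPositions sorted SNP positions (bp).
#' @param windowBp centred window width.
#' @param minPerBp required SNP density (strict inequality).
#' @return the filtered \linkS4class{AnchorSet} (a subset of the input).
#' @export
filterBySnpDensity <- function(anchors, snpPositions, windowBp = 50000,
                               minPerBp = 1 / 2000) {
    snp <- sort(snpPositions)
    lo <- anchors@positions - windowBp / 2
    hi <- anchors@positions + windowBp / 2
    cnt <- findInterval(hi, snp, left.open = TRUE) -
        findInterval(lo, snp, left.open = TRUE)
    subsetAnchors(anchors, cnt > windowBp * minPerBp)
}

## single-linkage chaining: successive gaps <= radius join a cluster
chainClusters <- function(pos, radiusBp) {
    if (!length(pos)) return(integer(0))
    cumsum(c(1L, as.integer(diff(pos) > radiusBp)))
}

#' Thin clustered anchors to the most central member
#'
#' Clusters are formed by single-linkage chaining at \code{radiusBp}; each
#' cluster contributes the member minimising the summed distance to the
#' other members (ties broken leftmost).
#'
#' @param anchors an \linkS4class{AnchorSet}.
#' @param radiusBp chaining radius (default 150).
#' @return the thinned \linkS4class{AnchorSet}.
#' @export
thinClustered <- function(anchors, radiusBp = 150) {
    pos <- anchors@positions
    cl <- chainClusters(pos, radiusBp)
    keep <- vapply(split(seq_along(pos), cl), function(i) {
        d <- vapply(pos[i], function(p) sum(abs(pos[i] - p)), numeric(1))
        i[which.min(d)]
    }, integer(1))
    subsetAnchors(anchors, sort(keep))
}

#' Thin peak calls to the most strongly signalled per cluster
#'
#' Peaks within \code{radiusBp} of one another (chained on interval
#' midpoints) are reduced to the peak with the smallest p-value (ties
#' leftmost). Anchor positions are interval midpoints.
#'
#' @param peaks data.frame with columns start, end, p.
#' @param radiusBp chaining radius (default 10000).
#' @return an \linkS4class{AnchorSet} with provenance \code{"peak"} and
#'   p-values in \code{strength}.
#' @export
thinPeaksStrongest <- function(peaks, radiusBp = 10000) {
    if (!nrow(peaks)) return(AnchorSet(numeric(0), "peak"))
    if (any(peaks$p <= 0 | peaks$p > 1))
        stopf("peak p-values must lie in (0, 1]")
    mid <- (peaks$start + peaks$end) / 2
    o <- order(mid)
    mid <- mid[o]; pv <- peaks$p[o]
    cl <- chainClusters(mid, radiusBp)
    keep <- vapply(split(seq_along(mid), cl),
                   function(i) i[which.min(pv[i])], integer(1))
    keep <- sort(keep)
    AnchorSet(mid[keep], "peak", pv[keep])
}

#' Keep anchors contained in annotation intervals
#'
#' Half-open containment: an anchor at an interval start is retained, one
#' at the end is not.
#'
#' @param anchors an \linkS4class{AnchorSet}.
#' @param annotation data.frame with sorted, non-overlapping start/end
#'   columns (bp, half-open).
#' @return the filtered \linkS4class{AnchorSet}.
#' @export
filterByAnnotation <- function(anchors, annotation) {
    if (!nrow(annotation)) return(subsetAnchors(anchors, logical(0)))
    pos <- anchors@positions
    idx <- findInterval(pos, annotation$start)
    keep <- idx >= 1L & pos < annotation$end[pmax(idx, 1L)]
    subsetAnchors(anchors, keep)
}

## ---------------------------------------------------------------------------
## BED-like I/O
## ---------------------------------------------------------------------------

#' Read peak intervals from BED-like text
#'
#' Three whitespace-delimited columns: start, end, p-value of the peak
#' call.
#' @param path file path.
#' @return data.frame with columns start, end, p.
#' @export
readPeaks <- function(path) {
    tab <- read.table(path, header = FALSE, comment.char = "#")
    data.frame(start = tab[[1L]], end = tab[[2L]], p = tab[[3L]])
}

#' Read / write anchor positions as single-column text
#' @param path file path.
#' @rdname anchorIO
#' @export
readAnchors <- function(path) {
    tab <- read.table(path, header = FALSE, comment.char = "#")
    AnchorSet(tab[[1L]],
              strength = if (ncol(tab) > 1L) tab[[2L]] else numeric(0))
}

#' @rdname anchorIO
#' @param anchors an \linkS4class{AnchorSet}.
#' @export
writeAnchors <- function(anchors, path) {
    d <- data.frame(pos = format(anchors@positions, digits = 17,
                                 scientific = FALSE, trim = TRUE))
    if (length(anchors@strength)) d$strength <- anchors@strength
    write.table(d, path, quote = FALSE, row.names = FALSE,
                col.names = FALSE, sep = "\t")
    invisible(path)
}

#' Read a sequence from FASTA
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet} returning the
#' first record as a \code{DNAString}.
#' @param path FASTA file.
#' @export
readSequence <- function(path) {
    Biostrings::readDNAStringSet(path)[[1L]]
}
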