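#' @include AllClasses.R
NULL

#' Accessors for the core classes
#'
#' Small accessor generics so that slot layout stays private: motif length,
#' number of input sites, the 4 x i frequency profile, the cached maximum
#' attainable raw score, family label, site sequences and provenance, genome
#' id, contig set and gene features, and the upstream-region sequence.
#'
#' @param x an object of the documented classes.
#' @return the corresponding component; see each method.
#' @name accessors
#' @rdname accessors
#' @examples
#' pfm <- buildPFM(c("ACGT", "ACGA", "ACTT", "GCGT"))
#' motifLength(pfm)
#' maxAttainable(pfm)
NULL

#' @rdname accessors
#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))

#' @rdname accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname accessors
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @rdname accessors
#' @export
setGeneric("maxAttainable", function(x) standardGeneric("maxAttainable"))

#' @rdname accessors
#' @export
setGeneric("familyLabel", function(x) standardGeneric("familyLabel"))

#' @rdname accessors
#' @export
setGeneric("siteSequences", function(x) standardGeneric("siteSequences"))

#' @rdname accessors
#' @export
setGeneric("siteProvenance", function(x) standardGeneric("siteProvenance"))

#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))

#' @rdname accessors
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))

#' @rdname accessors
#' @export
setGeneric("geneFeatures", function(x) standardGeneric("geneFeatures"))

#' @rdname accessors
#' @export
setGeneric("regionSequence", function(x) standardGeneric("regionSequence"))

#' Consensus sequence of a frequency matrix
#'
#' Per column: the single nucleotide when its fraction exceeds
#' \code{degeneracyThreshold}; otherwise the IUPAC code covering every
#' nucleotide with fraction >= 0.25; otherwise N.
#'
#' @param x a \linkS4class{FrequencyMatrix}.
#' @param degeneracyThreshold fraction above which a column is written as a
#'   single base (default 0.5).
#' @return a single IUPAC string of the motif length.
#' @examples
#' consensusIUPAC(buildPFM(c("ACGT", "ACGA", "ACTT", "GCGT")))
#' @export
setGeneric("consensusIUPAC",
           function(x, degeneracyThreshold = 0.5) standardGeneric("consensusIUPAC"))
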