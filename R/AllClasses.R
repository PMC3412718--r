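#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement consensusMatrix width
#' @importFrom GenomicRanges GRanges start end strand seqnames mcols
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols<-
#' @importFrom stats setNames runif
#' @importFrom utils read.delim read.table write.table
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' GenomeRecord: a bacterial genome with CDS features
#'
#' Container pairing contig sequences with protein-coding gene features.
#' Contigs are held as a named \link[Biostrings]{DNAStringSet}; features as a
#' \link[GenomicRanges]{GRanges} (1-based closed coordinates, the Bioconductor
#' convention) carrying \code{gene_id} and \code{locus_tag} metadata columns.
#'
#' @slot genomeId single genome identifier.
#' @slot contigs named \code{DNAStringSet} of contig sequences (A/C/G/T/N).
#' @slot features \code{GRanges} of CDS features, sorted by (contig, start).
#'
#' @exportClass GenomeRecord
setClass("GenomeRecord",
  representation(genomeId = "character",
                 contigs = "DNAStringSet",
                 features = "GRanges"))

setValidity("GenomeRecord", function(object) {
  msg <- character(0)
  if (length(object@genomeId) != 1L || !nzchar(object@genomeId))
    msg <- c(msg, "genomeId must be a single non-empty string")
  if (length(object@contigs) == 0L || any(width(object@contigs) == 0L))
    msg <- c(msg, "contig sequences must be non-empty")
  if (is.null(names(object@contigs)) || anyDuplicated(names(object@contigs)))
    msg <- c(msg, "contigs must have unique names")
  ft <- object@features
  if (length(ft)) {
    need <- c("gene_id", "locus_tag")
    if (!all(need %in% colnames(mcols(ft))))
      msg <- c(msg, "features need gene_id and locus_tag metadata columns")
    bad <- !(as.character(seqnames(ft)) %in% names(object@contigs))
    if (any(bad))
      msg <- c(msg, paste0("feature ", mcols(ft)$gene_id[bad][1L],
                           " references a contig absent from the sequence set"))
    len <- setNames(width(object@contigs), names(object@contigs))
    over <- end(ft) > len[as.character(seqnames(ft))] | start(ft) < 1L
    if (any(over, na.rm = TRUE))
      msg <- c(msg, "feature coordinates exceed contig bounds")
  }
  if (length(msg)) msg else TRUE
})

#' FrequencyMatrix: per-position nucleotide fractions of a binding motif
#'
#' The position frequency matrix (PFM) underlying Similar Motif Scoring: a
#' 4 x i matrix of fractions f_N(j), N in {A,C,G,T}, each column summing to 1.
#' The highest attainable raw score (sum over columns of the column maximum)
#' is cached at construction.
#'
#' @slot profile 4 x i numeric matrix, rows named A,C,G,T; columns sum to 1.
#' @slot nSites number of aligned sites the matrix was built from.
#' @slot maxAttainable cached sum of per-column maxima, in (0, i].
#' @slot familyLabel free-text label (e.g. the taxonomic family).
#'
#' @exportClass FrequencyMatrix
setClass("FrequencyMatrix",
  representation(profile = "matrix", nSites = "integer",
                 maxAttainable = "numeric", familyLabel = "character"))

setValidity("FrequencyMatrix", function(object) {
  p <- object@profile
  msg <- character(0)
  if (!is.numeric(p) || nrow(p) != 4L || !identical(rownames(p), c("A", "C", "G", "T")))
    msg <- c(msg, "profile must be a numeric matrix with rows A,C,G,T")
  else {
    if (any(p < 0 | p > 1)) msg <- c(msg, "frequencies must lie in [0,1]")
    if (any(abs(colSums(p) - 1) > 1e-9))
      msg <- c(msg, "each profile column must sum to 1 (tolerance 1e-9)")
    ma <- sum(apply(p, 2L, max))
    if (abs(ma - object@maxAttainable) > 1e-9)
      msg <- c(msg, "cached maxAttainable disagrees with the profile")
    if (object@maxAttainable <= 0 || object@maxAttainable > ncol(p) + 1e-9)
      msg <- c(msg, "maxAttainable must lie in (0, i]")
  }
  if (length(object@nSites) != 1L || object@nSites < 1L)
    msg <- c(msg, "nSites must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' BindingSiteSet: aligned equal-length binding sites with provenance
#'
#' @slot sites \code{DNAStringSet} of equal-width sequences over strict
#'   A/C/G/T (no ambiguity codes).
#' @slot provenance data.frame with one row per site: genome_id, gene_id,
#'   offset (1-based within the upstream region), strand.
#'
#' @exportClass BindingSiteSet
setClass("BindingSiteSet",
  representation(sites = "DNAStringSet", provenance = "data.frame"))

setValidity("BindingSiteSet", function(object) {
  msg <- character(0)
  s <- object@sites
  if (length(s) < 1L) msg <- c(msg, "at least one site is required")
  else {
    if (length(unique(width(s))) != 1L) msg <- c(msg, "sites must be equal length")
    cm <- consensusMatrix(s)
    extra <- setdiff(rownames(cm)[rowSums(cm) > 0], c("A", "C", "G", "T"))
    if (length(extra))
      msg <- c(msg, paste0("sites restricted to A/C/G/T; found: ",
                           paste(extra, collapse = ",")))
  }
  if (nrow(object@provenance) != length(s))
    msg <- c(msg, "provenance must have one row per site")
  if (length(msg)) msg else TRUE
})

#' SeedPattern: degenerate anchor-site description
#'
#' Describes the conserved site searched for in orthologous upstream regions:
#' an IUPAC pattern (default the palindromic TGTNA-N7-TNACA consensus), the
#' promoter -35 element it sits upstream of (default TTGAC), the admissible
#' spacer between site and -35 element, and the mismatch budget at defined
#' (non-N) pattern positions.
#'
#' @slot pattern IUPAC degenerate string.
#' @slot promoterElement exact -35 signature searched downstream of the site.
#' @slot spacerRange integer pair, admissible nt between site 3' end and the
#'   promoter element (default 3..6).
#' @slot maxMismatches mismatch budget at non-N pattern positions.
#'
#' @exportClass SeedPattern
setClass("SeedPattern",
  representation(pattern = "character", promoterElement = "character",
                 spacerRange = "integer", maxMismatches = "integer"))

setValidity("SeedPattern", function(object) {
  msg <- character(0)
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", object@pattern))
    msg <- c(msg, "pattern must be an IUPAC nucleotide string")
  if (length(object@spacerRange) != 2L ||
      object@spacerRange[1L] > object@spacerRange[2L])
    msg <- c(msg, "spacerRange must be an ordered integer pair")
  if (object@maxMismatches < 0L) msg <- c(msg, "maxMismatches must be >= 0")
  if (length(msg)) msg else TRUE
})

#' UpstreamRegion: the sequence immediately upstream of an operon leader
#'
#' Holds the regulatory window upstream of a translation start, in
#' coding-strand orientation (5' to 3' toward the start codon, so the last
#' base of \code{sequence} is at distance 1 from the start codon).
#'
#' @slot geneId leader gene the region belongs to.
#' @slot genomeId owning genome.
#' @slot contig contig name.
#' @slot sequence upstream sequence, coding-strand orientation; may be "".
#' @slot gstart,gend genomic span of the window, 1-based closed
#'   (\code{gend < gstart} for an empty region).
#' @slot strand strand of the leader gene.
#' @slot truncated TRUE when a contig edge clipped the requested window.
#' @slot divergonPartner gene id of the head-to-head partner, or NULL.
#'
#' @exportClass UpstreamRegion
setClass("UpstreamRegion",
  representation(geneId = "character", genomeId = "character",
                 contig = "character", sequence = "character",
                 gstart = "integer", gend = "integer", strand = "character",
                 truncated = "logical", divergonPartner = "characterOrNULL"))

setValidity("UpstreamRegion", function(object) {
  msg <- character(0)
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be + or -")
  n <- nchar(object@sequence)
  if (n > 0L && n != object@gend - object@gstart + 1L)
    msg <- c(msg, "sequence length disagrees with the genomic span")
  if (length(msg)) msg else TRUE
})

#' PresenceAbsenceMatrix: ortholog-family copy counts across genomes
#'
#' Family x genome copy counts with, in parallel, the number of copies whose
#' operon carries a predicted binding site ("regulated" copies). Rendered in
#' the conventional "total(regulated)" cell syntax, blank for absence.
#'
#' @slot counts integer matrix, families x genomes.
#' @slot regulated integer matrix of the same shape; regulated <= counts.
#'
#' @exportClass PresenceAbsenceMatrix
setClass("PresenceAbsenceMatrix",
  representation(counts = "matrix", regulated = "matrix"))

setValidity("PresenceAbsenceMatrix", function(object) {
  msg <- character(0)
  if (!identical(dim(object@counts), dim(object@regulated)))
    msg <- c(msg, "counts and regulated must share dimensions")
  else {
    if (any(object@counts < 0) || any(object@regulated < 0))
      msg <- c(msg, "counts must be non-negative")
    if (any(object@regulated > object@counts))
      msg <- c(msg, "regulated copies cannot exceed total copies")
  }
  if (length(msg)) msg else TRUE
})
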