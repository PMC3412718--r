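#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a GenomeRecord
#'
#' @param genomeId single genome identifier.
#' @param contigs named \link[Biostrings]{DNAStringSet} (or named character
#'   vector) of contig sequences.
#' @param features \link[GenomicRanges]{GRanges} of CDS features with
#'   \code{gene_id} and \code{locus_tag} metadata columns, 1-based closed.
#' @return a validated \linkS4class{GenomeRecord} with features sorted by
#'   (contig, start).
#' @export
GenomeRecord <- function(genomeId, contigs, features) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  ord <- order(as.character(GenomicRanges::seqnames(features)),
               GenomicRanges::start(features))
  new("GenomeRecord", genomeId = genomeId, contigs = contigs,
      features = features[ord])
}

#' @rdname accessors
#' @export
setMethod("genomeId", "GenomeRecord", function(x) x@genomeId)

#' @rdname accessors
#' @export
setMethod("contigs", "GenomeRecord", function(x) x@contigs)

#' @rdname accessors
#' @export
setMethod("geneFeatures", "GenomeRecord", function(x) x@features)

setMethod("show", "GenomeRecord", function(object) {
  cat("GenomeRecord", object@genomeId, "\n",
      " ", length(object@contigs), "contig(s),",
      sum(Biostrings::width(object@contigs)), "bp;",
      length(object@features), "CDS feature(s)\n")
})

#' Read a genome from FASTA + GFF3
#'
#' Loads contig sequences and CDS features. Coordinates are kept in the GFF3
#' convention (1-based closed), which is also the GRanges convention, so no
#' conversion is applied. Features lacking an explicit \code{ID} fall back to
#' \code{locus_tag} for their gene id.
#'
#' @param fastaPath path to a (multi-)FASTA file of contigs.
#' @param annotationPath path to a GFF3 file; only \code{type == "CDS"} rows
#'   are used.
#' @param genomeId identifier for the record; defaults to the FASTA basename.
#' @return a \linkS4class{GenomeRecord}.
#' @examples
#' spec <- simulationSpec(seed = 7, genesPerGenome = 4)
#' sim <- simulateGenome(spec, genomeId = "demo")
#' paths <- writeGenome(sim$genome, tempfile(), tempfile())
#' g <- readGenome(paths$fasta, paths$gff, genomeId = "demo")
#' geneFeatures(g)
#' @export
readGenome <- function(fastaPath, annotationPath, genomeId = NULL) {
  contigs <- Biostrings::readDNAStringSet(fastaPath)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  gr <- rtracklayer::import(annotationPath, format = "GFF3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "CDS"]
  if (length(gr) == 0L)
    stop("annotation contains no CDS features: ", annotationPath)
  missing <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                     names(contigs))
  if (length(missing)) {
    bad <- gr[as.character(GenomicRanges::seqnames(gr)) %in% missing][1L]
    stop("feature ", if (!is.null(bad$ID)) bad$ID else "<unnamed>",
         " references contig '", missing[1L], "' absent from the FASTA")
  }
  id <- if ("ID" %in% colnames(S4Vectors::mcols(gr))) as.character(gr$ID)
        else rep(NA_character_, length(gr))
  lt <- if ("locus_tag" %in% colnames(S4Vectors::mcols(gr)))
          as.character(gr$locus_tag) else rep(NA_character_, length(gr))
  id[is.na(id)] <- lt[is.na(id)]
  if (anyNA(id)) stop("CDS features need an ID or locus_tag attribute")
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::IRanges(GenomicRanges::start(gr),
                                                 GenomicRanges::end(gr)),
                                strand = GenomicRanges::strand(gr))
  out$gene_id <- id
  out$locus_tag <- ifelse(is.na(lt), id, lt)
  if (is.null(genomeId))
    genomeId <- sub("\\.(fa|fasta|fna)$", "", basename(fastaPath))
  GenomeRecord(genomeId, contigs, out)
}

#' Write a genome as FASTA + GFF3
#'
#' @param genome a \linkS4class{GenomeRecord}.
#' @param fastaPath,gffPath output paths.
#' @return invisibly, a list with the two paths.
#' @export
writeGenome <- function(genome, fastaPath, gffPath) {
  Biostrings::writeXStringSet(contigs(genome), fastaPath)
  gr <- geneFeatures(genome)
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::IRanges(GenomicRanges::start(gr),
                                                 GenomicRanges::end(gr)),
                                strand = GenomicRanges::strand(gr))
  out$type <- "CDS"
  out$phase <- 0L
  out$ID <- gr$gene_id
  out$locus_tag <- gr$locus_tag
  rtracklayer::export(out, gffPath, format = "GFF3")
  invisible(list(fasta = fastaPath, gff = gffPath))
}

#' Infer operons from gene order
#'
#' Consecutive genes (in coordinate order) on the same contig and strand
#' whose intergenic gap is at most \code{maxGap} nt are merged into one
#' operon; an interleaved opposite-strand gene breaks the chain. The leader
#' is the 5'-most member on the coding strand (leftmost for +, rightmost
#' for -). Single genes become singleton operons, so operons partition the
#' gene set.
#'
#' @param genome a \linkS4class{GenomeRecord}.
#' @param maxGap maximum intergenic distance (nt) merged within an operon;
#'   default 150, the common prokaryotic heuristic.
#' @return a data.frame with one row per operon: \code{operon_id},
#'   \code{contig}, \code{strand}, \code{leader_gene}, \code{leader_locus},
#'   \code{members} (comma-separated, 5' to 3'), \code{n_genes},
#'   \code{start}, \code{end}.
#' @export
inferOperons <- function(genome, maxGap = 150) {
  ft <- geneFeatures(genome)
  ctg <- as.character(GenomicRanges::seqnames(ft))
  str <- as.character(GenomicRanges::strand(ft))
  s <- GenomicRanges::start(ft); e <- GenomicRanges::end(ft)
  n <- length(ft)
  grp <- integer(n)
  g <- 0L
  for (k in seq_len(n)) {
    newgrp <- k == 1L || ctg[k] != ctg[k - 1L] || str[k] != str[k - 1L] ||
      (s[k] - e[k - 1L] - 1L) > maxGap
    if (newgrp) g <- g + 1L
    grp[k] <- g
  }
  ids <- as.character(ft$gene_id)
  lts <- as.character(ft$locus_tag)
  rows <- lapply(split(seq_len(n), grp), function(ix) {
    strand <- str[ix[1L]]
    ord <- if (strand == "+") ix else rev(ix)   # 5' -> 3' on coding strand
    leader <- ord[1L]
    data.frame(contig = ctg[leader], strand = strand,
               leader_gene = ids[leader], leader_locus = lts[leader],
               members = paste(ids[ord], collapse = ","),
               n_genes = length(ix),
               start = min(s[ix]), end = max(e[ix]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  out <- cbind(operon_id = sprintf("opn%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Member gene ids of each operon
#'
#' @param operons data.frame from \code{\link{inferOperons}}.
#' @return named list of character vectors (5' to 3').
#' @export
operonMembers <- function(operons) {
  setNames(strsplit(operons$members, ",", fixed = TRUE), operons$operon_id)
}

#' Extract the upstream region of an operon leader
#'
#' Returns the window of \code{window} nt immediately upstream of the
#' leader's translation start, in coding-strand orientation: for a + strand
#' leader starting at s the genomic span is [s - window, s - 1]; for a -
#' strand leader ending at e it is the reverse complement of
#' [e + 1, e + window]. The window is clipped (and flagged truncated) at
#' contig edges; a leader abutting the edge yields an empty region, not an
#' error. No clipping at upstream genes is performed: the window is fixed.
#'
#' @param genome a \linkS4class{GenomeRecord}.
#' @param operon one row of the \code{\link{inferOperons}} data.frame (or a
#'   leader gene id).
#' @param window upstream window size in nt (default 250).
#' @param divergons optional named vector from \code{\link{classifyDivergons}}
#'   used to annotate the region's partner.
#' @return an \linkS4class{UpstreamRegion}.
#' @export
extractUpstream <- function(genome, operon, window = 250, divergons = NULL) {
  ft <- geneFeatures(genome)
  if (is.character(operon)) {
    k <- match(operon, ft$gene_id)
    if (is.na(k)) stop("no such gene: ", operon)
    leader <- operon
    ctgName <- as.character(GenomicRanges::seqnames(ft))[k]
    strand <- as.character(GenomicRanges::strand(ft))[k]
    s <- GenomicRanges::start(ft)[k]; e <- GenomicRanges::end(ft)[k]
  } else {
    leader <- operon$leader_gene
    k <- match(leader, ft$gene_id)
    ctgName <- operon$contig
    strand <- operon$strand
    s <- GenomicRanges::start(ft)[k]; e <- GenomicRanges::end(ft)[k]
  }
  ctg <- contigs(genome)[[ctgName]]
  clen <- length(ctg)
  if (strand == "+") {
    gstart <- max(1L, s - as.integer(window)); gend <- s - 1L
    truncated <- (s - window) < 1L
  } else {
    gstart <- e + 1L; gend <- min(clen, e + as.integer(window))
    truncated <- (e + window) > clen
  }
  seq <- if (gend >= gstart)
    as.character(Biostrings::subseq(ctg, gstart, gend)) else ""
  if (strand == "-" && nzchar(seq)) seq <- .rc(seq)
  partner <- if (!is.null(divergons) && leader %in% names(divergons))
    unname(divergons[leader]) else NULL
  new("UpstreamRegion", geneId = leader, genomeId = genomeId(genome),
      contig = ctgName, sequence = seq,
      gstart = as.integer(gstart), gend = as.integer(gend),
      strand = strand, truncated = truncated, divergonPartner = partner)
}

#' @rdname accessors
#' @export
setMethod("regionSequence", "UpstreamRegion", function(x) x@sequence)

setMethod("show", "UpstreamRegion", function(object) {
  cat("UpstreamRegion", object@geneId, "(", object@genomeId, ")\n ",
      object@contig, ":", object@gstart, "-", object@gend,
      "strand", object@strand, ";", nchar(object@sequence), "nt",
      if (object@truncated) "(truncated)" else "", "\n")
})

#' Identify divergon partners
#'
#' Two operon leaders arranged head-to-head (a - strand operon immediately
#' followed by a + strand operon on the same contig) share one intergenic
#' regulatory interval; their leaders are mutual divergon partners. Tandem
#' and convergent arrangements never qualify.
#'
#' @param genome a \linkS4class{GenomeRecord}.
#' @param operons data.frame from \code{\link{inferOperons}}.
#' @return named character vector mapping each divergon leader to its
#'   partner leader gene id (both directions present).
#' @export
classifyDivergons <- function(genome, operons) {
  ops <- operons[order(operons$contig, operons$start), , drop = FALSE]
  out <- character(0)
  if (nrow(ops) < 2L) return(out)
  for (k in seq_len(nrow(ops) - 1L)) {
    a <- ops[k, ]; b <- ops[k + 1L, ]
    if (a$contig == b$contig && a$strand == "-" && b$strand == "+" &&
        a$end < b$start) {
      out[a$leader_gene] <- b$leader_gene
      out[b$leader_gene] <- a$leader_gene
    }
  }
  out
}

#' Write upstream regions as FASTA
#'
#' Headers follow \code{genome|gene|gstart-gend|strand}.
#'
#' @param regions list of \linkS4class{UpstreamRegion} objects.
#' @param path output FASTA path.
#' @return invisibly, \code{path}.
#' @export
writeUpstreamFasta <- function(regions, path) {
  keep <- vapply(regions, function(r) nzchar(r@sequence), TRUE)
  regions <- regions[keep]
  seqs <- Biostrings::DNAStringSet(vapply(regions, function(r) r@sequence, ""))
  names(seqs) <- vapply(regions, function(r)
    paste(r@genomeId, r@geneId, paste0(r@gstart, "-", r@gend), r@strand,
          sep = "|"), "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
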