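#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Similar Motif Scoring of one window
#'
#' The SMS statistic: the raw score of a window of the motif length i is the
#' sum over positions j of the matrix frequency of the window's nucleotide,
#' raw = sum_j f_w[j](j). Any non-A/C/G/T character (including N)
#' contributes 0. Dividing by i gives the similarity score (0..1); dividing
#' by the highest attainable raw score given the matrix gives the relative
#' similarity score (0..1) used for regulon selection.
#'
#' @param pfm a \linkS4class{FrequencyMatrix}.
#' @param window string of exactly the motif length.
#' @return list with \code{raw}, \code{similarity} and \code{relative}.
#' @examples
#' pfm <- buildPFM(c("ACGT", "ACGA", "ACTT", "GCGT"))
#' smsScore(pfm, "ACGT")   # raw 3.25, relative 1
#' smsScore(pfm, "GCTA")   # raw 1.75
#' @export
smsScore <- function(pfm, window) {
  i <- motifLength(pfm)
  window <- toupper(window)
  if (nchar(window) != i)
    stop("window length ", nchar(window), " != motif length ", i)
  p5 <- rbind(profileMatrix(pfm), 0)
  code <- .encode5(window)
  raw <- sum(p5[cbind(code, seq_len(i))])
  list(raw = raw, similarity = raw / i, relative = raw / maxAttainable(pfm))
}

#' Scan an upstream region for motif matches
#'
#' Every window of the motif length on the coding-strand sequence and (by
#' default) its reverse complement is scored with \code{\link{smsScore}};
#' hits with relative similarity at or above \code{threshold} are returned,
#' ranked by relative score (descending), then by smaller distance to the
#' translation start, + strand before -, then smaller offset. The boundary
#' is inclusive: the selection criterion ">87\%" is applied as
#' relative >= 0.87.
#'
#' @param pfm a \linkS4class{FrequencyMatrix}.
#' @param region an \linkS4class{UpstreamRegion} or plain sequence string.
#' @param bothStrands also score reverse-complement windows (default TRUE;
#'   the motif is near-palindromic and divergon sites read either way).
#' @param threshold minimum relative similarity retained (default 0.87).
#' @return data.frame of hits: \code{window_sequence} (as read on its
#'   strand), \code{raw}, \code{similarity}, \code{relative}, \code{offset}
#'   (1-based window start in forward region coordinates),
#'   \code{distance_to_start} (site 3' edge to translation start, 1 =
#'   adjacent), \code{strand}, \code{gene_id}, \code{genome_id}. The
#'   threshold is attached as attribute \code{"threshold"}.
#' @export
scanRegion <- function(pfm, region, bothStrands = TRUE, threshold = 0.87) {
  seq <- if (is(region, "UpstreamRegion")) regionSequence(region) else region
  gid <- if (is(region, "UpstreamRegion")) region@geneId else NA_character_
  gnm <- if (is(region, "UpstreamRegion")) region@genomeId else NA_character_
  i <- motifLength(pfm)
  L <- nchar(seq)
  empty <- data.frame(window_sequence = character(0), raw = numeric(0),
                      similarity = numeric(0), relative = numeric(0),
                      offset = integer(0), distance_to_start = integer(0),
                      strand = character(0), gene_id = character(0),
                      genome_id = character(0), stringsAsFactors = FALSE)
  attr(empty, "threshold") <- threshold
  if (L < i) return(empty)
  p5 <- rbind(profileMatrix(pfm), 0)
  ma <- maxAttainable(pfm)
  code <- .encode5(seq)
  offs <- seq_len(L - i + 1L)

  collect <- function(raws, strand) {
    rel <- raws / ma
    keep <- which(rel >= threshold)
    if (!length(keep)) return(NULL)
    o <- offs[keep]
    data.frame(
      window_sequence = substring(seq, o, o + i - 1L),
      raw = raws[keep], similarity = raws[keep] / i, relative = rel[keep],
      offset = o, distance_to_start = L - (o + i - 1L) + 1L,
      strand = strand, gene_id = gid, genome_id = gnm,
      stringsAsFactors = FALSE)
  }
  out <- collect(.windowScores(p5, code, i), "+")
  if (bothStrands) {
    rcCode <- rev(c(4L, 3L, 2L, 1L, 5L)[code])   # complement, reversed
    rcRaw <- .windowScores(p5, rcCode, i)
    ## window starting at o' on the reverse strand covers forward offset
    ## L - i - o' + 2; report in forward coordinates
    rcRel <- rcRaw / ma
    keep <- which(rcRel >= threshold)
    if (length(keep)) {
      o <- L - i - offs[keep] + 2L
      res <- data.frame(
        window_sequence = .rc(substring(seq, o, o + i - 1L)),
        raw = rcRaw[keep], similarity = rcRaw[keep] / i, relative = rcRel[keep],
        offset = o, distance_to_start = L - (o + i - 1L) + 1L,
        strand = "-", gene_id = gid, genome_id = gnm,
        stringsAsFactors = FALSE)
      out <- rbind(out, res)
    }
  }
  if (is.null(out)) return(empty)
  out <- out[.orderHits(out), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

#' Scan every operon upstream region of a genome
#'
#' Applies the two regulon-selection criteria: (i) relative similarity at or
#' above \code{threshold}, and (ii) the whole site within the \code{window}
#' nt upstream of the predicted translation start (extracted with
#' \code{\link{extractUpstream}}, so qualifying site 3' edges lie at
#' distances 1..window).
#'
#' @param pfm a \linkS4class{FrequencyMatrix}.
#' @param genome a \linkS4class{GenomeRecord}.
#' @param operons data.frame from \code{\link{inferOperons}}.
#' @param window upstream window (default 250 nt).
#' @param threshold relative-similarity cut-off (default 0.87).
#' @param bothStrands passed to \code{\link{scanRegion}}.
#' @return data.frame of hits across operons, with additional columns
#'   \code{operon_id}, \code{leader_locus}, \code{contig},
#'   \code{leader_strand}, \code{region_gstart}, \code{region_gend},
#'   \code{site_gstart}, \code{site_gend} (genomic span of the site).
#' @export
scanGenomeUpstreams <- function(pfm, genome, operons, window = 250,
                                threshold = 0.87, bothStrands = TRUE) {
  res <- lapply(seq_len(nrow(operons)), function(k) {
    op <- operons[k, ]
    reg <- extractUpstream(genome, op, window = window)
    hits <- scanRegion(pfm, reg, bothStrands = bothStrands,
                       threshold = threshold)
    if (nrow(hits) == 0L) return(NULL)
    i <- motifLength(pfm)
    if (op$strand == "+") {
      sg <- reg@gstart + hits$offset - 1L
      se <- sg + i - 1L
    } else {
      se <- reg@gend - hits$offset + 1L
      sg <- se - i + 1L
    }
    cbind(operon_id = op$operon_id, leader_locus = op$leader_locus,
          contig = op$contig, leader_strand = op$strand,
          region_gstart = reg@gstart, region_gend = reg@gend,
          site_gstart = sg, site_gend = se, hits,
          stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(operon_id = character(0), leader_locus = character(0),
                      contig = character(0), leader_strand = character(0),
                      region_gstart = integer(0), region_gend = integer(0),
                      site_gstart = integer(0), site_gend = integer(0),
                      window_sequence = character(0), raw = numeric(0),
                      similarity = numeric(0), relative = numeric(0),
                      offset = integer(0), distance_to_start = integer(0),
                      strand = character(0), gene_id = character(0),
                      genome_id = character(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "threshold") <- threshold
  res
}

#' Write scan hits as TSV or BED6
#'
#' The TSV keeps all columns. The BED6 uses genomic site coordinates
#' (0-based half-open starts, the BED convention), name
#' \code{operon_id/gene_id}, score \code{round(1000 * relative)} and the
#' genomic strand of the site (leader strand combined with the hit strand).
#'
#' @param hits data.frame from \code{\link{scanGenomeUpstreams}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeHitsTSV <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeHitsTSV
#' @export
writeHitsBED <- function(hits, path) {
  gstrand <- ifelse(hits$leader_strand == hits$strand, "+", "-")
  bed <- data.frame(hits$contig, hits$site_gstart - 1L, hits$site_gend,
                    paste(hits$operon_id, hits$gene_id, sep = "/"),
                    round(1000 * hits$relative), gstrand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
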