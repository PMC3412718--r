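#' @include AllClasses.R AllGenerics.R utils.R sms-scanner.R genome-io.R
NULL

#' Pipeline configuration
#'
#' Bundles the tunable thresholds of the prediction pipeline. The
#' \code{"high_confidence"} preset raises the relative-similarity cut-off
#' to 0.89, the stricter cut-off under which the majority of experimentally
#' validated sites is still captured.
#'
#' @param window upstream window in nt (default 250).
#' @param threshold relative-similarity cut-off, inclusive (default 0.87).
#' @param operonGap intergenic gap merged within an operon (default 150 nt).
#' @param minConservedSpecies species support needed to call an association
#'   conserved (default 3).
#' @param whitelist optional data.frame (\code{genome_id}, \code{gene_id})
#'   of loci with experimentally verified distant sites: for these the
#'   distance criterion is relaxed (window \code{whitelistWindow}) while the
#'   score criterion still applies.
#' @param whitelistWindow extended window for whitelisted loci (default 600).
#' @param bothStrands scan both orientations (default TRUE).
#' @param preset \code{"default"} or \code{"high_confidence"}.
#' @return list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(window = 250, threshold = 0.87, operonGap = 150,
                           minConservedSpecies = 3, whitelist = NULL,
                           whitelistWindow = 600, bothStrands = TRUE,
                           preset = c("default", "high_confidence")) {
  preset <- match.arg(preset)
  if (preset == "high_confidence" && missing(threshold)) threshold <- 0.89
  stopifnot(threshold > 0, threshold <= 1)
  out <- list(window = window, threshold = threshold, operonGap = operonGap,
              minConservedSpecies = minConservedSpecies,
              whitelist = whitelist, whitelistWindow = whitelistWindow,
              bothStrands = bothStrands, preset = preset)
  class(out) <- "pipelineConfig"
  out
}

#' @export
print.pipelineConfig <- function(x, ...) {
  cat("pipelineConfig [", x$preset, "]: window ", x$window,
      " nt; relative similarity >= ", x$threshold, "; operon gap ",
      x$operonGap, " nt; conserved at >= ", x$minConservedSpecies,
      " species\n", sep = "")
  invisible(x)
}

#' Predict the regulon of one genome
#'
#' Applies the two selection criteria (relative similarity at or above the
#' configured threshold; whole site within the configured window upstream
#' of the translation start) to every operon leader, keeps the single best
#' qualifying site per operon, and ranks entries genome-wide by descending
#' relative score (2-decimal precision; tied scores share the lower rank).
#' Divergon leaders whose site also lies inside the partner's window are
#' annotated, not filtered: which partner the regulator acts on is left to
#' the analyst. Whitelisted loci bypass only the distance criterion.
#'
#' @param genome a \linkS4class{GenomeRecord}.
#' @param pfm a \linkS4class{FrequencyMatrix}.
#' @param config a \code{\link{pipelineConfig}}.
#' @return data.frame of class \code{"regulonPrediction"} (attribute
#'   \code{"genome_id"}): \code{operon_id}, \code{target_genes}
#'   (comma-separated members), \code{leader_gene}, \code{leader_locus},
#'   site columns from the scan, \code{score} (= relative), \code{rank},
#'   \code{divergon_note}.
#' @export
predictRegulon <- function(genome, pfm, config = pipelineConfig()) {
  operons <- inferOperons(genome, maxGap = config$operonGap)
  divergons <- classifyDivergons(genome, operons)
  hits <- scanGenomeUpstreams(pfm, genome, operons,
                              window = config$window,
                              threshold = config$threshold,
                              bothStrands = config$bothStrands)
  members <- operonMembers(operons)

  bestPer <- function(h) h[.orderHits(h)[1L], , drop = FALSE]
  entries <- NULL
  if (nrow(hits)) {
    sp <- split(hits, hits$operon_id)
    entries <- do.call(rbind, lapply(sp, bestPer))
    entries$divergon_note <- ""
  }

  ## whitelist: rescan listed loci with the extended window
  wl <- config$whitelist
  if (!is.null(wl)) {
    wl <- wl[wl$genome_id == genomeId(genome), , drop = FALSE]
    for (gene in wl$gene_id) {
      k <- which(vapply(members, function(m) gene %in% m, TRUE))
      if (!length(k)) next
      op <- operons[operons$operon_id == names(members)[k[1L]], ]
      if (!is.null(entries) && op$operon_id %in% entries$operon_id) next
      h <- scanGenomeUpstreams(pfm, genome, op,
                               window = config$whitelistWindow,
                               threshold = config$threshold,
                               bothStrands = config$bothStrands)
      if (nrow(h) == 0L) next
      h <- bestPer(h)
      h$divergon_note <- "whitelist"
      entries <- rbind(entries, h)
    }
  }

  if (is.null(entries) || nrow(entries) == 0L) {
    out <- data.frame(operon_id = character(0), target_genes = character(0),
                      leader_gene = character(0), leader_locus = character(0),
                      site_sequence = character(0), score = numeric(0),
                      raw = numeric(0), similarity = numeric(0),
                      offset = integer(0), distance_to_start = integer(0),
                      strand = character(0), site_gstart = integer(0),
                      site_gend = integer(0), rank = integer(0),
                      divergon_note = character(0), stringsAsFactors = FALSE)
    attr(out, "genome_id") <- genomeId(genome)
    attr(out, "config") <- config
    class(out) <- c("regulonPrediction", "data.frame")
    return(out)
  }

  ## divergon annotation: does the site also sit in the partner's window?
  for (r in seq_len(nrow(entries))) {
    lead <- entries$gene_id[r]
    if (!lead %in% names(divergons)) next
    partner <- divergons[[lead]]
    pReg <- extractUpstream(genome, partner, window = config$window)
    inPartner <- entries$site_gstart[r] >= pReg@gstart &&
      entries$site_gend[r] <= pReg@gend
    if (inPartner) {
      pOp <- operons$operon_id[operons$leader_gene == partner]
      note <- paste0("divergon:", pOp[1L])
      entries$divergon_note[r] <- if (nzchar(entries$divergon_note[r]))
        paste(entries$divergon_note[r], note, sep = ";") else note
    }
  }

  out <- data.frame(
    operon_id = entries$operon_id,
    target_genes = vapply(entries$operon_id,
                          function(o) paste(members[[o]], collapse = ","), ""),
    leader_gene = entries$gene_id,
    leader_locus = entries$leader_locus,
    site_sequence = entries$window_sequence,
    score = entries$relative,
    raw = entries$raw,
    similarity = entries$similarity,
    offset = entries$offset,
    distance_to_start = entries$distance_to_start,
    strand = entries$strand,
    site_gstart = entries$site_gstart,
    site_gend = entries$site_gend,
    divergon_note = entries$divergon_note,
    stringsAsFactors = FALSE)
  out <- out[order(-round(out$score, 2), out$distance_to_start,
                   out$operon_id), , drop = FALSE]
  out$rank <- rank(-round(out$score, 2), ties.method = "min")
  rownames(out) <- NULL
  attr(out, "genome_id") <- genomeId(genome)
  attr(out, "config") <- config
  class(out) <- c("regulonPrediction", "data.frame")
  out
}

#' Assign a site hit to its target operon(s), divergon-aware
#'
#' A site in the shared interval of a head-to-head gene pair belongs to both
#' partners whenever it lies inside both upstream windows; both operons are
#' then reported, flagged \code{"divergon"}. Repressor-only reasoning about
#' which partner is actually controlled is annotation for the analyst, not a
#' filter.
#'
#' @param hit one row of a \code{\link{scanGenomeUpstreams}} data.frame.
#' @param genome a \linkS4class{GenomeRecord}.
#' @param operons data.frame from \code{\link{inferOperons}}.
#' @param divergons named vector from \code{\link{classifyDivergons}}.
#' @param window upstream window (default 250).
#' @return data.frame with \code{operon_id}, \code{leader_gene},
#'   \code{flag} ("" or "divergon").
#' @export
assignTargets <- function(hit, genome, operons, divergons, window = 250) {
  out <- data.frame(operon_id = hit$operon_id, leader_gene = hit$gene_id,
                    flag = "", stringsAsFactors = FALSE)
  lead <- hit$gene_id
  if (lead %in% names(divergons)) {
    partner <- divergons[[lead]]
    pReg <- extractUpstream(genome, partner, window = window)
    if (hit$site_gstart >= pReg@gstart && hit$site_gend <= pReg@gend) {
      pOp <- operons[operons$leader_gene == partner, ]
      out$flag <- "divergon"
      out <- rbind(out, data.frame(operon_id = pOp$operon_id[1L],
                                   leader_gene = partner, flag = "divergon",
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Aggregate predictions into conserved regulatory associations
#'
#' Groups prediction entries by the ortholog family of their target genes
#' and flags a family as conserved when it is supported in at least
#' \code{minConservedSpecies} genomes. Targets without a family mapping are
#' pooled under \code{"unassigned"}.
#'
#' @param predictions named list (genome id -> \code{\link{predictRegulon}}
#'   result).
#' @param families gene-to-family mapping: either a named character vector
#'   (gene id -> family) or a data.frame with columns \code{gene_id},
#'   \code{family} and optionally \code{genome_id}.
#' @param config a \code{\link{pipelineConfig}}.
#' @return data.frame of class \code{"conservationReport"}: \code{family},
#'   \code{n_supporting}, \code{conserved}, \code{supporting_genomes}
#'   (comma-separated), \code{best_scores} (comma-separated
#'   \code{genome:score}), sorted by support (descending) then family.
#' @export
conservedAssociations <- function(predictions, families,
                                  config = pipelineConfig()) {
  lookup <- function(genome, gene) {
    if (is.data.frame(families)) {
      rows <- families$gene_id == gene
      if ("genome_id" %in% names(families))
        rows <- rows & families$genome_id == genome
      f <- families$family[rows]
      if (length(f)) f[1L] else "unassigned"
    } else {
      f <- families[gene]
      if (!is.na(f)) unname(f) else "unassigned"
    }
  }
  rows <- NULL
  for (g in names(predictions)) {
    pred <- predictions[[g]]
    if (is.null(pred) || nrow(pred) == 0L) next
    for (r in seq_len(nrow(pred))) {
      genes <- strsplit(pred$target_genes[r], ",", fixed = TRUE)[[1L]]
      fams <- unique(vapply(genes, function(x) lookup(g, x), ""))
      rows <- rbind(rows, data.frame(genome_id = g, family = fams,
                                     score = pred$score[r],
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(rows)) {
    out <- data.frame(family = character(0), n_supporting = integer(0),
                      conserved = logical(0),
                      supporting_genomes = character(0),
                      best_scores = character(0), stringsAsFactors = FALSE)
    class(out) <- c("conservationReport", "data.frame")
    return(out)
  }
  out <- do.call(rbind, lapply(split(rows, rows$family), function(d) {
    best <- vapply(split(d$score, d$genome_id), max, 0)
    gs <- sort(names(best))
    data.frame(family = d$family[1L], n_supporting = length(gs),
               conserved = length(gs) >= config$minConservedSpecies,
               supporting_genomes = paste(gs, collapse = ","),
               best_scores = paste(paste0(gs, ":", .fmt2(best[gs])),
                                   collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$n_supporting, out$family), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("conservationReport", "data.frame")
  out
}

#' Write / read regulon and conservation reports as TSV
#'
#' Deterministic output: fixed column order and sort keys, scores formatted
#' to 2 decimals. Re-running on identical inputs is byte-identical.
#'
#' @param prediction a \code{\link{predictRegulon}} result.
#' @param path output path.
#' @return invisibly, \code{path} (writers); \code{readRegulonReport}
#'   returns the data.frame back (scores at 2-decimal precision).
#' @export
writeRegulonReport <- function(prediction, path) {
  df <- data.frame(
    operon = prediction$operon_id,
    target_genes = prediction$target_genes,
    locus_tag = prediction$leader_locus,
    site_sequence = prediction$site_sequence,
    distance_to_start = prediction$distance_to_start,
    strand = prediction$strand,
    score = .fmt2(prediction$score),
    rank = prediction$rank,
    divergon_note = prediction$divergon_note,
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRegulonReport
#' @export
readRegulonReport <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(score = "numeric", rank = "integer",
                            divergon_note = "character"))
}

#' @rdname writeRegulonReport
#' @param report a \code{\link{conservedAssociations}} result.
#' @export
writeConservationReport <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
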