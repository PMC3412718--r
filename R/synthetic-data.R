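#' @include AllClasses.R AllGenerics.R utils.R motif-builder.R genome-io.R
NULL

#' A sharp planting matrix for the GlnR/TnrA-like site
#'
#' Builds the frequency matrix that synthetic genomes plant sites from. The
#' consensus (default \code{TGTCAGAATTATTAACA}) conforms to the palindromic
#' TGTNA-N7-TNACA signature; every position holds the consensus base with
#' fraction \code{sharpness} and the three others uniformly. A sharpness of
#' 0.95 emulates a high-information binding motif whose site-to-site
#' variation is dominated by sampling; real GlnR spacers are less conserved
#' than this (see the package vignette).
#'
#' @param consensus 17-nt consensus the matrix is centred on.
#' @param sharpness consensus-base fraction per position (default 0.95).
#' @return a \linkS4class{FrequencyMatrix} (nSites is nominal).
#' @export
sitePFM <- function(consensus = "TGTCAGAATTATTAACA", sharpness = 0.95) {
  stopifnot(grepl("^[ACGT]+$", consensus), sharpness > 0.25, sharpness <= 1)
  ch <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  p <- matrix((1 - sharpness) / 3, 4L, length(ch),
              dimnames = list(.BASES, NULL))
  p[cbind(match(ch, .BASES), seq_along(ch))] <- sharpness
  new("FrequencyMatrix", profile = p, nSites = 1L,
      maxAttainable = sum(apply(p, 2L, max)), familyLabel = "planting")
}

#' Simulation settings for synthetic genomes
#'
#' Defaults describe the study conditions the synthetic benchmark runs
#' under: low-GC Gram-positive-like background (GC 0.40), genes of 300-900
#' nt on alternating strands separated by 250-450 nt intergenic stretches,
#' planted sites sampled column-wise from a sharp planting matrix with the
#' site 3' edge uniform at 20-200 nt upstream of the translation start, and
#' an anchor construct (pattern-conforming site, 3-6 nt spacer, TTGAC)
#' upstream of gene 1.
#'
#' @param seed integer seed; every generator draw derives from it.
#' @param genesPerGenome number of genes (default 30).
#' @param geneLength uniform integer range of gene lengths (default
#'   \code{c(300, 900)}).
#' @param intergenicLength uniform integer range of intergenic lengths
#'   (default \code{c(250, 450)}; at least the upstream window so planted
#'   windows never run into the neighbouring gene).
#' @param gcContent background GC fraction (default 0.40).
#' @param plantingPFM matrix sites are sampled from (default
#'   \code{\link{sitePFM}()}).
#' @param plantedFraction fraction of genes given a site when
#'   \code{targetGenes} is NULL (default 0).
#' @param targetGenes explicit gene ids to plant (overrides
#'   \code{plantedFraction}).
#' @param positionRange uniform range of the site 3' edge distance to the
#'   translation start (default \code{c(20, 200)}).
#' @param siteStrand \code{"coding"} (site written in the leader's coding
#'   orientation) or \code{"random"}.
#' @param geneStrands \code{"alternating"} (default), \code{"plus"} or
#'   \code{"random"}.
#' @param anchor plant the anchor construct upstream of gene 1
#'   (default TRUE).
#' @param anchorSpacerRange spacer between anchor site and TTGAC (default
#'   \code{c(3, 6)}).
#' @param anchorPromoterDistance uniform range of the TTGAC 3' edge distance
#'   to the start (default \code{c(10, 60)}).
#' @return list of class \code{"simulationSpec"}.
#' @export
simulationSpec <- function(seed = 1L, genesPerGenome = 30,
                           geneLength = c(300, 900),
                           intergenicLength = c(250, 450),
                           gcContent = 0.40, plantingPFM = sitePFM(),
                           plantedFraction = 0, targetGenes = NULL,
                           positionRange = c(20, 200),
                           siteStrand = c("coding", "random"),
                           geneStrands = c("alternating", "plus", "random"),
                           anchor = TRUE, anchorSpacerRange = c(3, 6),
                           anchorPromoterDistance = c(10, 60)) {
  out <- list(seed = as.integer(seed), genesPerGenome = genesPerGenome,
              geneLength = geneLength, intergenicLength = intergenicLength,
              gcContent = gcContent, plantingPFM = plantingPFM,
              plantedFraction = plantedFraction, targetGenes = targetGenes,
              positionRange = positionRange,
              siteStrand = match.arg(siteStrand),
              geneStrands = match.arg(geneStrands),
              anchor = anchor, anchorSpacerRange = anchorSpacerRange,
              anchorPromoterDistance = anchorPromoterDistance)
  class(out) <- "simulationSpec"
  out
}

.runif_int <- function(n, range) {
  if (range[1L] == range[2L]) rep(as.integer(range[1L]), n)
  else sample(seq(range[1L], range[2L]), n, replace = TRUE)
}

#' Simulate a bacterial genome with planted binding sites
#'
#' Generates an i.i.d. background contig at the configured GC, lays genes
#' with intergenic spacing per the spec, samples binding sites column-wise
#' from the planting matrix and writes them into the upstream windows of
#' the chosen target genes (collision-checked; a colliding placement is
#' redrawn, with an error after 100 attempts), and writes the anchor
#' construct upstream of gene 1 when requested. Identical seeds yield
#' identical output.
#'
#' @param spec a \code{\link{simulationSpec}}.
#' @param genomeId genome identifier (default \code{"synth1"}).
#' @param seed optional override of \code{spec$seed}.
#' @return list with \code{genome} (\linkS4class{GenomeRecord}) and
#'   \code{truth} (data.frame: genome_id, gene_id, site, offset,
#'   distance_to_start, strand, family; one row per planted site, anchor
#'   included under family \code{"anchor"}).
#' @export
simulateGenome <- function(spec, genomeId = "synth1", seed = NULL) {
  set.seed(if (is.null(seed)) spec$seed else as.integer(seed))
  n <- spec$genesPerGenome
  glen <- .runif_int(n, spec$geneLength)
  ilen <- .runif_int(n + 1L, spec$intergenicLength)
  strands <- switch(spec$geneStrands,
                    plus = rep("+", n),
                    alternating = rep(c("+", "-"), length.out = n),
                    random = sample(c("+", "-"), n, replace = TRUE))
  total <- sum(glen) + sum(ilen)
  bases <- .sampleBases(total, spec$gcContent)
  gstart <- integer(n); gend <- integer(n)
  pos <- 0L
  for (k in seq_len(n)) {
    pos <- pos + ilen[k]
    gstart[k] <- pos + 1L
    gend[k] <- pos + glen[k]
    pos <- gend[k]
  }

  occupied <- cbind(gstart, gend)   # genomic intervals sites must avoid
  i <- motifLength(spec$plantingPFM)
  prof <- profileMatrix(spec$plantingPFM)
  truth <- NULL

  writeSite <- function(gene, siteSeq, dist, siteStr, family) {
    slen <- nchar(siteSeq)
    if (strands[gene] == "+") {
      se <- gstart[gene] - dist
      sg <- se - slen + 1L
      genomicSeq <- if (siteStr == "+") siteSeq else .rc(siteSeq)
    } else {
      sg <- gend[gene] + dist
      se <- sg + slen - 1L
      genomicSeq <- if (siteStr == "+") .rc(siteSeq) else siteSeq
    }
    if (sg < 1L || se > total) return(NULL)
    hit <- any(occupied[, 1L] <= se & occupied[, 2L] >= sg)
    if (hit) return(NULL)
    bases[sg:se] <<- strsplit(genomicSeq, "", fixed = TRUE)[[1L]]
    occupied <<- rbind(occupied, c(sg, se))
    c(sg = sg, se = se)
  }

  plant <- function(gene, family, siteSeq = NULL) {
    siteSeq <- if (is.null(siteSeq)) .samplePFM(prof) else siteSeq
    siteStr <- if (spec$siteStrand == "coding") "+"
               else sample(c("+", "-"), 1L)
    for (try in 1:100) {
      dist <- .runif_int(1L, spec$positionRange)
      ok <- writeSite(gene, siteSeq, dist, siteStr, family)
      if (!is.null(ok)) {
        truth <<- rbind(truth, data.frame(
          genome_id = genomeId, gene_id = sprintf("g%02d", gene),
          site = siteSeq, offset = NA_integer_, distance_to_start = dist,
          strand = siteStr, family = family, stringsAsFactors = FALSE))
        return(invisible(TRUE))
      }
    }
    stop("could not place a site upstream of gene ", gene,
         " after 100 attempts")
  }

  ## anchor construct upstream of gene 1: site + spacer(3-6) + TTGAC
  if (isTRUE(spec$anchor)) {
    siteSeq <- .samplePFM(prof)
    sp <- .runif_int(1L, spec$anchorSpacerRange)
    dP <- .runif_int(1L, spec$anchorPromoterDistance)
    construct <- paste0(siteSeq, paste(.sampleBases(sp, spec$gcContent),
                                       collapse = ""), "TTGAC")
    ok <- writeSite(1L, construct, dP, "+", "anchor")
    if (is.null(ok)) stop("anchor construct does not fit upstream of gene 1")
    truth <- rbind(truth, data.frame(
      genome_id = genomeId, gene_id = "g01", site = siteSeq,
      offset = NA_integer_, distance_to_start = dP + 5L + sp,
      strand = "+", family = "anchor", stringsAsFactors = FALSE))
  }

  targets <- if (!is.null(spec$targetGenes))
    match(spec$targetGenes, sprintf("g%02d", seq_len(n)))
  else if (spec$plantedFraction > 0)
    sample(seq_len(n), round(spec$plantedFraction * n))
  else integer(0)
  for (gene in sort(targets)) plant(gene, sprintf("fam%02d", gene))

  contig <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(contig) <- "ctg1"
  gr <- GenomicRanges::GRanges("ctg1", IRanges::IRanges(gstart, gend),
                               strand = strands)
  gr$gene_id <- sprintf("g%02d", seq_len(n))
  gr$locus_tag <- sprintf("%s_%04d", toupper(genomeId), seq_len(n))
  genome <- GenomeRecord(genomeId, contig, gr)
  if (is.null(truth))
    truth <- data.frame(genome_id = character(0), gene_id = character(0),
                        site = character(0), offset = integer(0),
                        distance_to_start = integer(0), strand = character(0),
                        family = character(0), stringsAsFactors = FALSE)
  list(genome = genome, truth = truth)
}

#' Simulate a homology hit table with a planted in-group
#'
#' E-values are drawn log10-uniform: the in-group from
#' \code{inLog10Range}, the background from \code{bgLog10Range}. Subjects
#' are encoded \code{"genome|gene"}; in-group genomes carry the
#' \code{"in"} prefix, background the \code{"bg"} prefix, so planted
#' membership is recoverable. Rows follow the 12-column tabular layout
#' (dummy alignment statistics).
#'
#' @param nIn,nBg in-group and background hit counts.
#' @param inLog10Range,bgLog10Range log10 e-value ranges (defaults
#'   \code{c(-120, -40)} and \code{c(-12, -6)}).
#' @param seed integer seed.
#' @param query query id (default \code{"repQ"}).
#' @param path optional TSV output path.
#' @return data.frame of rows in hit-table column order (written to
#'   \code{path} when given), with attribute \code{"inSubjects"} naming the
#'   planted in-group subjects.
#' @export
simulateHitTable <- function(nIn, nBg, inLog10Range = c(-120, -40),
                             bgLog10Range = c(-12, -6), seed = 1L,
                             query = "repQ", path = NULL) {
  set.seed(as.integer(seed))
  ev <- c(10^runif(nIn, inLog10Range[1L], inLog10Range[2L]),
          10^runif(nBg, bgLog10Range[1L], bgLog10Range[2L]))
  subj <- c(if (nIn) sprintf("in%03d|geneA", seq_len(nIn)),
            if (nBg) sprintf("bg%03d|geneA", seq_len(nBg)))
  df <- data.frame(query, subj, 90, 100L, 0L, 0L, 1L, 100L, 1L, 100L,
                   format(ev, digits = 6, scientific = TRUE), 200,
                   stringsAsFactors = FALSE)
  if (!is.null(path))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  attr(df, "inSubjects") <- if (nIn) subj[seq_len(nIn)] else character(0)
  df
}

#' Simulate a multi-species panel with a shared planted regulon
#'
#' Each species gets its own genome (per-species seed = \code{spec$seed +
#' species index}). Family 1 is the anchor operon (gene 1; never dropped,
#' mirroring the universal regulator-operon association); families 2..k are
#' planted upstream of genes 2..k in every species unless removed by the
#' per-species dropout draw.
#'
#' @param spec a \code{\link{simulationSpec}}.
#' @param nSpecies number of species (default 10).
#' @param sharedFamilies number of planted families including the anchor
#'   (default 12; must not exceed \code{genesPerGenome}).
#' @param dropout per-species, per-family dropout probability for
#'   non-anchor families (default 0).
#' @param dir optional directory: genomes are written as FASTA + GFF3 and
#'   the truth table as TSV.
#' @return list with \code{genomes} (named list of
#'   \linkS4class{GenomeRecord}), \code{truth} (combined truth table with
#'   family column), \code{familyMap} (data.frame genome_id, gene_id,
#'   family for every family member, planted or not) and \code{families}
#'   (planted family names, anchor first).
#' @export
simulateSpeciesPanel <- function(spec, nSpecies = 10, sharedFamilies = 12,
                                 dropout = 0, dir = NULL) {
  stopifnot(sharedFamilies <= spec$genesPerGenome)
  famNames <- c("anchor", sprintf("fam%02d", seq_len(sharedFamilies))[-1L])
  genomes <- list(); truth <- NULL; familyMap <- NULL
  for (s in seq_len(nSpecies)) {
    gid <- sprintf("sp%02d", s)
    seedS <- spec$seed + s
    ## dropout draw under the species seed, before genome construction
    set.seed(seedS)
    keep <- c(TRUE, runif(sharedFamilies - 1L) >= dropout)
    targets <- sprintf("g%02d", seq_len(sharedFamilies)[keep])
    targets <- setdiff(targets, "g01")   # anchor handled by the construct
    specS <- spec
    specS$targetGenes <- targets
    specS$anchor <- TRUE
    sim <- simulateGenome(specS, genomeId = gid, seed = seedS + 1000L)
    sim$truth$family[sim$truth$family != "anchor"] <-
      sim$truth$gene_id[sim$truth$family != "anchor"]
    sim$truth$family <- ifelse(sim$truth$family == "anchor", "anchor",
                               sub("^g", "fam", sim$truth$family))
    genomes[[gid]] <- sim$genome
    truth <- rbind(truth, sim$truth)
    familyMap <- rbind(familyMap, data.frame(
      genome_id = gid, gene_id = sprintf("g%02d", seq_len(sharedFamilies)),
      family = famNames, stringsAsFactors = FALSE))
    if (!is.null(dir)) {
      writeGenome(sim$genome, file.path(dir, paste0(gid, ".fasta")),
                  file.path(dir, paste0(gid, ".gff3")))
    }
  }
  if (!is.null(dir))
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  list(genomes = genomes, truth = truth, familyMap = familyMap,
       families = famNames)
}

#' End-to-end planted-regulon benchmark
#'
#' Runs the whole pipeline on a synthetic species panel: simulate, collect
#' the anchor upstream regions, footprint them into a frequency matrix,
#' scan and predict each species' regulon, and aggregate conserved
#' associations. Reports how many planted families were recovered as
#' conserved and how many conserved families were not planted.
#'
#' @param seed integer seed for the replicate.
#' @param nSpecies,nFamilies panel shape (defaults 10 species, 12 families).
#' @param config a \code{\link{pipelineConfig}}.
#' @param spec optional \code{\link{simulationSpec}} (its seed is replaced
#'   by \code{seed}).
#' @return one-row data.frame: \code{n_planted}, \code{n_conserved_true},
#'   \code{n_false_conserved}, \code{n_genomes_footprinted}.
#' @export
plantedRegulonBenchmark <- function(seed, nSpecies = 10, nFamilies = 12,
                                    config = pipelineConfig(),
                                    spec = NULL) {
  ## all-plus gene layout: upstream windows are pairwise disjoint, so each
  ## planted site belongs to exactly one operon and "false conserved" is
  ## well-defined (a divergon-shared site is a correct double detection,
  ## not a false positive; divergons are exercised elsewhere)
  if (is.null(spec)) spec <- simulationSpec(seed = seed, geneStrands = "plus")
  else spec$seed <- as.integer(seed)
  panel <- simulateSpeciesPanel(spec, nSpecies = nSpecies,
                                sharedFamilies = nFamilies, dropout = 0)
  regions <- lapply(panel$genomes, function(g) {
    ops <- inferOperons(g, maxGap = config$operonGap)
    anchorOp <- ops[vapply(operonMembers(ops),
                           function(m) "g01" %in% m, TRUE), ][1L, ]
    extractUpstream(g, anchorOp, window = config$window)
  })
  fp <- footprintFamily(regions, seedPattern(), minGenomes = 4,
                        familyLabel = "panel")
  predictions <- lapply(panel$genomes, predictRegulon, pfm = fp$pfm,
                        config = config)
  report <- conservedAssociations(predictions, panel$familyMap, config)
  conserved <- report$family[report$conserved]
  data.frame(
    n_planted = nFamilies,
    n_conserved_true = length(intersect(conserved, panel$families)),
    n_false_conserved = length(setdiff(conserved, panel$families)),
    n_genomes_footprinted = nSites(fp$pfm))
}
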