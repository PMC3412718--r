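#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Construct a SeedPattern
#'
#' Defaults describe the palindromic GlnR/TnrA consensus TGTNA-N7-TNACA and
#' its promoter context: the site sits 3-6 nt upstream of a TTGAC -35
#' element.
#'
#' @param pattern IUPAC degenerate string (default \code{TGTNANNNNNNNTNACA}).
#' @param promoterElement exact -35 signature (default \code{TTGAC}).
#' @param spacerRange admissible nt between site 3' end and the promoter
#'   element (default \code{c(3, 6)}).
#' @param maxMismatches budget at defined (non-N) pattern positions
#'   (default 2).
#' @return a \linkS4class{SeedPattern}.
#' @export
seedPattern <- function(pattern = "TGTNANNNNNNNTNACA",
                        promoterElement = "TTGAC",
                        spacerRange = c(3L, 6L), maxMismatches = 2L) {
  new("SeedPattern", pattern = toupper(pattern),
      promoterElement = toupper(promoterElement),
      spacerRange = as.integer(spacerRange),
      maxMismatches = as.integer(maxMismatches))
}

setMethod("show", "SeedPattern", function(object) {
  cat("SeedPattern", object@pattern, "\n  -35 element", object@promoterElement,
      "at spacer", paste(object@spacerRange, collapse = ".."),
      "nt; <=", object@maxMismatches, "mismatch(es)\n")
})

## all candidate matches of an IUPAC pattern on one strand of a plain
## sequence; windows containing non-ACGT genome characters are rejected
.patternMatches <- function(seq, pattern) {
  i <- nchar(pattern)
  L <- nchar(seq)
  n <- L - i + 1L
  if (n < 1L) return(data.frame())
  pat <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  defined <- pat != "N"
  allowed <- matrix(FALSE, 4L, i, dimnames = list(.BASES, NULL))
  for (j in seq_len(i)) allowed[.IUPAC_SETS[[pat[j]]], j] <- TRUE
  code <- .encode5(seq)
  idx <- outer(seq_len(n), 0:(i - 1L), "+")
  b <- matrix(code[idx], n, i)
  ok <- b <= 4L
  mm <- matrix(FALSE, n, i)
  for (j in which(defined)) {
    aj <- allowed[, j]
    mm[, j] <- !(ok[, j] & aj[pmin(b[, j], 4L)])
  }
  data.frame(offset = seq_len(n),
             mismatches = rowSums(mm),
             clean = rowSums(!ok) == 0L)
}

#' Locate the conserved seed site in an upstream region
#'
#' Scans both orientations (the consensus is near-palindromic) for windows
#' matching the degenerate pattern with at most \code{maxMismatches}
#' mismatches at defined positions; N in the pattern matches any base, but a
#' genomic N anywhere in the window disqualifies it. Windows whose 3' end
#' lies within the spacer range upstream of an exact promoter-element
#' occurrence on the same strand are preferred ("promoter-anchored");
#' remaining ties are broken by fewer mismatches, then by proximity to the
#' translation start, then + strand, then smaller offset.
#'
#' @param region an \linkS4class{UpstreamRegion} (or plain sequence string).
#' @param pattern a \linkS4class{SeedPattern}.
#' @param bothStrands scan the reverse complement as well (default TRUE).
#' @return \code{NULL} when no window fits the budget; otherwise a list with
#'   \code{sequence} (site read 5' to 3' on its strand), \code{offset}
#'   (1-based start in region coordinates, forward orientation),
#'   \code{strand}, \code{mismatches}, \code{anchored} and
#'   \code{distance_to_start} (site 3' edge to translation start; 1 =
#'   adjacent).
#' @export
findSeedSite <- function(region, pattern = seedPattern(), bothStrands = TRUE) {
  seq <- if (is(region, "UpstreamRegion")) regionSequence(region) else region
  i <- nchar(pattern@pattern)
  L <- nchar(seq)
  if (L < i) return(NULL)

  strands <- if (bothStrands) c("+", "-") else "+"
  cand <- NULL
  for (st in strands) {
    s <- if (st == "+") seq else .rc(seq)
    m <- .patternMatches(s, pattern@pattern)
    if (nrow(m) == 0L) next
    m <- m[m$clean & m$mismatches <= pattern@maxMismatches, , drop = FALSE]
    if (nrow(m) == 0L) next
    ## promoter anchoring on the scanned strand
    pstarts <- gregexpr(pattern@promoterElement, s, fixed = TRUE)[[1L]]
    pstarts <- pstarts[pstarts > 0L]
    spacer <- outer(pstarts, m$offset + i, "-")          # = pstart - wend - 1
    anchored <- if (length(pstarts))
      apply(spacer >= pattern@spacerRange[1L] &
            spacer <= pattern@spacerRange[2L], 2L, any)
    else rep(FALSE, nrow(m))
    ## map minus-strand offsets back to forward region coordinates
    fwdOffset <- if (st == "+") m$offset else L - i - m$offset + 2L
    cand <- rbind(cand, data.frame(
      offset = fwdOffset, strand = st, mismatches = m$mismatches,
      anchored = anchored,
      distance_to_start = L - (fwdOffset + i - 1L) + 1L,
      stringsAsFactors = FALSE))
  }
  if (is.null(cand) || nrow(cand) == 0L) return(NULL)
  ord <- order(!cand$anchored, cand$mismatches, cand$distance_to_start,
               cand$strand != "+", cand$offset)
  best <- cand[ord[1L], ]
  win <- substr(seq, best$offset, best$offset + i - 1L)
  list(sequence = if (best$strand == "+") win else .rc(win),
       offset = best$offset, strand = best$strand,
       mismatches = best$mismatches, anchored = best$anchored,
       distance_to_start = best$distance_to_start)
}

#' Construct a BindingSiteSet
#'
#' @param sites character vector or \code{DNAStringSet} of equal-length
#'   A/C/G/T sequences.
#' @param provenance optional data.frame (genome_id, gene_id, offset, strand),
#'   one row per site.
#' @return a validated \linkS4class{BindingSiteSet}.
#' @export
BindingSiteSet <- function(sites, provenance = NULL) {
  if (is.character(sites)) sites <- Biostrings::DNAStringSet(toupper(sites))
  if (is.null(provenance))
    provenance <- data.frame(genome_id = NA_character_,
                             gene_id = NA_character_, offset = NA_integer_,
                             strand = NA_character_)[rep(1L, length(sites)), ]
  rownames(provenance) <- NULL
  new("BindingSiteSet", sites = sites, provenance = provenance)
}

#' @rdname accessors
#' @export
setMethod("siteSequences", "BindingSiteSet", function(x) x@sites)

#' @rdname accessors
#' @export
setMethod("siteProvenance", "BindingSiteSet", function(x) x@provenance)

#' @rdname accessors
#' @export
setMethod("motifLength", "BindingSiteSet",
          function(x) Biostrings::width(x@sites)[1L])

setMethod("length", "BindingSiteSet", function(x) length(x@sites))

setMethod("show", "BindingSiteSet", function(object) {
  cat("BindingSiteSet:", length(object@sites), "site(s) of length",
      motifLength(object), "\n")
})

#' Build a position frequency matrix from aligned sites
#'
#' f_N(j) = (count_N(j) + pseudocount) / (n_sites + 4 * pseudocount). The
#' default pseudocount of 0 keeps raw frequencies, so a nucleotide absent
#' from a column contributes exactly 0 to any score; a small Laplace
#' pseudocount is available for scans across distant taxa.
#'
#' @param sites a \linkS4class{BindingSiteSet}, \code{DNAStringSet} or
#'   character vector of equal-length A/C/G/T sequences.
#' @param pseudocount added to every count (default 0).
#' @param familyLabel label stored with the matrix.
#' @return a \linkS4class{FrequencyMatrix}.
#' @examples
#' pfm <- buildPFM(c("ACGT", "ACGA", "ACTT", "GCGT"))
#' profileMatrix(pfm)
#' maxAttainable(pfm)   # 3.25
#' @export
buildPFM <- function(sites, pseudocount = 0, familyLabel = "") {
  if (!is(sites, "BindingSiteSet")) sites <- BindingSiteSet(sites)
  s <- siteSequences(sites)
  cm <- Biostrings::consensusMatrix(s)
  counts <- matrix(0, 4L, motifLength(sites), dimnames = list(.BASES, NULL))
  for (b in intersect(rownames(cm), .BASES)) counts[b, ] <- cm[b, ]
  n <- length(s)
  f <- (counts + pseudocount) / (n + 4 * pseudocount)
  new("FrequencyMatrix", profile = f, nSites = as.integer(n),
      maxAttainable = sum(apply(f, 2L, max)), familyLabel = familyLabel)
}

#' @rdname accessors
#' @export
setMethod("motifLength", "FrequencyMatrix", function(x) ncol(x@profile))

#' @rdname accessors
#' @export
setMethod("nSites", "FrequencyMatrix", function(x) x@nSites)

#' @rdname accessors
#' @export
setMethod("profileMatrix", "FrequencyMatrix", function(x) x@profile)

#' @rdname accessors
#' @export
setMethod("maxAttainable", "FrequencyMatrix", function(x) x@maxAttainable)

#' @rdname accessors
#' @export
setMethod("familyLabel", "FrequencyMatrix", function(x) x@familyLabel)

setMethod("show", "FrequencyMatrix", function(object) {
  cat("FrequencyMatrix",
      if (nzchar(object@familyLabel)) paste0("[", object@familyLabel, "]") else "",
      "\n  length", ncol(object@profile), ", built from", object@nSites,
      "site(s); max attainable score", round(object@maxAttainable, 4), "\n",
      " consensus:", consensusIUPAC(object), "\n")
})

#' @describeIn consensusIUPAC method for FrequencyMatrix
#' @export
setMethod("consensusIUPAC", "FrequencyMatrix",
          function(x, degeneracyThreshold = 0.5) {
  p <- x@profile
  codes <- vapply(seq_len(ncol(p)), function(j) {
    col <- p[, j]
    if (max(col) > degeneracyThreshold) return(names(which.max(col)))
    set <- sort(names(col)[col >= 0.25])
    if (length(set) == 0L) return("N")
    unname(.IUPAC_FROM_SET[paste(set, collapse = "")])
  }, "")
  paste(codes, collapse = "")
})

#' Footprint a family: collect one seed site per genome and build the PFM
#'
#' The phylogenetic-footprinting step: for each orthologous upstream region
#' the best seed-pattern match is taken as that genome's binding site; the
#' collected sites form a \linkS4class{BindingSiteSet} from which the
#' family-specific frequency matrix is built. Genomes whose region yields no
#' admissible site are dropped with a message.
#'
#' @param regions named list (genome id -> \linkS4class{UpstreamRegion} or
#'   sequence string) of orthologous upstream regions.
#' @param pattern a \linkS4class{SeedPattern}.
#' @param minGenomes minimum number of genomes that must yield a site
#'   (default 4).
#' @param bothStrands passed to \code{\link{findSeedSite}}.
#' @param pseudocount,familyLabel passed to \code{\link{buildPFM}}.
#' @return list with \code{sites} (\linkS4class{BindingSiteSet}),
#'   \code{pfm} (\linkS4class{FrequencyMatrix}) and \code{dropped}
#'   (genome ids without a site).
#' @export
footprintFamily <- function(regions, pattern = seedPattern(), minGenomes = 4,
                            bothStrands = TRUE, pseudocount = 0,
                            familyLabel = "") {
  stopifnot(!is.null(names(regions)))
  found <- lapply(regions, findSeedSite, pattern = pattern,
                  bothStrands = bothStrands)
  ok <- !vapply(found, is.null, TRUE)
  dropped <- names(regions)[!ok]
  if (length(dropped))
    message("no seed site in ", length(dropped), " genome(s): ",
            paste(dropped, collapse = ", "))
  if (sum(ok) < minGenomes)
    stop("only ", sum(ok), " genome(s) yielded a seed site (need ",
         minGenomes, "); failing genomes: ",
         paste(dropped, collapse = ", "))
  found <- found[ok]
  prov <- data.frame(
    genome_id = names(found),
    gene_id = vapply(regions[ok], function(r)
      if (is(r, "UpstreamRegion")) r@geneId else NA_character_, ""),
    offset = vapply(found, function(h) h$offset, 0L),
    strand = vapply(found, function(h) h$strand, ""),
    stringsAsFactors = FALSE)
  sites <- BindingSiteSet(vapply(found, function(h) h$sequence, ""), prov)
  list(sites = sites,
       pfm = buildPFM(sites, pseudocount = pseudocount,
                      familyLabel = familyLabel),
       dropped = dropped)
}

#' Read/write frequency matrices as TSV
#'
#' Four rows (A, C, G, T) by i columns, preceded by comment header lines
#' recording \code{n_sites}, \code{family_label} and \code{max_attainable}.
#'
#' @param pfm a \linkS4class{FrequencyMatrix}.
#' @param path file path.
#' @return \code{writePFM} invisibly returns \code{path}; \code{readPFM}
#'   returns a \linkS4class{FrequencyMatrix}.
#' @export
writePFM <- function(pfm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# n_sites=", nSites(pfm)),
               paste0("# family_label=", familyLabel(pfm)),
               paste0("# max_attainable=",
                      format(maxAttainable(pfm), digits = 15))), con)
  write.table(profileMatrix(pfm), con, sep = "\t", quote = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writePFM
#' @export
readPFM <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) sub(paste0("^# ", key, "="), "",
                            grep(paste0("^# ", key, "="), hdr, value = TRUE))
  body <- read.table(text = grep("^#", lines, value = TRUE, invert = TRUE),
                     sep = "\t", row.names = 1L)
  p <- as.matrix(body)
  dimnames(p) <- list(rownames(body), NULL)
  p <- p[.BASES, , drop = FALSE]
  new("FrequencyMatrix", profile = p,
      nSites = as.integer(getv("n_sites")),
      maxAttainable = sum(apply(p, 2L, max)),
      familyLabel = getv("family_label"))
}

#' Read/write binding-site sets as aligned FASTA
#'
#' Headers carry \code{genome|gene|offset|strand} provenance.
#'
#' @param sites a \linkS4class{BindingSiteSet}.
#' @param path file path.
#' @return \code{writeSiteSet} invisibly returns \code{path};
#'   \code{readSiteSet} returns a \linkS4class{BindingSiteSet}.
#' @export
writeSiteSet <- function(sites, path) {
  s <- siteSequences(sites)
  pr <- siteProvenance(sites)
  names(s) <- paste(pr$genome_id, pr$gene_id, pr$offset, pr$strand, sep = "|")
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' @rdname writeSiteSet
#' @export
readSiteSet <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(s), "|", fixed = TRUE)
  prov <- data.frame(
    genome_id = vapply(parts, `[`, "", 1L),
    gene_id = vapply(parts, `[`, "", 2L),
    offset = suppressWarnings(as.integer(vapply(parts, `[`, "", 3L))),
    strand = vapply(parts, `[`, "", 4L),
    stringsAsFactors = FALSE)
  BindingSiteSet(s, prov)
}
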