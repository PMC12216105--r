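## VCF import/export of per-locus haplotype data.  Internally coordinates
## are 0-based half-open; VCF positions are 1-based per the standard.

#' Write a locus as a phased VCF
#'
#' Emits a minimal VCF (one contig, biallelic sites, phased `GT` haplotype
#' pairs, REF = ancestral, ALT = derived) for interchange with standard
#' tools.  Continuous internal coordinates are rounded to integer
#' positions; ties created by rounding are nudged to stay strictly
#' increasing.
#'
#' @param locus a [LocusData-class].
#' @param path output path (plain text).
#' @param contig contig name.
#' @return the path, invisibly.
#' @export
writeLocusVCF <- function(locus, path, contig = "locus1") {
  H <- haplotypes(locus)
  nInd <- nrow(H) %/% 2L
  pos <- floor(positions(locus)) + 1L          # 0-based -> 1-based
  if (length(pos) > 1L)
    for (i in 2:length(pos))
      if (pos[i] <= pos[i - 1L]) pos[i] <- pos[i - 1L] + 1L
  ids <- sprintf("%s_%d", rep(c("p1", "p2"), each = nInd %/% 2L),
                 rep(seq_len(nInd %/% 2L), 2L))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", contig,
                   as.integer(ceiling(locus@locusLength))),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  rows <- vapply(seq_along(pos), function(j) {
    gt <- paste(H[seq(1L, nrow(H), by = 2L), j],
                H[seq(2L, nrow(H), by = 2L), j], sep = "|")
    paste(c(contig, pos[j], ".", "A", "T", ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1L))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a locus from a phased VCF
#'
#' Parses a VCF of phased biallelic genotypes into a [LocusData-class]:
#' sample columns are split into two haplotypes each (in sample order,
#' the first half of the samples assigned to population 1), ALT alleles
#' are taken as derived, and 1-based positions convert to the package's
#' 0-based coordinates.
#'
#' @param path VCF path (plain text or gzipped).
#' @param locusLength locus length in bp.
#' @param popLabels optional population index per *sample* (1/2);
#'   defaults to first half vs second half.
#' @return a [LocusData-class].
#' @export
readLocusVCF <- function(path, locusLength, popLabels = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  nInd <- ncol(gt)
  if (is.null(popLabels))
    popLabels <- rep(1:2, each = ceiling(nInd / 2))[seq_len(nInd)]
  stopifnot(length(popLabels) == nInd)
  split <- strsplit(as.vector(gt), "[|/]")
  if (any(lengths(split) != 2L))
    stop("expected diploid phased genotypes (a|b) in ", path)
  al <- matrix(as.integer(unlist(split)), nrow = 2L)
  if (any(al > 1L, na.rm = TRUE))
    stop("only biallelic sites are supported")
  nSites <- nrow(gt)
  H <- matrix(0L, nrow = 2L * nInd, ncol = nSites)
  for (i in seq_len(nInd)) {
    cols <- (i - 1L) * nSites + seq_len(nSites)
    H[2L * i - 1L, ] <- al[1L, cols]
    H[2L * i, ] <- al[2L, cols]
  }
  ord <- order(popLabels)
  H <- H[as.vector(rbind(2L * ord - 1L, 2L * ord)), , drop = FALSE]
  pos <- as.numeric(vcfR::getPOS(v)) - 1     # 1-based -> 0-based
  keep <- colSums(H) > 0L & colSums(H) < nrow(H)
  locusData(H[, keep, drop = FALSE], pos[keep],
            rep(sort(popLabels), each = 2L), locusLength)
}
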