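#' Group UMI-tagged reads into read families
#'
#' Reads sharing an identical unique molecular identifier (UMI) and an
#' identical mapping position originate from the same DNA molecule and are
#' grouped into one read family. Grouping is by exact (umi, chrom, pos) key;
#' no edit-distance merging of near-identical UMIs is performed.
#'
#' @param reads data.frame with columns `umi`, `chrom`, `pos`, `seq`
#'   (equal-length base strings over A,C,G,T,N within a family).
#' @return A list of read families, ordered by key; each family is a list
#'   with elements `umi`, `chrom`, `pos` and `reads` (character vector).
#' @export
#' @examples
#' fams <- group_reads(data.frame(
#'   umi = c("AAT", "AAT"), chrom = "chr1", pos = 100L,
#'   seq = c("ACGT", "ACGT")))
#' consensus_sequence(fams[[1]])
group_reads <- function(reads) {
  stopifnot(all(c("umi", "chrom", "pos", "seq") %in% names(reads)))
  if (nrow(reads) == 0L) return(list())
  key <- paste(reads$umi, reads$chrom, reads$pos, sep = "\r")
  groups <- split(seq_len(nrow(reads)), key)
  groups <- groups[order(names(groups))]
  lapply(groups, function(idx) {
    seqs <- reads$seq[idx]
    if (length(unique(nchar(seqs))) != 1L)
      stop("reads of family (umi=", reads$umi[idx[1]], ", ",
           reads$chrom[idx[1]], ":", reads$pos[idx[1]],
           ") have unequal lengths")
    list(umi = reads$umi[idx[1]], chrom = reads$chrom[idx[1]],
         pos = as.integer(reads$pos[idx[1]]), reads = seqs)
  })
}

#' Build the consensus sequence of a read family
#'
#' Position-wise strict unanimity: position i of the consensus is base b iff
#' every read in the family carries b at i; any contradiction — including an
#' input "N", which cannot certify unanimity — is masked with "N". There is
#' no minimum family size (a single read passes through unchanged) and, by
#' default, no majority voting even at 2-vs-1. `majority = TRUE` switches to
#' plurality voting (ties masked with "N").
#'
#' @param family A read family from [group_reads()], or a character vector
#'   of equal-length reads.
#' @param majority Use plurality voting instead of strict unanimity.
#' @return A single consensus string of the common read length.
#' @export
consensus_sequence <- function(family, majority = FALSE) {
  reads <- if (is.list(family)) family$reads else family
  if (length(reads) == 0L) stop("empty read family")
  if (length(unique(nchar(reads))) != 1L)
    stop("reads have unequal lengths")
  mat <- matrix(unlist(strsplit(reads, "", fixed = TRUE)),
                nrow = length(reads), byrow = TRUE)
  cons <- apply(mat, 2L, function(col) {
    if (!majority) {
      u <- unique(col)
      if (length(u) == 1L && u != "N") u else "N"
    } else {
      col <- col[col != "N"]
      if (length(col) == 0L) return("N")
      tab <- table(col)
      top <- names(tab)[tab == max(tab)]
      if (length(top) == 1L) top else "N"
    }
  })
  paste(cons, collapse = "")
}

#' Consensus calling over a whole read table
#'
#' Convenience wrapper: groups reads by (umi, chrom, pos) and emits one
#' consensus row per family.
#'
#' @inheritParams group_reads
#' @inheritParams consensus_sequence
#' @return data.frame with columns umi, chrom, pos, consensus, family_size.
#' @export
consensus_table <- function(reads, majority = FALSE) {
  fams <- group_reads(reads)
  if (length(fams) == 0L)
    return(data.frame(umi = character(), chrom = character(),
                      pos = integer(), consensus = character(),
                      family_size = integer(), stringsAsFactors = FALSE))
  data.frame(
    umi = vapply(fams, `[[`, "", "umi"),
    chrom = vapply(fams, `[[`, "", "chrom"),
    pos = vapply(fams, `[[`, 0L, "pos"),
    consensus = vapply(fams, consensus_sequence, "", majority = majority),
    family_size = vapply(fams, function(f) length(f$reads), 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
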