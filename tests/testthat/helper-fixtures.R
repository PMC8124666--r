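# fixtures are built in code; nothing is read from disk except temp files
# written by the tests themselves

make_calls <- function(pos, ref, alt, alt_count, depth,
                       patient = "P01", sample = "TU1", chrom = "chr1",
                       gene = NA_character_, effect = NA_character_) {
  variant_calls(patient, sample, chrom, pos, ref, alt, alt_count, depth,
                gene, effect)
}

write_temp_vcf <- function(lines) {
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

vcf_header <- function(sample = "TU1") {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
}

tiny_pathway_db <- function() {
  list(PW1 = c("VHL", "PBRM1"),
       PW2 = c("TP53", "MUC16"),
       PW3 = c("SETD2", "BAP1", "GENE001"))
}

# independent per-column consensus oracle: counts distinct symbols per
# column with table(), emits the single base only when its count equals the
# family size and it is not "N"
oracle_consensus <- function(reads) {
  mat <- do.call(rbind, strsplit(reads, "", fixed = TRUE))
  paste(vapply(seq_len(ncol(mat)), function(j) {
    tab <- table(mat[, j])
    if (length(tab) == 1L && names(tab) != "N") names(tab) else "N"
  }, ""), collapse = "")
}

# exhaustive hypergeometric upper tail from first principles (choose sums)
oracle_hyper_tail <- function(k, m, n_bg, n_de) {
  j <- seq(k, min(m, n_de))
  if (k > min(m, n_de)) return(0)
  sum(choose(m, j) * choose(n_bg - m, n_de - j)) / choose(n_bg, n_de)
}

# brute-force null of the exclusivity statistic: per patient, enumerate
# every placement of the two fixed-size clone sets, record the exclusivity
# indicator of each placement, then convolve the *integer counts* across
# patients and read the tail of T
oracle_exclusivity_tail <- function(sizes_a, sizes_b, Ks, t_obs) {
  per_patient <- lapply(seq_along(Ks), function(i) {
    A <- utils::combn(Ks[i], sizes_a[i], simplify = FALSE)
    B <- utils::combn(Ks[i], sizes_b[i], simplify = FALSE)
    excl <- unlist(lapply(A, function(a) vapply(B, function(b)
      length(intersect(a, b)) == 0L, TRUE)))
    c(n_excl = sum(excl), n_tot = length(excl))
  })
  counts <- 1  # counts[t+1] = number-of-placement-combinations with T = t
  tot <- 1
  for (pp in per_patient) {
    counts <- c(counts * (pp["n_tot"] - pp["n_excl"]), 0) +
      c(0, counts * pp["n_excl"])
    tot <- tot * pp["n_tot"]
  }
  if (t_obs <= 0) return(1)
  unname(sum(counts[seq.int(t_obs + 1L, length(counts))]) / tot)
}
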