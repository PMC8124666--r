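#' Merge the variant calls of a patient's two tumour biopsies
#'
#' Variants are keyed by (chrom, pos, ref, alt); a key present in both
#' post-filter call sets is `shared`, a key present in only one is private
#' to that biopsy. No VAF re-thresholding happens here: presence means
#' appearing in the sample's call set, and detection thresholds live
#' upstream in calling and filtering. Indel keys are assumed left-aligned
#' upstream.
#'
#' @param tu1,tu2 Variant-call data.frames of samples TU1 and TU2 of one
#'   patient.
#' @return A merged data.frame with one row per distinct variant key:
#'   patient_id, chrom, pos, ref, alt, gene, effect, impact, per-sample
#'   counts (`alt_TU1`, `depth_TU1`, `vaf_TU1`, and likewise TU2),
#'   `in_TU1`, `in_TU2` and `status` in
#'   \{shared, private_TU1, private_TU2\}.
#' @export
merge_samples <- function(tu1, tu2) {
  validate_variant_calls(tu1); validate_variant_calls(tu2)
  pid <- unique(c(tu1$patient_id, tu2$patient_id))
  if (length(pid) > 1L)
    stop("merge_samples() expects variants of a single patient; got: ",
         paste(pid, collapse = ", "))
  k1 <- variant_key(tu1); k2 <- variant_key(tu2)
  if (anyDuplicated(k1)) stop("duplicate variant key within TU1: ",
                              k1[duplicated(k1)][1])
  if (anyDuplicated(k2)) stop("duplicate variant key within TU2: ",
                              k2[duplicated(k2)][1])
  keys <- sort(union(k1, k2))
  i1 <- match(keys, k1); i2 <- match(keys, k2)
  pick <- function(col) {
    v1 <- tu1[[col]][i1]; v2 <- tu2[[col]][i2]
    ifelse(is.na(i1), v2, v1)
  }
  out <- data.frame(
    patient_id = if (length(pid)) pid else NA_character_,
    chrom = pick("chrom"), pos = pick("pos"), ref = pick("ref"),
    alt = pick("alt"), gene = pick("gene"), effect = pick("effect"),
    impact = pick("impact"),
    alt_TU1 = ifelse(is.na(i1), 0L, tu1$alt_count[i1]),
    depth_TU1 = ifelse(is.na(i1), 0L, tu1$depth[i1]),
    vaf_TU1 = ifelse(is.na(i1), 0, tu1$vaf[i1]),
    alt_TU2 = ifelse(is.na(i2), 0L, tu2$alt_count[i2]),
    depth_TU2 = ifelse(is.na(i2), 0L, tu2$depth[i2]),
    vaf_TU2 = ifelse(is.na(i2), 0, tu2$vaf[i2]),
    in_TU1 = !is.na(i1), in_TU2 = !is.na(i2),
    stringsAsFactors = FALSE
  )
  out$status <- ifelse(out$in_TU1 & out$in_TU2, "shared",
                       ifelse(out$in_TU1, "private_TU1", "private_TU2"))
  out
}

#' Fraction of a patient's mutations private to one biopsy
#'
#' @param merged Output of [merge_samples()].
#' @return `(private_TU1 + private_TU2) / total`, a number in [0, 1].
#' @export
private_fraction <- function(merged) {
  if (nrow(merged) == 0L)
    stop("private_fraction() is undefined for an empty variant set")
  mean(merged$status != "shared")
}

#' Per-gene mutation frequency across a cohort
#'
#' @param cohort List of [merge_samples()] outputs, one per patient.
#' @return Named numeric vector: for each gene, the fraction of patients
#'   carrying at least one mutation (any status) in that gene; a patient
#'   with several mutations in a gene counts once.
#' @export
gene_frequency <- function(cohort) {
  if (length(cohort) == 0L) stop("empty cohort")
  per_patient <- lapply(cohort, function(m)
    unique(m$gene[!is.na(m$gene)]))
  tab <- table(unlist(per_patient))
  sort(stats::setNames(as.numeric(tab) / length(cohort), names(tab)),
       decreasing = TRUE)
}

#' Detect convergent evolution within a patient
#'
#' A gene shows a convergent pattern when it is hit by at least two
#' distinct mutations whose presence patterns across the two biopsies are
#' not all identical — e.g. a frameshift private to TU1 and a missense at a
#' different locus private to TU2. Two mutations both private to the same
#' biopsy are same-biopsy multiplicity, not cross-biopsy convergence.
#'
#' @param merged Output of [merge_samples()].
#' @return data.frame with one row per event: gene, n_loci, loci
#'   (";"-separated sorted keys) and statuses (";"-separated, same order).
#' @export
detect_convergence <- function(merged) {
  out <- data.frame(gene = character(), n_loci = integer(),
                    loci = character(), statuses = character(),
                    stringsAsFactors = FALSE)
  m <- merged[!is.na(merged$gene), , drop = FALSE]
  if (nrow(m) == 0L) return(out)
  for (g in sort(unique(m$gene))) {
    sub <- m[m$gene == g, , drop = FALSE]
    if (nrow(sub) < 2L) next
    pattern <- paste(sub$in_TU1, sub$in_TU2)
    if (length(unique(pattern)) < 2L) next
    ord <- order(sub$chrom, sub$pos, sub$ref, sub$alt)
    key <- paste(sub$chrom, sub$pos, sub$ref, sub$alt, sep = ":")[ord]
    out <- rbind(out, data.frame(
      gene = g, n_loci = nrow(sub),
      loci = paste(key, collapse = ";"),
      statuses = paste(sub$status[ord], collapse = ";"),
      stringsAsFactors = FALSE))
  }
  out
}

#' Cohort-level intra-tumour-heterogeneity summary
#'
#' @param cohort Named list of [merge_samples()] outputs, one per patient.
#' @return List with `per_patient` (data.frame: patient_id, n_shared,
#'   n_private_TU1, n_private_TU2, n_total, private_fraction),
#'   `mean_private_fraction`, `n_patients_with_private`,
#'   `gene_frequency` and `convergent_events` (with a patient_id column).
#' @export
cohort_summary <- function(cohort) {
  if (length(cohort) == 0L) stop("empty cohort")
  per <- do.call(rbind, lapply(cohort, function(m) {
    data.frame(
      patient_id = m$patient_id[1],
      n_shared = sum(m$status == "shared"),
      n_private_TU1 = sum(m$status == "private_TU1"),
      n_private_TU2 = sum(m$status == "private_TU2"),
      n_total = nrow(m),
      private_fraction = private_fraction(m),
      stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  conv <- do.call(rbind, lapply(cohort, function(m) {
    ev <- detect_convergence(m)
    if (nrow(ev)) cbind(patient_id = m$patient_id[1], ev) else NULL
  }))
  if (is.null(conv))
    conv <- data.frame(patient_id = character(), gene = character(),
                       n_loci = integer(), loci = character(),
                       statuses = character(), stringsAsFactors = FALSE)
  rownames(conv) <- NULL
  list(per_patient = per,
       mean_private_fraction = mean(per$private_fraction),
       n_patients_with_private =
         sum(per$n_private_TU1 + per$n_private_TU2 > 0),
       gene_frequency = gene_frequency(cohort),
       convergent_events = conv)
}
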