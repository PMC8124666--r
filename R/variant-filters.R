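.filter_report <- function(variants, remove, reason) {
  removed <- variants[remove, , drop = FALSE]
  removed$reason <- if (nrow(removed)) reason[remove] else character(0)
  structure(
    list(input_count = nrow(variants),
         retained = `rownames<-`(variants[!remove, , drop = FALSE], NULL),
         removed = `rownames<-`(removed, NULL)),
    class = "filter_report"
  )
}

#' @exportS3Method base::print
print.filter_report <- function(x, ...) {
  cat("Filter report:", x$input_count, "variants in,",
      nrow(x$retained), "retained,", nrow(x$removed), "removed\n")
  if (nrow(x$removed))
    print(table(x$removed$reason))
  invisible(x)
}

#' Filter low-VAF deamination changes (FFPE artifacts)
#'
#' Formalin fixation deaminates cytosines, producing spurious C>T and G>A
#' calls that concentrate below 10% VAF because the damage hits different
#' genomic positions in different cells. A variant is removed iff its
#' (ref, alt) pair is C>T or G>A and its VAF is strictly below
#' `vaf_threshold`. Indels are exempt (deamination produces substitutions);
#' the filter is strand-agnostic and applied per sample.
#'
#' @param variants Variant-call data.frame.
#' @param vaf_threshold Strict VAF cutoff (default 0.10: a C>T at exactly
#'   10% VAF is retained).
#' @return A `filter_report` with `retained` and `removed` (reason
#'   `"ffpe_artifact"`) variant tables.
#' @export
ffpe_filter <- function(variants, vaf_threshold = 0.10) {
  validate_variant_calls(variants)
  deam <- (variants$ref == "C" & variants$alt == "T") |
          (variants$ref == "G" & variants$alt == "A")
  remove <- deam & variants$vaf < vaf_threshold
  .filter_report(variants, remove,
                 rep("ffpe_artifact", nrow(variants)))
}

#' Find allelically imbalanced heterozygous germline SNPs
#'
#' An imbalanced heterozygous germline SNP has a VAF within
#' `normal_bounds` (default [0.40, 0.60], inclusive) in the matched normal
#' but a VAF strictly outside those bounds in the tumour sample, indicating
#' a potential copy-number change at that locus.
#'
#' @param snps Germline SNP data.frame (see [read_germline_tsv()]).
#' @param tumour_sample `"TU1"` or `"TU2"`; selects the `vaf_TU*` column.
#' @param normal_bounds Inclusive heterozygosity bounds.
#' @return The subset of `snps` that is imbalanced in the tumour sample.
#' @export
find_imbalanced_snps <- function(snps, tumour_sample,
                                 normal_bounds = c(0.40, 0.60)) {
  col <- paste0("vaf_", tumour_sample)
  if (!col %in% names(snps))
    stop("no tumour VAF column '", col, "' in germline SNP table")
  vt <- snps[[col]]
  if (anyNA(vt) || anyNA(snps$vaf_normal)) {
    bad <- which(is.na(vt) | is.na(snps$vaf_normal))[1]
    stop("missing VAF for germline SNP ", snps$chrom[bad], ":",
         snps$pos[bad])
  }
  het <- snps$vaf_normal >= normal_bounds[1] &
         snps$vaf_normal <= normal_bounds[2]
  out <- vt < normal_bounds[1] | vt > normal_bounds[2]
  snps[het & out, , drop = FALSE]
}

#' Filter variants near imbalanced germline SNPs (copy-number neutrality)
#'
#' Clone assignment assumes copy-number-neutral diploid loci, so mutations
#' in potential copy-number variant regions are removed: a variant is
#' filtered out iff an imbalanced heterozygous germline SNP lies on the
#' same chromosome within `window` base pairs (inclusive: distance 4000 is
#' removed, 4001 retained; positions are 1-based and distance is
#' `|pos_variant - pos_snp|`).
#'
#' @param variants Variant-call data.frame.
#' @param imbalanced Imbalanced SNPs from [find_imbalanced_snps()].
#' @param window Distance cutoff in bp.
#' @return A `filter_report` (removal reason `"near_imbalanced_snp"`).
#' @export
cn_neutral_filter <- function(variants, imbalanced, window = 4000L) {
  validate_variant_calls(variants)
  remove <- rep(FALSE, nrow(variants))
  if (nrow(variants) && NROW(imbalanced)) {
    for (chr in unique(variants$chrom)) {
      sp <- sort(imbalanced$pos[imbalanced$chrom == chr])
      if (!length(sp)) next
      vi <- which(variants$chrom == chr)
      nearest <- vapply(variants$pos[vi],
                        function(p) min(abs(p - sp)), 0)
      remove[vi] <- nearest <= window
    }
  }
  .filter_report(variants, remove,
                 rep("near_imbalanced_snp", nrow(variants)))
}

#' Filter silent variants by impact category
#'
#' For clonal-interaction analysis only non-silent mutations are kept:
#' all HIGH and MODERATE impact variants; LOW impact variants except
#' synonymous changes and retained start/stop codons; and no MODIFIER
#' variants (intronic, UTR, other non-coding).
#'
#' @param variants Variant-call data.frame with `impact` and `effect`.
#' @return A `filter_report` (removal reason `"silent_category"`).
#' @export
impact_filter <- function(variants) {
  validate_variant_calls(variants)
  if (nrow(variants) &&
      (anyNA(variants$impact) ||
       !all(variants$impact %in% c("HIGH", "MODERATE", "LOW", "MODIFIER"))))
    stop("unknown impact value; every variant needs impact in ",
         "HIGH/MODERATE/LOW/MODIFIER")
  low_drop <- c("synonymous", "start_retained", "stop_retained")
  remove <- if (nrow(variants))
    variants$impact == "MODIFIER" |
      (variants$impact == "LOW" & variants$effect %in% low_drop)
    else logical(0)
  .filter_report(variants, remove,
                 rep("silent_category", nrow(variants)))
}
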