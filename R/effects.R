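#' Variant effect categories and their impact classes
#'
#' The pipeline annotates every somatic variant with a functional effect
#' category (SnpEff-style) and the corresponding impact class. Frameshift
#' indels and gained stop/start codons are HIGH impact; missense and inframe
#' indels are MODERATE; splice-region, synonymous and retained start/stop
#' changes are LOW; intronic, UTR and other non-coding changes are MODIFIER.
#'
#' @return A data.frame with columns `effect` and `impact`, one row per
#'   recognised effect category.
#' @export
#' @examples
#' effect_impact_table()
effect_impact_table <- function() {
  data.frame(
    effect = c(
      "stop_gained", "start_gained", "frameshift_indel",
      "inframe_indel", "missense",
      "splice_site", "synonymous", "start_retained", "stop_retained",
      "five_prime_utr", "three_prime_utr", "intronic", "other_modifier"
    ),
    impact = c(
      "HIGH", "HIGH", "HIGH",
      "MODERATE", "MODERATE",
      "LOW", "LOW", "LOW", "LOW",
      "MODIFIER", "MODIFIER", "MODIFIER", "MODIFIER"
    ),
    stringsAsFactors = FALSE
  )
}

#' @rdname effect_impact_table
#' @param effect Character vector of effect categories.
#' @return `impact_of()` returns the impact class for each effect; unknown
#'   effects are an error.
#' @export
impact_of <- function(effect) {
  tab <- effect_impact_table()
  idx <- match(effect, tab$effect)
  if (anyNA(idx)) {
    stop("unknown effect category: ",
         paste(unique(effect[is.na(idx)]), collapse = ", "))
  }
  tab$impact[idx]
}

# Display priority used when one gene carries several mutations of equal
# shared/private status and a single effect must represent the gene.
.effect_priority <- c(
  "stop_gained", "start_gained", "frameshift_indel", "inframe_indel",
  "missense", "splice_site", "five_prime_utr", "three_prime_utr",
  "synonymous"
)

#' Pick the highest-priority variant effect
#'
#' When a gene is hit by several mutations of the same status, a single
#' effect is displayed, chosen by a fixed priority ordering (highest first):
#' stop gained, start gained, frameshift indel, inframe indel, missense,
#' splice site, five prime UTR, three prime UTR, synonymous. Effects outside
#' this ordering (retained start/stop, intronic, other non-coding) rank
#' below all listed ones and among themselves in table order.
#'
#' @param effects Non-empty character vector (or set) of effect categories.
#' @return The single highest-priority effect.
#' @export
#' @examples
#' prioritise_effect(c("missense", "synonymous"))  # "missense"
prioritise_effect <- function(effects) {
  effects <- unique(as.character(effects))
  if (length(effects) == 0L) stop("prioritise_effect() needs a non-empty set")
  known <- effect_impact_table()$effect
  bad <- setdiff(effects, known)
  if (length(bad)) stop("unknown effect category: ", paste(bad, collapse = ", "))
  rank <- match(effects, .effect_priority)
  # unlisted effects sort after all listed ones, stable by table order
  rank[is.na(rank)] <- length(.effect_priority) +
    match(effects[is.na(rank)], known)
  effects[which.min(rank)]
}
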