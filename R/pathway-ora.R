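#' Build the expressed-gene background for over-representation analysis
#'
#' Only expressed genes belong in the background of an enrichment test: a
#' gene is included iff its total fragment count across the compared
#' tumour and normal samples is at least `threshold` (inclusive).
#'
#' @param counts Named numeric vector or data.frame/matrix of non-negative
#'   fragment counts with genes as names/rownames; multiple columns are
#'   summed.
#' @param threshold Minimum total fragment count (default 10).
#' @return Character vector of background gene symbols.
#' @export
build_background <- function(counts, threshold = 10) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  totals <- if (is.matrix(counts)) rowSums(counts) else counts
  if (length(totals) == 0L) return(character(0))
  if (is.null(names(totals))) stop("counts must be named by gene")
  if (any(totals < 0)) stop("fragment counts must be non-negative")
  names(totals)[totals >= threshold]
}

#' Pathway over-representation analysis (hypergeometric upper tail)
#'
#' For each pathway with at least one background member, tests whether the
#' differentially expressed (DE) genes overlap the pathway more than
#' expected: `p = P(X >= k)` for X hypergeometric with population `n_bg`
#' (background size), `m` pathway members in the background, and `n_de`
#' draws. Pathway membership is intersected with the background first; DE
#' genes outside the background are dropped with a warning. q-values are
#' Benjamini-Hochberg across the tested pathways.
#'
#' @param de_genes Character vector of DE gene symbols.
#' @param background Character vector of expressed background genes.
#' @param db Named list of gene sets (see [read_gmt()]).
#' @return data.frame with columns pathway, k (DE genes in pathway), m
#'   (background genes in pathway), n_de, n_bg, p, q, sorted by p.
#' @export
ora_test <- function(de_genes, background, db) {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background gene list")
  de_genes <- unique(de_genes)
  outside <- setdiff(de_genes, background)
  if (length(outside)) {
    warning(length(outside), " DE gene(s) outside the background dropped")
    de_genes <- intersect(de_genes, background)
  }
  n_bg <- length(background); n_de <- length(de_genes)
  rows <- lapply(names(db), function(pw) {
    members <- intersect(db[[pw]], background)
    m <- length(members)
    if (m == 0L) return(NULL)
    k <- length(intersect(members, de_genes))
    # upper tail P(X >= k); P(X >= 0) = 1 by convention
    p <- stats::phyper(k - 1, m, n_bg - m, n_de, lower.tail = FALSE)
    data.frame(pathway = pw, k = k, m = m, n_de = n_de, n_bg = n_bg,
               p = min(p, 1), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(pathway = character(), k = integer(), m = integer(),
                      n_de = integer(), n_bg = integer(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$pathway), , drop = FALSE]
}
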