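#' Read a pathway database from a GMT file
#'
#' Standard GMT: one pathway per line, tab-separated as
#' `name<TAB>description<TAB>gene<TAB>gene...`. Duplicate genes within a
#' line are deduplicated; duplicate lines for the same pathway are merged
#' by gene-set union with a warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (pathway id -> member genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  db <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, " in ", path,
           ": expected name, description and at least one gene")
    name <- f[1L]
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L)
      stop("malformed GMT line ", i, " in ", path, ": empty gene set")
    if (!is.null(db[[name]])) {
      warning("duplicate GMT entry for '", name, "' at line ", i,
              "; merging gene sets")
      genes <- union(db[[name]], genes)
    }
    db[[name]] <- genes
  }
  db
}

#' @rdname read_gmt
#' @param db Named list of gene sets.
#' @param descriptions Optional character vector of per-pathway
#'   descriptions (recycled).
#' @return `write_gmt()` returns `path`, invisibly.
#' @export
write_gmt <- function(db, path, descriptions = "na") {
  stopifnot(length(db) == 0L || !is.null(names(db)))
  descriptions <- rep_len(descriptions, length(db))
  lines <- vapply(seq_along(db), function(i) {
    paste(c(names(db)[i], descriptions[i], db[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a pathway-by-clone (or gene-by-clone) binary matrix
#'
#' Expects a TSV with a header row of clone ids, a first column of entity
#' (pathway or gene) ids, and 0/1 cells: entry (e, c) = 1 means some
#' mutation of entity e was assigned to clone c in that patient.
#'
#' @param path Path to the TSV.
#' @param patient_id Patient label stored as the `"patient_id"` attribute.
#' @param transpose Set `TRUE` if the file is clone-by-entity instead
#'   (deposited matrix layouts vary in orientation).
#' @return A binary integer matrix, rows = entities, columns = clones, with
#'   attribute `patient_id`.
#' @export
read_clone_matrix <- function(path, patient_id = NA_character_,
                              transpose = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("clone matrix ", path,
                          " needs an id column plus >=1 clone column")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  bad <- which(!(m %in% c(0, 1)) | is.na(m))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(m))
    stop("non-binary cell in ", path, " at (row ", rc[1L], ", col ", rc[2L],
         "): value '", m[bad[1L]], "'")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  if (transpose) m <- t(m)
  attr(m, "patient_id") <- patient_id
  m
}

#' @rdname read_clone_matrix
#' @param mat Binary entity-by-clone matrix with dimnames.
#' @param id_col Header of the first (entity id) column.
#' @return `write_clone_matrix()` returns `path`, invisibly.
#' @export
write_clone_matrix <- function(mat, path, id_col = "entity") {
  stopifnot(is.matrix(mat), !is.null(colnames(mat)),
            nrow(mat) == 0L || !is.null(rownames(mat)))
  ids <- if (is.null(rownames(mat))) character(0) else rownames(mat)
  df <- data.frame(ids, mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write germline heterozygous SNP tables
#'
#' One row per germline SNP with the VAF observed in the matched normal and
#' in each tumour biopsy; used by the copy-number-neutrality filter to find
#' allelically imbalanced SNPs.
#'
#' @param path Path to a TSV with columns chrom, pos, vaf_normal, vaf_TU1,
#'   vaf_TU2.
#' @return A data.frame with those columns.
#' @export
read_germline_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "vaf_normal", "vaf_TU1", "vaf_TU2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("germline SNP table ", path, " lacks columns: ",
                         paste(miss, collapse = ", "))
  vafs <- unlist(df[c("vaf_normal", "vaf_TU1", "vaf_TU2")])
  if (any(!is.na(vafs) & (vafs < 0 | vafs > 1)))
    stop("germline SNP VAFs must lie in [0,1]")
  df
}

#' @rdname read_germline_tsv
#' @param snps Germline SNP data.frame.
#' @export
write_germline_tsv <- function(snps, path) {
  utils::write.table(snps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
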