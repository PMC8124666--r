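#' Construct a table of somatic variant calls
#'
#' Variant calls are plain data.frames with one row per called allele in one
#' sample. This constructor validates the invariants the rest of the
#' pipeline relies on: `0 <= alt_count <= depth`, `vaf == alt_count/depth`
#' where depth is positive, and `ref != alt`.
#'
#' @param patient_id,sample_id,chrom,pos,ref,alt,alt_count,depth Vectors of
#'   equal length (recycled where length 1). `sample_id` is one of
#'   `"TU1"`, `"TU2"`, `"N"`. Positions are 1-based (VCF convention).
#' @param gene,effect Optional annotation columns; `NA` where absent.
#' @return A data.frame with columns patient_id, sample_id, chrom, pos, ref,
#'   alt, alt_count, depth, vaf, gene, effect, impact.
#' @export
variant_calls <- function(patient_id, sample_id, chrom, pos, ref, alt,
                          alt_count, depth, gene = NA_character_,
                          effect = NA_character_) {
  df <- data.frame(
    patient_id = as.character(patient_id),
    sample_id = as.character(sample_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = as.character(ref),
    alt = as.character(alt),
    alt_count = as.integer(alt_count),
    depth = as.integer(depth),
    stringsAsFactors = FALSE
  )
  df$vaf <- ifelse(df$depth > 0, df$alt_count / df$depth, 0)
  df$gene <- rep_len(as.character(gene), nrow(df))
  df$effect <- rep_len(as.character(effect), nrow(df))
  df$impact <- ifelse(is.na(df$effect), NA_character_, "")
  has_eff <- !is.na(df$effect)
  if (any(has_eff)) df$impact[has_eff] <- impact_of(df$effect[has_eff])
  validate_variant_calls(df)
}

#' @rdname variant_calls
#' @param df A variant-call data.frame to validate.
#' @export
validate_variant_calls <- function(df) {
  need <- c("patient_id", "sample_id", "chrom", "pos", "ref", "alt",
            "alt_count", "depth", "vaf")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("variant table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) return(df)
  if (!all(df$sample_id %in% c("TU1", "TU2", "N")))
    stop("sample_id must be TU1, TU2 or N")
  if (any(df$alt_count < 0 | df$alt_count > df$depth))
    stop("alt_count must lie in [0, depth]")
  if (any(df$ref == df$alt)) stop("ref and alt alleles must differ")
  pos_d <- df$depth > 0
  if (any(abs(df$vaf[pos_d] - df$alt_count[pos_d] / df$depth[pos_d]) > 1e-12))
    stop("vaf inconsistent with alt_count/depth")
  df
}

#' Canonical variant key
#'
#' The `(chrom, pos, ref, alt)` key used everywhere a variant must be
#' matched across samples, filters and clone assignments. Indels are
#' assumed left-aligned upstream.
#'
#' @param df Data.frame with columns chrom, pos, ref, alt.
#' @return Character vector `"chrom:pos:ref:alt"`.
#' @export
variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

.parse_ann_info <- function(info, alt) {
  # ANN=Allele|effect|impact|gene[,...]: pick the entry matching the alt
  # allele, else the first entry
  m <- regmatches(info, regexpr("(?:^|;)ANN=[^;]+", info))
  if (length(m) == 0L) return(c(NA_character_, NA_character_, NA_character_))
  entries <- strsplit(sub("^(;)?ANN=", "", m), ",", fixed = TRUE)[[1]]
  fields <- strsplit(entries, "|", fixed = TRUE)
  hit <- which(vapply(fields, `[`, "", 1L) == alt)
  f <- fields[[if (length(hit)) hit[1L] else 1L]]
  f <- c(f, rep(NA_character_, max(0L, 4L - length(f))))
  c(effect = f[2L], impact = f[3L], gene = f[4L])
}

#' Read somatic variant calls from a VCF file
#'
#' Reads a VCF (v4.1+) with per-sample `AD` and `DP` FORMAT fields and
#' returns one variant-call row per ALT allele; multi-allelic records are
#' split. The VAF is recomputed from AD/DP. Gene and effect annotations are
#' taken from a SnpEff-style `ANN` INFO subfield
#' (`Allele|effect|impact|gene`) when present, else from the optional
#' `annotations` table keyed by (chrom, pos, ref, alt).
#'
#' @param path Path to a plain-text VCF file.
#' @param patient_id,sample_id Labels attached to every returned row.
#' @param ad_order AD field dialect: `"ref_first"` (GATK-style, default) or
#'   `"alt_first"`.
#' @param annotations Optional data.frame with columns chrom, pos, ref, alt,
#'   gene, effect used when the VCF has no ANN subfield.
#' @return A variant-call data.frame (see [variant_calls()]).
#' @export
read_vcf <- function(path, patient_id, sample_id,
                     ad_order = c("ref_first", "alt_first"),
                     annotations = NULL) {
  ad_order <- match.arg(ad_order)
  lines <- readLines(path, n = 1L)
  if (length(lines) == 0L || !grepl("^##fileformat=VCFv4", lines[1L]))
    stop("malformed VCF header in ", path, ": missing ##fileformat=VCFv4.x")
  n_body <- sum(!startsWith(readLines(path), "#"))
  if (n_body == 0L) {
    return(variant_calls(character(), character(), character(), integer(),
                         character(), character(), integer(), integer()))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  fix <- matrix(fix, ncol = 8L,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER", "INFO")))
  gt <- v@gt
  if (ncol(gt) < 2L) stop("VCF has no sample column: ", path)
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    fmt <- strsplit(gt[i, 1L], ":", fixed = TRUE)[[1]]
    val <- strsplit(gt[i, 2L], ":", fixed = TRUE)[[1]]
    i_ad <- match("AD", fmt); i_dp <- match("DP", fmt)
    if (is.na(i_ad) || is.na(i_dp) || is.na(val[i_ad]) || is.na(val[i_dp]))
      stop("counts unavailable: record ", fix[i, "CHROM"], ":", fix[i, "POS"],
           " lacks AD/DP")
    ad <- as.integer(strsplit(val[i_ad], ",", fixed = TRUE)[[1]])
    dp <- as.integer(val[i_dp])
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    if (length(ad) != length(alts) + 1L)
      stop("counts unavailable: AD has ", length(ad), " values for ",
           length(alts), " ALT allele(s) at ", fix[i, "CHROM"], ":",
           fix[i, "POS"])
    alt_counts <- if (ad_order == "ref_first") ad[-1L] else
      ad[seq_along(alts)]
    ann <- t(vapply(alts, function(a) .parse_ann_info(fix[i, "INFO"], a),
                    character(3)))
    out[[i]] <- data.frame(
      chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
      ref = fix[i, "REF"], alt = alts,
      alt_count = alt_counts, depth = dp,
      gene = ann[, 3L], effect = ann[, 1L],
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  out <- do.call(rbind, out)
  if (!is.null(annotations)) {
    key <- paste(out$chrom, out$pos, out$ref, out$alt, sep = ":")
    akey <- paste(annotations$chrom, annotations$pos, annotations$ref,
                  annotations$alt, sep = ":")
    idx <- match(key, akey)
    fill <- is.na(out$gene) & !is.na(idx)
    out$gene[fill] <- annotations$gene[idx[fill]]
    out$effect[fill] <- annotations$effect[idx[fill]]
  }
  variant_calls(patient_id, sample_id, out$chrom, out$pos, out$ref, out$alt,
                out$alt_count, out$depth, out$gene, out$effect)
}

#' Write somatic variant calls of one sample to a VCF file
#'
#' Emits a minimal VCF v4.2 with `AD`/`DP` FORMAT fields and a SnpEff-style
#' `ANN` INFO subfield carrying gene/effect/impact annotation. Round-trips
#' through [read_vcf()] exactly for chrom, pos, ref, alt, alt_count and
#' depth.
#'
#' @param variants Variant-call data.frame for a single sample.
#' @param path Output path.
#' @param ad_order AD dialect, as in [read_vcf()].
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, ad_order = c("ref_first", "alt_first")) {
  ad_order <- match.arg(ad_order)
  validate_variant_calls(variants)
  sample_name <- if (nrow(variants)) unique(variants$sample_id) else "SAMPLE"
  if (length(sample_name) != 1L)
    stop("write_vcf() writes one sample per file; got: ",
         paste(sample_name, collapse = ", "))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotation: Allele|Effect|Impact|Gene\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  body <- character(0)
  if (nrow(variants)) {
    v <- variants[order(variants$chrom, variants$pos, variants$ref,
                        variants$alt), , drop = FALSE]
    ref_n <- v$depth - v$alt_count
    ad <- if (ad_order == "ref_first") paste(ref_n, v$alt_count, sep = ",")
          else paste(v$alt_count, ref_n, sep = ",")
    info <- ifelse(
      is.na(v$effect) & is.na(v$gene), ".",
      paste0("ANN=", v$alt, "|",
             ifelse(is.na(v$effect), "", v$effect), "|",
             ifelse(is.na(v$impact), "", v$impact), "|",
             ifelse(is.na(v$gene), "", v$gene))
    )
    body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info,
                  "AD:DP", paste(ad, v$depth, sep = ":"), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
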