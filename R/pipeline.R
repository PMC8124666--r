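#' Derive a per-patient seed from the global seed
#'
#' Stable string hash of the patient id mixed with the global seed, so each
#' patient's results are reproducible independently of manifest order.
#'
#' @param patient_id Patient identifier string.
#' @param seed Global integer seed.
#' @return An integer seed below 2^31.
#' @export
stable_patient_seed <- function(patient_id, seed) {
  h <- as.numeric(seed) %% 2147483647
  for (c in utf8ToInt(patient_id)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Assemble a pipeline configuration
#'
#' The happy path `simulate -> filter -> heterogeneity -> clones ->
#' exclusivity` runs either on a synthetic cohort (give `sim`) or on
#' existing per-patient VCFs (give `manifest`: a data.frame with columns
#' patient_id, tu1_path, tu2_path, germline_path).
#'
#' @param out_dir Output directory (created if needed).
#' @param sim A [sim_config()], or `NULL` when a manifest is given.
#' @param manifest Optional manifest data.frame.
#' @param vaf_threshold,window,normal_bounds Filter parameters (see
#'   [ffpe_filter()], [cn_neutral_filter()], [find_imbalanced_snps()]).
#' @param k_range,n_restarts Clone-assignment parameters ([fit_clones()]).
#' @param level Exclusivity level: `"gene"` or `"pathway"` (pathway needs
#'   `pathway_db`).
#' @param min_patients Minimum patients per tested pair.
#' @param pathway_db Named list of gene sets for pathway-level analysis.
#' @param seed Global seed; per-patient seeds are derived by stable
#'   hashing of the patient id.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, sim = sim_config(), manifest = NULL,
                            vaf_threshold = 0.10, window = 4000L,
                            normal_bounds = c(0.40, 0.60),
                            k_range = c(1L, 5L), n_restarts = 20L,
                            level = c("gene", "pathway"),
                            min_patients = 2L, pathway_db = NULL,
                            seed = 1L) {
  level <- match.arg(level)
  if (level == "pathway" && is.null(pathway_db) &&
      (is.null(sim) || is.null(sim$pathway_db)))
    stop("pathway-level exclusivity needs a pathway_db")
  structure(list(out_dir = out_dir, sim = sim, manifest = manifest,
                 vaf_threshold = vaf_threshold, window = as.integer(window),
                 normal_bounds = normal_bounds, k_range = k_range,
                 n_restarts = as.integer(n_restarts), level = level,
                 min_patients = as.integer(min_patients),
                 pathway_db = if (!is.null(pathway_db)) pathway_db
                              else sim$pathway_db,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the paired-biopsy heterogeneity pipeline end to end
#'
#' Stages: cohort acquisition (synthetic simulation or manifest VCFs);
#' per-sample FFPE and copy-number-neutrality filtering (filtered VCFs and
#' a removal-report TSV per patient); shared/private classification and
#' cohort summary; clone assignment per patient (assignment and
#' clone-fraction TSVs, entity-by-clone matrices); clonal-exclusivity
#' testing across the cohort; and a run-metadata JSON. Reruns with an
#' identical configuration produce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results: `cohort` (merged
#'   per-patient variant tables), `summary`, `profiles`, `matrices`,
#'   `exclusivity`, and `paths` of the written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  # --- stage: cohort acquisition -------------------------------------
  if (!is.null(config$manifest)) {
    man <- config$manifest
    need <- c("patient_id", "tu1_path", "tu2_path", "germline_path")
    if (!all(need %in% names(man)))
      stop("manifest needs columns: ", paste(need, collapse = ", "))
    for (i in seq_len(nrow(man))) {
      for (col in c("tu1_path", "tu2_path", "germline_path")) {
        if (!file.exists(man[[col]][i]))
          stop("manifest row ", i, " (patient ", man$patient_id[i],
               "): missing file ", man[[col]][i])
      }
    }
    calls <- list(); germ <- list()
    for (i in seq_len(nrow(man))) {
      pid <- man$patient_id[i]
      calls[[pid]] <- rbind(read_vcf(man$tu1_path[i], pid, "TU1"),
                            read_vcf(man$tu2_path[i], pid, "TU2"))
      g <- read_germline_tsv(man$germline_path[i])
      g$patient_id <- pid
      germ[[pid]] <- g
    }
    variants <- do.call(rbind, calls)
    germline <- do.call(rbind, germ)
    truth <- NULL
  } else {
    sim <- simulate_cohort(config$sim)
    variants <- sim$variants
    germline <- sim$germline
    truth <- sim$truth
    for (pid in unique(variants$patient_id)) {
      for (s in c("TU1", "TU2")) {
        v <- variants[variants$patient_id == pid & variants$sample_id == s, ]
        write_vcf(v, file.path(config$out_dir,
                               paste0(pid, "_", s, ".vcf")))
      }
      # matched normal: no somatic calls
      write_vcf(variant_calls(character(), character(), character(),
                              integer(), character(), character(),
                              integer(), integer()),
                file.path(config$out_dir, paste0(pid, "_N.vcf")))
    }
    write_germline_tsv(germline,
                       file.path(config$out_dir, "germline_snps.tsv"))
    paths$germline <- file.path(config$out_dir, "germline_snps.tsv")
  }

  # --- stage: per-sample filtering -----------------------------------
  filtered <- list(); reports <- list()
  for (pid in unique(variants$patient_id)) {
    g <- germline[germline$patient_id == pid, , drop = FALSE]
    for (s in c("TU1", "TU2")) {
      v <- variants[variants$patient_id == pid & variants$sample_id == s, ,
                    drop = FALSE]
      r1 <- ffpe_filter(v, config$vaf_threshold)
      imb <- find_imbalanced_snps(g, s, config$normal_bounds)
      r2 <- cn_neutral_filter(r1$retained, imb, config$window)
      filtered[[paste(pid, s)]] <- r2$retained
      rep_df <- rbind(r1$removed, r2$removed)
      reports[[paste(pid, s)]] <- if (nrow(rep_df)) rep_df else NULL
      write_vcf(r2$retained,
                file.path(config$out_dir, paste0(pid, "_", s,
                                                 "_filtered.vcf")))
    }
    rep_all <- do.call(rbind, reports[paste(pid, c("TU1", "TU2"))])
    rep_out <- if (!is.null(rep_all))
      rep_all[, c("chrom", "pos", "ref", "alt", "sample_id", "reason")]
      else data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      sample_id = character(), reason = character())
    utils::write.table(rep_out,
                       file.path(config$out_dir,
                                 paste0(pid, "_filter_report.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- stage: shared/private classification --------------------------
  cohort <- list()
  for (pid in unique(variants$patient_id)) {
    cohort[[pid]] <- merge_samples(filtered[[paste(pid, "TU1")]],
                                   filtered[[paste(pid, "TU2")]])
  }
  summ <- cohort_summary(cohort)
  het <- do.call(rbind, cohort)
  rownames(het) <- NULL
  utils::write.table(het, file.path(config$out_dir, "heterogeneity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summ$per_patient,
                     file.path(config$out_dir, "cohort_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths$heterogeneity <- file.path(config$out_dir, "heterogeneity.tsv")

  # --- stage: clone assignment ---------------------------------------
  profiles <- list(); matrices <- list()
  for (pid in names(cohort)) {
    m <- cohort[[pid]]
    prof <- fit_clones(m, k_range = config$k_range,
                       n_restarts = config$n_restarts,
                       seed = stable_patient_seed(pid, config$seed))
    profiles[[pid]] <- prof
    utils::write.table(
      data.frame(key = names(prof$assignment), clone = prof$assignment,
                 row.names = NULL),
      file.path(config$out_dir, paste0(pid, "_clone_assignment.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(clone = rownames(prof$fractions), prof$fractions,
                 row.names = NULL),
      file.path(config$out_dir, paste0(pid, "_clone_fractions.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)

    # non-silent mutations only enter the clonal-interaction analysis
    ma <- m[!is.na(m$effect), , drop = FALSE]
    keep <- impact_filter(
      variant_calls(pid, "TU1", ma$chrom, ma$pos, ma$ref, ma$alt,
                    pmax(ma$alt_TU1, ma$alt_TU2),
                    pmax(ma$depth_TU1, ma$depth_TU2, 1L),
                    ma$gene, ma$effect))$retained
    keys <- variant_key(keep)
    emap <- data.frame(key = keys, entity = keep$gene,
                       stringsAsFactors = FALSE)
    emap <- emap[!is.na(emap$entity), , drop = FALSE]
    if (config$level == "pathway") {
      db <- config$pathway_db
      emap <- do.call(rbind, lapply(names(db), function(pw) {
        hit <- emap$key[emap$entity %in% db[[pw]]]
        if (length(hit)) data.frame(key = hit, entity = pw,
                                    stringsAsFactors = FALSE) else NULL
      }))
      if (is.null(emap)) emap <- data.frame(key = character(),
                                            entity = character())
    }
    mat <- to_entity_clone_matrix(prof, emap)
    matrices[[pid]] <- mat
    write_clone_matrix(mat, file.path(config$out_dir,
                                      paste0(pid, "_clone_matrix.tsv")),
                       id_col = config$level)
  }

  # --- stage: clonal exclusivity -------------------------------------
  excl <- test_all_pairs(matrices, min_patients = config$min_patients)
  utils::write.table(excl, file.path(config$out_dir, "exclusivity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths$exclusivity <- file.path(config$out_dir, "exclusivity.tsv")

  meta <- list(
    package = "clonepair",
    version = as.character(utils::packageVersion("clonepair")),
    seed = config$seed,
    parameters = list(vaf_threshold = config$vaf_threshold,
                      window = config$window,
                      normal_bounds = config$normal_bounds,
                      k_range = config$k_range,
                      n_restarts = config$n_restarts,
                      level = config$level,
                      min_patients = config$min_patients),
    patients = names(cohort)
  )
  jsonlite::write_json(meta, file.path(config$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  paths$metadata <- file.path(config$out_dir, "run_metadata.json")

  invisible(list(cohort = cohort, summary = summ, profiles = profiles,
                 matrices = matrices, exclusivity = excl, truth = truth,
                 paths = paths))
}
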