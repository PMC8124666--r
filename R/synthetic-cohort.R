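#' Configuration for the synthetic paired-biopsy cohort generator
#'
#' The generator emulates the structure of a multi-region tumour sequencing
#' study: for every patient, two spatially separated tumour biopsies (TU1,
#' TU2) and a matched normal (N); a clone tree with per-sample clone
#' fractions; copy-number-neutral diploid variant allele frequencies with
#' binomial read-count noise; low-VAF C>T/G>A FFPE deamination artifacts;
#' heterozygous germline SNPs whose allelic imbalance marks copy-number
#' variant regions; and, optionally, planted clonally exclusive pathway
#' pairs with ground-truth labels.
#'
#' @param n_patients Number of patients.
#' @param n_clones_range Inclusive integer range for the number of tumour
#'   clones per patient.
#' @param n_mutations_per_clone Somatic mutations assigned to each clone.
#' @param depth Sequencing depth per locus (reads).
#' @param purity Minimum tumour-cell content of a biopsy; the normal-cell
#'   fraction of every sample is floored at `1 - purity`.
#' @param p_clone_absent Probability that a non-founding clone is spatially
#'   restricted to a single biopsy (fraction 0 in the other); this is what
#'   makes mutations private to one sample.
#' @param ffpe_artifact_count FFPE artifacts planted per tumour sample.
#' @param ffpe_vaf_bounds True-VAF interval for planted artifacts; must lie
#'   within (0, 0.10].
#' @param n_germline_snps Germline heterozygous SNPs per patient.
#' @param cnv_region_count Copy-number variant regions per patient; each
#'   receives two imbalanced germline SNPs.
#' @param cnv_region_width Width (bp) of each CNV region.
#' @param p_mut_in_cnv Probability a somatic mutation is placed inside a
#'   CNV region (true positives for the copy-number-neutrality filter).
#' @param contig,contig_length Name and length of the single synthetic
#'   contig loci are placed on.
#' @param panel_genes Gene symbols mutations are drawn from.
#' @param pathway_db Optional named list of gene sets (see [read_gmt()]).
#' @param planted_exclusive_pairs List of length-2 character vectors of
#'   pathway ids; in every patient, one mutation of a gene private to each
#'   pathway is assigned to two distinct clones, making the pair clonally
#'   exclusive by construction.
#' @param effect_weights Named sampling weights over effect categories for
#'   true somatic mutations.
#' @param min_clone_spacing Minimum separation, in expected-VAF units, that
#'   every pair of clones must show in at least one sample (and that every
#'   clone's own expected VAF must reach somewhere) before a fraction draw
#'   is accepted. 0 (default) disables the constraint. Parameter-recovery
#'   benchmarks use a positive spacing so that recovery error measures the
#'   algorithm rather than information-theoretic non-identifiability of
#'   coincidentally overlapping clones.
#' @param noise `"binomial"` draws alt counts from Binomial(depth, VAF);
#'   `"none"` emits a variant in a sample exactly when its carrier clones
#'   have non-zero fraction there, with `alt = max(1, round(VAF * depth))`,
#'   so detection equals ground truth.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A validated config list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 16,
                       n_clones_range = c(2L, 4L),
                       n_mutations_per_clone = 8L,
                       depth = 933L,
                       purity = 0.7,
                       p_clone_absent = 0.6,
                       ffpe_artifact_count = 5L,
                       ffpe_vaf_bounds = c(0.01, 0.10),
                       n_germline_snps = 100L,
                       cnv_region_count = 2L,
                       cnv_region_width = 20000L,
                       p_mut_in_cnv = 0.1,
                       contig = "chr1",
                       contig_length = 1e7,
                       panel_genes = default_panel_genes(),
                       pathway_db = NULL,
                       planted_exclusive_pairs = list(),
                       effect_weights = c(missense = 0.55,
                                          splice_site = 0.15,
                                          stop_gained = 0.05,
                                          frameshift_indel = 0.15,
                                          inframe_indel = 0.10),
                       min_clone_spacing = 0,
                       noise = c("binomial", "none"),
                       seed = 1L) {
  noise <- match.arg(noise)
  cfg <- list(n_patients = as.integer(n_patients),
              n_clones_range = as.integer(n_clones_range),
              n_mutations_per_clone = as.integer(n_mutations_per_clone),
              depth = as.integer(depth), purity = purity,
              p_clone_absent = p_clone_absent,
              ffpe_artifact_count = as.integer(ffpe_artifact_count),
              ffpe_vaf_bounds = ffpe_vaf_bounds,
              n_germline_snps = as.integer(n_germline_snps),
              cnv_region_count = as.integer(cnv_region_count),
              cnv_region_width = as.integer(cnv_region_width),
              p_mut_in_cnv = p_mut_in_cnv,
              contig = contig, contig_length = contig_length,
              panel_genes = panel_genes, pathway_db = pathway_db,
              planted_exclusive_pairs = planted_exclusive_pairs,
              effect_weights = effect_weights,
              min_clone_spacing = min_clone_spacing, noise = noise,
              seed = as.integer(seed))
  stopifnot(cfg$n_patients >= 1, cfg$depth > 0,
            cfg$purity > 0, cfg$purity <= 1,
            length(cfg$n_clones_range) == 2L,
            cfg$n_clones_range[1] >= 1,
            cfg$n_clones_range[2] >= cfg$n_clones_range[1],
            cfg$n_mutations_per_clone >= 1)
  b <- cfg$ffpe_vaf_bounds
  if (length(b) != 2L || b[1] <= 0 || b[2] > 0.10 || b[1] >= b[2])
    stop("ffpe_vaf_bounds must lie within (0, 0.10]")
  if (length(cfg$planted_exclusive_pairs)) {
    if (is.null(cfg$pathway_db))
      stop("planted_exclusive_pairs requires a pathway_db")
    pws <- unique(unlist(cfg$planted_exclusive_pairs))
    miss <- setdiff(pws, names(cfg$pathway_db))
    if (length(miss)) stop("planted pathways missing from pathway_db: ",
                           paste(miss, collapse = ", "))
    genes <- unique(unlist(cfg$pathway_db[pws]))
    miss <- setdiff(genes, cfg$panel_genes)
    if (length(miss)) stop("pathway genes absent from panel_genes: ",
                           paste(miss, collapse = ", "))
  }
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_panel_genes <- function() {
  c("VHL", "PBRM1", "SETD2", "BAP1", "TP53", "MUC6", "MUC16", "MUC3A",
    "MTOR", "KDM5C", sprintf("GENE%03d", 1:50))
}

# uniform labelled rooted tree on n nodes: uniform labelled tree via a
# random Pruefer sequence, then a uniform root; returned as a parent vector
# with parent[root] == 0
.random_rooted_tree <- function(n) {
  if (n == 1L) return(0L)
  edges <- if (n == 2L) matrix(c(1L, 2L), ncol = 2) else {
    prufer <- sample.int(n, n - 2L, replace = TRUE)
    degree <- tabulate(prufer, n) + 1L
    e <- matrix(0L, n - 1L, 2L)
    ptr <- which(degree == 1L)
    for (i in seq_len(n - 2L)) {
      leaf <- min(ptr)
      e[i, ] <- c(leaf, prufer[i])
      degree[leaf] <- 0L
      degree[prufer[i]] <- degree[prufer[i]] - 1L
      ptr <- which(degree == 1L)
    }
    e[n - 1L, ] <- which(degree == 1L)
    e
  }
  root <- sample.int(n, 1L)
  parent <- integer(n)
  adj <- lapply(seq_len(n), function(i)
    c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1]))
  queue <- root; seen <- rep(FALSE, n); seen[root] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) {
      parent[w] <- v; seen[w] <- TRUE; queue <- c(queue, w)
    }
  }
  parent
}

# clone c plus all its descendants in the parent-vector tree
.clone_descendant_sets <- function(parent) {
  n <- length(parent)
  lapply(seq_len(n), function(c) {
    set <- c
    repeat {
      add <- which(parent %in% set & !(seq_len(n) %in% set))
      if (!length(add)) break
      set <- c(set, add)
    }
    sort(set)
  })
}

.rdirichlet1 <- function(n) {
  g <- stats::rgamma(n, shape = 1)
  g / sum(g)
}

# sample positions on the contig outside all CNV regions by at least margin
.sample_outside <- function(n, regions, margin, contig_length) {
  if (n == 0L) return(integer(0))
  out <- integer(0)
  while (length(out) < n) {
    cand <- sample.int(contig_length, n * 2L)
    if (nrow(regions)) {
      ok <- !vapply(cand, function(p)
        any(p >= regions$start - margin & p <= regions$end + margin), TRUE)
      cand <- cand[ok]
    }
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

.BASES <- c("A", "C", "G", "T")

# substitution pair for a true somatic SNV, never the deamination pairs
# (C>T, G>A), which are reserved for the artifact channel
.draw_substitution <- function() {
  repeat {
    ref <- sample(.BASES, 1L)
    alt <- sample(setdiff(.BASES, ref), 1L)
    if (!((ref == "C" && alt == "T") || (ref == "G" && alt == "A")))
      return(c(ref, alt))
  }
}

.draw_alleles <- function(effect) {
  if (effect == "frameshift_indel") {
    ref <- sample(.BASES, 1L)
    c(ref, paste0(ref, sample(.BASES, 1L)))
  } else if (effect == "inframe_indel") {
    ref <- sample(.BASES, 1L)
    c(ref, paste0(ref, paste(sample(.BASES, 3L, replace = TRUE),
                             collapse = "")))
  } else {
    .draw_substitution()
  }
}

#' Simulate a paired-biopsy tumour cohort with ground truth
#'
#' For each patient a clone tree and per-sample clone fractions are drawn,
#' mutations are assigned to clones, and the expected VAF of a mutation in
#' sample s is `0.5 * sum(F[carriers, s])` where the carriers are the
#' assigned clone plus its descendants (diploid, copy-number neutral).
#' Observed alt counts are Binomial(depth, VAF) (or noise-free, see
#' [sim_config()]). The matched normal carries no somatic mutations. FFPE
#' artifacts, imbalanced germline SNPs inside CNV regions, and planted
#' clonally exclusive pathway pairs are generated per the config.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `variants` (variant-call data.frame over
#'   all patients and samples), `germline` (germline SNP data.frame with a
#'   `patient_id` column), `truth` (per-patient list: `parent`, `fractions`
#'   ((K+1) x 2 matrix incl. the normal row "N"), `assignment`, `status`,
#'   `expected_vaf`, `artifacts`, `cnv_regions`, `pathway_clone` matrix),
#'   and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .simulate_cohort_impl(config))
}

.simulate_cohort_impl <- function(cfg) {
  all_var <- list(); all_germ <- list(); truth <- list()
  planted_genes <- if (length(cfg$planted_exclusive_pairs))
    unique(unlist(cfg$pathway_db[unique(unlist(cfg$planted_exclusive_pairs))]))
    else character(0)
  gene_pool <- setdiff(cfg$panel_genes, planted_genes)
  eff_names <- names(cfg$effect_weights)

  for (pi in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%02d", pi)
    ks <- seq(cfg$n_clones_range[1], cfg$n_clones_range[2])
    K <- ks[sample.int(length(ks), 1L)]
    parent <- .random_rooted_tree(K)
    root <- which(parent == 0L)
    desc <- .clone_descendant_sets(parent)

    # spatial restriction (non-root clones may be confined to one biopsy)
    # and per-sample fractions; with a positive min_clone_spacing, draws
    # are rejected until all clones are mutually separated and detectable
    # in expected-VAF space
    for (attempt in seq_len(1000L)) {
      present <- matrix(TRUE, K, 2, dimnames = list(NULL, c("TU1", "TU2")))
      for (c in seq_len(K)[-root]) {
        if (stats::runif(1) < cfg$p_clone_absent)
          present[c, sample(1:2, 1L)] <- FALSE
      }
      Fm <- matrix(0, K + 1L, 2,
                   dimnames = list(c(paste0("clone", seq_len(K)), "N"),
                                   c("TU1", "TU2")))
      for (s in 1:2) {
        idx <- which(present[, s])
        w <- .rdirichlet1(length(idx) + 1L)
        n0 <- max(w[length(w)], 1 - cfg$purity)
        cl <- w[-length(w)]
        cl <- cl / sum(cl) * (1 - n0)
        Fm[idx, s] <- cl
        Fm[K + 1L, s] <- n0
      }
      if (cfg$min_clone_spacing <= 0) break
      ev <- t(vapply(seq_len(K), function(c)
        0.5 * colSums(Fm[desc[[c]], , drop = FALSE]), numeric(2)))
      sep_ok <- all(vapply(seq_len(K), function(i)
        max(ev[i, ]) >= cfg$min_clone_spacing, TRUE))
      if (K > 1L && sep_ok) {
        for (i in seq_len(K - 1L)) for (j in seq.int(i + 1L, K)) {
          if (max(abs(ev[i, ] - ev[j, ])) < cfg$min_clone_spacing)
            sep_ok <- FALSE
        }
      }
      if (sep_ok) break
      if (attempt == 1000L)
        stop("could not satisfy min_clone_spacing after 1000 draws")
    }

    # CNV regions (non-overlapping, kept off the contig edges)
    regions <- data.frame(start = integer(0), end = integer(0))
    if (cfg$cnv_region_count > 0L) {
      margin <- cfg$cnv_region_width + 10000L
      starts <- integer(0)
      while (length(starts) < cfg$cnv_region_count) {
        s0 <- sample.int(cfg$contig_length - margin - 10000L, 1L) + 5000L
        if (all(abs(s0 - starts) > 2L * margin)) starts <- c(starts, s0)
      }
      regions <- data.frame(start = sort(starts),
                            end = sort(starts) + cfg$cnv_region_width - 1L)
    }

    # germline SNPs: two imbalanced ones inside each CNV region, the rest
    # balanced and placed clear of every region
    n_in <- 2L * nrow(regions)
    n_out <- max(0L, cfg$n_germline_snps - n_in)
    gpos <- integer(0); in_cnv <- logical(0)
    if (n_in > 0L) {
      gp <- unlist(lapply(seq_len(nrow(regions)), function(r)
        sample(seq(regions$start[r], regions$end[r]), 2L)))
      gpos <- c(gpos, gp); in_cnv <- c(in_cnv, rep(TRUE, n_in))
    }
    gpos <- c(gpos, .sample_outside(n_out, regions, 5000L, cfg$contig_length))
    in_cnv <- c(in_cnv, rep(FALSE, n_out))
    vaf_n <- stats::runif(length(gpos), 0.45, 0.55)
    displace <- function(n) {
      side <- sample(c(-1, 1), n, replace = TRUE)
      0.5 + side * stats::runif(n, 0.15, 0.35)
    }
    vaf_t1 <- ifelse(in_cnv, displace(length(gpos)),
                     stats::runif(length(gpos), 0.42, 0.58))
    vaf_t2 <- ifelse(in_cnv, displace(length(gpos)),
                     stats::runif(length(gpos), 0.42, 0.58))
    germ <- data.frame(patient_id = pid, chrom = cfg$contig, pos = gpos,
                       vaf_normal = vaf_n, vaf_TU1 = vaf_t1,
                       vaf_TU2 = vaf_t2, stringsAsFactors = FALSE)

    # somatic mutations: n_mutations_per_clone per clone, plus one mutation
    # per planted pathway per exclusive pair
    assign_clone <- rep(seq_len(K), each = cfg$n_mutations_per_clone)
    n_mut <- length(assign_clone)
    genes <- sample(gene_pool, n_mut, replace = TRUE)
    effects <- sample(eff_names, n_mut, replace = TRUE,
                      prob = cfg$effect_weights)
    if (length(cfg$planted_exclusive_pairs)) {
      for (pair in cfg$planted_exclusive_pairs) {
        cls <- sample(seq_len(K), 2L)
        for (j in 1:2) {
          other <- pair[-j]
          g_ok <- setdiff(cfg$pathway_db[[pair[j]]],
                          unlist(cfg$pathway_db[other]))
          if (!length(g_ok))
            stop("planted pathways ", pair[1], "/", pair[2],
                 " share all genes; cannot plant exclusivity")
          assign_clone <- c(assign_clone, cls[j])
          genes <- c(genes, sample(g_ok, 1L))
          effects <- c(effects, "missense")
        }
      }
      n_mut <- length(assign_clone)
    }
    in_cnv_mut <- stats::runif(n_mut) < cfg$p_mut_in_cnv &
      nrow(regions) > 0L
    pos <- integer(n_mut)
    pos[in_cnv_mut] <- vapply(which(in_cnv_mut), function(i) {
      r <- sample.int(nrow(regions), 1L)
      sample(seq(regions$start[r], regions$end[r]), 1L)
    }, 0L)
    pos[!in_cnv_mut] <- .sample_outside(sum(!in_cnv_mut), regions, 5000L,
                                        cfg$contig_length)
    alleles <- t(vapply(effects, .draw_alleles, character(2)))
    key <- paste(cfg$contig, pos, alleles[, 1], alleles[, 2], sep = ":")
    # rare position clashes are nudged until keys are unique
    while (anyDuplicated(key)) {
      dup <- which(duplicated(key))
      pos[dup] <- pos[dup] + 1L
      key <- paste(cfg$contig, pos, alleles[, 1], alleles[, 2], sep = ":")
    }

    evaf <- vapply(1:2, function(s)
      0.5 * vapply(assign_clone, function(c) sum(Fm[desc[[c]], s]), 0),
      numeric(n_mut))
    colnames(evaf) <- c("TU1", "TU2")
    status <- ifelse(evaf[, 1] > 0 & evaf[, 2] > 0, "shared",
                     ifelse(evaf[, 1] > 0, "private_TU1", "private_TU2"))

    rows <- list()
    for (s in c("TU1", "TU2")) {
      ev <- evaf[, s]
      if (cfg$noise == "binomial") {
        alt <- stats::rbinom(n_mut, cfg$depth, ev)
      } else {
        alt <- ifelse(ev > 0, pmax(1L, round(ev * cfg$depth)), 0L)
      }
      keep <- alt > 0L
      if (any(keep)) {
        rows[[s]] <- variant_calls(pid, s, cfg$contig, pos[keep],
                                   alleles[keep, 1], alleles[keep, 2],
                                   alt[keep], cfg$depth, genes[keep],
                                   effects[keep])
      }
    }

    # FFPE artifacts: deamination changes at low VAF, one sample each,
    # placed clear of CNV regions
    artifacts <- list(TU1 = character(0), TU2 = character(0))
    if (cfg$ffpe_artifact_count > 0L) {
      for (s in c("TU1", "TU2")) {
        na <- cfg$ffpe_artifact_count
        apos <- .sample_outside(na, regions, 5000L, cfg$contig_length)
        deam <- sample(1:2, na, replace = TRUE)
        aref <- c("C", "G")[deam]; aalt <- c("T", "A")[deam]
        avaf <- stats::runif(na, cfg$ffpe_vaf_bounds[1],
                             cfg$ffpe_vaf_bounds[2])
        aalt_n <- if (cfg$noise == "binomial")
          pmax(1L, stats::rbinom(na, cfg$depth, avaf)) else
          pmax(1L, round(avaf * cfg$depth))
        acalls <- variant_calls(pid, s, cfg$contig, apos, aref, aalt,
                                aalt_n, cfg$depth,
                                sample(gene_pool, na, replace = TRUE),
                                "missense")
        acalls$true_vaf <- avaf
        artifacts[[s]] <- data.frame(key = variant_key(acalls),
                                     true_vaf = avaf,
                                     stringsAsFactors = FALSE)
        acalls$true_vaf <- NULL
        rows[[paste0(s, "_ffpe")]] <- acalls
      }
    }

    var_df <- do.call(rbind, rows)
    rownames(var_df) <- NULL

    pw_clone <- NULL
    if (!is.null(cfg$pathway_db)) {
      pw_clone <- matrix(0L, length(cfg$pathway_db), K,
                         dimnames = list(names(cfg$pathway_db),
                                         paste0("clone", seq_len(K))))
      for (p in names(cfg$pathway_db)) {
        hit <- assign_clone[genes %in% cfg$pathway_db[[p]]]
        pw_clone[p, unique(hit)] <- 1L
      }
      attr(pw_clone, "patient_id") <- pid
    }

    truth[[pid]] <- list(
      patient_id = pid, K = K, parent = parent,
      fractions = Fm,
      assignment = stats::setNames(paste0("clone", assign_clone), key),
      gene = stats::setNames(genes, key),
      status = stats::setNames(status, key),
      expected_vaf = `rownames<-`(evaf, key),
      artifacts = artifacts,
      cnv_regions = regions,
      mut_in_cnv = stats::setNames(in_cnv_mut, key),
      pathway_clone = pw_clone
    )
    all_var[[pid]] <- var_df
    all_germ[[pid]] <- germ
  }

  variants <- do.call(rbind, all_var)
  rownames(variants) <- NULL
  germline <- do.call(rbind, all_germ)
  rownames(germline) <- NULL
  list(variants = variants, germline = germline, truth = truth,
       config = cfg)
}

#' Simulate UMI read families at one locus
#'
#' Each family derives from a single true molecule whose sequence is drawn
#' uniformly over A,C,G,T; every read copies the molecule with independent
#' per-base substitution errors at `error_rate` (the erroneous base is
#' uniform over the three alternatives). Family sizes are either fixed or
#' geometric with the given mean (shifted to be >= 1). Ground-truth
#' molecule sequences are retained.
#'
#' @param n_families Number of read families.
#' @param read_length Length of each read.
#' @param error_rate Per-base substitution probability in [0, 0.5).
#' @param family_size Fixed family size, or `NULL` for geometric sizes.
#' @param family_size_mean Mean of the geometric size distribution.
#' @param seed Integer seed.
#' @return List with `reads` (data.frame umi, chrom, pos, seq suitable for
#'   [group_reads()]) and `truth` (data.frame umi, pos, molecule).
#' @export
simulate_read_families <- function(n_families, read_length = 10L,
                                   error_rate = 0.01, family_size = NULL,
                                   family_size_mean = 3, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate < 0.5, n_families >= 1)
  withr::with_seed(seed, {
    sizes <- if (is.null(family_size))
      stats::rgeom(n_families, 1 / family_size_mean) + 1L
      else rep(as.integer(family_size), n_families)
    stopifnot(all(sizes >= 1L))
    umis <- vapply(seq_len(n_families), function(i)
      paste(sample(.BASES, 8L, replace = TRUE), collapse = ""), "")
    pos <- sample.int(1e7, n_families)  # distinct positions keep keys unique
    molecules <- vapply(seq_len(n_families), function(i)
      paste(sample(.BASES, read_length, replace = TRUE), collapse = ""), "")
    reads <- lapply(seq_len(n_families), function(i) {
      mol <- strsplit(molecules[i], "", fixed = TRUE)[[1]]
      seqs <- vapply(seq_len(sizes[i]), function(j) {
        err <- stats::runif(read_length) < error_rate
        r <- mol
        if (any(err)) {
          r[err] <- vapply(mol[err], function(b)
            sample(setdiff(.BASES, b), 1L), "")
        }
        paste(r, collapse = "")
      }, "")
      data.frame(umi = umis[i], chrom = "chr1", pos = pos[i], seq = seqs,
                 stringsAsFactors = FALSE)
    })
    list(reads = do.call(rbind, reads),
         truth = data.frame(umi = umis, pos = pos, molecule = molecules,
                            stringsAsFactors = FALSE))
  })
}
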