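# Binomial-mixture clustering of mutations in the 2-D space of paired
# tumour VAFs. Cluster c has centre (theta_c1, theta_c2) and
# alt_s ~ Binomial(depth_s, theta_cs) independently across samples.

.THETA_EPS <- 1e-6

.em_loglik <- function(alt, dep, theta, w) {
  # alt, dep: n x 2; theta: K x 2; w: K
  n <- nrow(alt); K <- nrow(theta)
  ll <- matrix(0, n, K)
  for (k in seq_len(K)) {
    ll[, k] <- log(w[k]) +
      stats::dbinom(alt[, 1], dep[, 1], theta[k, 1], log = TRUE) +
      stats::dbinom(alt[, 2], dep[, 2], theta[k, 2], log = TRUE)
  }
  mx <- apply(ll, 1, max)
  list(ll = sum(mx + log(rowSums(exp(ll - mx)))),
       resp = exp(ll - mx) / rowSums(exp(ll - mx)))
}

# k-means++-style seeding on the VAF pairs
.kmpp_centres <- function(vaf, K) {
  n <- nrow(vaf)
  idx <- sample.int(n, 1L)
  for (k in seq_len(K - 1L)) {
    d2 <- apply(vaf, 1, function(x)
      min(colSums((t(vaf[idx, , drop = FALSE]) - x)^2)))
    if (sum(d2) == 0) idx <- c(idx, sample.int(n, 1L))
    else idx <- c(idx, sample.int(n, 1L, prob = d2))
  }
  vaf[idx, , drop = FALSE]
}

.fit_em_once <- function(alt, dep, K, max_iter = 300L, tol = 1e-8) {
  n <- nrow(alt)
  vaf <- alt / pmax(dep, 1L)
  theta <- pmin(pmax(.kmpp_centres(vaf, K), .THETA_EPS), 1 - .THETA_EPS)
  w <- rep(1 / K, K)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    e <- .em_loglik(alt, dep, theta, w)
    resp <- e$resp
    w <- pmax(colMeans(resp), 1e-12)
    w <- w / sum(w)
    for (k in seq_len(K)) for (s in 1:2) {
      theta[k, s] <- sum(resp[, k] * alt[, s]) / max(sum(resp[, k] * dep[, s]),
                                                     1e-12)
    }
    theta <- pmin(pmax(theta, .THETA_EPS), 1 - .THETA_EPS)
    if (abs(e$ll - ll_old) < tol) break
    ll_old <- e$ll
  }
  e <- .em_loglik(alt, dep, theta, w)
  list(theta = theta, w = w, loglik = e$ll, resp = e$resp)
}

#' Cluster mutations into clones from paired-biopsy VAFs
#'
#' Mutations (pre-filtered to the copy-number-neutral set) are clustered
#' under a two-sample binomial mixture: cluster c has centres
#' (theta_c1, theta_c2) and per-sample alt counts
#' `alt_s ~ Binomial(depth_s, theta_cs)`. The number of clusters K is
#' selected over `k_range` by BIC (ties broken toward smaller K); for each
#' K the best of `n_restarts` k-means++-seeded EM runs by log-likelihood is
#' kept. The cancer cell fraction of cluster c in sample s is
#' `min(1, 2 * theta_cs)` (diploid, copy-number-neutral loci). Reported
#' per-clone fractions map the cluster CCFs to a linear chain ordered by
#' mean CCF (largest = ancestral): the fraction of clone i in sample s is
#' `CCF_i,s - CCF_(i+1),s`, and the normal row is `1 - max CCF`. Pigeonhole
#' violations (negative increments when the per-sample CCF order disagrees
#' with the mean order) are reported in `$chain_violations`, not corrected.
#'
#' @param merged Output of [merge_samples()]: needs columns `alt_TU1`,
#'   `depth_TU1`, `alt_TU2`, `depth_TU2` (0 where the variant is absent).
#' @param k_range Integer range of candidate clone numbers.
#' @param n_restarts EM restarts per K.
#' @param impute_absent_depth A variant absent from one biopsy's call set
#'   has alt = depth = 0 there, but on a deep targeted panel the locus was
#'   still covered, and observing zero alt reads is strong evidence of a
#'   near-zero clone fraction. With `"median"` (default), the absent side's
#'   depth is imputed as the median depth of that sample's present calls
#'   (alt stays 0); `"none"` leaves depth 0, making that dimension
#'   uninformative for private variants.
#' @param seed Integer seed; all randomness (seeding of restarts) flows
#'   from it, so results are deterministic given the seed.
#' @return An object of class `clone_profile`: `patient_id`, `K`,
#'   `centres` (K x 2 theta), `ccf` (K x 2), `fractions` ((K+1) x 2 with
#'   row "N" = normal), `assignment` (named vector, variant key -> clone
#'   id), `fit_score` (log-likelihood), `n_restarts`, `bic` (per-K table),
#'   `chain_violations`.
#' @export
fit_clones <- function(merged, k_range = c(1L, 5L), n_restarts = 20L,
                       impute_absent_depth = c("median", "none"),
                       seed = 1L) {
  impute_absent_depth <- match.arg(impute_absent_depth)
  ks <- seq(min(k_range), max(k_range))
  key <- paste(merged$chrom, merged$pos, merged$ref, merged$alt, sep = ":")
  dep <- cbind(merged$depth_TU1, merged$depth_TU2)
  alt <- cbind(merged$alt_TU1, merged$alt_TU2)
  if (impute_absent_depth == "median") {
    for (s in 1:2) {
      covered <- dep[, s] > 0L
      if (any(covered) && !all(covered))
        dep[!covered, s] <- as.integer(stats::median(dep[covered, s]))
    }
  }
  drop <- dep[, 1] == 0L & dep[, 2] == 0L
  if (any(drop)) {
    warning(sum(drop), " variant(s) with zero depth in both samples excluded")
    alt <- alt[!drop, , drop = FALSE]; dep <- dep[!drop, , drop = FALSE]
    key <- key[!drop]
  }
  n <- nrow(alt)
  if (n < min(ks)) stop("fewer mutations (", n, ") than smallest K (",
                        min(ks), ")")
  ks <- ks[ks <= n]
  withr::with_seed(seed, {
    fits <- list(); bic <- numeric(length(ks))
    for (i in seq_along(ks)) {
      K <- ks[i]
      best <- NULL
      for (r in seq_len(n_restarts)) {
        f <- .fit_em_once(alt, dep, K)
        if (is.null(best) || f$loglik > best$loglik) best <- f
      }
      fits[[i]] <- best
      bic[i] <- -2 * best$loglik + (3 * K - 1) * log(n)
    }
    # ties toward smaller K (ks ascending, strict < keeps the first)
    i_best <- which.min(bic)
    fit <- fits[[i_best]]; K <- ks[i_best]
    ccf <- 2 * fit$theta
    ccf[ccf > 1] <- 1
    ord <- order(rowMeans(ccf), decreasing = TRUE)
    theta <- fit$theta[ord, , drop = FALSE]
    ccf <- ccf[ord, , drop = FALSE]
    clone_ids <- paste0("clone", seq_len(K))
    dimnames(theta) <- dimnames(ccf) <- list(clone_ids, c("TU1", "TU2"))
    fractions <- matrix(0, K + 1L, 2,
                        dimnames = list(c(clone_ids, "N"), c("TU1", "TU2")))
    for (s in 1:2) {
      cc <- c(ccf[, s], 0)
      fractions[seq_len(K), s] <- cc[seq_len(K)] - cc[seq_len(K) + 1L]
      fractions[K + 1L, s] <- 1 - cc[1L]
    }
    violations <- which(fractions[seq_len(K), , drop = FALSE] < 0,
                        arr.ind = TRUE)
    resp <- fit$resp[, ord, drop = FALSE]
    assignment <- stats::setNames(clone_ids[max.col(resp, "first")], key)
    structure(list(
      patient_id = if ("patient_id" %in% names(merged))
        merged$patient_id[1] else NA_character_,
      K = K, centres = theta, ccf = ccf, fractions = fractions,
      assignment = assignment, fit_score = fit$loglik,
      n_restarts = n_restarts,
      bic = data.frame(K = ks, bic = bic),
      chain_violations = violations
    ), class = "clone_profile")
  })
}

#' @exportS3Method base::print
print.clone_profile <- function(x, ...) {
  cat("Clone profile", x$patient_id, "- K =", x$K,
      "(log-likelihood", format(x$fit_score, digits = 6), ")\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Build an entity-by-clone alteration matrix from a clone profile
#'
#' Entry (e, c) is 1 iff some mutation mapped to entity e (gene or, after
#' gene-to-pathway expansion, pathway) is assigned to clone c. Mutations
#' are counted in their assigned clone only (no propagation to descendant
#' clones), matching the representation of deposited clone matrices.
#'
#' @param profile A [fit_clones()] result (or any list with `assignment`
#'   and clone ids as assignment values, plus `patient_id`).
#' @param entity_map data.frame with columns `key` (variant key) and
#'   `entity`; a key may map to several entities (e.g. one gene in several
#'   pathways) and unmapped keys are dropped with a message.
#' @param parent Optional clone-tree parent vector (0 for the root, clone
#'   ids in assignment order `clone1..cloneK`); when given together with
#'   `propagate = TRUE`, a mutation also marks every descendant clone of
#'   its assigned clone, since descendants inherit ancestral mutations.
#' @param propagate Propagate alterations to descendant clones (needs
#'   `parent`); default `FALSE`, matching deposited clone-matrix
#'   representations that record the originating clone only.
#' @return Binary integer matrix (entities x clones) with attribute
#'   `patient_id`, consumable by the clonal-exclusivity test and
#'   round-trippable through [write_clone_matrix()]/[read_clone_matrix()].
#' @export
to_entity_clone_matrix <- function(profile, entity_map, parent = NULL,
                                   propagate = FALSE) {
  stopifnot(all(c("key", "entity") %in% names(entity_map)))
  if (propagate && is.null(parent))
    stop("propagate = TRUE needs a clone-tree parent vector")
  clones <- sort(unique(profile$assignment))
  keys <- names(profile$assignment)
  em <- entity_map[entity_map$key %in% keys, , drop = FALSE]
  n_unmapped <- length(setdiff(keys, entity_map$key))
  if (n_unmapped) message(n_unmapped, " mutation key(s) without entity ",
                          "mapping dropped")
  if (nrow(em) == 0L) {
    warning("empty entity map: returning 0-row matrix")
    m <- matrix(0L, 0L, length(clones),
                dimnames = list(character(0), clones))
    attr(m, "patient_id") <- profile$patient_id
    return(m)
  }
  entities <- sort(unique(em$entity))
  m <- matrix(0L, length(entities), length(clones),
              dimnames = list(entities, clones))
  cl <- profile$assignment[em$key]
  if (propagate) {
    desc <- .clone_descendant_sets(parent)
    for (i in seq_len(nrow(em))) {
      c0 <- as.integer(sub("clone", "", cl[i]))
      hit <- intersect(paste0("clone", desc[[c0]]), clones)
      m[em$entity[i], hit] <- 1L
    }
  } else {
    for (i in seq_len(nrow(em))) m[em$entity[i], cl[i]] <- 1L
  }
  attr(m, "patient_id") <- profile$patient_id
  m
}

#' Compare an inferred clone profile against simulation truth
#'
#' Assignment accuracy is computed under the best bijective matching of
#' inferred clusters to true clones (searched over all permutations of the
#' smaller label set). CCF recovery is the mean absolute error between the
#' inferred CCF matrix and the true cumulative clone fractions (assigned
#' clone plus descendants), which is the topology-free parameter the VAFs
#' identify.
#'
#' @param profile A [fit_clones()] result.
#' @param truth One patient's truth entry from [simulate_cohort()].
#' @return List with `accuracy`, `ccf_mae`, `K_true`, `K_est`.
#' @export
evaluate_clone_recovery <- function(profile, truth) {
  keys <- intersect(names(profile$assignment), names(truth$assignment))
  est <- profile$assignment[keys]
  tru <- truth$assignment[keys]
  est_ids <- sort(unique(est)); tru_ids <- sort(unique(tru))
  # best matching over permutations of the smaller side
  small <- if (length(est_ids) <= length(tru_ids)) est_ids else tru_ids
  large <- if (length(est_ids) <= length(tru_ids)) tru_ids else est_ids
  perms <- .permutations(seq_along(large))
  best_acc <- 0
  for (p in seq_len(nrow(perms))) {
    mapping <- stats::setNames(large[perms[p, seq_along(small)]], small)
    acc <- if (length(est_ids) <= length(tru_ids))
      mean(mapping[est] == tru) else mean(mapping[tru] == est)
    best_acc <- max(best_acc, acc)
  }
  # true cumulative fractions per clone (the quantity 2*VAF estimates)
  desc <- .clone_descendant_sets(truth$parent)
  true_ccf <- t(vapply(seq_len(truth$K), function(c)
    colSums(truth$fractions[desc[[c]], , drop = FALSE]),
    numeric(2)))
  # bijective alignment when K matches, else nearest-clone matching
  if (nrow(profile$ccf) == truth$K) {
    perms2 <- .permutations(seq_len(truth$K))
    mae <- min(vapply(seq_len(nrow(perms2)), function(p)
      mean(abs(profile$ccf - true_ccf[perms2[p, ], , drop = FALSE])), 0))
  } else {
    mae <- mean(vapply(seq_len(nrow(profile$ccf)), function(i) {
      min(rowMeans(abs(sweep(true_ccf, 2, profile$ccf[i, ]))))
    }, 0))
  }
  list(accuracy = best_acc, ccf_mae = mae, K_true = truth$K,
       K_est = profile$K)
}

.permutations <- function(v) {
  if (length(v) <= 1L) return(matrix(v, nrow = 1L))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], .permutations(v[-i])))
  out
}
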