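#' Label a pair of entities within one patient's clone matrix
#'
#' Two entities (genes or pathways) are clonally `exclusive` in a patient
#' when both are altered there but their clone sets are disjoint;
#' `co_occurring` when the clone sets intersect; `not_comparable` when
#' either entity has an empty clone set (or is absent from the matrix).
#'
#' @param matrix Binary entity-by-clone matrix (see [read_clone_matrix()]
#'   or [to_entity_clone_matrix()]).
#' @param a,b Entity ids.
#' @return List with `patient_id`, `entity_a`, `entity_b`, `clones_a`,
#'   `clones_b` (character vectors of clone ids) and `label`.
#' @export
label_pair <- function(matrix, a, b) {
  clones_of <- function(e) {
    if (!e %in% rownames(matrix)) return(character(0))
    colnames(matrix)[matrix[e, ] == 1L]
  }
  ca <- clones_of(a); cb <- clones_of(b)
  label <- if (length(ca) == 0L || length(cb) == 0L) "not_comparable"
    else if (length(intersect(ca, cb)) == 0L) "exclusive"
    else "co_occurring"
  list(patient_id = attr(matrix, "patient_id"), entity_a = a, entity_b = b,
       clones_a = ca, clones_b = cb, label = label)
}

#' Null probability that two entities are clonally exclusive
#'
#' Under the null, each entity's clone set is a uniformly random subset of
#' the patient's K clones of the observed size: conditioning on the two
#' set sizes (mutation burden per entity) and on K (clone count) — the two
#' obvious confounders — the probability of disjoint placement is
#' `P_excl = choose(K - |A|, |B|) / choose(K, |B|)`, symmetric in the two
#' entities, and exactly 0 when `|A| + |B| > K` (pigeonhole).
#'
#' @param K Number of clones in the patient.
#' @param size_a,size_b Observed clone-set sizes of the two entities
#'   (both >= 1).
#' @return The null exclusivity probability.
#' @export
#' @examples
#' pair_null_probability(3, 1, 1)  # 2/3
#' pair_null_probability(3, 2, 2)  # 0
pair_null_probability <- function(K, size_a, size_b) {
  stopifnot(K >= 1, size_a >= 1, size_b >= 1, size_a <= K, size_b <= K)
  choose(K - size_a, size_b) / choose(K, size_b)
}

#' Exact tail of a Poisson-binomial distribution
#'
#' Distribution of `T = sum of independent Bernoulli(p_i)`; the mass
#' function is computed exactly by sequential convolution and the returned
#' value is the upper tail `P(T >= t)`.
#'
#' @param probs Vector of Bernoulli success probabilities.
#' @param t Observed count.
#' @return `P(T >= t)` (1 when `t <= 0`).
#' @export
poisson_binomial_tail <- function(probs, t) {
  stopifnot(all(probs >= 0), all(probs <= 1))
  pmf <- 1
  for (p in probs) pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  if (t <= 0) return(1)
  if (t > length(probs)) return(0)
  sum(pmf[seq.int(t + 1L, length(pmf))])
}

#' Test an entity pair for clonal exclusivity across a cohort
#'
#' For every patient in which both entities are altered (non-empty clone
#' sets), the pair is labelled exclusive or co-occurring; the test
#' statistic T is the number of exclusive patients and its null
#' distribution is the Poisson-binomial sum of per-patient exclusivity
#' probabilities ([pair_null_probability()]), computed exactly by
#' convolution, so p-values are deterministic:
#' `p = P(T >= observed)`. A seeded Monte-Carlo permutation mode exists
#' for cross-checking.
#'
#' @param matrices List of per-patient binary entity-by-clone matrices.
#' @param a,b Entity ids.
#' @param min_patients Minimum number of patients with both entities
#'   altered for the pair to be tested (default 2); pairs below it return
#'   `NULL`.
#' @param n_perm If > 0, also compute a Monte-Carlo p-value from this many
#'   seeded random placements.
#' @param perm_seed Seed for the permutation mode.
#' @return `NULL` if untestable, else a list of class
#'   `exclusivity_result`: `entity_a`, `entity_b`, `n_patients_both`,
#'   `n_exclusive`, `p`, `q` (NA until adjusted across a family),
#'   `per_patient` (data.frame patient_id, size_a, size_b, K, label,
#'   p_excl), and `p_perm` when requested.
#' @export
exclusivity_test <- function(matrices, a, b, min_patients = 2L,
                             n_perm = 0L, perm_seed = 1L) {
  if (min_patients < 1L) stop("min_patients must be >= 1")
  per <- do.call(rbind, lapply(matrices, function(m) {
    o <- label_pair(m, a, b)
    if (o$label == "not_comparable") return(NULL)
    data.frame(patient_id = if (is.null(o$patient_id)) NA_character_
                 else o$patient_id,
               size_a = length(o$clones_a), size_b = length(o$clones_b),
               K = ncol(m), label = o$label,
               p_excl = pair_null_probability(ncol(m), length(o$clones_a),
                                              length(o$clones_b)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per) || nrow(per) < min_patients) return(NULL)
  rownames(per) <- NULL
  t_obs <- sum(per$label == "exclusive")
  p <- poisson_binomial_tail(per$p_excl, t_obs)
  res <- structure(list(entity_a = a, entity_b = b,
                        n_patients_both = nrow(per), n_exclusive = t_obs,
                        p = p, q = NA_real_, per_patient = per),
                   class = "exclusivity_result")
  if (n_perm > 0L) {
    res$p_perm <- withr::with_seed(perm_seed, {
      t_null <- vapply(seq_len(n_perm), function(r)
        sum(stats::runif(nrow(per)) < per$p_excl), 0L)
      mean(t_null >= t_obs)
    })
  }
  res
}

#' @exportS3Method base::print
print.exclusivity_result <- function(x, ...) {
  cat("Pair", x$entity_a, "/", x$entity_b, ": exclusive in",
      x$n_exclusive, "of", x$n_patients_both, "patients, p =",
      format(x$p, digits = 4), "\n")
  invisible(x)
}

#' Test all entity pairs across a cohort of clone matrices
#'
#' All unordered pairs of entities altered together in at least
#' `min_patients` patients are tested with [exclusivity_test()];
#' Benjamini-Hochberg q-values are computed across the tested family only,
#' and results are sorted by p, then lexicographically by entity ids.
#'
#' @inheritParams exclusivity_test
#' @param matrices List of per-patient binary entity-by-clone matrices,
#'   all at the same level (gene or pathway).
#' @return data.frame with one row per tested pair: entity_a, entity_b,
#'   n_patients_both, n_exclusive, p, q. The full per-pair objects are in
#'   attribute `"results"`.
#' @export
test_all_pairs <- function(matrices, min_patients = 2L) {
  entities <- sort(unique(unlist(lapply(matrices, rownames))))
  results <- list()
  if (length(entities) >= 2L) {
    for (i in seq_len(length(entities) - 1L)) {
      for (j in seq.int(i + 1L, length(entities))) {
        r <- exclusivity_test(matrices, entities[i], entities[j],
                              min_patients = min_patients)
        if (!is.null(r)) results[[length(results) + 1L]] <- r
      }
    }
  }
  if (length(results) == 0L)
    return(data.frame(entity_a = character(), entity_b = character(),
                      n_patients_both = integer(), n_exclusive = integer(),
                      p = numeric(), q = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(results, function(r)
    data.frame(entity_a = r$entity_a, entity_b = r$entity_b,
               n_patients_both = r$n_patients_both,
               n_exclusive = r$n_exclusive, p = r$p,
               stringsAsFactors = FALSE)))
  out$q <- stats::p.adjust(out$p, method = "BH")
  ord <- order(out$p, out$entity_a, out$entity_b)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  for (i in seq_along(results)) results[[i]]$q <- out$q[
    out$entity_a == results[[i]]$entity_a &
    out$entity_b == results[[i]]$entity_b]
  attr(out, "results") <- results[ord]
  out
}

#' Simulate clone matrices for exclusivity-test calibration and power
#'
#' Generates a cohort of per-patient clone matrices containing two
#' entities, "A" and "B", whose clone sets have fixed sizes. Under
#' `planted = FALSE` both sets are placed uniformly at random
#' (independently), i.e. the test's null; under `planted = TRUE` the sets
#' are forced disjoint in every patient (an always-exclusive pair).
#'
#' @param n_patients Number of patients.
#' @param K Clones per patient.
#' @param size_a,size_b Clone-set sizes of the two entities.
#' @param planted Force the pair exclusive in every patient.
#' @param seed Integer seed.
#' @return List of binary 2 x K matrices with `patient_id` attributes.
#' @export
simulate_exclusivity_cohort <- function(n_patients, K, size_a = 1L,
                                        size_b = 1L, planted = FALSE,
                                        seed = 1L) {
  stopifnot(size_a + size_b <= K || !planted)
  withr::with_seed(seed, {
    lapply(seq_len(n_patients), function(i) {
      ca <- sample.int(K, size_a)
      cb <- if (planted) {
        free <- setdiff(seq_len(K), ca)
        free[sample.int(length(free), size_b)]
      } else sample.int(K, size_b)
      m <- matrix(0L, 2L, K,
                  dimnames = list(c("A", "B"), paste0("clone", seq_len(K))))
      m["A", ca] <- 1L; m["B", cb] <- 1L
      attr(m, "patient_id") <- sprintf("P%02d", i)
      m
    })
  })
}
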