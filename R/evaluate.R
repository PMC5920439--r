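# External-validity arithmetic: cluster-label matching, success rates,
# per-type rates, general accuracy, Rand index, and the type x cluster
# cross-tabulations an evaluation report is built from.

# all permutations of 1..n, in lexicographic order (n small: used for k <= 6)
permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

as_cluster_codes <- function(x, k = NULL) {
  f <- if (is.factor(x)) x else factor(x)
  codes <- as.integer(f)
  if (!is.null(k) && nlevels(f) > k) {
    stop(sprintf("labels use %d distinct values but k = %d", nlevels(f), k),
         call. = FALSE)
  }
  codes
}

#' Match predicted clusters to reference clusters
#'
#' Finds the bijection between predicted and reference cluster indices that
#' maximizes the total overlap on the k x k contingency matrix, by
#' exhaustive search over the k! permutations (k is small). Ties resolve to
#' the lexicographically first permutation, deterministically.
#'
#' @param predicted,reference Equal-length cluster label vectors (integer,
#'   factor, or character).
#' @param k Number of clusters; defaults to the larger number of distinct
#'   labels on either side.
#' @return Integer vector `m` of length `k`: predicted cluster `i`
#'   corresponds to reference cluster `m[i]`. The achieved overlap is in
#'   attribute `"overlap"`.
#' @examples
#' match_clusters(c(2, 2, 1, 1), c("A", "A", "B", "B"))
#' @export
match_clusters <- function(predicted, reference, k = NULL) {
  if (length(predicted) != length(reference)) {
    stop("'predicted' and 'reference' must have equal length", call. = FALSE)
  }
  p <- as_cluster_codes(predicted)
  r <- as_cluster_codes(reference)
  if (is.null(k)) k <- max(p, r)
  if (max(p) > k || max(r) > k) {
    stop(sprintf("more than k = %d distinct labels", k), call. = FALSE)
  }
  cont <- matrix(0L, k, k)
  for (i in seq_along(p)) cont[p[i], r[i]] <- cont[p[i], r[i]] + 1L
  perms <- permutations(k)
  overlaps <- apply(perms, 1, function(pp) {
    sum(cont[cbind(seq_len(k), pp)])
  })
  best <- perms[which.max(overlaps), ]
  structure(as.integer(best), overlap = max(overlaps))
}

#' Success rate between two subject counts
#'
#' Agreement between a predicted and a reference cluster size, as a
#' percentage: `100 * min(a, b) / max(a, b)`, rounded half-up to two
#' decimals. Symmetric; equals 100 exactly when the counts agree.
#'
#' @param a,b Non-negative subject counts (vectorized).
#' @return Percentage in `[0, 100]`; `NA` where both counts are zero.
#' @examples
#' success_rate(46, 52)   # 88.46
#' success_rate(183, 218) # 83.94
#' @export
success_rate <- function(a, b) {
  if (any(c(a, b) < 0)) stop("counts must be >= 0", call. = FALSE)
  out <- ifelse(pmax(a, b) == 0, NA_real_,
                100 * pmin(a, b) / pmax(a, b))
  round_half_up(out, 2)
}

#' Share of a pathology type within a cluster
#'
#' `100 * type_count / cluster_total`, rounded half-up to two decimals.
#'
#' @param type_count Subjects of the type in the cluster.
#' @param cluster_total Total subjects in the cluster.
#' @return Percentage in `[0, 100]`; `NA` where the cluster is empty.
#' @examples
#' type_rate(49, 52)  # 94.23
#' @export
type_rate <- function(type_count, cluster_total) {
  if (any(type_count < 0) || any(cluster_total < 0)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  if (any(type_count > cluster_total)) {
    stop("'type_count' cannot exceed 'cluster_total'", call. = FALSE)
  }
  out <- ifelse(cluster_total == 0, NA_real_,
                100 * type_count / cluster_total)
  round_half_up(out, 2)
}

#' General accuracy between a real and an algorithmic type rate
#'
#' Agreement between two percentages (typically a real type share and the
#' share an algorithm found): `100 * min / max` of the two-decimal rates,
#' rounded half-up to two decimals. Computed from the already-rounded
#' rates, which is how the comparison tables this mirrors were built.
#'
#' @param rate_real,rate_algo Percentages in `(0, 100]` (vectorized).
#' @return Percentage in `(0, 100]`; `NA` where either rate is zero or
#'   missing (printed as "-" in the canonical tables).
#' @examples
#' general_accuracy(94.23, 91.30)  # 96.89
#' general_accuracy(1.92, 4.35)    # 44.14
#' @export
general_accuracy <- function(rate_real, rate_algo) {
  if (any(stats::na.omit(c(rate_real, rate_algo)) < 0) ||
      any(stats::na.omit(c(rate_real, rate_algo)) > 100)) {
    stop("rates must be percentages in [0, 100]", call. = FALSE)
  }
  ra <- round_half_up(rate_real, 2)
  rb <- round_half_up(rate_algo, 2)
  out <- ifelse(is.na(ra) | is.na(rb) | ra == 0 | rb == 0, NA_real_,
                100 * pmin(ra, rb) / pmax(ra, rb))
  round_half_up(out, 2)
}

#' Rand index between two partitions
#'
#' Fraction of the `n (n - 1) / 2` point pairs on which the two partitions
#' agree — both points together in both, or apart in both. 1 means the
#' partitions are identical up to relabeling; the value is symmetric and
#' invariant under relabeling of either side.
#'
#' @param a,b Equal-length cluster label vectors, `n >= 2` points.
#' @return A number in `[0, 1]`.
#' @examples
#' rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))  # 1/3
#' @export
rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    stop("partitions must have equal length", call. = FALSE)
  }
  n <- length(a)
  if (n < 2) stop("Rand index needs at least 2 points", call. = FALSE)
  tab <- table(a, b)
  same_both <- sum(choose(tab, 2))
  same_a <- sum(choose(rowSums(tab), 2))
  same_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  # agreements = together-in-both + apart-in-both
  (total + 2 * same_both - same_a - same_b) / total
}

#' Cross-tabulate pathology types against clusters
#'
#' @param types Factor (or labels) of pathology types, levels
#'   `TYPE1`/`TYPE2`/`TYPE3`.
#' @param clusters Factor (or labels) of cluster memberships, levels
#'   `C1`/`C2`/`C3`.
#' @return An integer 3 x 3 matrix of class `"crosstab"` (types in rows,
#'   clusters in columns); `print` adds the margin totals.
#' @export
cross_tabulate <- function(types, clusters) {
  if (length(types) != length(clusters)) {
    stop("'types' and 'clusters' must have equal length", call. = FALSE)
  }
  tf <- factor(types, levels = c("TYPE1", "TYPE2", "TYPE3"))
  cf <- factor(clusters, levels = c("C1", "C2", "C3"))
  if (anyNA(tf) || anyNA(cf)) {
    stop("labels must be TYPE1/TYPE2/TYPE3 and C1/C2/C3", call. = FALSE)
  }
  m <- unclass(table(tf, cf))
  dimnames(m) <- list(type = levels(tf), cluster = levels(cf))
  structure(m, class = c("crosstab", "matrix"))
}

#' @export
print.crosstab <- function(x, ...) {
  m <- unclass(x)
  out <- cbind(m, Total = rowSums(m))
  out <- rbind(out, Total = colSums(out))
  print(out, ...)
  invisible(x)
}

crosstab_from_counts <- function(counts) {
  m <- as.matrix(counts)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(type = c("TYPE1", "TYPE2", "TYPE3"),
                      cluster = c("C1", "C2", "C3"))
  structure(m, class = c("crosstab", "matrix"))
}

#' Evaluation report from type-by-cluster count matrices
#'
#' Computes the full comparison arithmetic from a real and an algorithmic
#' 3 x 3 (type x cluster) count matrix: per-cluster success rates between
#' the real and algorithmic cluster sizes, per-cluster type shares on both
#' sides, and the general accuracy between the paired shares.
#'
#' @param real_counts,algo_counts 3 x 3 numeric matrices of counts, types
#'   in rows (Type 1/2/3) and clusters in columns (Cluster 1/2/3).
#' @param rotation Optional rotation name carried into the report.
#' @return A list of class `"rotation_report"` (without a Rand index,
#'   which needs the subject-level partitions).
#' @examples
#' real <- rbind(c(3, 14, 34), c(49, 218, 147), c(0, 17, 2))
#' algo <- rbind(c(2, 10, 39), c(42, 218, 154), c(2, 11, 6))
#' report_from_counts(real, algo)$success_rates  # 88.46 95.98 91.96
#' @export
report_from_counts <- function(real_counts, algo_counts, rotation = NA_character_) {
  real_tab <- crosstab_from_counts(real_counts)
  algo_tab <- crosstab_from_counts(algo_counts)
  real_tot <- colSums(real_tab)
  algo_tot <- colSums(algo_tab)
  succ <- success_rate(real_tot, algo_tot)
  names(succ) <- colnames(real_tab)
  dn <- dimnames(unclass(real_tab))
  rate_real <- matrix(type_rate(as.vector(real_tab), rep(real_tot, each = 3)),
                      nrow = 3, dimnames = dn)
  rate_algo <- matrix(type_rate(as.vector(algo_tab), rep(algo_tot, each = 3)),
                      nrow = 3, dimnames = dn)
  gen_acc <- matrix(general_accuracy(as.vector(rate_real), as.vector(rate_algo)),
                    nrow = 3, dimnames = dn)
  structure(list(rotation = rotation,
                 crosstab_real = real_tab, crosstab_algo = algo_tab,
                 success_rates = succ,
                 type_rates_real = unclass(rate_real),
                 type_rates_algo = unclass(rate_algo),
                 general_accuracy = gen_acc,
                 rand_index = NA_real_,
                 n = sum(real_tab)),
            class = "rotation_report")
}

#' Evaluate a fitted partition against the anthropometric rule
#'
#' Builds the full evaluation report for one rotation: matches the fitted
#' clusters to the rule clusters of [assign_rule_cluster()] by maximum
#' overlap, types the chosen rotation's angles with
#' [classify_rotation_type()], cross-tabulates, and computes success
#' rates, type rates, general accuracies and the Rand index between the
#' fitted partition and the rule partition.
#'
#' @param subjects A subject `data.frame`.
#' @param cluster Integer (or factor) cluster assignment for each subject,
#'   e.g. `fitted(pso_kmeans(...))`.
#' @param rotation Which rotation to type: one of `"rter"`, `"rtir"`,
#'   `"lter"`, `"ltir"`.
#' @return An object of class `"rotation_report"`: the two cross-tabs,
#'   `success_rates` (per cluster), `type_rates_real`, `type_rates_algo`,
#'   `general_accuracy` (3 x 3 matrices), `rand_index`, `mapping`, `n`.
#' @examples
#' coh <- simulate_cohort(cohort_config(separated = TRUE), seed = 1)
#' fit <- pso_kmeans(subject_features(coh$subjects), seed = 1)
#' evaluate_partition(coh$subjects, fitted(fit), "ltir")
#' @export
evaluate_partition <- function(subjects, cluster,
                               rotation = c("rter", "rtir", "lter", "ltir")) {
  rotation <- match.arg(rotation)
  subjects <- validate_subjects(subjects)
  if (length(cluster) != nrow(subjects)) {
    stop("'cluster' must have one label per subject", call. = FALSE)
  }
  rule <- assign_rule_cluster(subjects$age, subjects$weight, subjects$height)
  mapping <- match_clusters(cluster, rule, k = 3)
  pred_codes <- as_cluster_codes(cluster, k = 3)
  matched <- factor(c("C1", "C2", "C3")[mapping[pred_codes]],
                    levels = c("C1", "C2", "C3"))
  types <- classify_rotation_type(subjects[[rotation]])
  rep <- report_from_counts(unclass(cross_tabulate(types, rule)),
                            unclass(cross_tabulate(types, matched)),
                            rotation = rotation)
  rep$rand_index <- rand_index(pred_codes, as.integer(rule))
  rep$mapping <- mapping
  rep$agreement <- mean(as.character(matched) == as.character(rule))
  rep
}

#' @export
print.rotation_report <- function(x, ...) {
  if (!is.na(x$rotation)) {
    cat(sprintf("Evaluation report, rotation %s (n = %d)\n",
                toupper(x$rotation), x$n))
  } else {
    cat(sprintf("Evaluation report (n = %d)\n", x$n))
  }
  cat("\nReal type x cluster counts:\n"); print(x$crosstab_real)
  cat("\nAlgorithm type x cluster counts:\n"); print(x$crosstab_algo)
  cat("\nPer-cluster success rates (%):\n"); print(x$success_rates)
  cat("\nGeneral accuracy (%), type x cluster:\n")
  print(x$general_accuracy)
  if (!is.na(x$rand_index)) {
    cat(sprintf("\nRand index vs rule clusters: %.4f\n", x$rand_index))
  }
  invisible(x)
}
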