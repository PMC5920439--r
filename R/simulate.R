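#' Configuration for the synthetic cohort generator
#'
#' Describes a three-group cohort whose physical characteristics respect the
#' anthropometric rule of [assign_rule_cluster()] by construction (group 1
#' all above 30 years; groups 2 and 3 at most 30 years, split at 60 kg), and
#' whose four tibial rotation angles are drawn from configurable pathology
#' type proportions. Defaults emulate the 484-subject reference cohort:
#' group sizes 52/249/183 and per-rotation type proportions matching the
#' published type counts.
#'
#' @param n_total Total number of subjects (default 484).
#' @param group_sizes Integer vector of three group sizes summing to
#'   `n_total` (default `c(52, 249, 183)`).
#' @param age_ranges,weight_ranges,height_ranges Lists of three `c(low, high)`
#'   ranges (years / kg / m), one per group. Age ranges may not straddle the
#'   30-year rule boundary, and group 2/3 weight ranges may not cross 60 kg.
#' @param type_props Named list with one length-3 probability vector per
#'   rotation (`rter`, `rtir`, `lter`, `ltir`) giving the Type 1/2/3
#'   proportions; each must sum to 1.
#' @param noise_sd Standard deviation (degrees) of truncated Gaussian jitter
#'   added to the angles, kept inside each type's interval (default 1).
#' @param separated If `TRUE`, use widely separated physical ranges (clear
#'   gaps at the 30-year and 60-kg thresholds) so that the three groups form
#'   well-separated clusters in feature space; used for recovery experiments.
#' @return An object of class `"cohort_config"`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_total = 484L,
                          group_sizes = c(52L, 249L, 183L),
                          age_ranges = NULL,
                          weight_ranges = NULL,
                          height_ranges = NULL,
                          type_props = NULL,
                          noise_sd = 1,
                          separated = FALSE) {
  if (is.null(age_ranges)) {
    age_ranges <- if (separated) {
      list(c(45, 60), c(18, 26), c(18, 26))
    } else {
      list(c(31, 60), c(18, 30), c(18, 30))
    }
  }
  if (is.null(weight_ranges)) {
    weight_ranges <- if (separated) {
      list(c(58, 72), c(45, 54), c(74, 92))
    } else {
      list(c(45, 95), c(45, 60), c(60, 95))
    }
  }
  if (is.null(height_ranges)) {
    height_ranges <- if (separated) {
      list(c(1.60, 1.80), c(1.52, 1.66), c(1.74, 1.90))
    } else {
      list(c(1.50, 1.90), c(1.50, 1.70), c(1.70, 1.90))
    }
  }
  if (is.null(type_props)) {
    # per-rotation Type 1/2/3 proportions of the 484-subject reference cohort
    type_props <- list(
      rter = c(39, 391, 54) / 484,
      rtir = c(33, 423, 28) / 484,
      lter = c(37, 357, 90) / 484,
      ltir = c(51, 414, 19) / 484
    )
  }
  cfg <- list(n_total = as.integer(n_total),
              group_sizes = as.integer(group_sizes),
              age_ranges = age_ranges,
              weight_ranges = weight_ranges,
              height_ranges = height_ranges,
              type_props = type_props,
              noise_sd = noise_sd,
              separated = isTRUE(separated))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (length(cfg$group_sizes) != 3L || any(cfg$group_sizes < 0)) {
    stop("'group_sizes' must be three non-negative counts", call. = FALSE)
  }
  if (sum(cfg$group_sizes) != cfg$n_total) {
    stop("'group_sizes' must sum to 'n_total'", call. = FALSE)
  }
  for (nm in c("age_ranges", "weight_ranges", "height_ranges")) {
    rs <- cfg[[nm]]
    if (!is.list(rs) || length(rs) != 3L ||
        any(vapply(rs, function(r) length(r) != 2L || r[1] >= r[2], TRUE))) {
      stop(sprintf("'%s' must be three (low, high) ranges with low < high", nm),
           call. = FALSE)
    }
  }
  # the rule must recover the generating group: no range may straddle a
  # rule threshold on the wrong side
  if (cfg$age_ranges[[1]][1] <= 30) {
    stop("group 1 age range must lie strictly above 30 years", call. = FALSE)
  }
  if (cfg$age_ranges[[2]][2] > 30 || cfg$age_ranges[[3]][2] > 30) {
    stop("group 2/3 age ranges must lie at or below 30 years", call. = FALSE)
  }
  if (cfg$weight_ranges[[2]][2] > 60) {
    stop("group 2 weight range must lie at or below 60 kg", call. = FALSE)
  }
  if (cfg$weight_ranges[[3]][1] < 60) {
    stop("group 3 weight range must lie above 60 kg", call. = FALSE)
  }
  if (!is.list(cfg$type_props) ||
      !setequal(names(cfg$type_props), c("rter", "rtir", "lter", "ltir"))) {
    stop("'type_props' must name rter, rtir, lter, ltir", call. = FALSE)
  }
  for (nm in names(cfg$type_props)) {
    p <- cfg$type_props[[nm]]
    if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop(sprintf("type proportions for '%s' must be three non-negative values summing to 1",
                   nm), call. = FALSE)
    }
  }
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd < 0) {
    stop("'noise_sd' must be a non-negative number of degrees", call. = FALSE)
  }
  invisible(cfg)
}

# Type intervals used by the generator.  Angles for each type are drawn
# uniformly inside these, then jittered without leaving the interval, so the
# generated type label always agrees with classify_rotation_type().
type_intervals <- list(TYPE1 = c(5, 20), TYPE2 = c(20, 65), TYPE3 = c(65, 90))

draw_angles <- function(types, noise_sd) {
  n <- length(types)
  ang <- numeric(n)
  for (tp in names(type_intervals)) {
    idx <- which(types == tp)
    if (!length(idx)) next
    iv <- type_intervals[[tp]]
    a <- stats::runif(length(idx), iv[1], iv[2])
    if (noise_sd > 0) {
      a <- a + stats::rnorm(length(idx), 0, noise_sd)
      # reflect jitter back into the half-open interval; epsilon keeps the
      # open lower end of (20, 65] and (65, 90] out of the lower type
      eps <- 1e-6
      a <- pmin(pmax(a, iv[1] + if (tp == "TYPE1") 0 else eps), iv[2])
    }
    ang[idx] <- a
  }
  ang
}

#' Generate a seeded synthetic cohort
#'
#' Draws `n_total` subjects in three groups whose (age, weight, height) lie
#' inside the configured per-group ranges — so the anthropometric rule of
#' [assign_rule_cluster()] recovers the generating group exactly — and whose
#' four rotation angles are sampled per rotation from the configured Type
#' 1/2/3 proportions: Type 1 angles uniform in \[5, 20\], Type 2 in
#' (20, 65\], Type 3 in (65, 90\], with truncated jitter. Row order is
#' shuffled so that group membership is not encoded in the ordering.
#'
#' @param config A [cohort_config()] object.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A list of class `"cohort"` with elements `subjects` (the subject
#'   `data.frame`), `group` (factor `C1`/`C2`/`C3` of generating groups) and
#'   `types` (`data.frame` of generating pathology type factors, one column
#'   per rotation).
#' @examples
#' coh <- simulate_cohort(cohort_config(), seed = 1)
#' table(coh$group)
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  validate_cohort_config(config)
  with_seed(seed, {
    sizes <- config$group_sizes
    n <- config$n_total
    group <- rep(c("C1", "C2", "C3"), times = sizes)
    age <- weight <- height <- numeric(n)
    for (g in 1:3) {
      idx <- which(group == c("C1", "C2", "C3")[g])
      age[idx] <- stats::runif(sizes[g], config$age_ranges[[g]][1],
                               config$age_ranges[[g]][2])
      weight[idx] <- stats::runif(sizes[g], config$weight_ranges[[g]][1],
                                  config$weight_ranges[[g]][2])
      height[idx] <- stats::runif(sizes[g], config$height_ranges[[g]][1],
                                  config$height_ranges[[g]][2])
    }
    types <- list()
    angles <- list()
    for (rot in c("rter", "rtir", "lter", "ltir")) {
      p <- config$type_props[[rot]]
      tp <- sample(c("TYPE1", "TYPE2", "TYPE3"), n, replace = TRUE, prob = p)
      types[[rot]] <- factor(tp, levels = c("TYPE1", "TYPE2", "TYPE3"))
      angles[[rot]] <- draw_angles(tp, config$noise_sd)
    }
    ord <- sample.int(n)
    subjects <- data.frame(
      id = sprintf("S%04d", seq_len(n)),
      age = age[ord], weight = weight[ord], height = height[ord],
      rter = angles$rter[ord], rtir = angles$rtir[ord],
      lter = angles$lter[ord], ltir = angles$ltir[ord],
      stringsAsFactors = FALSE
    )
    subjects <- validate_subjects(subjects, where = "simulated cohort")
    group <- factor(group[ord], levels = c("C1", "C2", "C3"))
    stopifnot(identical(as.character(group),
                        as.character(assign_rule_cluster(
                          subjects$age, subjects$weight, subjects$height))))
    types <- data.frame(lapply(types, function(tp) tp[ord]))
    structure(list(subjects = subjects, group = group, types = types,
                   config = config),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects in groups %s\n",
              nrow(x$subjects),
              paste(table(x$group), collapse = "/")))
  invisible(x)
}

#' Generate an isotropic Gaussian mixture
#'
#' Benchmark generator for clustering-recovery experiments: `sizes[i]`
#' points are drawn from an isotropic Gaussian at `means[i, ]` with
#' spread `sds[i]`.
#'
#' @param means Numeric matrix, one component mean per row.
#' @param sds Positive per-component standard deviations (recycled).
#' @param sizes Per-component point counts (recycled).
#' @param seed Integer seed for reproducibility.
#' @return A list with `points` (numeric matrix) and `labels` (integer
#'   component of each point).
#' @examples
#' mix <- simulate_mixture(rbind(c(0, 0), c(10, 10)), sds = 1,
#'                         sizes = 50, seed = 1)
#' @export
simulate_mixture <- function(means, sds, sizes, seed = NULL) {
  means <- as.matrix(means)
  k <- nrow(means)
  sds <- rep_len(sds, k)
  sizes <- rep_len(as.integer(sizes), k)
  if (any(sds <= 0)) stop("'sds' must be strictly positive", call. = FALSE)
  if (any(sizes < 1)) stop("'sizes' must be positive counts", call. = FALSE)
  with_seed(seed, {
    pts <- do.call(rbind, lapply(seq_len(k), function(i) {
      sweep(matrix(stats::rnorm(sizes[i] * ncol(means), sd = sds[i]),
                   ncol = ncol(means)),
            2, means[i, ], `+`)
    }))
    list(points = pts, labels = rep(seq_len(k), times = sizes))
  })
}
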