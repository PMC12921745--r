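#' Gamma profile functions
#'
#' A gamma profile gives the probability that a false identification
#' (an incorrect target or a decoy) carries the modification, as a function
#' of its score quantile q in \[0,1\] within the merged set. Supported
#' families: `constant` (`value`), `logistic` (`lo`, `hi`, `midpoint`,
#' `slope`), and `piecewise` (`x`, `y` linearly interpolated, constant
#' beyond the ends).
#'
#' @param profile list with a `type` element and the family's parameters.
#' @return `function(q)` returning modification probabilities.
#' @export
gamma_profile_fun <- function(profile) {
  type <- match.arg(profile$type, c("constant", "logistic", "piecewise"))
  switch(type,
    constant = {
      v <- profile$value
      stopifnot(v >= 0, v <= 1)
      function(q) rep(v, length(q))
    },
    logistic = {
      lo <- profile$lo; hi <- profile$hi
      mid <- if (is.null(profile$midpoint)) 0.5 else profile$midpoint
      k <- if (is.null(profile$slope)) 6 else profile$slope
      stopifnot(lo >= 0, hi <= 1, lo <= hi)
      function(q) lo + (hi - lo) * stats::plogis(k * (q - mid))
    },
    piecewise = {
      x <- profile$x; y <- profile$y
      stopifnot(length(x) == length(y), all(y >= 0), all(y <= 1))
      function(q) stats::approx(x, y, xout = q, rule = 2)$y
    })
}

.rgumbel <- function(n, location, scale) {
  location - scale * log(-log(stats::runif(n)))
}

#' Simulation configuration
#'
#' Defines a merged modified/unmodified PSM population with known ground
#' truth. Targets split into correct matches (scores from a right-shifted
#' distribution) and incorrect matches; decoys are generated in equal
#' number to the incorrect targets and share their null score distribution
#' (the equal-chance null of the target-decoy method). Modified membership
#' of correct targets is Bernoulli(`frac_modified_targets`); membership of
#' false matches follows `gamma_profile` evaluated at the PSM's score
#' quantile. Score families are Gumbel (right-skewed, hyperscore-like);
#' their exact shape is irrelevant to the rank-based statistics.
#'
#' @param n_total total number of PSMs (targets + decoys).
#' @param frac_modified_targets fraction of correct targets carrying the PTM.
#' @param frac_incorrect_targets incorrect fraction among targets (pi0).
#' @param gamma_profile see [gamma_profile_fun()].
#' @param score_null list(location, scale) for incorrect matches and decoys.
#' @param score_correct list(location, scale) for correct targets; its
#'   location must exceed the null's.
#' @param seed integer seed.
#' @param ptm list(name, residue, mass_delta) used to synthesize
#'   modification annotations.
#' @param file_name spectrum file name written into the records.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(n_total = 20000L,
                              frac_modified_targets = 0.1,
                              frac_incorrect_targets = 0.3,
                              gamma_profile = list(type = "logistic",
                                                   lo = 0.15, hi = 0.35,
                                                   midpoint = 0.5, slope = 6),
                              score_null = list(location = 15, scale = 3),
                              score_correct = list(location = 30, scale = 5),
                              seed = 1L,
                              ptm = list(name = "phospho", residue = "S",
                                         mass_delta = 79.966331),
                              file_name = "sim01.mgf") {
  stopifnot(n_total >= 10L,
            frac_modified_targets >= 0, frac_modified_targets <= 1,
            frac_incorrect_targets >= 0, frac_incorrect_targets <= 1)
  if (score_correct$location <= score_null$location) {
    stop("correct-match scores must be right-shifted relative to the null",
         call. = FALSE)
  }
  if (frac_modified_targets == 0 && gamma_profile$type != "constant") {
    stop("frac_modified_targets = 0 is infeasible with a non-constant ",
         "gamma profile", call. = FALSE)
  }
  gamma_profile_fun(gamma_profile)  # validate parameters early
  structure(list(n_total = as.integer(n_total),
                 frac_modified_targets = frac_modified_targets,
                 frac_incorrect_targets = frac_incorrect_targets,
                 gamma_profile = gamma_profile,
                 score_null = score_null, score_correct = score_correct,
                 seed = seed, ptm = ptm, file_name = file_name),
            class = "sim_config")
}

.random_peptides <- function(n, min_len = 8L, max_len = 20L) {
  aa <- c("A","D","E","F","G","H","I","L","N","P","Q","S","T","V","W","Y")
  lens <- sample(min_len:max_len, n, replace = TRUE)
  vapply(lens, function(L) {
    paste(c(sample(aa, L - 1L, replace = TRUE), sample(c("K", "R"), 1L)),
          collapse = "")
  }, "")
}

#' Simulate a merged PSM population with ground truth
#'
#' Generates targets and decoys per the configuration, with a hidden
#' `is_correct` column (decoys and incorrect targets are `FALSE`). The
#' records satisfy the canonical PSM layout, so they feed directly into
#' [rank_psms()]; estimators never see `is_correct`.
#'
#' @param config a [simulation_config()].
#' @return data.table of canonical PSM records plus `is_correct`.
#' @export
simulate_psm_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    f <- config$frac_incorrect_targets
    n_targets <- as.integer(round(config$n_total / (1 + f)))
    n_decoys <- config$n_total - n_targets
    n_incorrect <- n_decoys   # equal-chance null: one decoy per false target
    n_correct <- n_targets - n_incorrect
    if (n_correct < 0L) stop("infeasible fractions", call. = FALSE)

    score_correct <- .rgumbel(n_correct, config$score_correct$location,
                              config$score_correct$scale)
    score_null <- .rgumbel(n_incorrect + n_decoys,
                           config$score_null$location,
                           config$score_null$scale)
    is_decoy <- c(rep(FALSE, n_correct),                  # correct targets
                  rep(FALSE, n_incorrect),                # incorrect targets
                  rep(TRUE, n_decoys))
    is_correct <- c(rep(TRUE, n_correct), rep(FALSE, n_incorrect + n_decoys))
    score <- c(score_correct, score_null)

    qtl <- (rank(score, ties.method = "first") - 0.5) / length(score)
    gfun <- gamma_profile_fun(config$gamma_profile)
    is_modified <- logical(length(score))
    if (n_correct > 0L) {
      is_modified[seq_len(n_correct)] <-
        stats::runif(n_correct) < config$frac_modified_targets
    }
    null_idx <- seq(n_correct + 1L, length.out = n_incorrect + n_decoys)
    is_modified[null_idx] <- stats::runif(length(null_idx)) < gfun(qtl[null_idx])

    n <- length(score)
    peptide <- .random_peptides(n)
    modifications <- character(n)
    mod_idx <- which(is_modified)
    if (length(mod_idx)) {
      pos <- vapply(nchar(peptide[mod_idx]), function(L) {
        sample.int(max(L - 1L, 1L), 1L)
      }, 0L)
      pep <- peptide[mod_idx]
      substr(pep, pos, pos) <- config$ptm$residue
      peptide[mod_idx] <- pep
      delta <- format(config$ptm$mass_delta, trim = TRUE,
                      scientific = FALSE, digits = 10)
      modifications[mod_idx] <- sprintf("%s%d[%s+%s]", config$ptm$residue,
                                        pos, config$ptm$name, delta)
    }
    prot <- sprintf("SIMP%05d", seq_len(n))
    out <- data.table::data.table(
      file = config$file_name, scan = seq_len(n),
      charge = sample(2:4, n, replace = TRUE, prob = c(0.5, 0.35, 0.15)),
      peptide = peptide, modifications = modifications,
      score = score, is_decoy = is_decoy, is_modified = is_modified,
      proteins = ifelse(is_decoy, paste0("DECOY_", prot), prot),
      is_correct = is_correct)
    out
  })
}

#' Empirical false discovery proportion
#'
#' The calibration metric: proportion of accepted PSMs whose hidden ground
#' truth is incorrect. An empty acceptance yields 0 with attribute
#' `empty = TRUE`.
#'
#' @param accepted data.frame of accepted records with an `is_correct`
#'   column.
#' @return the proportion, with attributes `n` and `empty`.
#' @export
empirical_fdp <- function(accepted) {
  n <- nrow(accepted)
  if (n == 0L) {
    return(structure(0, n = 0L, empty = TRUE))
  }
  structure(sum(!accepted$is_correct) / n, n = n, empty = FALSE)
}

#' Simulate gamma-curve observations with known truth
#'
#' Generates binomially noised gamma observations on a threshold grid —
#' `D_k(r) ~ Binomial(D(r), gamma_true(r))` — for spline-recovery and
#' error-propagation tests where the true curve is known exactly.
#'
#' @param profile gamma profile (see [gamma_profile_fun()]), evaluated at
#'   the normalized grid position.
#' @param n_thresholds number of grid points.
#' @param decoy_counts positive, non-increasing vector of total decoy
#'   counts D(r), length `n_thresholds`.
#' @param seed integer seed.
#' @param thresholds optional explicit grid (default `1:n_thresholds`).
#' @param sigma_cutoff stability cutoff for the mask.
#' @return a `gamma_curve` data.table with an extra `gamma_true` column.
#' @export
simulate_gamma_observations <- function(profile, n_thresholds, decoy_counts,
                                        seed = NULL, thresholds = NULL,
                                        sigma_cutoff = 0.01) {
  stopifnot(length(decoy_counts) == n_thresholds, all(decoy_counts > 0),
            !is.unsorted(rev(decoy_counts)))
  if (is.null(thresholds)) thresholds <- seq_len(n_thresholds)
  qn <- (thresholds - min(thresholds)) /
    max(max(thresholds) - min(thresholds), 1)
  gtrue <- gamma_profile_fun(profile)(qn)
  .with_seed(seed, {
    D <- as.integer(round(decoy_counts))
    D_k <- stats::rbinom(n_thresholds, D, gtrue)
    sigma <- error_propagation(D_k, D)
    out <- data.table::data.table(
      threshold = thresholds, D = D, D_k = D_k,
      gamma_hat = ifelse(D > 0L, D_k / D, NA_real_),
      sigma = sigma,
      stable = !is.na(sigma) & sigma <= sigma_cutoff & D > 0L,
      gamma_true = gtrue)
    data.table::setattr(out, "sigma_cutoff", sigma_cutoff)
    data.table::setattr(out, "class", c("gamma_curve", class(out)))
    out
  })
}
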