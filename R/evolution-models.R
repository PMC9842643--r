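#' Classify genes and normalize fitness for outcome models
#'
#' Splits genes into putatively neutral (|s| below `neutral_band` AND not
#' called significantly non-neutral; both conditions are required),
#' significantly beneficial, and significantly deleterious; other genes are
#' excluded. Fitness is normalized by the median of the relevant non-neutral
#' class, `s_tilde = s / med(s_non-neutral)`, so regression slopes read as
#' the difference between a neutral knockout and the "typical" beneficial
#' (or deleterious) one.
#'
#' @param s fitness estimates.
#' @param significant logical significance calls (q <= alpha).
#' @param neutral_band half-width of the neutral band (1/generation).
#' @return data.frame with `s`, `class` (factor: neutral / beneficial /
#'   deleterious / excluded), `s_tilde_plus` (normalized by the beneficial
#'   median), `s_tilde_minus` (normalized by the deleterious median).
#' @export
classify_and_normalize <- function(s, significant, neutral_band = 0.005) {
  stopifnot(length(s) == length(significant))
  class <- rep("excluded", length(s))
  class[abs(s) < neutral_band & !significant] <- "neutral"
  class[significant & s > 0] <- "beneficial"
  class[significant & s < 0] <- "deleterious"
  med_plus <- stats::median(s[class == "beneficial"])
  med_minus <- stats::median(s[class == "deleterious"])
  data.frame(s = s,
             class = factor(class, levels = c("neutral", "beneficial",
                                              "deleterious", "excluded")),
             s_tilde_plus = s / med_plus,
             s_tilde_minus = s / med_minus)
}

# Shared scaffolding: model frame for one sign class pooled with neutrals.
outcome_frame <- function(cls, sign = c("beneficial", "deleterious")) {
  sign <- match.arg(sign)
  tilde <- if (sign == "beneficial") cls$s_tilde_plus else cls$s_tilde_minus
  use <- cls$class %in% c("neutral", sign)
  if (!any(cls$class == sign) || !any(cls$class == "neutral")) return(NULL)
  data.frame(idx = which(use), s_tilde = tilde[use])
}

#' Logistic model of mutation establishment
#'
#' Fits `logit P(mutated) = s_tilde * beta_est + beta_0` separately for the
#' beneficial and the deleterious class, each pooled with the neutral class
#' (neutral genes enter with their own small normalized values). A positive
#' `beta_est` for the beneficial class means genes whose knockout is
#' beneficial are more likely to acquire a mutation. Wald standard errors
#' and p-values come from the ML fit; p-values of both classes are pooled
#' for a BH-FDR correction.
#'
#' @param cls output of [classify_and_normalize()].
#' @param mutated 0/1 (or logical) mutated-status flags, aligned with `cls`.
#' @return data.frame of class `regression_result`, one row per fitted
#'   class: `class`, `beta`, `se`, `p`, `q`, `beta0`, `n`, `n_events`,
#'   `separation` (TRUE when the fit is degenerate).
#' @export
establishment_logit <- function(cls, mutated) {
  mutated <- as.integer(mutated)
  stopifnot(all(mutated %in% c(0L, 1L)), length(mutated) == nrow(cls))
  rows <- lapply(c("beneficial", "deleterious"), function(sgn) {
    fr <- outcome_frame(cls, sgn)
    if (is.null(fr)) return(NULL)
    y <- mutated[fr$idx]
    if (length(unique(y)) < 2) {
      return(data.frame(class = sgn, beta = NA_real_, se = NA_real_,
                        p = NA_real_, beta0 = NA_real_, n = length(y),
                        n_events = sum(y), separation = TRUE))
    }
    fit <- suppressWarnings(stats::glm(y ~ fr$s_tilde,
                                       family = stats::binomial()))
    cf <- summary(fit)$coefficients
    sep <- !fit$converged || any(abs(cf[, "Estimate"]) > 15)
    data.frame(class = sgn, beta = cf[2, 1], se = cf[2, 2], p = cf[2, 4],
               beta0 = cf[1, 1], n = length(y), n_events = sum(y),
               separation = sep)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no fittable class (need neutral plus a non-neutral class)")
  res$q <- stats::p.adjust(res$p, method = "BH")
  structure(res[, c("class", "beta", "se", "p", "q", "beta0", "n",
                    "n_events", "separation")],
            class = c("regression_result", "data.frame"))
}

#' Permutation test for a slope difference between two intervals
#'
#' Tests whether the establishment-model slope differs between two time
#' intervals by shuffling, per gene, which interval its mutated flag belongs
#' to, refitting both models, and recording the slope difference. The
#' two-sided p-value uses the plus-one estimator.
#'
#' @param cls output of [classify_and_normalize()] (shared gene set).
#' @param mutated_a,mutated_b mutated flags in the two intervals.
#' @param class which fitness class's slope to compare.
#' @param n_perm number of permutations (must be positive).
#' @param seed RNG seed.
#' @return list with `observed` (slope difference a - b), `p`, `null`
#'   (the permuted differences).
#' @export
slope_permutation_test <- function(cls, mutated_a, mutated_b,
                                   class = "beneficial", n_perm = 1000,
                                   seed = 1) {
  if (n_perm < 1) stop("n_perm must be positive")
  mutated_a <- as.integer(mutated_a); mutated_b <- as.integer(mutated_b)
  stopifnot(length(mutated_a) == nrow(cls),
            length(mutated_b) == nrow(cls))
  slope <- function(flags) {
    res <- establishment_logit(cls, flags)
    res$beta[res$class == class]
  }
  obs <- slope(mutated_a) - slope(mutated_b)
  null <- with_seed(seed, function() {
    vapply(seq_len(n_perm), function(b) {
      swap <- stats::runif(length(mutated_a)) < 0.5
      fa <- ifelse(swap, mutated_b, mutated_a)
      fb <- ifelse(swap, mutated_a, mutated_b)
      slope(fa) - slope(fb)
    }, 0)
  })
  ok <- is.finite(null)
  p <- (sum(abs(null[ok]) >= abs(obs)) + 1) / (sum(ok) + 1)
  list(observed = obs, p = p, null = null)
}

#' Weighted-least-squares model of expression change
#'
#' Fits `delta_E = s_tilde * beta_exp + beta_0` separately for beneficial
#' and deleterious classes (each pooled with neutrals) by weighted least
#' squares with weights proportional to `1/var(delta_E)`, and pools the
#' p-values for a BH-FDR correction.
#'
#' @param cls output of [classify_and_normalize()].
#' @param delta_e per-gene expression log-fold changes.
#' @param var_delta_e per-gene variances of `delta_e` (must be positive
#'   where `delta_e` is present).
#' @return a `regression_result` data.frame (`class`, `beta`, `se`, `p`,
#'   `q`, `beta0`, `n`).
#' @export
expression_wls <- function(cls, delta_e, var_delta_e) {
  stopifnot(length(delta_e) == nrow(cls),
            length(var_delta_e) == nrow(cls))
  if (any(!is.na(delta_e) & (is.na(var_delta_e) | var_delta_e <= 0))) {
    stop("variances must be positive wherever delta_e is present")
  }
  rows <- lapply(c("beneficial", "deleterious"), function(sgn) {
    fr <- outcome_frame(cls, sgn)
    if (is.null(fr)) return(NULL)
    y <- delta_e[fr$idx]
    w <- 1 / var_delta_e[fr$idx]
    ok <- is.finite(y) & is.finite(w)
    if (sum(ok) < 3) return(NULL)
    fit <- stats::lm(y[ok] ~ fr$s_tilde[ok], weights = w[ok])
    cf <- summary(fit)$coefficients
    data.frame(class = sgn, beta = cf[2, 1], se = cf[2, 2], p = cf[2, 4],
               beta0 = cf[1, 1], n = sum(ok))
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no fittable class")
  res$q <- stats::p.adjust(res$p, method = "BH")
  structure(res[, c("class", "beta", "se", "p", "q", "beta0", "n")],
            class = c("regression_result", "data.frame"))
}

#' Rank comparison of expression change across fitness classes
#'
#' Splits the chosen non-neutral class at its median fitness magnitude into
#' "lower 50%" and "upper 50%" halves (sizes differing by at most one),
#' then runs Mann-Whitney U tests of `delta_e` between every pair of groups
#' (neutral, lower, upper) with a BH-FDR correction across pairs.
#'
#' @param cls output of [classify_and_normalize()].
#' @param delta_e per-gene expression log-fold changes.
#' @param class non-neutral class to split.
#' @return data.frame with one row per group pair: `group_a`, `group_b`,
#'   `n_a`, `n_b`, `statistic`, `p`, `q`.
#' @export
rank_compare <- function(cls, delta_e, class = "beneficial") {
  stopifnot(length(delta_e) == nrow(cls))
  groups <- list(neutral = which(cls$class == "neutral" & !is.na(delta_e)))
  sel <- which(cls$class == class & !is.na(delta_e))
  if (length(sel) >= 2) {
    o <- sel[order(abs(cls$s[sel]))]
    half <- floor(length(o) / 2)
    groups$lower50 <- o[seq_len(half)]
    groups$upper50 <- o[(half + 1):length(o)]
  }
  groups <- groups[vapply(groups, length, 0L) >= 2]
  if (length(groups) < 2) stop("need at least two groups with >= 2 members")
  pairs <- utils::combn(names(groups), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    wt <- stats::wilcox.test(delta_e[groups[[a]]], delta_e[groups[[b]]],
                             exact = FALSE)
    data.frame(group_a = a, group_b = b, n_a = length(groups[[a]]),
               n_b = length(groups[[b]]), statistic = unname(wt$statistic),
               p = wt$p.value)
  })
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}
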