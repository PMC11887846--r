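# Construction of matched high- versus low-PRS extreme donor groups:
# extreme-pool selection, propensity estimation, and greedy 1:1
# nearest-neighbor matching with exact sex.

#' Select the extreme polygenic-risk candidate pools
#'
#' Returns the `n_extreme` donors with the highest and the lowest PRS for a
#' trait. Ties spanning the pool boundary are broken by ascending
#' `donor_id`, which makes the selection deterministic.
#'
#' @param cohort Cohort tibble including a `prs_<trait>` column.
#' @param trait Trait name.
#' @param n_extreme Pool size per tail (default 20).
#' @return The cohort restricted to the candidates, with a `pool` column
#'   (`"high"` / `"low"`).
#' @export
select_extreme_candidates <- function(cohort, trait, n_extreme = 20) {
  col <- paste0("prs_", trait)
  if (!col %in% names(cohort)) {
    stop("cohort lacks PRS column '", col, "'", call. = FALSE)
  }
  if (nrow(cohort) < 2 * n_extreme) {
    stop("need at least ", 2 * n_extreme, " donors for two pools of ",
         n_extreme, call. = FALSE)
  }
  prs <- cohort[[col]]
  ord_high <- order(-prs, cohort$donor_id)
  ord_low <- order(prs, cohort$donor_id)
  high <- cohort[ord_high[seq_len(n_extreme)], ]
  low <- cohort[ord_low[seq_len(n_extreme)], ]
  dplyr::bind_rows(
    dplyr::mutate(high, pool = "high"),
    dplyr::mutate(low, pool = "low")
  )
}

#' Estimate propensity scores for pool membership
#'
#' Logistic regression of high-pool membership on the continuous matching
#' covariates (sex is handled by exact matching and therefore excluded from
#' the model). Constant covariates are dropped with a warning. Under
#' complete separation the logistic fit is abandoned and a fallback score
#' based on the mean of standardized covariates is returned, flagged in the
#' `method` attribute.
#'
#' @param candidates Tibble from [select_extreme_candidates()] (RIN must be
#'   imputed).
#' @param covariates Continuous covariates (default age, pH, PMI, RIN).
#' @return Numeric vector of scores in (0, 1), one per candidate, with
#'   attribute `method` (`"logistic"` or `"fallback_distance"`).
#' @export
estimate_propensity <- function(candidates,
                                covariates = c("age", "pH", "pmi", "rin")) {
  y <- as.numeric(candidates$pool == "high")
  keep <- character()
  for (cv in covariates) {
    v <- candidates[[cv]]
    if (is.null(v)) stop("covariate '", cv, "' not found", call. = FALSE)
    if (anyNA(v)) stop("covariate '", cv, "' has missing values", call. = FALSE)
    if (stats::sd(v) == 0) {
      warning("covariate '", cv, "' is constant; dropped from the propensity model",
              call. = FALSE)
    } else {
      keep <- c(keep, cv)
    }
  }
  if (!length(keep)) {
    p <- rep(mean(y), length(y))
    attr(p, "method") <- "logistic"
    return(p)
  }
  x <- scale(as.matrix(candidates[keep]))
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, x), y, family = stats::binomial())
  )
  p <- fit$fitted.values
  separated <- !fit$converged || any(p < 1e-8) || any(p > 1 - 1e-8) ||
    max(abs(fit$coefficients[-1])) > 15
  if (separated) {
    warning("separation in the propensity model; falling back to a ",
            "standardized-covariate distance score", call. = FALSE)
    s <- rowMeans(x)
    p <- stats::plogis((s - mean(s)) / max(stats::sd(s), 1e-8))
    attr(p, "method") <- "fallback_distance"
  } else {
    attr(p, "method") <- "logistic"
  }
  p
}

#' Greedy 1:1 nearest-neighbor matching with exact sex
#'
#' Within each sex stratum, high-pool members are processed in descending
#' propensity order and each is paired, without replacement, with the
#' unmatched low-pool member minimizing the absolute difference in logit
#' propensity. A pair is only formed when that distance is within the
#' caliper, expressed in standard deviations of the logit propensity
#' (`Inf` disables it). The default of 1.0 SD sits at the permissive end of
#' the conventional 0.2--1.0 range: extreme-PRS pools are far apart on any
#' confounded covariate by construction, and a tight caliper would discard
#' more donors than the emulated study retains. Unmatched donors are
#' excluded.
#'
#' @param candidates Tibble with `donor_id`, `sex`, `pool`.
#' @param propensity Numeric vector aligned with `candidates`.
#' @param caliper Maximum pair distance in SDs of the logit propensity.
#' @return Tibble of pairs: `pair_id`, `sex`, `high_donor`, `low_donor`,
#'   `distance`.
#' @export
greedy_match_exact_sex <- function(candidates, propensity, caliper = 1) {
  stopifnot(length(propensity) == nrow(candidates))
  lp <- stats::qlogis(pmin(pmax(propensity, 1e-12), 1 - 1e-12))
  max_d <- if (is.finite(caliper)) caliper * stats::sd(lp) else Inf
  if (is.na(max_d)) max_d <- Inf
  pairs <- list()
  pair_id <- 0L
  for (sx in sort(unique(candidates$sex))) {
    hi <- which(candidates$sex == sx & candidates$pool == "high")
    lo <- which(candidates$sex == sx & candidates$pool == "low")
    if (!length(hi) || !length(lo)) next
    hi <- hi[order(-propensity[hi], candidates$donor_id[hi])]
    avail <- lo
    for (h in hi) {
      if (!length(avail)) break
      d <- abs(lp[h] - lp[avail])
      best <- avail[order(d, candidates$donor_id[avail])][1]
      if (abs(lp[h] - lp[best]) > max_d) next
      pair_id <- pair_id + 1L
      pairs[[pair_id]] <- tibble::tibble(
        pair_id = pair_id, sex = sx,
        high_donor = candidates$donor_id[h],
        low_donor = candidates$donor_id[best],
        distance = abs(lp[h] - lp[best])
      )
      avail <- setdiff(avail, best)
    }
  }
  if (!length(pairs)) {
    return(tibble::tibble(pair_id = integer(), sex = character(),
                          high_donor = character(), low_donor = character(),
                          distance = numeric()))
  }
  dplyr::bind_rows(pairs)
}

smd <- function(x, g) {
  m1 <- mean(x[g]); m0 <- mean(x[!g])
  s <- sqrt((stats::var(x[g]) + stats::var(x[!g])) / 2)
  if (!is.finite(s) || s == 0) return(0)
  (m1 - m0) / s
}

#' Define matched extreme polygenic-risk groups
#'
#' Orchestrates candidate selection, RIN imputation, propensity estimation
#' and greedy exact-sex matching, and reports covariate balance
#' (standardized mean differences before and after matching). The matched
#' groups are always equal-sized and every pair shares a sex.
#'
#' @param cohort Cohort tibble with the trait's PRS column.
#' @param trait Trait name.
#' @param n_extreme Pool size per tail (default 20).
#' @param covariates Continuous matching covariates.
#' @param caliper Matching caliper in SDs of the logit propensity (see
#'   [greedy_match_exact_sex()]).
#' @return Object of class `risk_group_assignment`: list with `assignment`
#'   (donor_id, trait, group in high/low/excluded, propensity, pair_id),
#'   `pairs`, `balance` (covariate, smd_pre, smd_post), `trait`,
#'   `mixes_cases_and_controls`.
#' @export
define_risk_groups <- function(cohort, trait, n_extreme = 20,
                               covariates = c("age", "pH", "pmi", "rin"),
                               caliper = 1) {
  cand <- select_extreme_candidates(cohort, trait, n_extreme)
  cand <- impute_rin(cand)
  prop <- estimate_propensity(cand, covariates = covariates)
  pairs <- greedy_match_exact_sex(cand, prop, caliper = caliper)
  matched <- c(pairs$high_donor, pairs$low_donor)
  assignment <- cohort |>
    dplyr::transmute(
      donor_id = .data$donor_id, trait = trait,
      group = dplyr::case_when(
        .data$donor_id %in% pairs$high_donor ~ "high",
        .data$donor_id %in% pairs$low_donor ~ "low",
        TRUE ~ "excluded"
      )
    ) |>
    dplyr::left_join(
      tibble::tibble(donor_id = cand$donor_id, propensity = as.numeric(prop)),
      by = "donor_id"
    ) |>
    dplyr::left_join(
      dplyr::bind_rows(
        tibble::tibble(donor_id = pairs$high_donor, pair_id = pairs$pair_id),
        tibble::tibble(donor_id = pairs$low_donor, pair_id = pairs$pair_id)
      ),
      by = "donor_id"
    )
  is_high_pre <- cand$pool == "high"
  post <- cand[cand$donor_id %in% matched, ]
  is_high_post <- post$pool == "high"
  balance <- purrr::map_dfr(covariates, function(cv) {
    tibble::tibble(
      covariate = cv,
      smd_pre = smd(cand[[cv]], is_high_pre),
      smd_post = if (nrow(post)) smd(post[[cv]], is_high_post) else NA_real_
    )
  })
  mixes <- assignment |>
    dplyr::filter(.data$group != "excluded") |>
    dplyr::left_join(dplyr::select(cohort, "donor_id", "disease_status"),
                     by = "donor_id") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarize(mixed = dplyr::n_distinct(.data$disease_status) > 1,
                     .groups = "drop")
  stopifnot(sum(assignment$group == "high") == sum(assignment$group == "low"))
  structure(
    list(assignment = assignment, pairs = pairs, balance = balance,
         trait = trait, propensity_method = attr(prop, "method"),
         mixes_cases_and_controls = all(mixes$mixed)),
    class = "risk_group_assignment"
  )
}

#' @method print risk_group_assignment
#' @export
print.risk_group_assignment <- function(x, ...) {
  n <- sum(x$assignment$group == "high")
  cat(sprintf("<risk_group_assignment:%s> %d matched pairs (%s propensity)\n",
              x$trait, n, x$propensity_method))
  invisible(x)
}

#' @export
tidy.risk_group_assignment <- function(x, ...) x$assignment

#' @export
glance.risk_group_assignment <- function(x, ...) {
  tibble::tibble(
    trait = x$trait,
    n_high = sum(x$assignment$group == "high"),
    n_low = sum(x$assignment$group == "low"),
    n_excluded = sum(x$assignment$group == "excluded"),
    mean_abs_smd_pre = mean(abs(x$balance$smd_pre)),
    mean_abs_smd_post = mean(abs(x$balance$smd_post)),
    propensity_method = x$propensity_method,
    mixes_cases_and_controls = x$mixes_cases_and_controls
  )
}

#' Donor table for a risk contrast
#'
#' Convenience accessor: the cohort restricted to matched donors with a
#' `risk_group` column, ready for [run_differential()].
#'
#' @param cohort Cohort tibble.
#' @param assignment A `risk_group_assignment`.
#' @return Tibble of matched donors.
#' @export
risk_contrast_table <- function(cohort, assignment) {
  cohort |>
    dplyr::inner_join(
      assignment$assignment |>
        dplyr::filter(.data$group != "excluded") |>
        dplyr::select("donor_id", risk_group = "group"),
      by = "donor_id"
    )
}
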