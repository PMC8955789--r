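# Analytic calibration of the generator's selection parameters: choose the
# nonsynonymous placement odds so that the *expected* pooled dN/dS of a
# designated transcript scope equals a target value.

# Expected per-change pick counts for V variants planted without replacement
# under per-change weights w: positions are included with probability
# 1 - exp(-lambda * w_pos) (conditional-Poisson approximation), with lambda
# solved so inclusion probabilities sum to V; alts split within a position
# proportionally to change weights.
expected_class_counts <- function(changes, w, n_var) {
  site_w <- rowsum(w, changes$site)[, 1]
  n_sites <- length(site_w)
  if (n_var > n_sites) stop_config("n_var exceeds available sites")
  if (n_var == 0) {
    return(c(synonymous = 0, nonsynonymous = 0, stopgain = 0, noncoding = 0))
  }
  f <- function(lambda) sum(1 - exp(-lambda * site_w)) - n_var
  upper <- n_var / sum(site_w)
  while (f(upper) < 0) upper <- upper * 2
  lambda <- uniroot(f, c(0, upper), tol = 1e-10)$root
  pi_site <- 1 - exp(-lambda * site_w)
  pi_change <- pi_site[changes$site] * w / site_w[changes$site]
  vapply(split(pi_change, changes$class), sum, numeric(1))[
    c("synonymous", "nonsynonymous", "stopgain", "noncoding")]
}

#' Calibrate a nonsynonymous placement multiplier to a target dN/dS
#'
#' Finds the odds multiplier `x` on nonsynonymous candidate changes of the
#' `apply_ids` transcripts (all transcripts when `NULL`) such that the
#' expected pooled Nei--Gojobori dN/dS over the `measure_ids` scope equals
#' `target_dnds`, under the configured ts/tv model, variant count and any
#' base `nonsyn_weight` already present in the config.  The expectation uses
#' a conditional-Poisson approximation of the generator's weighted
#' without-replacement placement, so the returned multiplier plants the
#' target as the expected value of the downstream estimator.
#'
#' @param reference The list returned by [generate_reference()].
#' @param config A [simulation_config()]; its `nonsyn_weight` acts as the
#'   global base odds during calibration.
#' @param target_dnds Target expected pooled dN/dS.
#' @param apply_ids Transcripts whose nonsynonymous odds receive the solved
#'   multiplier (`NULL` = all).
#' @param measure_ids Transcripts over which the expected pooled dN/dS is
#'   evaluated (default: `apply_ids`, or all when that is `NULL`).
#' @param changes Optional precomputed site-change table (internal reuse).
#' @return The solved multiplier (positive scalar), with attribute
#'   `expected_dnds` (the achieved expectation).
#' @export
calibrate_nonsyn_weight <- function(reference, config, target_dnds,
                                    apply_ids = NULL, measure_ids = NULL,
                                    changes = NULL) {
  validate_simulation_config(config)
  if (is.null(changes)) changes <- site_change_table(reference$sequences,
                                                     reference$orfs)
  if (is.null(measure_ids)) measure_ids <- apply_ids
  if (is.null(measure_ids)) measure_ids <- reference$orfs$transcript_id

  # NG86 site totals over the measured scope
  om <- reference$orfs[reference$orfs$transcript_id %in% measure_ids &
                         !is.na(reference$orfs$start), , drop = FALSE]
  if (nrow(om) == 0) stop_config("no ORF-bearing transcripts in measure scope")
  sites <- t(mapply(function(id, s, e) {
    sc <- ng86_site_counts(substr(reference$sequences[[id]], s, e))
    c(sc$syn_sites, sc$nonsyn_sites)
  }, om$transcript_id, om$start, om$end))
  syn_sites <- sum(sites[, 1])
  nonsyn_sites <- sum(sites[, 2])

  t_prob <- config$titv_target / (1 + config$titv_target)
  w_base <- ifelse(changes$transition, t_prob, (1 - t_prob) / 2)
  nonsyn <- changes$class == "nonsynonymous"
  w_base[nonsyn] <- w_base[nonsyn] * config$nonsyn_weight
  in_apply <- if (is.null(apply_ids)) rep(TRUE, nrow(changes)) else
    changes$transcript_id %in% apply_ids
  in_measure <- changes$transcript_id %in% om$transcript_id

  expected_ratio <- function(log_x) {
    w <- w_base
    sel <- nonsyn & in_apply
    w[sel] <- w[sel] * exp(log_x)
    site_w <- rowsum(w, changes$site)[, 1]
    f <- function(lambda) sum(1 - exp(-lambda * site_w)) - config$variants_per_library
    upper <- config$variants_per_library / sum(site_w)
    while (f(upper) < 0) upper <- upper * 2
    lambda <- uniroot(f, c(0, upper), tol = 1e-10)$root
    pi_change <- (1 - exp(-lambda * site_w))[changes$site] * w / site_w[changes$site]
    e_syn <- sum(pi_change[in_measure & changes$class == "synonymous"])
    e_nonsyn <- sum(pi_change[in_measure & changes$class == "nonsynonymous"])
    p_n <- e_nonsyn / nonsyn_sites
    p_s <- e_syn / syn_sites
    # past JC saturation the ratio is effectively unbounded; cap it so the
    # root search stays on finite values (the root lies below saturation)
    if (p_n >= 0.75) return(1e9)
    if (p_s >= 0.75) return(0)
    jc_distance(p_n) / jc_distance(p_s)
  }

  lower <- log(1e-4)
  if (expected_ratio(lower) > target_dnds) {
    stop_config("target dN/dS of ", target_dnds,
                " is below what the mutation model can reach")
  }
  upper <- 0
  while (expected_ratio(upper) < target_dnds) {
    upper <- upper + 1
    if (upper > log(1e6)) {
      stop_config("target dN/dS of ", target_dnds, " is unreachable")
    }
  }
  sol <- uniroot(function(lx) expected_ratio(lx) - target_dnds,
                 lower = lower, upper = upper, tol = 1e-6)
  structure(exp(sol$root), expected_dnds = expected_ratio(sol$root))
}

#' Calibrate a study configuration to planted dN/dS targets
#'
#' Returns a copy of `config` whose `nonsyn_weight` and
#' `soldier_nonsyn_enrichment` are solved so that the expected pooled dN/dS
#' of the caste-associated subset is `background_dnds` in non-soldier
#' libraries and `subset_dnds` in soldier libraries — the planted selection
#' signal that the downstream estimator is expected to recover.  The
#' reference realisation is fully determined by the config's structural
#' fields and seed, so the calibrated config regenerates the identical
#' reference.
#'
#' @param config A [simulation_config()].
#' @param subset_dnds Target expected subset dN/dS of soldier libraries.
#' @param background_dnds Target expected subset dN/dS elsewhere.
#' @return The updated `simulation_config`, with attribute `calibration`
#'   (a list with the solved weight, enrichment and achieved expectations).
#' @export
calibrate_study <- function(config, subset_dnds = 4.3, background_dnds = 1.7) {
  validate_simulation_config(config)
  ref <- generate_reference(config)
  if (length(ref$design$subset_ids) == 0) {
    stop_config("cannot calibrate: the design has no subset transcripts")
  }
  changes <- site_change_table(ref$sequences, ref$orfs)

  base_cfg <- config
  base_cfg$nonsyn_weight <- 1
  m0 <- calibrate_nonsyn_weight(ref, base_cfg, background_dnds,
                                apply_ids = NULL,
                                measure_ids = ref$design$subset_ids,
                                changes = changes)
  cfg1 <- config
  cfg1$nonsyn_weight <- as.numeric(m0)
  enr <- calibrate_nonsyn_weight(ref, cfg1, subset_dnds,
                                 apply_ids = ref$design$subset_ids,
                                 measure_ids = ref$design$subset_ids,
                                 changes = changes)
  out <- config
  out$nonsyn_weight <- as.numeric(m0)
  out$soldier_nonsyn_enrichment <- max(1, as.numeric(enr))
  validate_simulation_config(out)
  attr(out, "calibration") <- list(
    nonsyn_weight = as.numeric(m0),
    soldier_nonsyn_enrichment = as.numeric(enr),
    expected_background_dnds = attr(m0, "expected_dnds"),
    expected_soldier_subset_dnds = attr(enr, "expected_dnds")
  )
  out
}
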