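#' Pipeline configuration
#'
#' Collects every tunable of the calling pipeline with its documented
#' default. The defaults — FTR 1, FDR < 0.1, 100,000 null draws, digestion
#' efficiency 0.7, neighbourhood half-width 5 — are the standard operating
#' point.
#'
#' @param ftr Fragment threshold rate.
#' @param fdr_threshold Local FDR cut-off.
#' @param np Empirical-null resampling draws.
#' @param efficiency Digestion efficiency E.
#' @param k_neighbors Neighbourhood half-width K (fragments).
#' @param bg_threshold Background-likelihood threshold (`"auto"` or a
#'   number).
#' @param n_boot Bootstrap rounds for the mixture fit; 0 disables the
#'   bootstrap and uses a single EM fit.
#' @param d_min Short-range bound of the distance profile (bp).
#' @param intra_only Restrict calling to intra-chromosomal records.
#' @param seed Integer seed for all stochastic stages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(ftr = 1L, fdr_threshold = 0.1, np = 1e5,
                       efficiency = 0.7, k_neighbors = 5L,
                       bg_threshold = "auto", n_boot = 50L, d_min = 1000,
                       intra_only = TRUE, seed = 1L) {
  structure(
    list(ftr = as.integer(ftr), fdr_threshold = fdr_threshold, np = np,
         efficiency = efficiency, k_neighbors = as.integer(k_neighbors),
         bg_threshold = bg_threshold, n_boot = as.integer(n_boot),
         d_min = d_min, intra_only = intra_only, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full SIF-calling pipeline
#'
#' Executes the stages in order: ligation QC and score-table construction;
#' mixture fit (bootstrapped EM); power-law background fit and
#' digestion-efficiency likelihood filtering; FDR-table construction; FTR +
#' local-FDR calling; equal-score merging. The report records counts at
#' every stage and all fitted parameters.
#'
#' @param pairs Pairs tibble (see [read_pairs()]).
#' @param map Fragment map tibble.
#' @param config A [run_config()].
#' @return A list of class `sif_run`: `sifs` (merged SIF tibble),
#'   `candidates` (pre-merge SIFs), `fit` (mixture fit), `power_law`,
#'   `fdr_table`, `background` (filter result), `qc` (QC report), `report`
#'   (one-row tibble of stage counts), `config`.
#' @export
run_pipeline <- function(pairs, map, config = run_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  classified <- stage("qc", classify_pairs(dedup_pairs(pairs), map))
  qc <- stage("qc", qc_report(classified))
  usf <- stage("usf", build_usf_table(classified, map,
                                      intra_only = config$intra_only,
                                      dedup = FALSE))
  fit <- stage("fit", {
    if (config$n_boot > 0) {
      bootstrap_fit(usf$score, n_boot = config$n_boot, seed = config$seed)
    } else {
      em_fit(usf$score)
    }
  })
  profile <- stage("background",
                   distance_profile(classified[classified$class == "valid", ],
                                    d_min = config$d_min))
  pl <- stage("background", fit_power_law(profile))
  bg_cfg <- background_config(config$efficiency, config$k_neighbors,
                              config$bg_threshold)
  filt <- stage("background", filter_background(usf, map, bg_cfg, pl))
  # the empirical null resamples from the full observed score multiset; the
  # background filter prunes the candidate set only
  fdr_tab <- stage("call", build_fdr_table(usf$score, fit,
                                           np = config$np,
                                           seed = config$seed + 1L))
  candidates <- stage("call", call_sifs(filt$retained, fdr_tab,
                                        ftr = config$ftr,
                                        fdr_threshold = config$fdr_threshold))
  sifs <- stage("merge", merge_equal_score(candidates, map))
  report <- tibble::tibble(
    n_pairs = nrow(pairs),
    n_dedup = nrow(classified),
    n_self = qc$n_self, n_re = qc$n_re, n_valid = qc$n_valid,
    n_usf = nrow(usf),
    n_bg_removed = filt$n_removed, n_bg_retained = filt$n_retained,
    n_candidates = nrow(candidates), n_sifs = nrow(sifs),
    omega1 = fit$weights[1], omega2 = fit$weights[2],
    lambda1 = fit$lambda[1], lambda2 = fit$lambda[2],
    alpha = pl$alpha, bg_threshold = filt$threshold
  )
  structure(
    list(sifs = sifs, candidates = candidates, fit = fit, power_law = pl,
         fdr_table = fdr_tab, background = filt, qc = qc, report = report,
         config = config),
    class = "sif_run"
  )
}

#' @export
print.sif_run <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    paste0("SIF pipeline run: %d pairs -> %d valid -> %d records -> ",
           "%d candidates -> %d SIFs\n"),
    r$n_pairs, r$n_valid, r$n_usf, r$n_candidates, r$n_sifs))
  cat(sprintf("  mixture: omega = (%.3f, %.3f), lambda = (%.3f, %.3f)\n",
              r$omega1, r$omega2, r$lambda1, r$lambda2))
  cat(sprintf("  background: alpha = %.3f, %d records removed\n",
              r$alpha, r$n_bg_removed))
  invisible(x)
}

#' @method glance sif_run
#' @export
glance.sif_run <- function(x, ...) {
  x$report
}

#' Score a pipeline run against simulation truth
#'
#' Sensitivity is the fraction of planted loops recovered by a called SIF
#' (the planted fragment pair contained in the SIF's member fragments); the
#' false discovery proportion is the fraction of called SIFs containing no
#' planted pair.
#'
#' @param run A `sif_run` (or a SIF tibble).
#' @param truth A `sim_truth`.
#' @return A one-row tibble `n_true`, `n_called`, `n_recovered`, `n_false`,
#'   `sensitivity`, `fdp`.
#' @export
score_against_truth <- function(run, truth) {
  sifs <- if (inherits(run, "sif_run")) run$sifs else run
  loops <- truth$loops
  hit_loop <- logical(nrow(loops))
  sif_true <- logical(nrow(sifs))
  for (s in seq_len(nrow(sifs))) {
    f1 <- sifs$frags1[[s]]
    f2 <- sifs$frags2[[s]]
    m <- loops$index1 %in% f1 & loops$index2 %in% f2
    if (any(m)) {
      sif_true[s] <- TRUE
      hit_loop[m] <- TRUE
    }
  }
  tibble::tibble(
    n_true = nrow(loops), n_called = nrow(sifs),
    n_recovered = sum(hit_loop), n_false = sum(!sif_true),
    sensitivity = ifelse(nrow(loops) > 0, mean(hit_loop), NA_real_),
    fdp = ifelse(nrow(sifs) > 0, mean(!sif_true), NA_real_)
  )
}
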