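#' Empirical null (false-positive) score density
#'
#' Builds the null distribution of interaction scores by resampling: `np`
#' scores are drawn uniformly with replacement from the observed score
#' multiset, and their normalised histogram over integer scores is the
#' empirical false-positive density. Because no biological replicates exist
#' at the fragment level, no population inference (p-values) is possible;
#' the local FDR built on this resampled null is used instead.
#'
#' @param scores Observed integer score vector (non-empty).
#' @param np Number of resampling draws (default 1e5, which stabilises the
#'   density to about three decimals over typical score ranges).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A tibble `score`, `fp` (density summing to 1 over the sampled
#'   support).
#' @export
empirical_null <- function(scores, np = 1e5, seed = NULL) {
  if (length(scores) == 0L) {
    stop("Cannot build an empirical null from zero records", call. = FALSE)
  }
  stopifnot(np >= 1)
  draw <- function() scores[sample.int(length(scores), np, replace = TRUE)]
  s <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tab <- table(factor(s, levels = 0:max(scores)))
  tibble::tibble(score = 0:max(scores), fp = as.numeric(tab) / np)
}

#' True-positive score density
#'
#' The proximate-ligation (high-mean) mixture component's Poisson pmf,
#' evaluated over the integer score support, is taken as the density of
#' true-positive scores.
#'
#' @param fit A `pmm_fit` with distinct component means.
#' @param max_score Upper end of the returned support (default: the 0.99999
#'   Poisson quantile of the proximate mean).
#' @return A tibble `score`, `tp`.
#' @export
tp_density <- function(fit, max_score = NULL) {
  if (fit$lambda[2] <= fit$lambda[1] + 1e-9) {
    stop("Components indistinct (lambda_2 <= lambda_1); ",
         "true-positive density undefined", call. = FALSE)
  }
  if (is.null(max_score)) {
    max_score <- stats::qpois(0.99999, fit$lambda[2])
  }
  tibble::tibble(score = 0:max_score,
                 tp = stats::dpois(0:max_score, fit$lambda[2]))
}

#' Local false discovery rate at a score
#'
#' `FDR_d = FP_d / (FP_d + TP_d)` for false-positive density `FP_d` and
#' true-positive density `TP_d` at integer score `d`.
#'
#' @param fp,tp Non-negative density values (vectorised).
#' @return FDR values in `[0, 1]`; `NA` where `fp + tp == 0` (undefined).
#' @export
local_fdr <- function(fp, tp) {
  if (any(fp < 0 | tp < 0, na.rm = TRUE)) {
    stop("Densities must be non-negative", call. = FALSE)
  }
  out <- fp / (fp + tp)
  out[fp + tp == 0] <- NA_real_
  out
}

#' Build the per-score FDR table
#'
#' Joins the empirical null and the true-positive density over the union of
#' their supports and computes the local FDR at every integer score. Scores
#' above the table's support inherit the last defined FDR (conservative tail
#' handling), applied by [call_sifs()].
#'
#' The raw per-score FDR of a finite resampled null is noisy wherever the
#' null holds only a handful of records, and can dip and rise again across
#' neighbouring scores, which would discard a mid-score record while keeping
#' records on either side of it. Since a higher score can only be stronger
#' evidence of a proximate ligation, the applied FDR (`fdr_mono`) is the
#' running minimum of the raw FDR over increasing score, anchored at the
#' smallest score observed in the null — the same monotonicity enforcement
#' q-value procedures apply to adjusted p-values.
#'
#' @param scores Observed scores feeding the empirical null (use the
#'   background-filtered record set so linear-closeness artifacts do not
#'   inflate the null).
#' @param fit A `pmm_fit`.
#' @param np Resampling draws for the null.
#' @param seed Integer seed for the null resampling.
#' @return A tibble `score`, `fp`, `tp`, `fdr` (raw), `fdr_mono`
#'   (monotonised, used for gating) with attribute `np`.
#' @export
build_fdr_table <- function(scores, fit, np = 1e5, seed = NULL) {
  null <- empirical_null(scores, np = np, seed = seed)
  tp <- tp_density(fit, max_score = max(max(null$score), max(scores)))
  tab <- dplyr::full_join(null, tp, by = "score")
  tab <- dplyr::arrange(tab, .data$score)
  tab$fp <- tidyr::replace_na(tab$fp, 0)
  tab$tp <- tidyr::replace_na(tab$tp, 0)
  tab$fdr <- local_fdr(tab$fp, tab$tp)
  first_obs <- min(scores)
  mono <- tab$fdr
  mono[tab$score < first_obs] <- NA_real_
  run <- 1
  for (i in seq_len(nrow(tab))) {
    if (tab$score[i] < first_obs) next
    v <- tab$fdr[i]
    if (!is.na(v)) run <- min(run, v)
    mono[i] <- run
  }
  tab$fdr_mono <- mono
  attr(tab, "np") <- np
  tab
}

fdr_at_score <- function(fdr_table, score) {
  col <- if ("fdr_mono" %in% names(fdr_table)) fdr_table$fdr_mono
         else fdr_table$fdr
  idx <- match(score, fdr_table$score)
  out <- col[idx]
  # scores above the support inherit the last defined FDR
  above <- is.na(idx) & score > max(fdr_table$score)
  if (any(above)) {
    last_def <- rev(col[!is.na(col)])[1]
    out[above] <- last_def
  }
  out
}

#' Call significant interacting fragments
#'
#' Applies the double filter: a record is a significant-interaction
#' candidate only when its score strictly exceeds the fragment threshold
#' rate (FTR), and a candidate is retained only when its local FDR is below
#' the FDR threshold. Each retained record becomes a single-fragment-anchor
#' SIF carrying its score, FDR and per-anchor resolutions (the anchor
#' lengths in bp).
#'
#' @param records USF record tibble.
#' @param fdr_table FDR table from [build_fdr_table()].
#' @param ftr Fragment threshold rate (integer; scores must be `> ftr`).
#'   Default 1.
#' @param fdr_threshold Local FDR cut-off (retained when `fdr <
#'   fdr_threshold`). Default 0.1. The (FTR = 1, FDR < 0.1) operating point
#'   is the default working configuration.
#' @return A SIF tibble: `chrom1`, `start1`, `end1`, `chrom2`, `start2`,
#'   `end2`, `name`, `score`, `fdr`, `res1`, `res2`, plus list columns
#'   `frags1`, `frags2` of member fragment indices.
#' @export
call_sifs <- function(records, fdr_table, ftr = 1L, fdr_threshold = 0.1) {
  if (nrow(records) == 0L) return(empty_sifs())
  fdr <- fdr_at_score(fdr_table, records$score)
  keep <- records$score > ftr & !is.na(fdr) & fdr < fdr_threshold
  rec <- records[keep, ]
  if (nrow(rec) == 0L) return(empty_sifs())
  tibble::tibble(
    chrom1 = rec$chrom1, start1 = rec$start1, end1 = rec$end1,
    chrom2 = rec$chrom2, start2 = rec$start2, end2 = rec$end2,
    name = paste0("sif_", seq_len(nrow(rec))),
    score = rec$score,
    fdr = fdr[keep],
    res1 = rec$end1 - rec$start1,
    res2 = rec$end2 - rec$start2,
    frags1 = as.list(rec$index1),
    frags2 = as.list(rec$index2)
  )
}

empty_sifs <- function() {
  tibble::tibble(
    chrom1 = character(), start1 = integer(), end1 = integer(),
    chrom2 = character(), start2 = integer(), end2 = integer(),
    name = character(), score = integer(), fdr = numeric(),
    res1 = integer(), res2 = integer(),
    frags1 = list(), frags2 = list()
  )
}

#' Merge equal-score adjacent SIFs and define resolution
#'
#' Two SIFs merge when their first-anchor fragments are adjacent (index
#' offset 1), their second-anchor fragments are adjacent, and their scores
#' are equal — the fragment-level analogue of collapsing a ChIP-seq peak to
#' its summit. Merging is transitive; a merged anchor spans its member
#' fragments and its resolution is the summed member length.
#'
#' @param sifs SIF tibble from [call_sifs()] (single-fragment anchors).
#' @param map Fragment map tibble (for member fragment coordinates).
#' @return A SIF tibble in the same shape with merged anchors, updated
#'   `res1`/`res2` and member fragment index list columns.
#' @export
merge_equal_score <- function(sifs, map) {
  n <- nrow(sifs)
  if (n <= 1L) return(sifs)
  i1 <- purrr::map_int(sifs$frags1, ~ as.integer(.x[1]))
  i2 <- purrr::map_int(sifs$frags2, ~ as.integer(.x[1]))

  # union-find over SIFs
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[rb] <<- ra
  }
  ord <- order(sifs$chrom1, i1, i2)
  for (a_i in seq_len(n - 1L)) {
    a <- ord[a_i]
    for (b_i in (a_i + 1L):n) {
      b <- ord[b_i]
      if (sifs$chrom1[a] != sifs$chrom1[b]) break
      if (i1[b] - i1[a] > 1L) break
      if (sifs$chrom2[a] == sifs$chrom2[b] &&
          abs(i1[a] - i1[b]) == 1L && abs(i2[a] - i2[b]) == 1L &&
          sifs$score[a] == sifs$score[b]) {
        union(a, b)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))

  merged <- purrr::map_dfr(unique(comp), function(cid) {
    members <- which(comp == cid)
    f1 <- sort(unique(unlist(sifs$frags1[members])))
    f2 <- sort(unique(unlist(sifs$frags2[members])))
    chrom1 <- sifs$chrom1[members[1]]
    chrom2 <- sifs$chrom2[members[1]]
    m1 <- map[map$chrom == chrom1 & map$index %in% f1, ]
    m2 <- map[map$chrom == chrom2 & map$index %in% f2, ]
    tibble::tibble(
      chrom1 = chrom1, start1 = min(m1$start), end1 = max(m1$end),
      chrom2 = chrom2, start2 = min(m2$start), end2 = max(m2$end),
      name = NA_character_,
      score = sifs$score[members[1]],
      fdr = sifs$fdr[members[1]],
      res1 = sum(m1$end - m1$start),
      res2 = sum(m2$end - m2$start),
      frags1 = list(f1), frags2 = list(f2)
    )
  })
  merged <- dplyr::arrange(merged, .data$chrom1, .data$start1, .data$start2)
  merged$name <- paste0("sif_", seq_len(nrow(merged)))
  merged
}

#' Write SIF calls as BEDPE
#'
#' Eleven columns: the six anchor coordinates, then `name`, `score`, `fdr`,
#' `res1`, `res2`.
#'
#' @param sifs SIF tibble.
#' @param path Output path.
#' @param header Optional `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_sif_bedpe <- function(sifs, path, header = NULL) {
  write_bedpe(sifs, path, header = header)
}

#' Read SIF calls from BEDPE
#'
#' @param path BEDPE written by [write_sif_bedpe()].
#' @return A SIF tibble (without member fragment list columns).
#' @export
read_sif_bedpe <- function(path) {
  read_bedpe(path)
}
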