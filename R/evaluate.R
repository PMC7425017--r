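#' Aggregate peak analysis of a loop set
#'
#' For every loop whose bin pair lies further than `2 * window` bins from
#' the diagonal (avoiding diagonal contamination), the
#' `(2*window+1) x (2*window+1)` submatrix of the binned contact matrix
#' centred on the loop's bin pair is extracted, and submatrices are summed
#' element-wise across loops. The APA value is the central pixel divided by
#' the mean of the `window x window` lower-left corner block; the analogous
#' ratios for the other three corners are reported as diagnostics. A value
#' near 1 means loop centres are no more contact-rich than their local
#' background; focal loop enrichment drives it above 1.
#'
#' @param loops Loop tibble (BEDPE columns); anchor midpoints define the
#'   bin pair.
#' @param matrix Contact-matrix tibble from [read_contact_matrix()]
#'   (attribute `bin_size`, or pass `bin_size`).
#' @param window Half-width of the aggregation window in bins (>= 1).
#' @param bin_size Bin size in bp.
#' @return A list of class `apa_result`: `apa` (the lower-left APA value),
#'   `corners` (tibble of the four corner ratios), `matrix` (the summed
#'   submatrix), `n_loops` (loops used), `n_excluded` (too close to the
#'   diagonal or inter-chromosomal).
#' @export
apa <- function(loops, matrix, window = 5L,
                bin_size = attr(matrix, "bin_size")) {
  stopifnot(window >= 1L)
  if (is.null(bin_size)) stop("`bin_size` is required", call. = FALSE)
  w <- as.integer(window)
  side <- 2L * w + 1L

  intra <- loops$chrom1 == loops$chrom2
  bi <- floor(((loops$start1 + loops$end1) / 2) / bin_size)
  bj <- floor(((loops$start2 + loops$end2) / 2) / bin_size)
  lo <- pmin(bi, bj)
  hi <- pmax(bi, bj)
  eligible <- intra & (hi - lo) > 2L * w
  if (!any(eligible)) {
    stop("No eligible loops (all inter-chromosomal or within 2*window bins ",
         "of the diagonal)", call. = FALSE)
  }

  key <- paste(matrix$chrom, matrix$bin_i, matrix$bin_j, sep = ":")
  lookup <- matrix$count
  names(lookup) <- key

  agg <- base::matrix(0, side, side)
  offs <- (-w):w
  for (idx in which(eligible)) {
    ii <- lo[idx] + offs
    jj <- hi[idx] + offs
    qi <- rep(ii, times = side)
    qj <- rep(jj, each = side)
    a <- pmin(qi, qj)
    b <- pmax(qi, qj)
    v <- lookup[paste(loops$chrom1[idx], a, b, sep = ":")]
    v[is.na(v)] <- 0
    agg <- agg + base::matrix(v, side, side)
  }

  centre <- agg[w + 1L, w + 1L]
  block_mean <- function(rows, cols) mean(agg[rows, cols])
  corners <- tibble::tibble(
    corner = c("lower_left", "lower_right", "upper_left", "upper_right"),
    ratio = c(
      centre / block_mean((w + 2L):side, 1L:w),
      centre / block_mean((w + 2L):side, (w + 2L):side),
      centre / block_mean(1L:w, 1L:w),
      centre / block_mean(1L:w, (w + 2L):side)
    )
  )
  structure(
    list(apa = corners$ratio[corners$corner == "lower_left"],
         corners = corners, matrix = agg,
         n_loops = sum(eligible), n_excluded = sum(!eligible)),
    class = "apa_result"
  )
}

#' @export
print.apa_result <- function(x, ...) {
  cat(sprintf("APA value %.4f over %d loops (%d excluded)\n",
              x$apa, x$n_loops, x$n_excluded))
  invisible(x)
}

#' Plot an aggregated APA submatrix
#'
#' @param object An `apa_result`.
#' @param ... Unused.
#' @return A ggplot heat map of the summed submatrix with the APA value in
#'   the title.
#' @method autoplot apa_result
#' @export
autoplot.apa_result <- function(object, ...) {
  side <- nrow(object$matrix)
  w <- (side - 1L) / 2L
  df <- tidyr::expand_grid(i = seq_len(side), j = seq_len(side))
  df$count <- object$matrix[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j - w - 1, y = .data$i - w - 1,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "bin offset (anchor 2)", y = "bin offset (anchor 1)",
                  title = sprintf("APA = %.3f (n = %d)", object$apa,
                                  object$n_loops)) +
    ggplot2::theme_minimal()
}

# Best sweep value of any called loop matching each universe loop; -Inf when
# none matches.
best_match_value <- function(universe, called, value, slack) {
  out <- rep(-Inf, nrow(universe))
  if (nrow(called) == 0L) return(out)
  key_u <- paste(universe$chrom1, universe$chrom2)
  by_key <- split(seq_len(nrow(called)), paste(called$chrom1, called$chrom2))
  for (i in seq_len(nrow(universe))) {
    cc <- by_key[[key_u[i]]]
    if (is.null(cc)) next
    ov1 <- called$start1[cc] - slack < universe$end1[i] + slack &
      universe$start1[i] - slack < called$end1[cc] + slack
    ov2 <- called$start2[cc] - slack < universe$end2[i] + slack &
      universe$start2[i] - slack < called$end2[cc] + slack
    hit <- cc[ov1 & ov2]
    if (length(hit)) out[i] <- max(value[hit])
  }
  out
}

#' ROC curve of a called loop set against a reference
#'
#' Each loop of a supplied putative-loop universe is labelled positive when
#' it overlaps the reference loop set (reciprocal anchor overlap with
#' `slack` bp), and predicted when it overlaps the called set at the
#' sweeping threshold. At every threshold: TP — called and reference both
#' identify the loop; TN — neither does; FP — called only; FN — reference
#' only. TPR = TP / (TP + FN), FPR = FP / (FP + TN); the AUC is the
#' trapezoid area under the (FPR, TPR) points closed with (0,0) and (1,1).
#'
#' @param universe Putative-loop tibble (BEDPE columns). Constructing the
#'   universe (e.g. promoter/enhancer mark windows around factor peaks) is
#'   the caller's job.
#' @param called Called loop tibble; the sweep value is `-fdr` when `sweep =
#'   "fdr"`, else `score` (a constant 1 when absent, giving a single
#'   threshold).
#' @param reference Reference loop tibble.
#' @param slack Anchor slack in bp for overlap (default 5000).
#' @param sweep `"score"` or `"fdr"`.
#' @return An object of class `roc_result`: `points` (tibble `threshold`,
#'   `tp`, `fp`, `tn`, `fn`, `tpr`, `fpr`), `auc`, `n_positive`,
#'   `n_negative`.
#' @export
roc_curve <- function(universe, called, reference, slack = 5000,
                      sweep = c("score", "fdr")) {
  sweep <- match.arg(sweep)
  if (nrow(universe) == 0L) {
    stop("Empty putative-loop universe", call. = FALSE)
  }
  label <- match_loops(universe, reference, slack)
  if (all(label) || !any(label)) {
    stop("Universe labels are single-class; ROC undefined", call. = FALSE)
  }
  value <- if (sweep == "fdr") {
    -called$fdr
  } else if ("score" %in% names(called)) {
    called$score
  } else {
    rep(1, nrow(called))
  }
  s <- best_match_value(universe, called, value, slack)

  n_pos <- sum(label)
  n_neg <- sum(!label)
  # cumulative confusion counts down the score ordering; one point per
  # distinct finite threshold (ties grouped)
  ord <- order(s, decreasing = TRUE)
  ss <- s[ord]
  ll <- label[ord]
  cum_tp <- cumsum(ll)
  cum_fp <- cumsum(!ll)
  last_of_run <- !duplicated(ss, fromLast = TRUE) & is.finite(ss)
  pos <- which(last_of_run)
  pts <- tibble::tibble(
    threshold = ss[pos],
    tp = cum_tp[pos], fp = cum_fp[pos],
    tn = n_neg - cum_fp[pos], fn = n_pos - cum_tp[pos],
    tpr = cum_tp[pos] / n_pos, fpr = cum_fp[pos] / n_neg
  )
  fpr <- c(0, pts$fpr, 1)
  tpr <- c(0, pts$tpr, 1)
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (utils::head(tpr[ord], -1) +
                                 utils::tail(tpr[ord], -1)) / 2)
  structure(
    list(points = pts, auc = auc, n_positive = n_pos, n_negative = n_neg),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.4f over %d positives / %d negatives\n",
              x$auc, x$n_positive, x$n_negative))
  invisible(x)
}

#' Plot a ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot of the (FPR, TPR) curve with the chance diagonal.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  df <- tibble::tibble(
    fpr = c(0, object$points$fpr, 1),
    tpr = c(0, object$points$tpr, 1)
  )
  df <- df[order(df$fpr, df$tpr), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false-positive rate", y = "true-positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}
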