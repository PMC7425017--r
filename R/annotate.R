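#' Promoter and distal windows for a gene set
#'
#' Promoter windows are strand-aware mirrors of "-5 kb / +1 kb around the
#' TSS": `[TSS - 5000, TSS + 1000)` on the `+` strand and
#' `[TSS - 1000, TSS + 5000)` on the `-` strand. Distal (non-promoter)
#' windows span `[TSS - 100000, TSS + 100000)`.
#'
#' @param genes Gene tibble from [read_genes()].
#' @param promoter_up,promoter_down Upstream/downstream promoter extents
#'   (bp).
#' @param distal_half_width Distal window half-width (bp).
#' @return `genes` with added columns `prom_start`, `prom_end`,
#'   `distal_start`, `distal_end`.
#' @export
gene_windows <- function(genes, promoter_up = 5000L, promoter_down = 1000L,
                         distal_half_width = 100000L) {
  dplyr::mutate(
    genes,
    prom_start = ifelse(.data$strand == "+", .data$tss - promoter_up,
                        .data$tss - promoter_down),
    prom_end = ifelse(.data$strand == "+", .data$tss + promoter_down,
                      .data$tss + promoter_up),
    distal_start = .data$tss - distal_half_width,
    distal_end = .data$tss + distal_half_width
  )
}

#' Classify SIFs into promoter-distal loop categories
#'
#' A promoter-distal loop (PDL) has one anchor in a gene's promoter window
#' and the other in a distal (non-promoter) window within 100 kb of some
#' TSS. If the distal anchor's closest gene (minimal |anchor midpoint -
#' TSS| over all genes) is the same gene as the promoter's, the loop is
#' `P1D1`; if it is a different gene, `P1D2`; everything else is `not_PDL`.
#' Anchor membership is tested by anchor midpoint, so each anchor sits in at
#' most one promoter; ties to multiple promoters are broken by nearest TSS,
#' then lexicographic gene id.
#'
#' @param sifs SIF tibble (intra-chromosomal).
#' @param genes Gene tibble from [read_genes()].
#' @param promoter_up,promoter_down,distal_half_width Window geometry, see
#'   [gene_windows()].
#' @return `sifs` with added columns `category` (factor `P1D1`, `P1D2`,
#'   `not_PDL`), `promoter_gene`, `distal_gene`.
#' @export
classify_pdl <- function(sifs, genes, promoter_up = 5000L,
                         promoter_down = 1000L,
                         distal_half_width = 100000L) {
  gw <- gene_windows(genes, promoter_up, promoter_down, distal_half_width)
  n <- nrow(sifs)
  category <- rep("not_PDL", n)
  promoter_gene <- rep(NA_character_, n)
  distal_gene <- rep(NA_character_, n)

  mid1 <- (sifs$start1 + sifs$end1) / 2
  mid2 <- (sifs$start2 + sifs$end2) / 2

  promoter_of <- function(chrom, mid) {
    g <- gw[gw$chrom == chrom & gw$prom_start <= mid & mid < gw$prom_end, ]
    if (nrow(g) == 0L) return(NA_character_)
    g <- g[order(abs(g$tss - mid), g$gene_id), ]
    g$gene_id[1]
  }
  in_distal <- function(chrom, mid) {
    g <- gw[gw$chrom == chrom, ]
    in_win <- any(g$distal_start <= mid & mid < g$distal_end)
    in_prom <- any(g$prom_start <= mid & mid < g$prom_end)
    in_win && !in_prom
  }
  closest_gene <- function(chrom, mid) {
    g <- gw[gw$chrom == chrom, ]
    if (nrow(g) == 0L) return(NA_character_)
    g <- g[order(abs(g$tss - mid), g$gene_id), ]
    g$gene_id[1]
  }

  for (i in seq_len(n)) {
    if (sifs$chrom1[i] != sifs$chrom2[i]) next
    chrom <- sifs$chrom1[i]
    p1 <- promoter_of(chrom, mid1[i])
    p2 <- promoter_of(chrom, mid2[i])
    # pick the promoter anchor; the other anchor must be distal
    if (!is.na(p1) && in_distal(chrom, mid2[i])) {
      prom <- p1; dmid <- mid2[i]
    } else if (!is.na(p2) && in_distal(chrom, mid1[i])) {
      prom <- p2; dmid <- mid1[i]
    } else {
      next
    }
    dg <- closest_gene(chrom, dmid)
    promoter_gene[i] <- prom
    distal_gene[i] <- dg
    category[i] <- if (identical(dg, prom)) "P1D1" else "P1D2"
  }

  dplyr::mutate(
    sifs,
    category = factor(category, levels = c("P1D1", "P1D2", "not_PDL")),
    promoter_gene = promoter_gene,
    distal_gene = distal_gene
  )
}

# Reciprocal anchor-pair matching between two loop sets after extending each
# anchor by `slack` bp on each side. Returns a logical vector per row of `a`:
# does it match any row of `b`?
match_loops <- function(a, b, slack = 0) {
  if (nrow(a) == 0L) return(logical(0))
  out <- logical(nrow(a))
  if (nrow(b) == 0L) return(out)
  key_a <- paste(a$chrom1, a$chrom2)
  by_key <- split(seq_len(nrow(b)), paste(b$chrom1, b$chrom2))
  for (i in seq_len(nrow(a))) {
    cand <- by_key[[key_a[i]]]
    if (is.null(cand)) next
    ov1 <- b$start1[cand] - slack < a$end1[i] + slack &
      a$start1[i] - slack < b$end1[cand] + slack
    ov2 <- b$start2[cand] - slack < a$end2[i] + slack &
      a$start2[i] - slack < b$end2[cand] + slack
    out[i] <- any(ov1 & ov2)
  }
  out
}

#' Compare SIF sets between two conditions
#'
#' Two SIFs match when both anchor pairs reciprocally overlap after
#' extending each anchor by `slack` bp on each side. A SIF is "common" when
#' it matches at least one SIF in the other set; matching is one-to-many
#' aware, so the two sides of the resulting Venn overlap may count different
#' numbers of SIFs.
#'
#' @param sifs_a,sifs_b SIF tibbles from two conditions (same genome build).
#' @param slack Anchor extension in bp (default 0).
#' @return A list with tibbles `common_a`, `common_b`, `unique_a` (lost in
#'   b), `unique_b` (gained in b) and a one-row `counts` tibble.
#' @export
compare_conditions <- function(sifs_a, sifs_b, slack = 0) {
  in_b <- match_loops(sifs_a, sifs_b, slack)
  in_a <- match_loops(sifs_b, sifs_a, slack)
  list(
    common_a = sifs_a[in_b, ],
    common_b = sifs_b[in_a, ],
    unique_a = sifs_a[!in_b, ],
    unique_b = sifs_b[!in_a, ],
    counts = tibble::tibble(
      n_a = nrow(sifs_a), n_b = nrow(sifs_b),
      common_a = sum(in_b), common_b = sum(in_a),
      unique_a = sum(!in_b), unique_b = sum(!in_a)
    )
  )
}

#' Replicate-overlap fractions across anchor sizes and FDR cut-offs
#'
#' For every combination of anchor extension and FDR cut-off, both SIF sets
#' are restricted to calls with `fdr < cutoff`, anchors are resized around
#' their midpoints to at least the stated fragment size, and the fraction of
#' set-a SIFs matched in set-b is reported. An empty set-a after the cut-off
#' yields `NA` (undefined), not 0.
#'
#' @param sifs_a,sifs_b SIF tibbles carrying `fdr`.
#' @param extensions Numeric vector of anchor sizes (bp).
#' @param fdr_cutoffs Numeric vector of FDR cut-offs.
#' @return A tibble `extension`, `fdr_cutoff`, `n_a`, `n_b`, `overlap`
#'   (fraction of a matched in b).
#' @export
replicate_overlap <- function(sifs_a, sifs_b,
                              extensions = c(5000, 10000, 20000),
                              fdr_cutoffs = c(0.05, 0.1, 0.25)) {
  resize <- function(s, size) {
    w1 <- s$end1 - s$start1
    w2 <- s$end2 - s$start2
    g1 <- pmax(0, (size - w1) / 2)
    g2 <- pmax(0, (size - w2) / 2)
    dplyr::mutate(s,
                  start1 = floor(.data$start1 - g1),
                  end1 = ceiling(.data$end1 + g1),
                  start2 = floor(.data$start2 - g2),
                  end2 = ceiling(.data$end2 + g2))
  }
  grid <- tidyr::expand_grid(extension = extensions,
                             fdr_cutoff = fdr_cutoffs)
  purrr::pmap_dfr(grid, function(extension, fdr_cutoff) {
    a <- resize(sifs_a[sifs_a$fdr < fdr_cutoff, ], extension)
    b <- resize(sifs_b[sifs_b$fdr < fdr_cutoff, ], extension)
    frac <- if (nrow(a) == 0L) NA_real_ else mean(match_loops(a, b))
    tibble::tibble(extension = extension, fdr_cutoff = fdr_cutoff,
                   n_a = nrow(a), n_b = nrow(b), overlap = frac)
  })
}
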