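#' Read paired-end contacts
#'
#' Reads a tab-delimited 7-column pairs file
#' (`readID chr1 pos1 chr2 pos2 strand1 strand2`); lines starting with `#`
#' are ignored. Pairs are normalised so that end 1 is not after end 2 in
#' genome order (chromosome name, then position).
#'
#' @param path Pairs file path.
#' @return A tibble with columns `read_id`, `chrom1`, `pos1`, `strand1`,
#'   `chrom2`, `pos2`, `strand2`.
#' @export
read_pairs <- function(path) {
  df <- readr::read_tsv(
    path,
    col_names = c("read_id", "chrom1", "pos1", "chrom2", "pos2",
                  "strand1", "strand2"),
    col_types = "ccicicc", comment = "#", progress = FALSE
  )
  normalize_pairs(tibble::tibble(
    read_id = df$read_id,
    chrom1 = df$chrom1, pos1 = df$pos1, strand1 = df$strand1,
    chrom2 = df$chrom2, pos2 = df$pos2, strand2 = df$strand2
  ))
}

#' Normalise pair orientation
#'
#' Swaps ends so that (`chrom1`, `pos1`) <= (`chrom2`, `pos2`) in genome
#' order. Strands travel with their ends.
#'
#' @param pairs Pairs tibble (see [read_pairs()]).
#' @return The pairs tibble with ends ordered.
#' @export
normalize_pairs <- function(pairs) {
  swap <- pairs$chrom2 < pairs$chrom1 |
    (pairs$chrom1 == pairs$chrom2 & pairs$pos2 < pairs$pos1)
  out <- pairs
  out$chrom1[swap] <- pairs$chrom2[swap]
  out$pos1[swap] <- pairs$pos2[swap]
  out$strand1[swap] <- pairs$strand2[swap]
  out$chrom2[swap] <- pairs$chrom1[swap]
  out$pos2[swap] <- pairs$pos1[swap]
  out$strand2[swap] <- pairs$strand1[swap]
  out
}

#' Write paired-end contacts
#'
#' @param pairs Pairs tibble.
#' @param path Output path.
#' @param header Optional character vector of `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path, header = NULL) {
  out <- pairs[, c("read_id", "chrom1", "pos1", "chrom2", "pos2",
                   "strand1", "strand2")]
  write_tsv_with_header(out, path, header)
}

#' Read a BEDPE interval-pair file
#'
#' @param path BEDPE path; at least six columns
#'   (`chrom1 start1 end1 chrom2 start2 end2`), optionally `name`, `score`
#'   and further numeric columns, which are kept under their header-less
#'   positional names `name`, `score`, `fdr`, `res1`, `res2`.
#' @return A tibble.
#' @export
read_bedpe <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         progress = FALSE, show_col_types = FALSE)
  base <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "name", "score", "fdr", "res1", "res2")
  nm <- base[seq_len(min(ncol(raw), length(base)))]
  if (ncol(raw) > length(base)) {
    nm <- c(nm, paste0("extra", seq_len(ncol(raw) - length(base))))
  }
  names(raw) <- nm
  for (col in intersect(c("start1", "end1", "start2", "end2", "res1", "res2"),
                        names(raw))) {
    raw[[col]] <- as.integer(raw[[col]])
  }
  tibble::as_tibble(raw)
}

#' Write a BEDPE interval-pair file
#'
#' Writes the six coordinate columns plus any of `name`, `score`, `fdr`,
#' `res1`, `res2` that are present, in that order.
#'
#' @param x Tibble with BEDPE columns.
#' @param path Output path.
#' @param header Optional `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(x, path, header = NULL) {
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "name", "score", "fdr", "res1", "res2")
  out <- x[, intersect(cols, names(x))]
  write_tsv_with_header(out, path, header)
}

#' Read gene annotation (TSS table)
#'
#' Reads either a GTF (gene feature lines; TSS = `start - 1` for `+` strand,
#' `end - 1` for `-` strand, converted to 0-based) or a 6-column BED
#' (`chrom start end name score strand`; TSS = `start` for `+`, `end - 1`
#' for `-`).
#'
#' @param path GTF (`.gtf`) or BED file path.
#' @param format `"auto"` (by extension), `"gtf"` or `"bed"`.
#' @return A tibble with columns `gene_id`, `chrom`, `tss` (0-based),
#'   `strand`.
#' @export
read_genes <- function(path, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf"
              else "bed"
  }
  if (format == "gtf") {
    gtf <- readr::read_tsv(
      path,
      col_names = c("chrom", "source", "feature", "start", "end", "gtf_score",
                    "strand", "frame", "attribute"),
      col_types = "cccddcccc", comment = "#", progress = FALSE
    )
    gtf <- gtf[gtf$feature == "gene", ]
    gid <- stringr::str_match(gtf$attribute, 'gene_id[ =]+"?([^";]+)"?')[, 2]
    tibble::tibble(
      gene_id = gid,
      chrom = gtf$chrom,
      tss = as.integer(ifelse(gtf$strand == "+", gtf$start - 1, gtf$end - 1)),
      strand = gtf$strand
    )
  } else {
    bed <- readr::read_tsv(
      path,
      col_names = c("chrom", "start", "end", "name", "score", "strand"),
      col_types = "ciiccc", comment = "#", progress = FALSE
    )
    tibble::tibble(
      gene_id = bed$name,
      chrom = bed$chrom,
      tss = as.integer(ifelse(bed$strand == "+", bed$start, bed$end - 1L)),
      strand = bed$strand
    )
  }
}

#' Read a binned contact matrix from text triples
#'
#' Reads a sparse upper-triangular binned contact matrix stored as
#' whitespace-delimited `chrom bin_i bin_j count` rows. A header line of the
#' form `# bin_size=5000` declares the bin size; alternatively pass
#' `bin_size` explicitly.
#'
#' @param path Triples file path.
#' @param bin_size Bin size in bp (overrides any header).
#' @return A tibble `chrom`, `bin_i`, `bin_j`, `count` (with `bin_i <=
#'   bin_j`), carrying attribute `bin_size`.
#' @export
read_contact_matrix <- function(path, bin_size = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(bin_size) && grepl("bin_size\\s*=\\s*[0-9]+", first)) {
    bin_size <- as.integer(sub(".*bin_size\\s*=\\s*([0-9]+).*", "\\1", first))
  }
  if (is.null(bin_size)) {
    stop("Bin size not given and no 'bin_size=' header found", call. = FALSE)
  }
  df <- readr::read_tsv(path, col_names = c("chrom", "bin_i", "bin_j", "count"),
                        col_types = "ciid", comment = "#", progress = FALSE)
  i <- pmin(df$bin_i, df$bin_j)
  j <- pmax(df$bin_i, df$bin_j)
  out <- tibble::tibble(chrom = df$chrom, bin_i = i, bin_j = j,
                        count = df$count)
  attr(out, "bin_size") <- bin_size
  out
}

#' Write a binned contact matrix as text triples
#'
#' @param mat Contact-matrix tibble with attribute `bin_size` (or pass
#'   `bin_size`).
#' @param path Output path.
#' @param bin_size Bin size in bp.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(mat, path, bin_size = attr(mat, "bin_size")) {
  write_tsv_with_header(mat[, c("chrom", "bin_i", "bin_j", "count")], path,
                        paste0("bin_size=", bin_size))
}

# Write optional '#'-prefixed header lines, then the body as header-less TSV.
write_tsv_with_header <- function(df, path, header = NULL) {
  if (is.null(header)) {
    readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  } else {
    writeLines(paste0("#", sub("^#", "", header)), path)
    readr::write_tsv(df, path, col_names = FALSE, append = TRUE,
                     progress = FALSE)
  }
  invisible(path)
}
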