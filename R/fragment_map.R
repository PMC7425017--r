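#' Built-in restriction enzyme presets
#'
#' Recognition sites and cut offsets for the enzymes commonly used in Hi-C
#' library preparation. HindIII (`A^AGCTT`) is a 6-cutter producing ~4 kb
#' fragments on mammalian genomes; MboI and DpnII (`^GATC`) are 4-cutters
#' producing ~256 bp fragments.
#'
#' @param enzyme One of `"HindIII"`, `"MboI"`, `"DpnII"`.
#' @return A list with elements `site` (recognition motif) and `cut_offset`
#'   (0-based cut position within the motif).
#' @export
#' @examples
#' enzyme_preset("HindIII")
enzyme_preset <- function(enzyme) {
  presets <- list(
    HindIII = list(site = "AAGCTT", cut_offset = 1L),
    MboI    = list(site = "GATC",   cut_offset = 0L),
    DpnII   = list(site = "GATC",   cut_offset = 0L)
  )
  if (!enzyme %in% names(presets)) {
    stop("Unknown enzyme preset: ", enzyme,
         ". Available: ", paste(names(presets), collapse = ", "), call. = FALSE)
  }
  presets[[enzyme]]
}

validate_site <- function(site, cut_offset) {
  if (!is.character(site) || length(site) != 1L || nchar(site) == 0L) {
    stop("`site` must be a non-empty motif string", call. = FALSE)
  }
  site <- toupper(site)
  if (grepl("[^ACGT]", site)) {
    stop("Degenerate (IUPAC) recognition sites are not supported; ",
         "`site` must contain only A, C, G, T", call. = FALSE)
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(site)))
  if (rc != site) {
    stop("Non-palindromic recognition site '", site,
         "': forward-strand-only digestion would miss cuts", call. = FALSE)
  }
  if (!is.numeric(cut_offset) || length(cut_offset) != 1L ||
      cut_offset < 0 || cut_offset > nchar(site)) {
    stop("`cut_offset` must be in [0, nchar(site)]", call. = FALSE)
  }
  list(site = site, cut_offset = as.integer(cut_offset))
}

#' Digest genome sequences in silico
#'
#' Scans each sequence for a literal restriction-site motif on the forward
#' strand (overlapping occurrences included) and places a cut at
#' `occurrence_start + cut_offset` (0-based). The resulting restriction
#' fragments are the half-open intervals between consecutive cuts plus the
#' sequence ends; zero-length fragments from cuts coinciding with sequence
#' ends are dropped. Only palindromic, non-degenerate sites are accepted, so
#' the forward-strand scan is exhaustive.
#'
#' @param sequences A named character vector of DNA sequences, a
#'   [Biostrings::DNAStringSet], or the path to a FASTA file.
#' @param site Recognition motif (literal, ACGT only, palindromic). Ignored if
#'   `enzyme` is given.
#' @param cut_offset 0-based cut position within the motif. Ignored if
#'   `enzyme` is given.
#' @param enzyme Optional preset name passed to [enzyme_preset()].
#' @return A fragment map: a tibble with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `index` (0-based ordinal within chromosome),
#'   sorted, non-overlapping and tiling each sequence. The enzyme name, site
#'   and cut offset are stored as attributes `enzyme`, `site`, `cut_offset`;
#'   chromosome lengths as attribute `chrom_sizes`.
#' @export
#' @examples
#' digest_genome(c(chr1 = "AAAAGCTTAAA"), enzyme = "HindIII")
digest_genome <- function(sequences, site = NULL, cut_offset = NULL,
                          enzyme = NULL) {
  if (!is.null(enzyme)) {
    preset <- enzyme_preset(enzyme)
    site <- preset$site
    cut_offset <- preset$cut_offset
  } else {
    enzyme <- "custom"
  }
  if (is.null(site) || is.null(cut_offset)) {
    stop("Provide either `enzyme` or both `site` and `cut_offset`",
         call. = FALSE)
  }
  v <- validate_site(site, cut_offset)

  if (is.character(sequences) && length(sequences) == 1L &&
      is.null(names(sequences)) && file.exists(sequences)) {
    sequences <- Biostrings::readDNAStringSet(sequences)
    names(sequences) <- sub("\\s.*$", "", names(sequences))
  }
  if (is.character(sequences)) {
    if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
      stop("`sequences` must be named by chromosome", call. = FALSE)
    }
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  if (length(sequences) == 0L) {
    stop("Empty sequence set", call. = FALSE)
  }

  frags <- purrr::map2_dfr(as.list(sequences), names(sequences),
                           function(seq, chrom) {
    len <- length(seq)
    hits <- Biostrings::matchPattern(v$site, seq)
    cuts <- BiocGenerics::start(hits) - 1L + v$cut_offset  # 0-based cut coords
    bounds <- sort(unique(c(0L, cuts, len)))
    bounds <- bounds[bounds >= 0L & bounds <= len]
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1L]
    keep <- ends > starts
    tibble::tibble(chrom = chrom, start = starts[keep], end = ends[keep])
  })
  frags <- dplyr::group_by(frags, .data$chrom)
  frags <- dplyr::mutate(dplyr::arrange(frags, .data$start),
                         index = dplyr::row_number() - 1L)
  frags <- dplyr::ungroup(frags)

  chrom_sizes <- stats::setNames(BiocGenerics::width(sequences),
                                 names(sequences))
  new_fragment_map(frags, enzyme = enzyme, site = v$site,
                   cut_offset = v$cut_offset, chrom_sizes = chrom_sizes)
}

new_fragment_map <- function(frags, enzyme = NA_character_,
                             site = NA_character_, cut_offset = NA_integer_,
                             chrom_sizes = NULL) {
  frags <- tibble::as_tibble(frags)[, c("chrom", "start", "end", "index")]
  frags$start <- as.integer(frags$start)
  frags$end <- as.integer(frags$end)
  frags$index <- as.integer(frags$index)
  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(frags$end, frags$chrom, max)
    chrom_sizes <- stats::setNames(as.integer(chrom_sizes), names(chrom_sizes))
  }
  attr(frags, "enzyme") <- enzyme
  attr(frags, "site") <- site
  attr(frags, "cut_offset") <- as.integer(cut_offset)
  attr(frags, "chrom_sizes") <- chrom_sizes
  frags
}

#' Assign genomic positions to restriction fragments
#'
#' Looks up, for each (chrom, pos), the unique fragment with
#' `start <= pos < end` under the 0-based half-open convention.
#'
#' @param map A fragment map tibble from [digest_genome()] or
#'   [read_fragment_bed()].
#' @param chrom,pos Vectors (recycled to common length) of chromosome names
#'   and 0-based positions.
#' @return A tibble with one row per query: `chrom`, `start`, `end`, `index`.
#' @export
assign_to_fragment <- function(map, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(pos, n)
  bad <- !chrom %in% unique(map$chrom)
  if (any(bad)) {
    stop("Unknown chromosome(s): ",
         paste(unique(chrom[bad]), collapse = ", "), call. = FALSE)
  }
  hit <- fragment_index_of(map, chrom, pos)
  tibble::tibble(chrom = chrom, start = hit$start, end = hit$end,
                 index = hit$index)
}

# Fast path used internally: returns integer fragment index (0-based) and the
# fragment start/end, vectorised, without per-row tibble assembly.
fragment_index_of <- function(map, chrom, pos) {
  n <- length(pos)
  index <- integer(n)
  start <- integer(n)
  end <- integer(n)
  ok <- logical(n)
  for (cn in unique(chrom)) {
    sub <- map[map$chrom == cn, ]
    if (nrow(sub) == 0L) next
    sub <- sub[order(sub$start), ]
    sel <- which(chrom == cn)
    p <- pos[sel]
    j <- findInterval(p, sub$start)
    valid <- j >= 1L & p < sub$end[pmax(j, 1L)]
    index[sel] <- sub$index[pmax(j, 1L)]
    start[sel] <- sub$start[pmax(j, 1L)]
    end[sel] <- sub$end[pmax(j, 1L)]
    ok[sel] <- valid
  }
  if (!all(ok)) {
    stop("Position(s) not assignable to any fragment", call. = FALSE)
  }
  tibble::tibble(index = index, start = start, end = end)
}

#' Write a fragment map to BED
#'
#' Serialises the map as 4-column BED (`chrom start end name`) with names
#' `frag_<chrom>_<index>`.
#'
#' @param map Fragment map tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fragment_bed <- function(map, path) {
  out <- tibble::tibble(
    chrom = map$chrom, start = map$start, end = map$end,
    name = paste0("frag_", map$chrom, "_", map$index)
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a fragment map from BED
#'
#' @param path 4-column BED file as written by [write_fragment_bed()].
#' @return A fragment map tibble (see [digest_genome()]).
#' @export
read_fragment_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                         col_types = "ciic", comment = "#", progress = FALSE)
  frags <- dplyr::group_by(bed, .data$chrom)
  frags <- dplyr::mutate(dplyr::arrange(frags, .data$start),
                         index = dplyr::row_number() - 1L)
  frags <- dplyr::ungroup(frags)
  new_fragment_map(frags)
}
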