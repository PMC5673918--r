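#' Tile a genome into fixed-width bins
#'
#' Divides each chromosome into non-overlapping, contiguous windows of
#' `bin_width` base pairs (1 Mb by default, the resolution at which large
#' somatic copy-number alterations are visible in ~0.1x coverage data). The
#' last bin of a chromosome is truncated at the chromosome end. Coordinates
#' are 0-based, half-open.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in base
#'   pairs, or a two-column data frame (chromosome, length).
#' @param bin_width Bin width in base pairs.
#'
#' @return A tibble with columns `chrom`, `start`, `end`, `bin` (1..T) and
#'   `valid` (all `TRUE`; see [mask_gaps()]).
#' @examples
#' build_bin_grid(c(chr1 = 2.5e6), bin_width = 1e6)
#' @export
build_bin_grid <- function(chrom_sizes, bin_width = 1e6) {
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- setNames(as.numeric(chrom_sizes[[2]]), as.character(chrom_sizes[[1]]))
  }
  if (length(chrom_sizes) == 0) {
    abort("`chrom_sizes` is empty; at least one chromosome is required.")
  }
  if (any(!is.finite(chrom_sizes)) || any(chrom_sizes <= 0)) {
    abort("all chromosome lengths must be positive and finite.")
  }
  if (!is.finite(bin_width) || bin_width <= 0) {
    abort("`bin_width` must be positive.")
  }
  grid <- purrr::imap(chrom_sizes, function(len, chrom) {
    starts <- seq(0, len - 1, by = bin_width)
    tibble::tibble(chrom = chrom, start = starts, end = pmin(starts + bin_width, len))
  }) |>
    purrr::list_rbind()
  grid$bin <- seq_len(nrow(grid))
  grid$valid <- TRUE
  grid
}

#' Read a UCSC-style chrom.sizes file
#'
#' @param path Two-column tab-separated file (chromosome, length).
#' @param chroms Optional subset of chromosome names to keep, in the given
#'   order.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path, chroms = NULL) {
  tab <- utils::read.table(path, sep = "\t", col.names = c("chrom", "size"),
                           colClasses = c("character", "numeric"))
  sizes <- setNames(tab$size, tab$chrom)
  if (!is.null(chroms)) {
    miss <- setdiff(chroms, names(sizes))
    if (length(miss) > 0) abort(paste0("chromosomes not in file: ", paste(miss, collapse = ", ")))
    sizes <- sizes[chroms]
  }
  sizes
}

#' hg19 chromosome sizes
#'
#' Chromosome lengths for the hg19 human reference, shipped with the package.
#'
#' @param chroms Which chromosomes to return; defaults to the 22 autosomes.
#' @return Named numeric vector of lengths.
#' @export
hg19_chrom_sizes <- function(chroms = paste0("chr", 1:22)) {
  read_chrom_sizes(system.file("extdata", "hg19.chrom.sizes", package = "ulpcna"),
                   chroms = chroms)
}

#' hg19 centromere gap regions
#'
#' Centromere coordinates (UCSC gap table, acen) for hg19 as a tibble of
#' 0-based half-open intervals, for use with [mask_gaps()].
#'
#' @return Tibble with columns `chrom`, `start`, `end`.
#' @export
hg19_centromeres <- function() {
  tab <- utils::read.table(
    system.file("extdata", "hg19_centromeres.bed", package = "ulpcna"),
    sep = "\t", col.names = c("chrom", "start", "end"),
    colClasses = c("character", "numeric", "numeric")
  )
  tibble::as_tibble(tab)
}

#' Count aligned reads per bin
#'
#' Each read increments exactly one bin: the bin containing its (1-based)
#' leftmost aligned position. Reads on chromosomes absent from the grid are
#' skipped and their number recorded in the `skipped_reads` attribute, so
#' `sum(count) + skipped_reads` equals the number of input reads.
#'
#' @param reads Data frame with columns `chrom` and `pos` (1-based leftmost
#'   aligned position).
#' @param grid A bin grid from [build_bin_grid()].
#' @return The grid with a `count` column added.
#' @export
count_reads_in_bins <- function(reads, grid) {
  assert_columns(reads, c("chrom", "pos"), "reads")
  assert_columns(grid, c("chrom", "start", "end", "bin"), "grid")
  known <- reads$chrom %in% unique(grid$chrom)
  skipped <- sum(!known)
  if (skipped > 0) {
    inform(sprintf("skipped %d read(s) on chromosomes absent from the bin grid", skipped))
  }
  reads <- reads[known, , drop = FALSE]
  counts <- integer(nrow(grid))
  for (ch in unique(grid$chrom)) {
    g <- grid[grid$chrom == ch, ]
    pos <- reads$pos[reads$chrom == ch]
    if (length(pos) == 0) next
    idx <- findInterval(pos - 1, g$start)  # 0-based position vs bin starts
    counts[g$bin] <- counts[g$bin] + tabulate(idx, nbins = nrow(g))
  }
  out <- grid
  out$count <- counts
  attr(out, "skipped_reads") <- skipped
  out
}

#' Count reads per bin from a coordinate-sorted BAM file
#'
#' Thin wrapper over `Rsamtools` that streams read positions into
#' [count_reads_in_bins()]. Duplicate-flagged reads are excluded by default,
#' matching the convention that duplicates are removed before coverage
#' analysis.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param grid A bin grid.
#' @param exclude_duplicates Drop reads with the duplicate flag set.
#' @param min_mapq Minimum mapping quality.
#' @return The grid with a `count` column.
#' @export
count_reads_bam <- function(bam, grid, exclude_duplicates = TRUE, min_mapq = 0) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("BAM input requires the Rsamtools package.")
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isDuplicate = if (exclude_duplicates) FALSE else NA
  )
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("rname", "pos", "mapq"))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(res$pos) & (is.na(res$mapq) | res$mapq >= min_mapq)
  reads <- tibble::tibble(chrom = as.character(res$rname)[keep], pos = res$pos[keep])
  count_reads_in_bins(reads, grid)
}

#' Mask bins near assembly gaps
#'
#' Marks invalid every bin overlapping a gap interval or lying within `flank`
#' base pairs of one (one 1 Mb bin up- and downstream by default, which
#' removes centromere-adjacent bins whose coverage is unreliable). Gaps are
#' 0-based half-open. The operation is idempotent and never re-validates a
#' bin.
#'
#' @param grid A bin grid.
#' @param gaps Data frame with columns `chrom`, `start`, `end`.
#' @param flank Flank in base pairs added on both sides of each gap.
#' @return The grid with its `valid` column updated.
#' @export
mask_gaps <- function(grid, gaps, flank = 1e6) {
  assert_columns(grid, c("chrom", "start", "end", "valid"), "grid")
  if (is.null(gaps) || nrow(gaps) == 0) return(grid)
  assert_columns(gaps, c("chrom", "start", "end"), "gaps")
  hit <- rep(FALSE, nrow(grid))
  for (i in seq_len(nrow(gaps))) {
    lo <- gaps$start[i] - flank
    hi <- gaps$end[i] + flank
    hit <- hit | (grid$chrom == gaps$chrom[i] & grid$start < hi & grid$end > lo)
  }
  grid$valid <- grid$valid & !hit
  grid
}

#' Read gap/centromere regions from a BED file
#'
#' @param path BED file of gap intervals (0-based half-open, as BED).
#' @return Tibble with columns `chrom`, `start`, `end`.
#' @export
read_gaps_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("BED input requires the rtracklayer package.")
  }
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  tibble::tibble(
    chrom = as.character(gr$seqnames),
    start = gr$start - 1,  # back to BED's 0-based starts
    end = as.numeric(gr$end)
  )
}
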