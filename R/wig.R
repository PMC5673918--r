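#' Write a per-bin track as fixedStep WIG
#'
#' Emits one `fixedStep` block per chromosome with `start=1` (WIG is
#' 1-based) and step/span equal to the bin width. A truncated final bin is
#' written as an ordinary value line under the same span, the dialect used
#' by bin-level read counters. Integer values are written exactly, so a
#' write/read cycle is bit-exact for integer counts.
#'
#' @param track Tibble with `chrom`, `start`, `end` and the value column.
#' @param path Output file.
#' @param value Name of the column to write.
#' @export
write_wig <- function(track, path, value = "count") {
  assert_columns(track, c("chrom", "start", "end", value), "track")
  width <- as.integer(max(track$end - track$start))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in unique(track$chrom)) {
    rows <- track[track$chrom == ch, ]
    writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d", ch, width, width), con)
    v <- rows[[value]]
    out <- if (is.integer(v) || all(v == round(v), na.rm = TRUE)) {
      format(v, scientific = FALSE, trim = TRUE)
    } else {
      format(v, digits = 17, scientific = FALSE, trim = TRUE)
    }
    writeLines(out, con)
  }
  invisible(path)
}

#' Read a fixedStep WIG file into a bin track
#'
#' @param path WIG file with one fixedStep block per chromosome.
#' @param chrom_sizes Optional named vector of chromosome lengths used to
#'   truncate the final bin of each chromosome; without it every bin spans
#'   the declared step.
#' @param value Name for the value column.
#' @return Tibble with `chrom`, `start`, `end`, `bin`, `valid` and the value
#'   column.
#' @export
read_wig <- function(path, chrom_sizes = NULL, value = "count") {
  lines <- readLines(path)
  hdr <- grepl("^fixedStep", lines)
  if (!any(hdr)) abort("no fixedStep header found; only fixedStep WIG is supported")
  blocks <- cumsum(hdr)
  out <- vector("list", max(blocks))
  for (b in seq_len(max(blocks))) {
    block <- lines[blocks == b]
    head <- block[1]
    get_field <- function(name, default = NA_character_) {
      m <- regmatches(head, regexec(paste0(name, "=([^ ]+)"), head))[[1]]
      if (length(m) == 2) m[2] else default
    }
    chrom <- get_field("chrom")
    start1 <- as.numeric(get_field("start", "1"))
    step <- as.numeric(get_field("step"))
    vals <- as.numeric(block[-1])
    starts <- (start1 - 1) + step * (seq_along(vals) - 1)
    ends <- starts + step
    if (!is.null(chrom_sizes) && chrom %in% names(chrom_sizes)) {
      ends <- pmin(ends, chrom_sizes[[chrom]])
    }
    out[[b]] <- tibble::tibble(chrom = chrom, start = starts, end = ends, !!value := vals)
  }
  res <- purrr::list_rbind(out)
  res$bin <- seq_len(nrow(res))
  res$valid <- TRUE
  res[, c("chrom", "start", "end", "bin", "valid", value)]
}

#' Write copy-number segments in SEG format
#'
#' Standard tab-delimited SEG: sample, chromosome, 1-based start, end,
#' number of bins, median log2 ratio, plus the decoded state label.
#'
#' @param segments Segment tibble as produced by [path_to_segments()].
#' @param path Output file.
#' @param sample Sample identifier written in the first column.
#' @export
write_seg <- function(segments, path, sample = "sample") {
  out <- tibble::tibble(
    sample = sample,
    chrom = segments$chrom,
    start = segments$start + 1,  # SEG is 1-based inclusive
    end = segments$end,
    n_bins = segments$n_bins,
    median_l = segments$median_l,
    state = segments$state
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a SEG file written by [write_seg()]
#'
#' @param path SEG file.
#' @return Tibble of segments with 0-based half-open coordinates.
#' @export
read_seg <- function(path) {
  seg <- readr::read_tsv(path, show_col_types = FALSE)
  seg$start <- seg$start - 1
  seg
}
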