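#' Read a SEG file of log2 copy-number segments
#'
#' Parses the IGV SEG dialect: tab-delimited, header line, columns sample,
#' chromosome, start, end, optionally a number-of-markers column, and the
#' segment mean (log2 ratio) as the last column. SEG coordinates are 1-based
#' inclusive and are converted to the package-internal 0-based half-open
#' convention on read; \code{write_seg} converts back.
#'
#' @param path path to a SEG file.
#' @param header logical; set FALSE for the headerless variant (columns are
#'   then taken positionally: sample, chrom, start, end, \[num_mark,\]
#'   seg_mean).
#' @return a data.frame with columns \code{sample_id}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), \code{log2_ratio}.
#' @export
read_seg <- function(path, header = TRUE) {
  tab <- read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(tab) < 5)
    stop("malformed SEG file '", path, "': expected at least 5 columns, got ",
         ncol(tab))
  out <- data.frame(
    sample_id = as.character(tab[[1]]),
    chrom = as.character(tab[[2]]),
    start = suppressWarnings(as.numeric(tab[[3]])),
    end = suppressWarnings(as.numeric(tab[[4]])),
    log2_ratio = suppressWarnings(as.numeric(tab[[ncol(tab)]])),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(out$start) | is.na(out$end) | is.na(out$log2_ratio))
  if (length(bad) > 0)
    stop("malformed SEG file '", path, "': non-numeric fields at data line ",
         bad[1])
  validate_segments(out, one_based = TRUE)
  out$start <- out$start - 1  # to 0-based half-open
  out
}

#' @rdname read_seg
#' @param segments data.frame as returned by \code{read_seg} (0-based
#'   half-open coordinates).
#' @export
write_seg <- function(segments, path) {
  validate_segments(segments)
  out <- data.frame(
    sample = segments$sample_id,
    chrom = segments$chrom,
    start = format(segments$start + 1, scientific = FALSE, trim = TRUE),
    end = format(segments$end, scientific = FALSE, trim = TRUE),
    seg_mean = segments$log2_ratio
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_segments <- function(segments, one_based = FALSE) {
  req <- c("chrom", "start", "end", "log2_ratio")
  miss <- setdiff(req, names(segments))
  if (length(miss) > 0)
    stop("segment table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(segments) == 0) return(invisible(segments))
  if (any(!nzchar(segments$chrom)))
    stop("segment table: empty chromosome name")
  if (any(!is.finite(segments$log2_ratio)))
    stop("segment table: non-finite log2 ratio")
  lo <- if (one_based) segments$end < segments$start else segments$end <= segments$start
  if (any(lo))
    stop("segment table: segment end precedes start at row ", which(lo)[1])
  invisible(segments)
}
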