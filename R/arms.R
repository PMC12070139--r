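#' Load chromosome-arm definitions
#'
#' Reads a tab-delimited table of chromosome-arm bounds (the denominators for
#' arm-loss fractions). The bundled hg19-style table
#' (\code{system.file("extdata", "arms_hg19.tsv", package = "meningrisk")})
#' splits each autosome at the centromere gap: the p arm runs from 0 to the
#' gap start, the q arm from the gap end to the chromosome end.
#'
#' Coordinates are handled internally as 0-based half-open. Tables written in
#' 1-based inclusive convention (e.g., derived from UCSC cytoband browser
#' output) are converted on read via \code{one_based = TRUE}.
#'
#' @param path file path to a tab-delimited table with a header and columns
#'   \code{chrom}, \code{arm}, \code{start}, \code{end}; alternatively a
#'   data.frame with those columns.
#' @param one_based logical; if TRUE, input coordinates are 1-based inclusive
#'   and are converted to 0-based half-open.
#' @return a data.frame of class \code{mnr_arms} with columns \code{chrom},
#'   \code{arm}, \code{start}, \code{end}, \code{arm_key} (e.g. \code{"1p"})
#'   and \code{length}.
#' @export
load_arm_definitions <- function(path, one_based = FALSE) {
  tab <- if (is.data.frame(path)) path else read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "arm", "start", "end")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop("arm table is missing required column(s): ", paste(miss, collapse = ", "))
  tab <- tab[req]
  tab$chrom <- as.character(tab$chrom)
  tab$arm <- as.character(tab$arm)
  if (any(is.na(tab$chrom)) || any(!nzchar(tab$chrom)))
    stop("arm table: empty chromosome name")
  if (!all(tab$arm %in% c("p", "q")))
    stop("arm table: arm label must be 'p' or 'q'")
  tab$start <- as.numeric(tab$start)
  tab$end <- as.numeric(tab$end)
  if (any(is.na(tab$start)) || any(is.na(tab$end)))
    stop("arm table: non-numeric coordinates")
  if (one_based) tab$start <- tab$start - 1
  if (any(tab$end <= tab$start))
    stop("arm table: end must exceed start for every arm")
  if (any(duplicated(paste(tab$chrom, tab$arm))))
    stop("arm table: duplicated chromosome/arm entry")
  # p and q on one chromosome must not overlap
  for (chr in unique(tab$chrom)) {
    sub <- tab[tab$chrom == chr, ]
    if (nrow(sub) == 2) {
      p <- sub[sub$arm == "p", ]; q <- sub[sub$arm == "q", ]
      if (nrow(p) == 1 && nrow(q) == 1 &&
          max(p$start, q$start) < min(p$end, q$end))
        stop("arm table: p and q arms overlap on ", chr)
    }
  }
  tab$arm_key <- paste0(sub("^chr", "", tab$chrom), tab$arm)
  tab$length <- tab$end - tab$start
  class(tab) <- c("mnr_arms", "data.frame")
  tab
}

#' Load locus definitions
#'
#' Reads a tab-delimited table of named loci (header + columns \code{name},
#' \code{chrom}, \code{start}, \code{end}). The bundled table carries the
#' CDKN2A/B locus (9p21.3) used for the homozygous-deletion call.
#'
#' @inheritParams load_arm_definitions
#' @return a data.frame with columns \code{name}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open).
#' @export
load_locus_definitions <- function(path, one_based = FALSE) {
  tab <- if (is.data.frame(path)) path else read.delim(path, stringsAsFactors = FALSE)
  req <- c("name", "chrom", "start", "end")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop("locus table is missing required column(s): ", paste(miss, collapse = ", "))
  tab <- tab[req]
  tab$start <- as.numeric(tab$start)
  tab$end <- as.numeric(tab$end)
  if (one_based) tab$start <- tab$start - 1
  if (any(tab$end <= tab$start)) stop("locus table: end must exceed start")
  tab
}

#' Paths to the bundled hg19-style annotation tables
#'
#' @return file path of the packaged arm (resp. locus) definition table.
#' @export
default_arm_table <- function() {
  system.file("extdata", "arms_hg19.tsv", package = "meningrisk")
}

#' @rdname default_arm_table
#' @export
default_locus_table <- function() {
  system.file("extdata", "loci_hg19.tsv", package = "meningrisk")
}
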