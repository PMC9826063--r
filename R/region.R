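#' Define an amplicon target region
#'
#' A region is the reference interval spanned by a PCR amplicon: a contig
#' name, 1-based inclusive coordinates and the reference sequence of the
#' interval. All positions elsewhere in the package are 1-based genomic
#' coordinates on `contig` (VCF convention).
#'
#' @param contig contig/chromosome name.
#' @param start,end 1-based inclusive interval, `end >= start`.
#' @param reference_seq uppercase DNA string (A/C/G/T) of length
#'   `end - start + 1`.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(contig, start, end, reference_seq) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(contig) == 1L, is.character(contig),
            !is.na(start), !is.na(end), end >= start, start >= 1L)
  reference_seq <- toupper(reference_seq)
  if (nchar(reference_seq) != end - start + 1L)
    stop("reference_seq length (", nchar(reference_seq),
         ") does not match coordinates [", start, ", ", end, "]")
  if (grepl("[^ACGT]", reference_seq))
    stop("reference_seq contains characters outside {A,C,G,T}")
  structure(list(contig = contig, start = start, end = end,
                 reference_seq = reference_seq,
                 ref_chars = strsplit(reference_seq, "", fixed = TRUE)[[1]]),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("<region_spec> %s:%d-%d (%d bp)\n",
              x$contig, x$start, x$end, x$end - x$start + 1L))
  invisible(x)
}

region_length <- function(region) region$end - region$start + 1L

#' Reference base(s) at genomic position(s)
#' @param region a [region_spec()].
#' @param pos integer vector of 1-based positions inside the region.
#' @return character vector of bases.
#' @export
ref_base <- function(region, pos) {
  i <- as.integer(pos) - region$start + 1L
  if (any(i < 1L | i > region_length(region)))
    stop("position outside region ", region$contig, ":",
         region$start, "-", region$end)
  region$ref_chars[i]
}

#' Generate a random reference sequence for simulations
#' @param length sequence length in bp.
#' @param gc GC content.
#' @return DNA string.
#' @export
random_reference <- function(length, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
}

#' Write / read a region as FASTA
#'
#' The record is named `contig:start-end` so that coordinates survive a
#' round trip through the file.
#' @param region a [region_spec()].
#' @param file FASTA path.
#' @export
write_region_fasta <- function(region, file) {
  x <- Biostrings::DNAStringSet(region$reference_seq)
  names(x) <- sprintf("%s:%d-%d", region$contig, region$start, region$end)
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' @rdname write_region_fasta
#' @param file FASTA path written by [write_region_fasta()].
#' @export
read_region_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  nm <- names(x)[1]
  m <- regmatches(nm, regexec("^(\\S+):(\\d+)-(\\d+)", nm))[[1]]
  if (length(m) != 4L)
    stop("FASTA record name '", nm, "' is not of the form contig:start-end")
  region_spec(m[2], as.integer(m[3]), as.integer(m[4]),
              as.character(x[[1]]))
}

# logical vector over the region: TRUE where the base lies inside a
# homopolymer run of length >= min_run
homopolymer_mask <- function(region, min_run = 3L) {
  r <- rle(region$ref_chars)
  rep(r$lengths >= min_run, r$lengths)
}
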