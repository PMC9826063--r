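#' Aligned read sets
#'
#' Reads are held in a plain `data.frame` mirroring the mandatory SAM
#' columns: `qname`, `flag`, `rname`, `pos` (1-based leftmost aligned
#' position), `mapq`, `cigar`, `seq`, `qual` (phred+33 string). A read
#' *covers* a reference position only if the position is aligned to a
#' non-clipped, non-deleted read base; positions inside deletions are
#' reported with the distinct marker `"-"`, positions outside the alignment
#' as `NA`.
#'
#' @param qname,flag,rname,pos,mapq,cigar,seq,qual SAM fields.
#' @return data.frame of class `aligned_reads`.
#' @export
aligned_reads <- function(qname, flag, rname, pos, mapq, cigar, seq, qual) {
  df <- data.frame(qname = as.character(qname), flag = as.integer(flag),
                   rname = as.character(rname), pos = as.integer(pos),
                   mapq = as.integer(mapq), cigar = as.character(cigar),
                   seq = as.character(seq), qual = as.character(qual),
                   stringsAsFactors = FALSE)
  class(df) <- c("aligned_reads", "data.frame")
  df
}

int_to_qual <- function(q) {
  vapply(q, function(v) rawToChar(as.raw(v + 33L)), "", USE.NAMES = FALSE)
}

qual_to_int <- function(s) {
  lapply(s, function(v) as.integer(charToRaw(v)) - 33L)
}

parse_cigar <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  n <- nchar(toks)
  list(len = as.integer(substr(toks, 1L, n - 1L)),
       op = substr(toks, n, n))
}

# Resolve one alignment into per-base coordinates.
# Returns: ref_pos/q_idx for aligned (M/=/X) bases, deleted reference
# positions, and the reference position immediately left of each insertion.
decode_alignment <- function(pos, cigar, seq) {
  cg <- parse_cigar(cigar)
  rp <- pos; qp <- 1L
  ref_pos <- vector("list", length(cg$op))
  q_idx <- vector("list", length(cg$op))
  del <- vector("list", length(cg$op))
  ins <- vector("list", length(cg$op))
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]; len <- cg$len[k]
    if (op %in% c("M", "=", "X")) {
      ref_pos[[k]] <- rp:(rp + len - 1L)
      q_idx[[k]] <- qp:(qp + len - 1L)
      rp <- rp + len; qp <- qp + len
    } else if (op == "I") {
      ins[[k]] <- rp - 1L
      qp <- qp + len
    } else if (op == "D") {
      del[[k]] <- rp:(rp + len - 1L)
      rp <- rp + len
    } else if (op == "N") {
      rp <- rp + len
    } else if (op == "S") {
      qp <- qp + len
    } # H, P consume nothing tracked here
  }
  list(ref_pos = unlist(ref_pos), q_idx = unlist(q_idx),
       del_pos = unlist(del), ins_pos = unlist(ins))
}

#' Bases carried by each read at reference positions
#'
#' @param reads an [aligned_reads()] data.frame.
#' @param positions integer vector of reference positions.
#' @return A character matrix (reads x positions): the read base, `"-"` for
#'   a position spanned by a deletion in the read, `NA` where the read does
#'   not cover the position.
#' @export
bases_matrix <- function(reads, positions) {
  positions <- as.integer(positions)
  out <- matrix(NA_character_, nrow = nrow(reads), ncol = length(positions),
                dimnames = list(reads$qname, as.character(positions)))
  for (i in seq_len(nrow(reads))) {
    dec <- decode_alignment(reads$pos[i], reads$cigar[i], reads$seq[i])
    chars <- strsplit(reads$seq[i], "", fixed = TRUE)[[1]]
    j <- match(positions, dec$ref_pos)
    hit <- !is.na(j)
    out[i, hit] <- chars[dec$q_idx[j[hit]]]
    if (length(dec$del_pos))
      out[i, !hit & positions %in% dec$del_pos] <- DEL_MARK
  }
  out
}

#' @rdname bases_matrix
#' @param position a single reference position.
#' @export
bases_at <- function(reads, position) {
  drop(bases_matrix(reads, position))
}

#' Write aligned reads as SAM
#'
#' Emits a minimal coordinate-addressable SAM file with a single `@SQ`
#' header line covering the target contig.
#'
#' @param reads an [aligned_reads()] data.frame.
#' @param region a [region_spec()] supplying the contig header.
#' @param file output path.
#' @export
write_sam <- function(reads, region, file) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", region$contig, region$end))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  reads$qname, reads$flag, reads$rname, reads$pos,
                  reads$mapq, reads$cigar, reads$seq, reads$qual)
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' @rdname write_sam
#' @export
read_sam <- function(file) {
  ln <- readLines(file)
  ln <- ln[!startsWith(ln, "@")]
  if (!length(ln))
    return(aligned_reads(character(), integer(), character(), integer(),
                         integer(), character(), character(), character()))
  f <- strsplit(ln, "\t", fixed = TRUE)
  pick <- function(i) vapply(f, `[[`, "", i)
  aligned_reads(qname = pick(1), flag = as.integer(pick(2)),
                rname = pick(3), pos = as.integer(pick(4)),
                mapq = as.integer(pick(5)), cigar = pick(6),
                seq = pick(10), qual = pick(11))
}

# number of reference bases consumed by an alignment
cigar_ref_span <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "=", "X", "D", "N")])
}
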