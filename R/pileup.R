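#' Build a per-position pileup over a region
#'
#' Tabulates, for every reference position of the region, the count of each
#' base among covering reads, the number of reads whose deletion spans the
#' position, the number of insertion events anchored immediately right of
#' the position, and the mean base quality per base. Depth is defined as
#' base counts plus deletion count, so `A + C + G + T + del == depth` holds
#' by construction.
#'
#' @param reads an [aligned_reads()] data.frame (may be empty).
#' @param region a [region_spec()].
#' @return A data.frame of class `pileup` with one row per reference
#'   position: `pos`, `ref`, `A`, `C`, `G`, `T`, `del`, `ins`, `depth` and
#'   `mq_A` .. `mq_T` (mean phred quality, `NA` where a base is unseen).
#' @export
build_pileup <- function(reads, region) {
  L <- region_length(region)
  n <- nrow(reads)
  idx_l <- vector("list", n); qual_l <- vector("list", n)
  del_l <- vector("list", n); ins_l <- vector("list", n)
  for (i in seq_len(n)) {
    dec <- decode_alignment(reads$pos[i], reads$cigar[i], reads$seq[i])
    chars <- strsplit(reads$seq[i], "", fixed = TRUE)[[1]]
    quals <- if (reads$qual[i] == "*") rep(NA_integer_, nchar(reads$seq[i]))
             else as.integer(charToRaw(reads$qual[i])) - 33L
    off <- dec$ref_pos - region$start + 1L
    keep <- off >= 1L & off <= L
    b <- match(chars[dec$q_idx[keep]], BASES)
    okb <- !is.na(b)
    idx_l[[i]] <- (b[okb] - 1L) * L + off[keep][okb]
    qual_l[[i]] <- quals[dec$q_idx[keep]][okb]
    doff <- dec$del_pos - region$start + 1L
    del_l[[i]] <- doff[doff >= 1L & doff <= L]
    ioff <- dec$ins_pos - region$start + 1L
    ins_l[[i]] <- ioff[ioff >= 1L & ioff <= L]
  }
  idx <- as.integer(unlist(idx_l)); quals <- as.integer(unlist(qual_l))
  counts <- matrix(tabulate(idx, nbins = 4L * L), nrow = L,
                   dimnames = list(NULL, BASES))
  qsum <- matrix(0, nrow = L, ncol = 4L)
  qok <- !is.na(quals)
  if (any(qok)) {
    qs <- rowsum(as.numeric(quals[qok]), idx[qok])
    qsum[as.integer(rownames(qs))] <- qs[, 1]
  }
  del <- tabulate(as.integer(unlist(del_l)), nbins = L)
  ins <- tabulate(as.integer(unlist(ins_l)), nbins = L)
  mq <- qsum / counts
  mq[!is.finite(mq)] <- NA_real_
  out <- data.frame(pos = region$start:region$end,
                    ref = region$ref_chars,
                    A = counts[, "A"], C = counts[, "C"],
                    G = counts[, "G"], T = counts[, "T"],
                    del = del, ins = ins,
                    depth = rowSums(counts) + del,
                    mq_A = mq[, 1], mq_C = mq[, 2],
                    mq_G = mq[, 3], mq_T = mq[, 4],
                    stringsAsFactors = FALSE)
  class(out) <- c("pileup", "data.frame")
  out
}
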