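#' Quality-trim read ends and drop short reads
#'
#' Mirrors the standard pre-mapping clean-up on aligned reads: bases are
#' trimmed from both read ends while the terminal base quality is below
#' `q_threshold`, and reads retaining fewer than `min_len` bases are
#' removed. Trimming is applied to the alignment as well: the CIGAR loses
#' the trimmed columns (boundary deletions are dropped) and the alignment
#' start advances over trimmed reference-consuming bases. The operation is
#' idempotent.
#'
#' @param reads an [aligned_reads()] data.frame.
#' @param q_threshold phred threshold below which terminal bases are
#'   trimmed.
#' @param min_len minimum retained read length in bases.
#' @param on_missing_qual what to do with reads whose quality string is
#'   `"*"`: `"pass"` keeps them untrimmed with a warning, `"error"` stops.
#' @return the filtered reads, with an attribute `qc` carrying counts:
#'   `n_in`, `n_removed`, `bases_trimmed`.
#' @export
qc_reads <- function(reads, q_threshold = 10L, min_len = 30L,
                     on_missing_qual = c("pass", "error")) {
  on_missing_qual <- match.arg(on_missing_qual)
  n_in <- nrow(reads)
  keep <- logical(n_in)
  bases_trimmed <- 0L
  out <- reads
  warned <- FALSE
  for (i in seq_len(n_in)) {
    if (reads$qual[i] == "*") {
      if (on_missing_qual == "error") stop("read ", reads$qname[i],
                                           " has no base qualities")
      if (!warned) {
        warning("reads without base qualities passed through untrimmed")
        warned <- TRUE
      }
      keep[i] <- nchar(reads$seq[i]) >= min_len
      next
    }
    cg <- parse_cigar(reads$cigar[i])
    seqop <- rep(cg$op[cg$op != "D"], cg$len[cg$op != "D"])
    # deletion events: number of seq bases preceding each, and length
    d_after <- integer(0); d_len <- integer(0)
    nb <- 0L
    for (k in seq_along(cg$op)) {
      if (cg$op[k] == "D") {
        d_after <- c(d_after, nb); d_len <- c(d_len, cg$len[k])
      } else nb <- nb + cg$len[k]
    }
    q <- as.integer(charToRaw(reads$qual[i])) - 33L
    n <- length(q)
    t_left <- 0L
    while (t_left < n && q[t_left + 1L] < q_threshold) t_left <- t_left + 1L
    t_right <- 0L
    while (t_right < n - t_left && q[n - t_right] < q_threshold)
      t_right <- t_right + 1L
    n_keep <- n - t_left - t_right
    bases_trimmed <- bases_trimmed + t_left + t_right
    if (n_keep < min_len) next
    keep[i] <- TRUE
    if (t_left == 0L && t_right == 0L) next
    i1 <- t_left + 1L; i2 <- n - t_right
    # reference consumed by the trimmed left end
    shift <- sum(seqop[seq_len(t_left)] == "M") +
      sum(d_len[d_after <= t_left])
    inner <- d_after > t_left & d_after < i2
    key <- c(i1:i2, d_after[inner] + 0.5)
    op <- c(seqop[i1:i2], rep("D", sum(inner)))
    o <- order(key)
    ops_o <- op[o]
    lens_o <- rep(1L, length(ops_o))
    lens_o[ops_o == "D"] <- d_len[inner]  # D events stay in position order
    r <- rle(rep(ops_o, lens_o))
    out$cigar[i] <- paste0(r$lengths, r$values, collapse = "")
    out$pos[i] <- reads$pos[i] + shift
    out$seq[i] <- substr(reads$seq[i], i1, i2)
    out$qual[i] <- substr(reads$qual[i], i1, i2)
  }
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "qc") <- list(n_in = n_in, n_removed = sum(!keep),
                          bases_trimmed = bases_trimmed)
  res
}

#' Target manifest for pooled amplicon runs
#'
#' A manifest lists one row per pooled target: `sample_id`, `contig`,
#' `start`, `end` and the validated DNM (`dnm_pos`, `ref`, `alt`). Targets
#' in one pool must not overlap in genome coordinates, since demultiplexing
#' is by region extraction.
#'
#' @param file TSV path with the columns above.
#' @return data.frame of class `target_manifest`.
#' @export
read_manifest <- function(file) {
  m <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("sample_id", "contig", "start", "end", "dnm_pos", "ref", "alt")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  class(m) <- c("target_manifest", "data.frame")
  m
}

manifest_overlaps <- function(manifest) {
  n <- nrow(manifest)
  bad <- list()
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    if (manifest$contig[i] == manifest$contig[j] &&
        manifest$start[i] <= manifest$end[j] &&
        manifest$start[j] <= manifest$end[i])
      bad[[length(bad) + 1L]] <- c(manifest$sample_id[i],
                                   manifest$sample_id[j])
  }
  bad
}

#' Demultiplex pooled reads by genomic region
#'
#' Assigns each read to the unique target whose region contains the read's
#' alignment start; reads starting outside every region go to the
#' `unassigned` bin. Overlapping regions in the manifest are a hard error
#' (raised before any extraction), because assignment would be ambiguous.
#'
#' @param reads pooled [aligned_reads()].
#' @param manifest a manifest data.frame (see [read_manifest()]).
#' @return list with `targets` (named list of read sets, one per
#'   `sample_id`), `unassigned` (read set) and `counts` (named integer
#'   vector including `unassigned`).
#' @export
demultiplex_by_region <- function(reads, manifest) {
  bad <- manifest_overlaps(manifest)
  if (length(bad))
    stop("overlapping targets in manifest: ",
         paste(vapply(bad, paste, "", collapse = " / "), collapse = "; "))
  idx <- rep(NA_integer_, nrow(reads))
  for (k in seq_len(nrow(manifest))) {
    hit <- reads$rname == manifest$contig[k] &
      reads$pos >= manifest$start[k] & reads$pos <= manifest$end[k]
    idx[hit] <- k
  }
  targets <- lapply(seq_len(nrow(manifest)), function(k) {
    r <- reads[!is.na(idx) & idx == k, , drop = FALSE]
    rownames(r) <- NULL
    r
  })
  names(targets) <- manifest$sample_id
  unassigned <- reads[is.na(idx), , drop = FALSE]
  rownames(unassigned) <- NULL
  counts <- c(vapply(targets, nrow, 0L), unassigned = nrow(unassigned))
  list(targets = targets, unassigned = unassigned, counts = counts)
}
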