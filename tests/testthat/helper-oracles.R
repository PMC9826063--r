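# Independent brute-force oracles. These deliberately re-derive alignment
# coordinates with a character-by-character CIGAR walk (no shared code with
# the package internals) so that pileups, split groups and allele tables
# can be checked read by read.

oracle_base_at <- function(pos, cigar, seq, target) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  ops <- character(0)
  num <- ""
  for (ch in strsplit(cigar, "", fixed = TRUE)[[1]]) {
    if (ch >= "0" && ch <= "9") num <- paste0(num, ch)
    else {
      ops <- c(ops, rep(ch, as.integer(num)))
      num <- ""
    }
  }
  rp <- pos
  qp <- 1L
  for (op in ops) {
    if (op %in% c("M", "=", "X")) {
      if (rp == target) return(chars[qp])
      rp <- rp + 1L; qp <- qp + 1L
    } else if (op == "D") {
      if (rp == target) return("-")
      rp <- rp + 1L
    } else if (op == "N") {
      if (rp == target) return(NA_character_)
      rp <- rp + 1L
    } else if (op %in% c("I", "S")) {
      qp <- qp + 1L
    }
  }
  NA_character_
}

oracle_bases <- function(reads, target) {
  vapply(seq_len(nrow(reads)), function(i)
    oracle_base_at(reads$pos[i], reads$cigar[i], reads$seq[i], target),
    NA_character_)
}

oracle_pileup_column <- function(reads, target) {
  b <- oracle_bases(reads, target)
  c(A = sum(b == "A", na.rm = TRUE), C = sum(b == "C", na.rm = TRUE),
    G = sum(b == "G", na.rm = TRUE), T = sum(b == "T", na.rm = TRUE),
    del = sum(b == "-", na.rm = TRUE))
}

oracle_split_counts <- function(reads, dnm) {
  b <- oracle_bases(reads, dnm$position)
  c(ref = sum(b == dnm$ref_base, na.rm = TRUE),
    alt = sum(b == dnm$alt_base, na.rm = TRUE),
    other = sum(!is.na(b) & b != dnm$ref_base & b != dnm$alt_base),
    not_covering = sum(is.na(b)))
}

oracle_allele_table <- function(reads, p1, p2) {
  b1 <- oracle_bases(reads, p1)
  b2 <- oracle_bases(reads, p2)
  span <- !is.na(b1) & !is.na(b2)
  tab <- table(paste(b1[span], b2[span], sep = "|"))
  tab[order(names(tab))]
}

# Build full-span error-free reads carrying explicit bases at chosen
# positions on top of the reference (for constructed fixtures).
make_reads <- function(region, n, overrides = list(), prefix = "r") {
  tmpl <- strsplit(region$reference_seq, "", fixed = TRUE)[[1]]
  L <- length(tmpl)
  seqs <- character(n)
  for (i in seq_len(n)) {
    chars <- tmpl
    for (ov in overrides) {
      # ov: list(reads = indices, pos = position, base = base)
      if (i %in% ov$reads) chars[ov$pos - region$start + 1L] <- ov$base
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  aligned_reads(qname = sprintf("%s%04d", prefix, seq_len(n)), flag = 0L,
                rname = region$contig, pos = region$start, mapq = 60L,
                cigar = paste0(L, "M"), seq = seqs,
                qual = strrep(rawToChar(as.raw(33L + 30L)), L))
}

# small deterministic region with no homopolymer runs
flat_region <- function(len = 100L, contig = "ampl1", start = 1L) {
  region_spec(contig, start, start + len - 1L,
              paste(rep(c("A", "C", "G", "T"), length.out = len),
                    collapse = ""))
}

# random small simulated instance for oracle-equivalence checks
random_instance <- function(seed) {
  set.seed(seed)
  n_reads <- sample(5:50, 1)
  simulate_dnm_target(seed = seed, coverage = n_reads,
                      region_length = sample(80:200, 1),
                      isnp_offsets = sample(10:30, 1),
                      error = error_model(e_sub = runif(1, 0, 0.1),
                                          e_indel = runif(1, 0, 0.04)),
                      wes_coverage = 40)
}
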