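#' Split reads by their base at the DNM position
#'
#' The anchoring step: every read covering the validated DNM position is
#' assigned to `ref` (wild-type base), `alt` (validated mutant base) or
#' `other` (any other base, or a deletion spanning the position). Group
#' membership is determined solely by the read base at that position.
#'
#' @param reads an [aligned_reads()] data.frame.
#' @param dnm a [dnm_record()].
#' @return list of class `split_reads` with read subsets `ref`, `alt`,
#'   `other` and a `counts` vector (including `not_covering`).
#' @export
split_reads_by_dnm <- function(reads, dnm) {
  stopifnot(inherits(dnm, "dnm_record"))
  b <- bases_at(reads, dnm$position)
  covering <- !is.na(b)
  if (!any(covering))
    stop("no reads cover the DNM position ", dnm$position)
  grp <- function(sel) {
    r <- reads[sel, , drop = FALSE]; rownames(r) <- NULL; r
  }
  is_ref <- covering & b == dnm$ref_base
  is_alt <- covering & b == dnm$alt_base
  is_other <- covering & !is_ref & !is_alt
  structure(list(ref = grp(is_ref), alt = grp(is_alt), other = grp(is_other),
                 counts = c(ref = sum(is_ref), alt = sum(is_alt),
                            other = sum(is_other),
                            not_covering = sum(!covering)),
                 dnm = dnm),
            class = "split_reads")
}

#' Check candidate variants for agreement with the DNM-split read groups
#'
#' A genuine informative SNP lies on one haplotype, so the anchored
#' (DNM-alt) read group must look effectively homozygous for one of the
#' candidate's two alleles, and the majority allele must differ between
#' the two groups. Homogeneity is measured over the candidate's allele
#' pair only (reads showing a third/fourth base or a deletion at the
#' candidate position are sequencing error by construction and are
#' accounted for in the error metrics instead); this keeps the test
#' calibrated when the anchored group is small, as it is for mosaic DNMs.
#' A candidate produced by noise fails either test: noise is symmetric
#' across groups (equal majorities), and an unlinked mixture drags the
#' anchored-group majority towards 50%. The wild-type group is
#' deliberately *not* required to be homozygous, because a postzygotic DNM
#' legitimately leaves both iSNP bases in the wild-type group (the third
#' allelic form). The agreement score reported is the mean of the two
#' within-group majority fractions.
#'
#' @param groups a [split_reads_by_dnm()] result.
#' @param candidates a [call_variants()] (or polished) data.frame.
#' @param control a [phase_control()].
#' @return the heterozygous SNV candidates annotated with
#'   `alt_group_base`, `ref_group_base`, `f_alt_group`, `f_ref_group`,
#'   `n_alt_group`, `n_ref_group`, `agreement` and `status`
#'   (`"linked"`/`"discordant"`/`"insufficient"`).
#' @export
find_linked_variants <- function(groups, candidates,
                                 control = phase_control()) {
  stopifnot(inherits(groups, "split_reads"))
  cand <- candidates[candidates$type == "snv" & !candidates$is_dnm &
                       candidates$genotype == "het", , drop = FALSE]
  n <- nrow(cand)
  cols <- data.frame(alt_group_base = character(n),
                     ref_group_base = character(n),
                     f_alt_group = numeric(n), f_ref_group = numeric(n),
                     n_alt_group = integer(n), n_ref_group = integer(n),
                     agreement = numeric(n), status = character(n),
                     stringsAsFactors = FALSE)
  if (n) {
    bm_alt <- bases_matrix(groups$alt, cand$pos)
    bm_ref <- bases_matrix(groups$ref, cand$pos)
    for (i in seq_len(n)) {
      alleles <- c(cand$ref[i], cand$alt[i])
      maj <- function(bm) {
        b <- bm[, i]
        b <- b[!is.na(b)]
        nb <- length(b)
        n1 <- sum(b == alleles[1]); n2 <- sum(b == alleles[2])
        if (!nb || n1 + n2 == 0L)
          return(list(base = NA_character_, f = NA_real_, n = nb))
        list(base = alleles[if (n1 >= n2) 1L else 2L],
             f = max(n1, n2) / (n1 + n2), n = nb)
      }
      a <- maj(bm_alt); r <- maj(bm_ref)
      cols$alt_group_base[i] <- a$base; cols$ref_group_base[i] <- r$base
      cols$f_alt_group[i] <- a$f; cols$f_ref_group[i] <- r$f
      cols$n_alt_group[i] <- a$n; cols$n_ref_group[i] <- r$n
      cols$agreement[i] <- mean(c(a$f, r$f))
      cols$status[i] <-
        if (a$n < control$min_spanning || r$n < control$min_spanning)
          "insufficient"
        else if (is.na(a$f) || a$f < control$min_group_agreement)
          "discordant"
        else if (identical(a$base, r$base) && !is.na(r$f) &&
                 r$f >= control$min_group_agreement)
          "discordant"  # both groups homozygous for the same base
        else "linked"
    }
  }
  out <- cbind(cand, cols)
  class(out) <- c("variant_calls", "data.frame")
  rownames(out) <- NULL
  out
}

#' Assign orthogonal-support categories to candidates
#'
#' Mirrors the tiered validation of the pipeline: `primary` — the
#' candidate matches a proband exome heterozygote *and* the parental exome
#' genotypes type it (it is an exome trio iSNP); `secondary` — matching
#' proband exome heterozygote only; `tertiary` — typed only from parental
#' long-read data; `unvalidated` — no orthogonal support. Parental allele
#' attribution (`pat_allele`/`mat_allele`) is attached from the exome trio
#' where available, otherwise from the parental long-read typing.
#'
#' @param candidates candidates (usually already polished, carrying a
#'   `wes_support` column; candidates without one are treated as exome
#'   unsupported).
#' @param wes_isnps a [discover_wes_isnps()] result (exome trio iSNPs).
#' @param parental_isnps a [discover_ont_parental_isnps()] result, or an
#'   empty set when no parental long reads exist.
#' @return candidates with `category`, `pat_allele`, `mat_allele` columns.
#' @export
assign_support_category <- function(candidates, wes_isnps = empty_isnps(),
                                    parental_isnps = empty_isnps()) {
  n <- nrow(candidates)
  category <- rep("unvalidated", n)
  pat <- rep(NA_character_, n); mat <- rep(NA_character_, n)
  wes_ok <- if ("wes_support" %in% names(candidates))
    candidates$wes_support == "validated" else rep(FALSE, n)
  for (i in seq_len(n)) {
    if (isTRUE(candidates$is_dnm[i])) { category[i] <- "anchored"; next }
    wi <- which(wes_isnps$pos == candidates$pos[i])
    pi <- which(parental_isnps$pos == candidates$pos[i])
    if (length(wi) && wes_ok[i]) {
      category[i] <- "primary"
      pat[i] <- wes_isnps$pat_allele[wi[1]]
      mat[i] <- wes_isnps$mat_allele[wi[1]]
    } else if (wes_ok[i]) {
      category[i] <- "secondary"
      if (length(pi)) {
        pat[i] <- parental_isnps$pat_allele[pi[1]]
        mat[i] <- parental_isnps$mat_allele[pi[1]]
      }
    } else if (length(pi)) {
      category[i] <- "tertiary"
      pat[i] <- parental_isnps$pat_allele[pi[1]]
      mat[i] <- parental_isnps$mat_allele[pi[1]]
    }
  }
  candidates$category <- category
  candidates$pat_allele <- pat
  candidates$mat_allele <- mat
  candidates
}

#' Remove indel candidates without orthogonal support
#'
#' Indel calls in raw long-read data are overwhelmingly false (homopolymer
#' noise), so any insertion/deletion candidate whose support category is
#' `unvalidated` is dropped. SNVs are never removed by this rule.
#'
#' @param candidates candidates carrying `type` and `category` columns.
#' @return the filtered candidates, with attribute `n_dropped_indels`.
#' @export
drop_unsupported_indels <- function(candidates) {
  drop <- candidates$type != "snv" & candidates$category == "unvalidated"
  out <- candidates[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_indels") <- sum(drop)
  out
}

#' Select the informative SNP used for final phasing
#'
#' Eligible candidates are linked heterozygous SNVs with known parental
#' attribution. Ranking is lexicographic: support category (primary >
#' secondary > tertiary > unvalidated), then split-read agreement, then
#' spanning coverage (reads informative in the two groups), then smaller
#' absolute distance to the DNM, then leftmost position — making the
#' selection a pure, order-independent function of its inputs.
#'
#' @param candidates annotated candidates (after
#'   [find_linked_variants()] and [assign_support_category()]).
#' @param dnm a [dnm_record()].
#' @return list of class `chosen_isnp`, or `NULL` when no candidate is
#'   eligible (the target is unphaseable, not an error).
#' @export
select_isnp <- function(candidates, dnm) {
  elig <- candidates[candidates$type == "snv" &
                       !is.na(candidates$status) &
                       candidates$status == "linked" &
                       !is.na(candidates$pat_allele) &
                       !is.na(candidates$mat_allele), , drop = FALSE]
  if (!nrow(elig)) return(NULL)
  cat_rank <- match(elig$category,
                    c("primary", "secondary", "tertiary", "unvalidated"))
  spanning <- elig$n_alt_group + elig$n_ref_group
  dist <- elig$pos - dnm$position
  o <- order(cat_rank, -elig$agreement, -spanning, abs(dist), elig$pos)
  top <- elig[o[1], ]
  # iSNP base of the wild-type (non-mutant) haplotype: the candidate
  # allele not linked to the DNM alt
  other_base <- setdiff(c(top$ref, top$alt), top$alt_group_base)[1]
  structure(list(pos = top$pos, ref = top$ref, alt = top$alt,
                 pat_allele = top$pat_allele, mat_allele = top$mat_allele,
                 category = top$category, agreement = top$agreement,
                 f_alt_group = top$f_alt_group,
                 f_ref_group = top$f_ref_group,
                 alt_group_base = top$alt_group_base,
                 ref_group_base = top$ref_group_base,
                 other_base = other_base,
                 spanning = spanning[o[1]],
                 distance = dist[o[1]],
                 ranking = elig[o, , drop = FALSE]),
            class = "chosen_isnp")
}

#' Cross-tabulate read bases at the DNM and chosen iSNP positions
#'
#' Counts, over all reads covering both positions, every ordered
#' (DNM-position base, iSNP-position base) combination; a deletion at
#' either position is tallied under the marker `"-"`. Fractions are
#' computed over the spanning reads.
#'
#' @param reads an [aligned_reads()] data.frame.
#' @param dnm a [dnm_record()].
#' @param chosen a [select_isnp()] result (or any list with `pos`).
#' @param control a [phase_control()].
#' @return data.frame of class `allele_table` (`dnm_base`, `isnp_base`,
#'   `count`, `frac`) with attributes `total` (spanning reads) and
#'   `sufficient` (at least `min_spanning` spanning reads).
#' @export
build_allele_table <- function(reads, dnm, chosen,
                               control = phase_control()) {
  bm <- bases_matrix(reads, c(dnm$position, chosen$pos))
  span <- !is.na(bm[, 1]) & !is.na(bm[, 2])
  db <- bm[span, 1]; ib <- bm[span, 2]
  tab <- table(dnm_base = db, isnp_base = ib)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("dnm_base", "isnp_base", "count")
  df <- df[df$count > 0L, , drop = FALSE]
  df <- df[order(-df$count), , drop = FALSE]
  total <- sum(df$count)
  df$frac <- if (total) df$count / total else numeric(nrow(df))
  rownames(df) <- NULL
  structure(df, class = c("allele_table", "data.frame"),
            total = total, dnm_pos = dnm$position, isnp_pos = chosen$pos,
            sufficient = total >= control$min_spanning)
}

# count of one ordered pair in an allele table
pair_count <- function(table, dnm_base, isnp_base) {
  hit <- table$dnm_base == dnm_base & table$isnp_base == isnp_base
  if (any(hit)) sum(table$count[hit]) else 0L
}
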