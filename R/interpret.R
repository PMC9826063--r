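#' Background error metrics from an allele table
#'
#' Two summaries of each kind, following the method's error accounting:
#' the *total* error sums the fractions of all known-false categories, and
#' the *max* error is the single most prevalent false category. Base-level
#' metrics are computed at the iSNP position (where the two parental
#' alleles are the only credible bases; the per-target `max_false_base` is
#' what the cohort background-noise mean summarises); allele-level metrics
#' are computed over the ordered (DNM base, iSNP base) pairs, where the
#' credible set is the mutant pair, the wild-type pair, and — once deemed
#' credible — the third allelic form.
#'
#' @param table an [build_allele_table()] result.
#' @param dnm a [dnm_record()].
#' @param chosen a [select_isnp()] result.
#' @param credible_third logical: is the third allelic form
#'   (DNM wild-type base on the mutant haplotype's iSNP background) part of
#'   the credible set? Use `TRUE` for the provisional metrics that feed
#'   [detect_third_allele()] (its own fraction must not inflate the bar it
#'   is judged against), then recompute with its verdict.
#' @return list of class `error_metrics`: `total_base_error`,
#'   `max_false_base`, `total_allele_error`, `max_false_allele`.
#' @export
compute_error_metrics <- function(table, dnm, chosen,
                                  credible_third = FALSE) {
  total <- attr(table, "total")
  linked <- chosen$alt_group_base
  other <- chosen$other_base
  # base-level, at the iSNP position
  ib <- stats::aggregate(count ~ isnp_base, data = table, sum)
  false_b <- ib[!(ib$isnp_base %in% c(linked, other)), , drop = FALSE]
  fb <- if (nrow(false_b)) false_b$count / total else numeric(0)
  # allele-level
  cred <- data.frame(d = c(dnm$alt_base, dnm$ref_base),
                     i = c(linked, other), stringsAsFactors = FALSE)
  if (credible_third)
    cred <- rbind(cred, data.frame(d = dnm$ref_base, i = linked))
  is_cred <- mapply(function(d, i) any(cred$d == d & cred$i == i),
                    table$dnm_base, table$isnp_base)
  fa <- if (any(!is_cred)) table$count[!is_cred] / total else numeric(0)
  structure(list(
    total_base_error = sum(fb),
    max_false_base = if (length(fb)) max(fb) else 0,
    total_allele_error = sum(fa),
    max_false_allele = if (length(fa)) max(fa) else 0),
    class = "error_metrics")
}

#' Detect a third allelic form (postzygotic signature)
#'
#' The only biologically admissible extra allele pair is the DNM wild-type
#' base on the *mutant* haplotype's iSNP background — the cells in which
#' the mutation never happened. Any other extra pair fails this relevance
#' screen regardless of its size. The candidate is credible when its
#' fraction exceeds both an absolute floor and a multiple of the largest
#' single false-allele fraction.
#'
#' @param table an [build_allele_table()] result.
#' @param dnm a [dnm_record()].
#' @param chosen a [select_isnp()] result.
#' @param metrics provisional [compute_error_metrics()] computed with
#'   `credible_third = TRUE`, so that the candidate pair itself is not part
#'   of the false set it is judged against.
#' @param control a [phase_control()] supplying `third_allele_floor` and
#'   `third_allele_k`.
#' @return list: `pair` (the two bases), `fraction`, `credible`,
#'   `threshold`.
#' @export
detect_third_allele <- function(table, dnm, chosen, metrics,
                                control = phase_control()) {
  linked <- chosen$alt_group_base
  frac <- pair_count(table, dnm$ref_base, linked) / attr(table, "total")
  thr <- max(control$third_allele_floor,
             control$third_allele_k * metrics$max_false_allele)
  list(pair = c(dnm_base = dnm$ref_base, isnp_base = linked),
       fraction = frac, credible = frac > thr, threshold = thr)
}

#' Raw and polished allele frequencies from an allele table
#'
#' The raw mutant allele fraction is the mutant pair count over all
#' spanning reads. The polished fraction removes known-false allele data:
#' its denominator keeps only the credible pairs — the mutant pair, the
#' wild-type pair, and the third allelic form if (and only if) credible.
#'
#' @param table an [build_allele_table()] result.
#' @param dnm a [dnm_record()].
#' @param chosen a [select_isnp()] result.
#' @param credible_third is the third allelic form credible?
#' @return list: `raw_allele`, `polished_allele`, `counts` (named: mutant,
#'   wildtype, third, total).
#' @export
compute_frequencies <- function(table, dnm, chosen, credible_third = FALSE) {
  linked <- chosen$alt_group_base
  other <- chosen$other_base
  total <- attr(table, "total")
  n_mut <- pair_count(table, dnm$alt_base, linked)
  n_wt <- pair_count(table, dnm$ref_base, other)
  n_third <- pair_count(table, dnm$ref_base, linked)
  denom <- n_mut + n_wt + if (credible_third) n_third else 0L
  list(raw_allele = n_mut / total,
       polished_allele = if (denom) n_mut / denom else NA_real_,
       counts = c(mutant = n_mut, wildtype = n_wt, third = n_third,
                  total = total))
}

#' Classify the zygosity (timing) of the DNM
#'
#' Combines the three evidence categories: exome DNM base information,
#' long-read DNM base information, and long-read allele information.
#' Prezygotic: polished mutant allele fraction inside the prezygotic band
#' (around 50%) with no credible third allelic form. Postzygotic: a
#' credible third allelic form, or an out-of-band polished fraction
#' corroborated by the long-read DNM base fraction deviating beyond the
#' measured base noise. A fraction deviation whose base frequencies remain
#' in the prezygotic band is attributed to allelic sequencing bias and
#' reported prezygotic with a flag. Missing exome DNM evidence lowers
#' confidence but does not block classification.
#'
#' @param polished polished mutant allele fraction.
#' @param third a [detect_third_allele()] result.
#' @param ont_base_fraction raw DNM mutant-base fraction in the long
#'   reads.
#' @param metrics final [compute_error_metrics()].
#' @param wes_dnm_support exome evidence at the DNM (`depth`,
#'   `alt_count`), or `NULL` when unavailable.
#' @param control a [phase_control()].
#' @return list: `zygosity` (`"prezygotic"`/`"postzygotic"`/
#'   `"ambiguous"`), `flags` (character vector, possibly empty),
#'   `wes_base_fraction`.
#' @export
classify_zygosity <- function(polished, third, ont_base_fraction,
                              metrics, wes_dnm_support = NULL,
                              control = phase_control()) {
  band <- control$prezygotic_band
  flags <- character(0)
  wes_bf <- NA_real_
  if (is.null(wes_dnm_support) || !wes_dnm_support$depth) {
    flags <- c(flags, "low_confidence_wes")
  } else {
    wes_bf <- wes_dnm_support$alt_count / wes_dnm_support$depth
  }
  in_band <- function(x) !is.na(x) && x >= band[1] && x <= band[2]
  if (third$credible) {
    zyg <- "postzygotic"
  } else if (in_band(polished)) {
    zyg <- "prezygotic"
  } else if (!is.na(ont_base_fraction) &&
             (ont_base_fraction < band[1] - metrics$total_base_error ||
              ont_base_fraction > band[2] + metrics$total_base_error)) {
    zyg <- "postzygotic"
  } else if (in_band(ont_base_fraction)) {
    zyg <- "prezygotic"
    flags <- c(flags, "allelic_bias")
  } else {
    zyg <- "ambiguous"
  }
  list(zygosity = zyg, flags = flags, wes_base_fraction = wes_bf)
}

#' Parent-of-origin of the DNM
#'
#' The mutation arose on the haplotype whose iSNP base co-occurs with the
#' DNM alternate base in the anchored read group; the parent that
#' contributed that base is the parent of origin. Ambiguous attribution
#' yields `"undetermined"`.
#'
#' @param chosen a [select_isnp()] result.
#' @return `"paternal"`, `"maternal"` or `"undetermined"`.
#' @export
assign_parent_of_origin <- function(chosen) {
  if (is.null(chosen)) return("undetermined")
  linked <- chosen$alt_group_base
  if (is.na(linked)) return("undetermined")
  if (identical(linked, chosen$pat_allele)) "paternal"
  else if (identical(linked, chosen$mat_allele)) "maternal"
  else "undetermined"
}

#' Phase a DNM from exome short reads alone (category-1 control)
#'
#' Applies the same two-locus allele-table logic to proband paired short
#' reads, combining the two mates of a fragment (they share a read name)
#' so that a fragment spanning both positions is one observation. The
#' result is acceptable only when each of the two credible alleles has
#' more than `wes_allele_min_reads` supporting fragments; an insufficient
#' result is returned marked unacceptable, not raised as an error.
#'
#' @param wes_reads proband short reads ([aligned_reads()]), mates sharing
#'   a `qname`.
#' @param dnm a [dnm_record()].
#' @param isnp one row of an `isnp_candidates` data.frame (the iSNP must
#'   already be typed in the trio exomes).
#' @param control a [phase_control()].
#' @return list of class `wes_phasing`: `parent`, `acceptable`,
#'   `mutant_fraction`, `allele_counts`, `n_fragments`.
#' @export
phase_wes_only <- function(wes_reads, dnm, isnp,
                           control = phase_control()) {
  bm <- bases_matrix(wes_reads, c(dnm$position, isnp$pos))
  frag_base <- function(col) {
    v <- tapply(col, wes_reads$qname, function(b) {
      b <- unique(b[!is.na(b)])
      if (length(b) == 1L) b else NA_character_
    })
    v
  }
  d <- frag_base(bm[, 1]); s <- frag_base(bm[, 2])
  span <- !is.na(d) & !is.na(s)
  d <- d[span]; s <- s[span]
  alleles <- c(isnp$pat_allele, isnp$mat_allele)
  # mutant-linked iSNP base: the allele most often paired with the DNM alt
  n_by_allele <- vapply(alleles,
                        function(a) sum(d == dnm$alt_base & s == a), 0L)
  linked <- alleles[which.max(n_by_allele)]
  other <- setdiff(alleles, linked)
  n_mut <- sum(d == dnm$alt_base & s == linked)
  n_wt <- sum(d == dnm$ref_base & s == other)
  acceptable <- n_mut > control$wes_allele_min_reads &&
    n_wt > control$wes_allele_min_reads
  parent <- if (identical(linked, isnp$pat_allele)) "paternal"
            else if (identical(linked, isnp$mat_allele)) "maternal"
            else "undetermined"
  structure(list(parent = parent, acceptable = acceptable,
                 mutant_fraction = if (n_mut + n_wt) n_mut / (n_mut + n_wt)
                                   else NA_real_,
                 allele_counts = c(mutant = n_mut, wildtype = n_wt),
                 n_fragments = sum(span)),
            class = "wes_phasing")
}
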