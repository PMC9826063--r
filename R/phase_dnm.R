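#' Anchored phasing of a validated de novo mutation
#'
#' The central fitting function of the package. Given deep proband long
#' reads over the amplicon, the validated DNM and (optionally) trio exome
#' evidence and parental long reads, it runs the full anchored-phasing
#' pipeline: pileup and candidate variant calling, exome error polishing,
#' splitting of reads by the validated DNM base, linkage vetting of every
#' candidate against the split groups, support categorisation, removal of
#' unsupported indels, informative-SNP selection, allele-table
#' construction, frequency estimation with false-allele removal, third
#' allelic form detection, zygosity classification and parent-of-origin
#' assignment.
#'
#' @param reads proband long reads, an [aligned_reads()] data.frame (e.g.
#'   from [read_sam()] or [simulate_long_reads()]).
#' @param dnm a [dnm_record()] — the Sanger-validated DNM that anchors
#'   phasing.
#' @param region a [region_spec()] for the amplicon.
#' @param wes optional [wes_evidence()] with trio exome genotypes, depths
#'   and DNM support.
#' @param parental_reads optional `list(father = , mother = )` of parental
#'   long-read [aligned_reads()] (category-3 targets).
#' @param target_id identifier carried into reports.
#' @param control a [phase_control()].
#' @return An object of class `dnm_phase`; see [summary.dnm_phase()].
#'   Key elements: `phased` (logical), `parent`, `zygosity`, `flags`,
#'   `frequencies` (`raw_base`, `raw_allele`, `polished_allele`),
#'   `third_allele`, `metrics`, `category`, `chosen`, `allele_table`,
#'   `candidates`, `split_counts`.
#' @seealso [simulate_dnm_target()] for generating test data,
#'   [summarize_cohort()] for cohort-level reporting.
#' @examples
#' sim <- simulate_dnm_target(seed = 42, coverage = 200)
#' fit <- phase_dnm(sim$lr$reads, sim$dnm, sim$region, wes = sim$wes)
#' summary(fit)
#' coef(fit)
#' @export
phase_dnm <- function(reads, dnm, region, wes = NULL, parental_reads = NULL,
                      target_id = NULL, control = phase_control()) {
  stopifnot(inherits(dnm, "dnm_record"), inherits(region, "region_spec"))
  pileup <- build_pileup(reads, region)
  calls <- call_variants(pileup, dnm, control)
  wes_isnps <- empty_isnps()
  category <- NA_integer_
  if (!is.null(wes)) {
    calls <- wes_polish(calls, wes, control)
    wes_isnps <- discover_wes_isnps(wes, dnm, control$long_window, control)
    category <- classify_target(dnm, wes_isnps, control)
  }
  parental_isnps <- empty_isnps()
  if (!is.null(parental_reads)) {
    fp <- build_pileup(parental_reads$father, region)
    mp <- build_pileup(parental_reads$mother, region)
    parental_isnps <- discover_ont_parental_isnps(calls, fp, mp, dnm, control)
  }
  splits <- split_reads_by_dnm(reads, dnm)
  raw_base <- unname(splits$counts["alt"] /
                       sum(splits$counts[c("ref", "alt", "other")]))
  candidates <- assign_support_category(calls, wes_isnps, parental_isnps)
  candidates <- drop_unsupported_indels(candidates)
  n_dropped_indels <- attr(candidates, "n_dropped_indels")
  candidates <- find_linked_variants(splits, candidates, control)
  chosen <- select_isnp(candidates, dnm)
  res <- structure(list(
    target_id = target_id, dnm = dnm, region = region,
    control = control, category = category,
    split_counts = splits$counts,
    candidates = candidates,
    n_dropped_indels = n_dropped_indels,
    wes_isnps = wes_isnps, parental_isnps = parental_isnps,
    chosen = chosen, allele_table = NULL,
    frequencies = list(raw_base = raw_base, raw_allele = NA_real_,
                       polished_allele = NA_real_),
    third_allele = NULL, metrics = NULL,
    parent = "undetermined", zygosity = NA_character_,
    flags = character(0), phased = FALSE,
    unphaseable_reason = NULL), class = "dnm_phase")
  if (is.null(chosen)) {
    res$unphaseable_reason <- "no eligible informative SNP"
    return(res)
  }
  tab <- build_allele_table(reads, dnm, chosen, control)
  res$allele_table <- tab
  if (!attr(tab, "sufficient")) {
    res$unphaseable_reason <-
      sprintf("only %d reads span DNM and iSNP (< %d)",
              attr(tab, "total"), control$min_spanning)
    return(res)
  }
  # provisional metrics exclude the candidate third-allele pair from the
  # false set, else its own fraction would inflate its credibility bar
  provisional <- compute_error_metrics(tab, dnm, chosen,
                                       credible_third = TRUE)
  third <- detect_third_allele(tab, dnm, chosen, provisional, control)
  metrics <- compute_error_metrics(tab, dnm, chosen,
                                   credible_third = third$credible)
  freqs <- compute_frequencies(tab, dnm, chosen,
                               credible_third = third$credible)
  zyg <- classify_zygosity(freqs$polished_allele, third, raw_base, metrics,
                           wes_dnm_support = if (!is.null(wes))
                             wes$dnm_support,
                           control = control)
  res$third_allele <- third
  res$metrics <- metrics
  res$frequencies <- list(raw_base = raw_base,
                          raw_allele = freqs$raw_allele,
                          polished_allele = freqs$polished_allele,
                          counts = freqs$counts)
  res$parent <- assign_parent_of_origin(chosen)
  res$zygosity <- zyg$zygosity
  res$flags <- zyg$flags
  res$wes_base_fraction <- zyg$wes_base_fraction
  res$phased <- res$parent != "undetermined"
  res
}

#' @export
print.dnm_phase <- function(x, ...) {
  cat("Anchored DNM phasing\n")
  id <- if (is.null(x$target_id)) "" else paste0(" [", x$target_id, "]")
  cat(sprintf("  DNM%s: %s:%d %s>%s\n", id, x$dnm$contig, x$dnm$position,
              x$dnm$ref_base, x$dnm$alt_base))
  if (!x$phased) {
    cat("  unphased:", x$unphaseable_reason %||% "undetermined parent", "\n")
    return(invisible(x))
  }
  cat(sprintf("  parent-of-origin: %s   zygosity: %s%s\n", x$parent,
              x$zygosity,
              if (length(x$flags)) paste0(" (", paste(x$flags, collapse = ", "),
                                          ")") else ""))
  cat(sprintf("  polished mutant allele fraction: %.3f (raw %.3f, base %.3f)\n",
              x$frequencies$polished_allele, x$frequencies$raw_allele,
              x$frequencies$raw_base))
  invisible(x)
}

#' Summarise an anchored phasing result
#'
#' @param object a [phase_dnm()] result.
#' @param ... unused.
#' @export
summary.dnm_phase <- function(object, ...) {
  structure(list(fit = object), class = "summary.dnm_phase")
}

#' @export
print.summary.dnm_phase <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nRead split at DNM:\n")
  print(f$split_counts)
  if (!is.null(f$chosen)) {
    cat(sprintf("\nChosen iSNP: pos %d (%s/%s), category %s, agreement %.3f, distance %d bp\n",
                f$chosen$pos, f$chosen$pat_allele, f$chosen$mat_allele,
                f$chosen$category, f$chosen$agreement, f$chosen$distance))
    cat("\nAllele table (DNM base x iSNP base):\n")
    print(as.data.frame(f$allele_table))
  }
  if (!is.null(f$metrics)) {
    cat(sprintf("\nBackground error: total base %.4f (max %.4f), total allele %.4f (max %.4f)\n",
                f$metrics$total_base_error, f$metrics$max_false_base,
                f$metrics$total_allele_error, f$metrics$max_false_allele))
    cat(sprintf("Third allelic form: fraction %.3f (%s)\n",
                f$third_allele$fraction,
                if (f$third_allele$credible) "credible" else "not credible"))
  }
  if (!is.na(f$category)) cat(sprintf("Phasing category: %d\n", f$category))
  invisible(x)
}

#' Extract estimated fractions from a phasing result
#'
#' @param object a [phase_dnm()] result.
#' @param ... unused.
#' @return named numeric vector: `raw_base`, `raw_allele`,
#'   `polished_allele`, `third_allele`.
#' @export
coef.dnm_phase <- function(object, ...) {
  c(raw_base = object$frequencies$raw_base,
    raw_allele = object$frequencies$raw_allele,
    polished_allele = object$frequencies$polished_allele,
    third_allele = if (is.null(object$third_allele)) NA_real_
                   else object$third_allele$fraction)
}

#' Plot the allele table of a phasing result
#'
#' Barplot of allele-pair fractions, credible pairs highlighted.
#' @param x a [phase_dnm()] result.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.dnm_phase <- function(x, ...) {
  tab <- x$allele_table
  if (is.null(tab) || !nrow(tab)) {
    warning("no allele table to plot")
    return(invisible(x))
  }
  lab <- paste0(tab$dnm_base, "-", tab$isnp_base)
  linked <- x$chosen$alt_group_base
  other <- x$chosen$other_base
  cred <- (tab$dnm_base == x$dnm$alt_base & tab$isnp_base == linked) |
    (tab$dnm_base == x$dnm$ref_base & tab$isnp_base == other) |
    (isTRUE(x$third_allele$credible) &
       tab$dnm_base == x$dnm$ref_base & tab$isnp_base == linked)
  graphics::barplot(tab$frac, names.arg = lab,
                    col = ifelse(cred, "steelblue", "grey70"),
                    ylab = "fraction of spanning reads",
                    xlab = "DNM base - iSNP base", ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a phasing result as a JSON-ready record
#'
#' @param x a [phase_dnm()] result.
#' @param file optional path; when given, the record is written as JSON.
#' @return the record list, invisibly when written to file.
#' @export
phase_record <- function(x, file = NULL) {
  stopifnot(inherits(x, "dnm_phase"))
  rec <- list(
    target_id = x$target_id,
    dnm = list(contig = x$dnm$contig, position = x$dnm$position,
               ref = x$dnm$ref_base, alt = x$dnm$alt_base),
    category = x$category,
    phased = x$phased,
    parent_of_origin = x$parent,
    zygosity = x$zygosity,
    flags = as.list(x$flags),
    frequencies = x$frequencies[c("raw_base", "raw_allele",
                                  "polished_allele")],
    third_allele = if (!is.null(x$third_allele))
      x$third_allele[c("fraction", "credible")],
    error_metrics = if (!is.null(x$metrics)) unclass(x$metrics),
    chosen_isnp = if (!is.null(x$chosen))
      x$chosen[c("pos", "category", "agreement", "distance",
                 "pat_allele", "mat_allele")],
    split_counts = as.list(x$split_counts),
    unphaseable_reason = x$unphaseable_reason)
  if (!is.null(file)) {
    jsonlite::write_json(rec, file, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(rec))
  }
  rec
}
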