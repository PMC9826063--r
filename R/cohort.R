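#' Cohort summary over phased DNM targets
#'
#' Aggregates a list of [phase_dnm()] results into the cohort-level
#' quantities the method reports: fraction of targets phased, paternal
#' fraction overall and within zygosity strata, mean and standard error
#' (SEM, sd/sqrt(n)) of the polished mutant allele fractions for
#' prezygotic and postzygotic targets, and the mean background noise (the
#' cohort mean of each target's largest single false-base fraction at its
#' iSNP).
#'
#' @param results list of `dnm_phase` objects.
#' @return An object of class `dnm_cohort`: a list with `table` (one row
#'   per target) and `summary` (named list of cohort statistics).
#' @export
summarize_cohort <- function(results) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, TRUE, "dnm_phase")))
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(
      target_id = r$target_id %||% paste0("target_", i),
      phased = r$phased,
      parent = r$parent,
      zygosity = if (is.na(r$zygosity %||% NA)) NA_character_ else r$zygosity,
      category = r$category,
      raw_base = r$frequencies$raw_base,
      raw_allele = r$frequencies$raw_allele,
      polished_allele = r$frequencies$polished_allele,
      third_allele = if (is.null(r$third_allele)) NA_real_
                     else r$third_allele$fraction,
      max_false_base = if (is.null(r$metrics)) NA_real_
                       else r$metrics$max_false_base,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  sem <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) NA_real_ else stats::sd(x) / sqrt(length(x))
  }
  ph <- tab[tab$phased, , drop = FALSE]
  pre <- ph[!is.na(ph$zygosity) & ph$zygosity == "prezygotic", , drop = FALSE]
  post <- ph[!is.na(ph$zygosity) & ph$zygosity == "postzygotic", , drop = FALSE]
  pat_frac <- function(d) if (nrow(d)) mean(d$parent == "paternal") else NA_real_
  summary <- list(
    n_targets = nrow(tab),
    n_phased = nrow(ph),
    phased_fraction = nrow(ph) / nrow(tab),
    paternal_fraction = pat_frac(ph),
    paternal_fraction_prezygotic = pat_frac(pre),
    paternal_fraction_postzygotic = pat_frac(post),
    n_prezygotic = nrow(pre),
    n_postzygotic = nrow(post),
    prezygotic_mean_polished = mean(pre$polished_allele),
    prezygotic_sem_polished = sem(pre$polished_allele),
    postzygotic_mean_polished = mean(post$polished_allele),
    postzygotic_sem_polished = sem(post$polished_allele),
    mean_background_noise = mean(ph$max_false_base, na.rm = TRUE))
  structure(list(table = tab, summary = summary), class = "dnm_cohort")
}

#' @export
print.dnm_cohort <- function(x, ...) {
  s <- x$summary
  cat("DNM phasing cohort summary\n")
  cat(sprintf("  targets: %d, phased: %d (%.0f%%)\n", s$n_targets,
              s$n_phased, 100 * s$phased_fraction))
  cat(sprintf("  paternal: %.0f%% overall (prezygotic %.0f%%, postzygotic %s)\n",
              100 * s$paternal_fraction,
              100 * s$paternal_fraction_prezygotic,
              if (is.na(s$paternal_fraction_postzygotic)) "-"
              else sprintf("%.0f%%", 100 * s$paternal_fraction_postzygotic)))
  cat(sprintf("  prezygotic (n=%d): polished fraction %.3f (SEM %s)\n",
              s$n_prezygotic, s$prezygotic_mean_polished,
              if (is.na(s$prezygotic_sem_polished)) "-"
              else sprintf("%.4f", s$prezygotic_sem_polished)))
  if (s$n_postzygotic)
    cat(sprintf("  postzygotic (n=%d): polished fraction %.3f (SEM %s)\n",
                s$n_postzygotic, s$postzygotic_mean_polished,
                if (is.na(s$postzygotic_sem_polished)) "-"
                else sprintf("%.4f", s$postzygotic_sem_polished)))
  cat(sprintf("  mean background noise at iSNPs: %.4f\n",
              s$mean_background_noise))
  invisible(x)
}

#' Write a cohort summary to TSV and JSON
#'
#' @param cohort a [summarize_cohort()] result.
#' @param tsv,json output paths (either may be `NULL` to skip).
#' @export
write_cohort <- function(cohort, tsv = NULL, json = NULL) {
  stopifnot(inherits(cohort, "dnm_cohort"))
  if (!is.null(tsv))
    utils::write.table(cohort$table, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(cohort$summary, json, auto_unbox = TRUE,
                         digits = NA, null = "null")
  invisible(cohort)
}
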