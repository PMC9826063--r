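#' Write / read trio exome evidence as a minimal VCF
#'
#' The VCF carries GT and DP for samples FATHER, MOTHER and PROBAND; the
#' proband's allelic depths (AD) and the flag `DNM` are attached to the
#' validated DNM row when that evidence is present. [read_trio_vcf()]
#' parses the file back (via the vcfR package) into a [wes_evidence()]
#' object.
#'
#' @param wes a [wes_evidence()] object.
#' @param region a [region_spec()] for the header.
#' @param file output path.
#' @export
write_trio_vcf <- function(wes, region, file) {
  stopifnot(inherits(wes, "wes_evidence"))
  s <- wes$sites
  ds <- wes$dnm_support
  gt_idx <- function(gtstr, ref, alts) {
    al <- strsplit(gtstr, "/", fixed = TRUE)[[1]]
    paste(match(al, c(ref, alts)) - 1L, collapse = "/")
  }
  rows <- character(0)
  seen_dnm_row <- FALSE
  for (k in seq_len(nrow(s))) {
    alts <- if (s$alt[k] == ".") character(0) else
      strsplit(s$alt[k], ",", fixed = TRUE)[[1]]
    is_dnm <- !is.null(ds) && s$pos[k] == ds$pos
    seen_dnm_row <- seen_dnm_row || is_dnm
    fmt <- if (is_dnm) "GT:DP:AD" else "GT:DP"
    samp <- function(gt, dp, ad = NULL) {
      v <- paste(gt_idx(gt, s$ref[k], alts), dp, sep = ":")
      if (is_dnm) v <- paste(v, if (is.null(ad)) "." else ad, sep = ":")
      v
    }
    ad_pr <- if (is_dnm) paste(ds$depth - ds$alt_count, ds$alt_count, sep = ",")
    rows <- c(rows, paste(
      region$contig, s$pos[k], ".", s$ref[k],
      if (length(alts)) paste(alts, collapse = ",") else ".",
      ".", "PASS", if (is_dnm) "DNM" else ".", fmt,
      samp(s$gt_fa[k], s$dp_fa[k]),
      samp(s$gt_mo[k], s$dp_mo[k]),
      samp(s$gt_pr[k], s$dp_pr[k], ad_pr), sep = "\t"))
  }
  if (!is.null(ds) && !seen_dnm_row) {
    hom <- paste(ds$ref, ds$ref, sep = "/")
    rows <- c(rows, paste(
      region$contig, ds$pos, ".", ds$ref, ds$alt, ".", "PASS", "DNM",
      "GT:DP:AD", paste0("0/0:", ds$depth, ":."),
      paste0("0/0:", ds$depth, ":."),
      paste0("0/0:", ds$depth, ":",
             ds$depth - ds$alt_count, ",", ds$alt_count), sep = "\t"))
    s2 <- rbind(data.frame(pos = s$pos), data.frame(pos = ds$pos))
    o <- order(s2$pos)
    rows <- rows[o]
  }
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", region$contig, region$end),
           "##INFO=<ID=DNM,Number=0,Type=Flag,Description=\"Validated de novo mutation site\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "FATHER", "MOTHER", "PROBAND", sep = "\t"))
  writeLines(c(hdr, rows), file)
  invisible(file)
}

#' @rdname write_trio_vcf
#' @param depth_file optional TSV (`pos`, `dp_fa`, `dp_mo`, `dp_pr`) with
#'   the exome coverage footprint, as written by [write_dataset()]; without
#'   it only the variant sites themselves count as exome-covered.
#' @export
read_trio_vcf <- function(file, depth_file = NULL) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                 error = function(e) NULL)
  info <- v@fix[, "INFO"]
  n <- nrow(fix)
  to_bases <- function(idx_gt, ref, alts) {
    if (is.na(idx_gt)) return(NA_character_)
    i <- as.integer(strsplit(idx_gt, "[/|]")[[1]])
    paste(c(ref, alts)[i + 1L], collapse = "/")
  }
  rows <- vector("list", n)
  dnm_support <- NULL
  for (k in seq_len(n)) {
    ref <- unname(fix[k, "REF"])
    altf <- unname(fix[k, "ALT"])
    alts <- if (is.na(altf) || altf == ".") character(0) else
      strsplit(altf, ",", fixed = TRUE)[[1]]
    pos <- as.integer(fix[k, "POS"])
    is_dnm <- !is.na(info[k]) && grepl("(^|;)DNM($|;)", info[k])
    if (is_dnm && !is.null(ad) && !is.na(ad[k, "PROBAND"]) &&
        ad[k, "PROBAND"] != ".") {
      adv <- as.integer(strsplit(ad[k, "PROBAND"], ",", fixed = TRUE)[[1]])
      dnm_support <- list(pos = pos, ref = ref, alt = alts[1],
                          depth = sum(adv), alt_count = adv[2])
    }
    gpr <- to_bases(gt[k, "PROBAND"], ref, alts)
    # a DNM row written only to carry AD (hom-ref everywhere) is not a site
    if (is_dnm && !is.na(gpr) &&
        length(unique(strsplit(gpr, "/")[[1]])) == 1L) next
    rows[[k]] <- data.frame(
      pos = pos, ref = ref,
      alt = if (length(alts)) paste(alts, collapse = ",") else ".",
      gt_fa = to_bases(gt[k, "FATHER"], ref, alts),
      gt_mo = to_bases(gt[k, "MOTHER"], ref, alts),
      gt_pr = gpr,
      dp_fa = as.integer(dp[k, "FATHER"]),
      dp_mo = as.integer(dp[k, "MOTHER"]),
      dp_pr = as.integer(dp[k, "PROBAND"]),
      stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, c(rows[!vapply(rows, is.null, TRUE)],
                            list(make.row.names = FALSE)))
  if (is.null(sites))
    sites <- data.frame(pos = integer(), ref = character(), alt = character(),
                        gt_fa = character(), gt_mo = character(),
                        gt_pr = character(), dp_fa = integer(),
                        dp_mo = integer(), dp_pr = integer(),
                        stringsAsFactors = FALSE)
  depth <- if (!is.null(depth_file))
    utils::read.delim(depth_file, stringsAsFactors = FALSE)
  wes_evidence(sites, depth, dnm_support)
}
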