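# Posterior probability of heterozygosity for one pileup column under a
# symmetric-error multinomial model. The pair of alleles considered is
# (ref, top non-ref base); the error rate is estimated from the counts of
# the remaining two bases (each wrong base receives e/3), floored to keep
# the likelihood proper.
het_posterior <- function(counts, ref, error_floor = 1e-3) {
  stopifnot(all(BASES %in% names(counts)))
  cn <- counts[BASES]
  nonref <- setdiff(BASES, ref)
  alt <- nonref[which.max(cn[nonref])]
  n <- sum(cn)
  if (n == 0L)
    return(list(alt = alt, conf_het = NA_real_, genotype = NA_character_,
                e_hat = NA_real_))
  others <- setdiff(BASES, c(ref, alt))
  e_hat <- max(error_floor, min(0.74, 1.5 * sum(cn[others]) / n))
  p_of <- function(gt) {
    p <- stats::setNames(rep(e_hat / 3, 4L), BASES)
    if (length(gt) == 1L) p[gt] <- 1 - e_hat
    else p[gt] <- 0.5 - e_hat / 3
    p
  }
  ll <- c(hom_ref = sum(cn * log(p_of(ref))),
          het = sum(cn * log(p_of(c(ref, alt)))),
          hom_alt = sum(cn * log(p_of(alt))))
  post <- exp(ll - max(ll)); post <- post / sum(post)
  list(alt = alt, conf_het = unname(post["het"]),
       genotype = names(post)[which.max(post)], e_hat = e_hat)
}

empty_calls <- function() {
  structure(data.frame(pos = integer(), ref = character(), alt = character(),
                       type = character(), alt_count = integer(),
                       depth = integer(), af = numeric(), conf = numeric(),
                       genotype = character(), hp_flag = logical(),
                       is_dnm = logical(), stringsAsFactors = FALSE),
            class = c("variant_calls", "data.frame"))
}

#' Call candidate variants from a proband pileup
#'
#' Emits heterozygous SNV candidates passing the published filters: depth
#' strictly above `min_depth`, allele fraction inside the inclusive
#' `af_window`, and heterozygosity confidence of at least `min_conf` under
#' a symmetric-error multinomial genotype posterior (a documented stand-in
#' for the original caller's confidence; the threshold itself is kept at
#' 0.96). At the DNM position only the Sanger-validated alternate allele is
#' admitted, and since the site is independently validated it is exempt
#' from the allele-fraction and confidence filters — mosaic DNMs may sit
#' far below 20%. Homozygous-alt calls are retained (flagged `hom_alt`)
#' for the linked-variant search. Deletion and insertion candidates are
#' called from the pileup's event counts and carry a homopolymer-context
#' flag, since indel error concentrates in homopolymer runs.
#'
#' @param pileup a [build_pileup()] result.
#' @param dnm a [dnm_record()].
#' @param control a [phase_control()].
#' @return data.frame of class `variant_calls` with columns `pos`, `ref`,
#'   `alt` (`"<DEL>"`/`"<INS>"` for indels), `type`, `alt_count`, `depth`,
#'   `af`, `conf`, `genotype`, `hp_flag`, `is_dnm`.
#' @export
call_variants <- function(pileup, dnm, control = phase_control()) {
  stopifnot(inherits(pileup, "pileup"), inherits(dnm, "dnm_record"))
  dnm_row <- which(pileup$pos == dnm$position)
  if (!length(dnm_row) || pileup$depth[dnm_row] == 0L)
    stop("DNM position ", dnm$position,
         " is not covered by the pileup: amplicon failed")
  # homopolymer context: inside or adjacent to a run of >= 3 identical bases
  r <- rle(pileup$ref)
  in_run <- rep(r$lengths >= 3L, r$lengths)
  hp <- in_run | c(in_run[-1], FALSE) | c(FALSE, in_run[-length(in_run)])
  af_lo <- control$af_window[1]; af_hi <- control$af_window[2]
  cmat <- as.matrix(pileup[, BASES])
  rows <- vector("list", 64L)
  nr <- 0L
  add <- function(row) {
    nr <<- nr + 1L
    rows[[nr]] <<- row
    invisible(NULL)
  }
  for (k in seq_len(nrow(pileup))) {
    depth <- pileup$depth[k]
    if (depth <= control$min_depth) next
    ref <- pileup$ref[k]
    cn <- stats::setNames(cmat[k, ], BASES)
    is_dnm <- pileup$pos[k] == dnm$position
    nonref <- setdiff(BASES, ref)
    alt <- if (is_dnm) dnm$alt_base else nonref[which.max(cn[nonref])]
    af <- unname(cn[alt]) / depth
    if (is_dnm || af >= af_lo) {
      hp_ <- het_posterior(cn, ref, control$error_floor)
      conf <- if (is_dnm) hp_$conf_het else hp_$conf_het
      if (is_dnm) {
        add(data.frame(pos = pileup$pos[k], ref = ref, alt = alt,
                       type = "snv", alt_count = unname(cn[alt]),
                       depth = depth, af = af, conf = conf,
                       genotype = "het", hp_flag = FALSE, is_dnm = TRUE,
                       stringsAsFactors = FALSE))
      } else if (af <= af_hi) {
        if (hp_$alt == alt && hp_$conf_het >= control$min_conf)
          add(data.frame(pos = pileup$pos[k], ref = ref, alt = alt,
                         type = "snv", alt_count = unname(cn[alt]),
                         depth = depth, af = af, conf = hp_$conf_het,
                         genotype = "het", hp_flag = FALSE, is_dnm = FALSE,
                         stringsAsFactors = FALSE))
      } else if (hp_$genotype == "hom_alt") {
        add(data.frame(pos = pileup$pos[k], ref = ref, alt = alt,
                       type = "snv", alt_count = unname(cn[alt]),
                       depth = depth, af = af,
                       conf = 1 - hp_$conf_het,
                       genotype = "hom_alt", hp_flag = FALSE, is_dnm = FALSE,
                       stringsAsFactors = FALSE))
      }
    }
    # indel candidates against the non-event majority
    for (ev in c("del", "ins")) {
      cnt <- pileup[[ev]][k]
      evd <- if (ev == "del") depth else depth + cnt
      afi <- cnt / evd
      if (afi >= af_lo && afi <= af_hi) {
        # two-category symmetric-error posterior (event vs no event)
        e2 <- control$error_floor
        llh <- c(hom = cnt * log(e2) + (evd - cnt) * log(1 - e2),
                 het = cnt * log(0.5) + (evd - cnt) * log(0.5))
        post <- exp(llh - max(llh)); post <- post / sum(post)
        if (post["het"] >= control$min_conf)
          add(data.frame(pos = pileup$pos[k], ref = ref,
                         alt = if (ev == "del") "<DEL>" else "<INS>",
                         type = ev, alt_count = cnt, depth = evd,
                         af = afi, conf = unname(post["het"]),
                         genotype = "het", hp_flag = hp[k], is_dnm = FALSE,
                         stringsAsFactors = FALSE))
      }
    }
  }
  out <- if (nr) do.call(rbind, c(rows[seq_len(nr)],
                                  list(make.row.names = FALSE)))
         else empty_calls()
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' Error-polish candidate variants against trio exome evidence
#'
#' A candidate at an exome-covered position (proband depth at least
#' `wes_min_depth`) is removed unless the exome genotype of the proband
#' contains the same alternate allele; below that depth the exome is
#' treated as uninformative and the candidate passes through flagged
#' `unvalidated`. The anchored DNM itself is never polished away (it is
#' independently validated). Adds a `wes_support` column.
#'
#' @param candidates a [call_variants()] result.
#' @param wes a [wes_evidence()] object.
#' @param control a [phase_control()].
#' @return the surviving candidates with `wes_support` in
#'   `"validated"`/`"unvalidated"`/`"anchored"`.
#' @export
wes_polish <- function(candidates, wes, control = phase_control()) {
  stopifnot(inherits(wes, "wes_evidence"))
  if (!nrow(candidates)) {
    candidates$wes_support <- character(0)
    return(candidates)
  }
  depth_at <- function(pos) {
    d <- wes$depth
    if (!is.null(d)) {
      hit <- d$pos == pos
      if (any(hit)) return(d$dp_pr[hit][1])
      return(0L)
    }
    hit <- wes$sites$pos == pos
    if (any(hit)) wes$sites$dp_pr[hit][1] else 0L
  }
  keep <- logical(nrow(candidates))
  support <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    if (candidates$is_dnm[i]) {
      keep[i] <- TRUE; support[i] <- "anchored"; next
    }
    pos <- candidates$pos[i]
    if (depth_at(pos) < control$wes_min_depth) {
      keep[i] <- TRUE; support[i] <- "unvalidated"; next
    }
    hit <- wes$sites[wes$sites$pos == pos, , drop = FALSE]
    agree <- FALSE
    if (nrow(hit) && candidates$type[i] == "snv") {
      al <- strsplit(hit$gt_pr[1], "/", fixed = TRUE)[[1]]
      agree <- candidates$alt[i] %in% al
    }
    if (agree) { keep[i] <- TRUE; support[i] <- "validated" }
  }
  out <- candidates[keep, , drop = FALSE]
  out$wes_support <- support[keep]
  rownames(out) <- NULL
  out
}

empty_isnps <- function() {
  structure(data.frame(pos = integer(), ref = character(), alt = character(),
                       pat_allele = character(), mat_allele = character(),
                       distance = integer(), dp_fa = integer(),
                       dp_mo = integer(), dp_pr = integer(),
                       source = character(), stringsAsFactors = FALSE),
            class = c("isnp_candidates", "data.frame"))
}

#' Discover informative SNPs from trio exome genotypes
#'
#' An informative SNP (iSNP) is a biallelic proband-heterozygous site where
#' each of the two alleles is uniquely attributable to one parent and both
#' parents have exome depth of at least `isnp_min_parent_depth` (default
#' 5x). Sites farther than `window_bp` from the DNM are ignored.
#'
#' @param wes a [wes_evidence()] object.
#' @param dnm a [dnm_record()].
#' @param window_bp search radius around the DNM.
#' @param control a [phase_control()].
#' @return data.frame of class `isnp_candidates` (possibly empty) with the
#'   parental attribution of each proband allele and the signed distance to
#'   the DNM.
#' @export
discover_wes_isnps <- function(wes, dnm, window_bp = 10000L,
                               control = phase_control()) {
  stopifnot(inherits(wes, "wes_evidence"), inherits(dnm, "dnm_record"))
  s <- wes$sites
  out <- empty_isnps()
  for (k in seq_len(nrow(s))) {
    if (s$pos[k] == dnm$position) next
    if (abs(s$pos[k] - dnm$position) > window_bp) next
    if (grepl(",", s$alt[k], fixed = TRUE)) next  # multi-allelic
    pr <- strsplit(s$gt_pr[k], "/", fixed = TRUE)[[1]]
    if (length(unique(pr)) != 2L) next
    if (is.na(s$dp_fa[k]) || is.na(s$dp_mo[k])) next
    if (s$dp_fa[k] < control$isnp_min_parent_depth ||
        s$dp_mo[k] < control$isnp_min_parent_depth) next
    fa <- strsplit(s$gt_fa[k], "/", fixed = TRUE)[[1]]
    mo <- strsplit(s$gt_mo[k], "/", fixed = TRUE)[[1]]
    ap <- attribution_pairs(pr[1], pr[2], fa, mo)
    if (length(ap) != 1L) next
    out <- rbind(out, data.frame(
      pos = s$pos[k], ref = s$ref[k], alt = s$alt[k],
      pat_allele = ap[[1]][["paternal"]], mat_allele = ap[[1]][["maternal"]],
      distance = s$pos[k] - dnm$position,
      dp_fa = s$dp_fa[k], dp_mo = s$dp_mo[k], dp_pr = s$dp_pr[k],
      source = "WES", stringsAsFactors = FALSE))
  }
  class(out) <- c("isnp_candidates", "data.frame")
  rownames(out) <- NULL
  out
}

#' Classify a target into a phasing category
#'
#' Category 1: an exome-typed iSNP lies within paired short-read range of
#' the DNM, so the exome alone may phase it. Category 2: an exome-typed
#' iSNP lies within the long-read amplicon window, so proband long reads
#' suffice. Category 3: no exome iSNP within the window — intronic iSNPs
#' must be typed from parental long reads.
#'
#' @param dnm a [dnm_record()].
#' @param wes_isnps a [discover_wes_isnps()] result.
#' @param control a [phase_control()].
#' @return integer 1, 2 or 3.
#' @export
classify_target <- function(dnm, wes_isnps, control = phase_control()) {
  if (!nrow(wes_isnps)) return(3L)
  d <- min(abs(wes_isnps$distance))
  if (d <= control$short_read_span) 1L
  else if (d <= control$long_window) 2L
  else 3L
}

#' Type proband candidates from parental long-read pileups
#'
#' For category-3 targets: a proband heterozygous candidate becomes an
#' informative SNP when the parental long-read base fractions attribute its
#' two alleles uniquely — a parent supports an allele when its fraction is
#' at least `parental_support_af` at depth of at least
#' `parental_min_depth`. Parents below the depth threshold exclude the
#' candidate.
#'
#' @param candidates proband heterozygous [call_variants()] rows (SNVs).
#' @param father_pileup,mother_pileup [build_pileup()] results for the
#'   parents.
#' @param dnm a [dnm_record()].
#' @param control a [phase_control()].
#' @return data.frame of class `isnp_candidates`, `source = "ONT_parent"`.
#' @export
discover_ont_parental_isnps <- function(candidates, father_pileup,
                                        mother_pileup, dnm,
                                        control = phase_control()) {
  out <- empty_isnps()
  snvs <- candidates[candidates$type == "snv" & !candidates$is_dnm &
                       candidates$genotype == "het", , drop = FALSE]
  for (i in seq_len(nrow(snvs))) {
    pos <- snvs$pos[i]
    if (abs(pos - dnm$position) > control$trio_window) next
    al <- c(snvs$ref[i], snvs$alt[i])
    supported <- function(pu) {
      k <- which(pu$pos == pos)
      if (!length(k)) return(NULL)
      depth <- pu$depth[k]
      if (depth < control$parental_min_depth) return(NULL)
      cn <- unlist(pu[k, BASES])
      BASES[cn / depth >= control$parental_support_af]
    }
    fa <- supported(father_pileup); mo <- supported(mother_pileup)
    if (is.null(fa) || is.null(mo)) next
    pairs <- list()
    for (p in intersect(fa, al)) for (m in intersect(mo, al))
      if (setequal(c(p, m), al))
        pairs[[length(pairs) + 1L]] <- c(paternal = p, maternal = m)
    pairs <- unique(pairs)
    if (length(pairs) != 1L) next
    out <- rbind(out, data.frame(
      pos = pos, ref = snvs$ref[i], alt = snvs$alt[i],
      pat_allele = pairs[[1]][["paternal"]],
      mat_allele = pairs[[1]][["maternal"]],
      distance = pos - dnm$position,
      dp_fa = father_pileup$depth[father_pileup$pos == pos],
      dp_mo = mother_pileup$depth[mother_pileup$pos == pos],
      dp_pr = snvs$depth[i],
      source = "ONT_parent", stringsAsFactors = FALSE))
  }
  class(out) <- c("isnp_candidates", "data.frame")
  rownames(out) <- NULL
  out
}
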