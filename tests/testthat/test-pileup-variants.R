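make_pileup <- function(rows, region_len = NULL) {
  # rows: data.frame with pos, ref and any of A,C,G,T,del,ins
  for (b in c("A", "C", "G", "T", "del", "ins"))
    if (is.null(rows[[b]])) rows[[b]] <- 0L
  rows$depth <- rows$A + rows$C + rows$G + rows$T + rows$del
  for (b in c("A", "C", "G", "T"))
    rows[[paste0("mq_", b)]] <- NA_real_
  class(rows) <- c("pileup", "data.frame")
  rows
}

test_that("pileup columns match per-read counting oracles", {
  region <- flat_region(30)
  geno <- simulate_trio_genotypes(region, 10,
                                  schemes = list(list(father = c("A", "A"),
                                                      mother = c("G", "G"))))
  rd <- simulate_long_reads(geno, 10,
                            error_model(e_sub = 0, e_indel = 0),
                            seed = 3)$reads
  pu <- build_pileup(rd, region)
  # error-free: every column is pure reference except the het site
  expect_equal(pu$depth, rep(10L, 30))
  ref_count <- mapply(function(p, r) pu[[r]][pu$pos == p],
                      pu$pos, pu$ref)
  expect_true(all(ref_count[pu$pos != 10] == 10))
  expect_equal(pu$A[pu$pos == 10] + pu$G[pu$pos == 10], 10L)
  # invariant: base counts + deletions = depth, on noisy data too
  sim <- random_instance(91)
  pun <- build_pileup(sim$lr$reads, sim$region)
  expect_equal(pun$A + pun$C + pun$G + pun$T + pun$del, pun$depth)
  for (p in sample(pun$pos, 10)) {
    o <- oracle_pileup_column(sim$lr$reads, p)
    got <- unlist(pun[pun$pos == p, c("A", "C", "G", "T", "del")])
    expect_equal(unname(got), unname(o))
  }
  # a read deleted at a position increments del, not a base
  del <- aligned_reads("d", 0L, "ampl1", 1L, 60L, "5M2D5M",
                       "AAAAAAAAAA", strrep("I", 10))
  pud <- build_pileup(del, flat_region(12))
  expect_equal(pud$del[pud$pos %in% 6:7], c(1L, 1L))
  expect_equal(sum(pud[pud$pos == 6, c("A", "C", "G", "T")]), 0)
  # empty read set: empty pileup, not an error
  p0 <- build_pileup(del[0, ], flat_region(12))
  expect_equal(p0$depth, rep(0L, 12))
})

test_that("pileup agrees with an independent BAM pileup engine", {
  sim <- simulate_dnm_target(seed = 95, coverage = 40, region_length = 150,
                             isnp_offsets = 30)
  d <- withr::local_tempdir()
  sam <- file.path(d, "r.sam")
  write_sam(sim$lr$reads, sim$region, sam)
  bam <- Rsamtools::asBam(sam, file.path(d, "r"), overwrite = TRUE)
  pp <- Rsamtools::pileup(
    bam, pileupParam = Rsamtools::PileupParam(
      max_depth = 10000, min_base_quality = 0L, min_mapq = 0L,
      min_nucleotide_depth = 0L, distinguish_strands = FALSE,
      include_deletions = TRUE))
  mine <- build_pileup(sim$lr$reads, sim$region)
  m <- stats::xtabs(count ~ pos + nucleotide,
                    data = pp[pp$nucleotide %in% c("A", "C", "G", "T"), ])
  for (b in c("A", "C", "G", "T")) {
    v <- stats::setNames(rep(0L, nrow(mine)), mine$pos)
    v[rownames(m)] <- m[, b]
    expect_equal(unname(v), mine[[b]])
  }
  dl <- pp[pp$nucleotide == "-", ]
  v <- stats::setNames(rep(0L, nrow(mine)), mine$pos)
  v[as.character(dl$pos)] <- dl$count
  expect_equal(unname(v), mine$del)
})

test_that("heterozygote confidence matches a direct multinomial posterior", {
  # independent arithmetic: uniform prior over the three genotypes,
  # multinomial likelihood with the same error decomposition
  direct <- function(cn, ref) {
    alt <- names(which.max(cn[setdiff(names(cn), ref)]))
    others <- setdiff(names(cn), c(ref, alt))
    e <- max(1e-3, min(0.74, 1.5 * sum(cn[others]) / sum(cn)))
    pv <- function(gt) {
      p <- stats::setNames(rep(e / 3, 4), c("A", "C", "G", "T"))
      if (length(gt) == 1) p[gt] <- 1 - e else p[gt] <- 0.5 - e / 3
      p
    }
    lik <- c(stats::dmultinom(cn, prob = pv(ref)),
             stats::dmultinom(cn, prob = pv(c(ref, alt))),
             stats::dmultinom(cn, prob = pv(alt)))
    lik[2] / sum(lik)
  }
  cases <- list(c(A = 480, C = 8, G = 500, T = 12),
                c(A = 55, C = 45, G = 0, T = 0),
                c(A = 90, C = 10, G = 0, T = 0),
                c(A = 30, C = 3, G = 2, T = 1),
                c(A = 60, C = 20, G = 15, T = 5))
  for (cn in cases) {
    got <- anchorphase:::het_posterior(cn, "A")
    expect_equal(got$conf_het, direct(cn, "A"), tolerance = 1e-12)
  }
})

test_that("variant filters remove exactly the offending candidates", {
  dnm <- dnm_record("amp", 1, "A", "G")
  toy <- make_pileup(data.frame(
    pos = 1:6,
    ref = "A",
    A = c(250, 55, 10, 90, 60, 55),
    G = c(250, 45, 9, 10, 20, 45),
    T = c(0, 0, 0, 0, 15, 0),
    C = c(0, 0, 0, 0, 5, 0),
    stringsAsFactors = FALSE))
  # pos 1: DNM, admitted; pos 2: clean het, kept
  # pos 3: depth 19 <= 20, removed; pos 4: AF 0.10 < 0.20, removed
  # pos 5: AF in window but high third/fourth-base noise sinks the
  #        heterozygosity posterior below 0.96, removed
  # pos 6: clean het, kept (then removed by exome disagreement below)
  calls <- call_variants(toy, dnm)
  expect_setequal(calls$pos, c(1L, 2L, 6L))
  expect_true(calls$is_dnm[calls$pos == 1])
  # exome polishing: pos 6 contradicted by a hom-ref exome at depth 60
  wes <- wes_evidence(
    sites = data.frame(pos = 2L, ref = "A", alt = "G",
                       gt_fa = "A/A", gt_mo = "G/G", gt_pr = "A/G",
                       dp_fa = 30L, dp_mo = 30L, dp_pr = 60L,
                       stringsAsFactors = FALSE),
    depth = data.frame(pos = c(2L, 6L), dp_fa = 60L, dp_mo = 60L,
                       dp_pr = 60L))
  polished <- wes_polish(calls, wes)
  expect_setequal(polished$pos, c(1L, 2L))
  expect_equal(polished$wes_support[polished$pos == 2], "validated")
  expect_equal(polished$wes_support[polished$pos == 1], "anchored")
  # uncovered positions pass through unvalidated
  wes0 <- wes_evidence(sites = wes$sites[0, ],
                       depth = data.frame(pos = integer(), dp_fa = integer(),
                                          dp_mo = integer(),
                                          dp_pr = integer()))
  through <- wes_polish(calls, wes0)
  expect_setequal(through$pos, c(1L, 2L, 6L))
  expect_true(all(through$wes_support[!through$is_dnm] == "unvalidated"))
})

test_that("the anchored DNM site is admitted regardless of allele fraction", {
  dnm <- dnm_record("amp", 3, "A", "T")
  toy <- make_pileup(data.frame(pos = 3L, ref = "A", A = 940L, T = 60L,
                                stringsAsFactors = FALSE))
  calls <- call_variants(toy, dnm)
  expect_equal(calls$alt, "T")   # only the validated alternate
  expect_equal(calls$af, 0.06)
  toy2 <- make_pileup(data.frame(pos = 3L, ref = "A", A = 500L, G = 480L,
                                 T = 20L, stringsAsFactors = FALSE))
  expect_equal(call_variants(toy2, dnm)$alt, "T")
  expect_error(call_variants(make_pileup(
    data.frame(pos = 9L, ref = "A", A = 50L, stringsAsFactors = FALSE)),
    dnm), "amplicon failed")
})

test_that("filters are monotone in depth and confidence thresholds", {
  set.seed(7)
  dnm <- dnm_record("amp", 1, "A", "G")
  for (rep in 1:20) {
    n <- 40
    toy <- make_pileup(data.frame(
      pos = seq_len(n), ref = sample(c("A", "C", "G", "T"), n, TRUE),
      A = rpois(n, 30), C = rpois(n, 10), G = rpois(n, 10),
      T = rpois(n, 5), stringsAsFactors = FALSE))
    toy$A[1] <- 50L; toy$G[1] <- 50L  # keep the DNM position covered
    toy$depth <- toy$A + toy$C + toy$G + toy$T + toy$del
    base <- call_variants(toy, dnm, phase_control(min_depth = 20,
                                                  min_conf = 0.9))
    stricter_depth <- call_variants(toy, dnm,
                                    phase_control(min_depth = 40,
                                                  min_conf = 0.9))
    stricter_conf <- call_variants(toy, dnm,
                                   phase_control(min_depth = 20,
                                                 min_conf = 0.99))
    expect_true(all(stricter_depth$pos %in% base$pos))
    expect_true(all(stricter_conf$pos %in% base$pos))
  }
})

test_that("exome trio iSNP discovery applies inheritance and depth rules", {
  dnm <- dnm_record("amp", 100, "A", "G")
  site <- function(pos, gf, gm, gp, df = 30L, dm = 30L, alt = "G") {
    data.frame(pos = pos, ref = "A", alt = alt, gt_fa = gf, gt_mo = gm,
               gt_pr = gp, dp_fa = df, dp_mo = dm, dp_pr = 40L,
               stringsAsFactors = FALSE)
  }
  wes <- wes_evidence(rbind(
    site(150, "A/A", "G/G", "A/G"),              # informative
    site(160, "A/G", "A/G", "A/G"),              # both parents het
    site(170, "A/A", "G/G", "A/G", dm = 4L),     # mother depth 4 < 5
    site(180, "A/G", "G/G", "A/G"),              # het x hom: informative
    site(190, "A/A", "G/G", "A/A"),              # proband homozygous
    site(200, "A/A", "G/G", "A/G", alt = "G,T"), # multi-allelic
    site(20000, "A/A", "G/G", "A/G")))           # outside window
  isnps <- discover_wes_isnps(wes, dnm, window_bp = 10000)
  expect_setequal(isnps$pos, c(150L, 180L))
  expect_equal(isnps$pat_allele[isnps$pos == 150], "A")
  expect_equal(isnps$mat_allele[isnps$pos == 150], "G")
  expect_equal(isnps$pat_allele[isnps$pos == 180], "A")
  expect_equal(isnps$distance[isnps$pos == 150], 50L)
})

test_that("targets fall into the documented phasing categories", {
  dnm <- dnm_record("amp", 1000, "A", "G")
  mk <- function(dists) {
    out <- anchorphase:::empty_isnps()
    for (d in dists)
      out <- rbind(out, data.frame(pos = 1000L + d, ref = "A", alt = "G",
                                   pat_allele = "A", mat_allele = "G",
                                   distance = d, dp_fa = 30L, dp_mo = 30L,
                                   dp_pr = 30L, source = "WES",
                                   stringsAsFactors = FALSE))
    class(out) <- c("isnp_candidates", "data.frame")
    out
  }
  expect_equal(classify_target(dnm, mk(150L)), 1L)
  expect_equal(classify_target(dnm, mk(c(-6000L, 7000L))), 2L)
  expect_equal(classify_target(dnm, mk(integer(0))), 3L)
  expect_equal(classify_target(dnm, mk(300L)), 1L)   # boundary inclusive
  expect_equal(classify_target(dnm, mk(301L)), 2L)
})

test_that("parental long-read typing enforces support and depth thresholds", {
  dnm <- dnm_record("amp", 100, "A", "G")
  cand <- data.frame(pos = 150L, ref = "A", alt = "G", type = "snv",
                     alt_count = 50L, depth = 100L, af = 0.5, conf = 1,
                     genotype = "het", hp_flag = FALSE, is_dnm = FALSE,
                     stringsAsFactors = FALSE)
  pu <- function(A, G, depth = A + G) {
    make_pileup(data.frame(pos = 150L, ref = "A", A = A, G = G,
                           stringsAsFactors = FALSE))
  }
  # father ~ all A, mother ~ all G: typed, tertiary source
  got <- discover_ont_parental_isnps(cand, pu(98, 2), pu(3, 97), dnm)
  expect_equal(nrow(got), 1L)
  expect_equal(got$pat_allele, "A")
  expect_equal(got$mat_allele, "G")
  expect_equal(got$source, "ONT_parent")
  # both parents heterozygous: not attributable
  expect_equal(nrow(discover_ont_parental_isnps(cand, pu(50, 48),
                                                pu(49, 51), dnm)), 0L)
  # father depth below the threshold: excluded
  expect_equal(nrow(discover_ont_parental_isnps(cand, pu(10, 5),
                                                pu(3, 97), dnm)), 0L)
  # boundary: depth exactly at the threshold is accepted
  got20 <- discover_ont_parental_isnps(cand, pu(19, 1), pu(1, 19), dnm)
  expect_equal(nrow(got20), 1L)
})
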