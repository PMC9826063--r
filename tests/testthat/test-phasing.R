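# constructed fixture: DNM C>T at 50, iSNP A(pat)/G(mat) at 80 on a 100 bp
# region; read composition configurable per haplotype pair
fixture_region <- function() {
  set.seed(424)
  seq <- random_reference(100)
  seq <- paste0(substr(seq, 1, 49), "C", substr(seq, 51, 79), "A",
                substr(seq, 81, 100))
  region_spec("amp", 1, 100, seq)
}

fixture_reads <- function(region, n_TA, n_CA, n_CG, extra = list()) {
  n <- n_TA + n_CA + n_CG
  overrides <- list(
    list(reads = seq_len(n_TA), pos = 50, base = "T"),
    list(reads = seq_len(n_TA), pos = 80, base = "A"),
    list(reads = n_TA + seq_len(n_CA), pos = 80, base = "A"),
    list(reads = n_TA + n_CA + seq_len(n_CG), pos = 80, base = "G"))
  make_reads(region, n, c(overrides, extra))
}

fixture_isnp <- function() {
  data.frame(pos = 80L, ref = "A", alt = "G", pat_allele = "A",
             mat_allele = "G", distance = 30L, dp_fa = 30L, dp_mo = 30L,
             dp_pr = 40L, source = "WES", stringsAsFactors = FALSE)
}

test_that("read splitting partitions DNM-covering reads by base", {
  region <- fixture_region()
  dnm <- dnm_record("amp", 50, "C", "T")
  rd <- fixture_reads(region, 25, 0, 25)
  # one read with an unexpected base, one deleted at the DNM
  rd$seq[3] <- paste0(substr(rd$seq[3], 1, 49), "G", substr(rd$seq[3], 51, 100))
  rd$cigar[7] <- "49M1D50M"
  rd$seq[7] <- paste0(substr(rd$seq[7], 1, 49), substr(rd$seq[7], 51, 100))
  rd$qual[7] <- substr(rd$qual[7], 1, 99)
  sp <- split_reads_by_dnm(rd, dnm)
  expect_equal(unname(sp$counts), unname(oracle_split_counts(rd, dnm)))
  expect_equal(sum(sp$counts), nrow(rd))
  expect_true(rd$qname[3] %in% sp$other$qname)  # wrong base
  expect_true(rd$qname[7] %in% sp$other$qname)  # deletion
  expect_error(split_reads_by_dnm(rd[0, ], dnm), "no reads cover")
})

test_that("linkage vetting accepts true iSNPs and flags noise variants", {
  region <- fixture_region()
  dnm <- dnm_record("amp", 50, "C", "T")
  cand <- function(pos, ref, alt) {
    data.frame(pos = pos, ref = ref, alt = alt, type = "snv",
               alt_count = 50L, depth = 100L, af = 0.5, conf = 1,
               genotype = "het", hp_flag = FALSE, is_dnm = FALSE,
               stringsAsFactors = FALSE)
  }
  # perfectly linked prezygotic iSNP
  rd <- fixture_reads(region, 50, 0, 50)
  sp <- split_reads_by_dnm(rd, dnm)
  lk <- find_linked_variants(sp, cand(80, "A", "G"))
  expect_equal(lk$status, "linked")
  expect_equal(lk$agreement, 1.0)
  expect_equal(lk$alt_group_base, "A")
  # a "false variant": half the reads carry G at position 20 regardless of
  # haplotype -> near-50% majorities in both groups, discordant
  set.seed(11)
  noisy <- fixture_reads(region, 50, 0, 50,
                         extra = list(list(reads = sample(100, 50),
                                           pos = 20, base = "G")))
  ref20 <- ref_base(region, 20)
  lk2 <- find_linked_variants(split_reads_by_dnm(noisy, dnm),
                              cand(20, ref20, "G"))
  expect_equal(lk2$status, "discordant")
  expect_lt(lk2$f_alt_group, 0.75)
  # insufficient spanning reads in the alt group
  tiny <- fixture_reads(region, 10, 0, 90)
  lk3 <- find_linked_variants(split_reads_by_dnm(tiny, dnm),
                              cand(80, "A", "G"))
  expect_equal(lk3$status, "insufficient")
  # postzygotic pattern: mixed wild-type group must stay linked
  post <- fixture_reads(region, 34, 66, 100)
  lk4 <- find_linked_variants(split_reads_by_dnm(post, dnm),
                              cand(80, "A", "G"))
  expect_equal(lk4$status, "linked")
  expect_equal(lk4$f_alt_group, 1.0)
})

test_that("noisy linked iSNP agreement matches its sampling expectation", {
  e <- 0.04
  sim <- simulate_dnm_target(seed = 131, coverage = 2000,
                             region_length = 400, isnp_offsets = 100,
                             error = error_model(e_sub = e, e_indel = 0))
  fit <- phase_dnm(sim$lr$reads, sim$dnm, sim$region, wes = sim$wes)
  # within each group, majority fraction over the allele pair: the
  # majority allele needs no error at either locus; the minority allele
  # arises from an iSNP error on a correct-haplotype read or from a
  # cross-contaminating read (DNM-position error) showing its own allele
  p_right <- 0.5 * (1 - e) * (1 - e) + 0.5 * (e / 3) * (e / 3)
  p_wrong <- 0.5 * (1 - e) * (e / 3) + 0.5 * (e / 3) * (1 - e)
  expected <- p_right / (p_right + p_wrong)
  expect_lt(abs(fit$chosen$f_alt_group - expected), 0.02)
  expect_lt(abs(fit$chosen$f_ref_group - expected), 0.02)
  expect_gt(fit$chosen$agreement, 0.9)
})

test_that("support categories follow the orthogonal-evidence tiers", {
  base <- data.frame(pos = c(80L, 80L, 80L, 80L), ref = "A", alt = "G",
                     type = "snv", alt_count = 50L, depth = 100L, af = 0.5,
                     conf = 1, genotype = "het", hp_flag = FALSE,
                     is_dnm = FALSE,
                     wes_support = c("validated", "validated",
                                     "unvalidated", "unvalidated"),
                     stringsAsFactors = FALSE)
  wes_isnps <- fixture_isnp()
  par_isnps <- fixture_isnp(); par_isnps$source <- "ONT_parent"
  got <- assign_support_category(base[1, ], wes_isnps)
  expect_equal(got$category, "primary")
  expect_equal(got$pat_allele, "A")
  got2 <- assign_support_category(base[2, ])        # proband exome only
  expect_equal(got2$category, "secondary")
  expect_true(is.na(got2$pat_allele))
  got3 <- assign_support_category(base[3, ],
                                  parental_isnps = par_isnps)
  expect_equal(got3$category, "tertiary")
  expect_equal(got3$mat_allele, "G")
  got4 <- assign_support_category(base[4, ])
  expect_equal(got4$category, "unvalidated")
})

test_that("only unsupported indels are dropped", {
  cand <- data.frame(pos = 1:4, ref = "A",
                     alt = c("<DEL>", "<DEL>", "G", "<INS>"),
                     type = c("del", "del", "snv", "ins"),
                     category = c("unvalidated", "secondary",
                                  "unvalidated", "unvalidated"),
                     stringsAsFactors = FALSE)
  out <- drop_unsupported_indels(cand)
  expect_setequal(out$pos, c(2L, 3L))
  expect_equal(attr(out, "n_dropped_indels"), 2L)
})

test_that("iSNP selection is lexicographic and order-independent", {
  mk <- function(pos, category, agreement, span = 200L) {
    data.frame(pos = pos, ref = "A", alt = "G", type = "snv",
               alt_count = 50L, depth = 100L, af = 0.5, conf = 1,
               genotype = "het", hp_flag = FALSE, is_dnm = FALSE,
               category = category, pat_allele = "A", mat_allele = "G",
               alt_group_base = "A", ref_group_base = "G",
               f_alt_group = agreement, f_ref_group = agreement,
               n_alt_group = span %/% 2L, n_ref_group = span - span %/% 2L,
               agreement = agreement, status = "linked",
               stringsAsFactors = FALSE)
  }
  dnm <- dnm_record("amp", 100, "C", "T")
  # category dominates agreement
  cands <- rbind(mk(150, "primary", 0.95), mk(160, "tertiary", 0.99))
  expect_equal(select_isnp(cands, dnm)$pos, 150)
  # within a category, agreement decides
  cands2 <- rbind(mk(150, "primary", 0.93), mk(160, "primary", 0.97))
  expect_equal(select_isnp(cands2, dnm)$pos, 160)
  # full tie: smaller |distance|, then leftmost
  cands3 <- rbind(mk(300, "primary", 0.95), mk(150, "primary", 0.95),
                  mk(50, "primary", 0.95))
  expect_equal(select_isnp(cands3, dnm)$pos, 50)  # |d| = 50 for both, left
  # stable under input permutation
  for (i in 1:5) {
    perm <- cands3[sample(nrow(cands3)), ]
    expect_equal(select_isnp(perm, dnm)$pos, 50)
  }
  # no eligible candidate: unphaseable, not an error
  disc <- mk(150, "primary", 0.95); disc$status <- "discordant"
  expect_null(select_isnp(disc, dnm))
  noattr <- mk(150, "unvalidated", 0.95)
  noattr$pat_allele <- NA_character_; noattr$mat_allele <- NA_character_
  expect_null(select_isnp(noattr, dnm))
})

test_that("allele tables equal a per-read double lookup", {
  region <- fixture_region()
  dnm <- dnm_record("amp", 50, "C", "T")
  chosen <- list(pos = 80L)
  rd <- fixture_reads(region, 17, 33, 50)
  tab <- build_allele_table(rd, dnm, chosen)
  expect_equal(attr(tab, "total"), 100L)
  expect_equal(sum(tab$count), attr(tab, "total"))
  expect_equal(sum(tab$frac), 1)
  got <- stats::setNames(tab$count, paste(tab$dnm_base, tab$isnp_base,
                                          sep = "|"))
  oracle <- oracle_allele_table(rd, 50, 80)
  expect_equal(got[order(names(got))], unlist(oracle), ignore_attr = TRUE)
  # conserved under read order permutation
  set.seed(3)
  tab2 <- build_allele_table(rd[sample(nrow(rd)), ], dnm, chosen)
  expect_equal(tab2[order(tab2$dnm_base, tab2$isnp_base), ],
               tab[order(tab$dnm_base, tab$isnp_base), ],
               ignore_attr = TRUE)
  # deletions tallied under the marker
  rd2 <- rd
  rd2$cigar[1] <- "79M1D20M"
  rd2$seq[1] <- paste0(substr(rd2$seq[1], 1, 79), substr(rd2$seq[1], 81, 100))
  rd2$qual[1] <- substr(rd2$qual[1], 1, 99)
  tab3 <- build_allele_table(rd2, dnm, chosen)
  expect_equal(anchorphase:::pair_count(tab3, "T", "-"), 1L)
  # too few spanning reads: flagged insufficient
  few <- build_allele_table(rd[1:5, ], dnm, chosen)
  expect_false(attr(few, "sufficient"))
})

test_that("anchoring removes more candidates than the basic filters alone", {
  e <- 0.04
  sim <- simulate_dnm_target(seed = 141, coverage = 500,
                             region_length = 600, isnp_offsets = 150,
                             error = error_model(e_sub = e, e_indel = 0))
  rd <- sim$lr$reads
  # inject 6 false heterozygous sites: a random half of reads mutated,
  # independent of haplotype, so they pass depth/AF/confidence but cannot
  # be linked to the DNM split
  set.seed(142)
  false_pos <- sample(setdiff(seq(20, 580), c(300, 450)), 6) + sim$region$start - 1L
  for (p in false_pos) {
    ref <- ref_base(sim$region, p)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    idx <- sample(nrow(rd), nrow(rd) %/% 2)
    for (i in idx) {
      dec <- anchorphase:::decode_alignment(rd$pos[i], rd$cigar[i], rd$seq[i])
      q <- match(p, dec$ref_pos)
      if (!is.na(q))
        substr(rd$seq[i], dec$q_idx[q], dec$q_idx[q]) <- alt
    }
  }
  pileup <- build_pileup(rd, sim$region)
  calls <- call_variants(pileup, sim$dnm)
  basic <- calls[!calls$is_dnm & calls$genotype == "het", ]
  expect_true(all(false_pos %in% basic$pos))  # basic filters keep them
  sp <- split_reads_by_dnm(rd, sim$dnm)
  lk <- find_linked_variants(sp, calls)
  surviving <- lk[lk$status == "linked", ]
  n_removed <- nrow(basic) - nrow(surviving)
  expect_gte(n_removed, 0L)
  expect_gt(n_removed, 0L)
  expect_false(any(false_pos %in% surviving$pos))
  expect_true(all(lk$status[lk$pos %in% false_pos] == "discordant"))
})
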