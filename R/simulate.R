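#' Long-read error model for the simulator
#'
#' Substitution and indel error are applied independently per base; indel
#' error is multiplied inside homopolymer runs, where single-base
#' insertions/deletions dominate real nanopore data. Substituted bases are
#' drawn uniformly from the three non-true bases. The published description
#' of the platform does not decompose its per-base error into substitution
#' versus indel components; the default preset reproduces the ~4%
#' substitution-scale background noise observed at informative-SNP
#' positions and is fully overridable.
#'
#' @param e_sub per-base substitution probability in `[0, 1)`.
#' @param e_indel per-base indel probability in `[0, 1)` outside
#'   homopolymers.
#' @param hp_multiplier multiplier (>= 1) applied to `e_indel` inside
#'   homopolymer runs of length >= `hp_min_run`.
#' @param hp_min_run minimum run length that counts as a homopolymer.
#' @param q_true,q_error phred-like base quality assigned to correctly
#'   copied and to erroneous (substituted/inserted) bases.
#' @return list of class `error_model`.
#' @export
error_model <- function(e_sub = 0.04, e_indel = 0.01, hp_multiplier = 5,
                        hp_min_run = 3L, q_true = 25L, q_error = 12L) {
  stopifnot(e_sub >= 0, e_sub < 1, e_indel >= 0, e_indel < 1,
            hp_multiplier >= 1, hp_min_run >= 2)
  structure(list(e_sub = e_sub, e_indel = e_indel,
                 hp_multiplier = hp_multiplier,
                 hp_min_run = as.integer(hp_min_run),
                 q_true = as.integer(q_true), q_error = as.integer(q_error)),
            class = "error_model")
}

#' A ground-truth de novo mutation record
#'
#' @param position 1-based position of the DNM.
#' @param ref_base,alt_base single reference and mutant bases (SNV).
#' @param origin parental haplotype carrying the mutation.
#' @param m mosaic fraction in `(0, 1]`: the fraction of molecules of the
#'   origin haplotype that carry the mutant base. `m = 1` corresponds to a
#'   prezygotic (germline) event; the expected mutant fraction over all
#'   molecules is `m / 2`.
#' @return list of class `dnm_truth`.
#' @export
dnm_truth <- function(position, ref_base, alt_base,
                      origin = c("paternal", "maternal"), m = 1) {
  origin <- match.arg(origin)
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  stopifnot(ref_base %in% BASES, alt_base %in% BASES, m > 0, m <= 1)
  if (ref_base == alt_base) stop("ref_base and alt_base must differ")
  structure(list(position = as.integer(position), ref_base = ref_base,
                 alt_base = alt_base, origin = origin, m = m),
            class = "dnm_truth")
}

#' Validated DNM record used to anchor phasing
#'
#' The pipeline-facing counterpart of [dnm_truth()]: contig, position and
#' the Sanger-validated reference/alternate bases, with no knowledge of
#' origin or mosaicism.
#' @param contig contig name.
#' @param position 1-based position.
#' @param ref_base,alt_base validated single bases.
#' @return list of class `dnm_record`.
#' @export
dnm_record <- function(contig, position, ref_base, alt_base) {
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  stopifnot(ref_base %in% BASES, alt_base %in% BASES)
  if (ref_base == alt_base) stop("ref_base and alt_base must differ")
  structure(list(contig = contig, position = as.integer(position),
                 ref_base = ref_base, alt_base = alt_base),
            class = "dnm_record")
}

# all ordered (paternal, maternal) transmissions from the parental
# genotypes that produce the unordered proband genotype {x, y}
attribution_pairs <- function(x, y, father, mother) {
  out <- list()
  for (p in unique(father)) for (m in unique(mother)) {
    if (setequal(c(p, m), c(x, y)) && length(unique(c(p, m))) == length(unique(c(x, y))))
      out[[length(out) + 1L]] <- c(paternal = p, maternal = m)
  }
  unique(out)
}

#' Simulate Mendelian trio genotypes with informative SNP sites
#'
#' Places heterozygous proband sites at the requested positions such that
#' each of the proband's two alleles is uniquely attributable to one parent
#' (an informative SNP). By default one parent is homozygous reference and
#' the other homozygous for a non-reference base; an explicit `schemes`
#' list can request other parental genotypes, which are rejected if they
#' cannot yield a uniquely attributable heterozygous proband.
#'
#' @param region a [region_spec()].
#' @param isnp_positions integer positions of the informative sites.
#' @param schemes optional list (parallel to `isnp_positions`) of
#'   `list(father = c(b1, b2), mother = c(b1, b2))` genotypes.
#' @param seed optional integer seed.
#' @return list of class `trio_genotypes` with a `sites` data.frame
#'   (`pos`, `ref`, `fa1`, `fa2`, `mo1`, `mo2`, `pat_allele`, `mat_allele`)
#'   and `dnm = NULL` until [place_dnm()] is applied.
#' @export
simulate_trio_genotypes <- function(region, isnp_positions, schemes = NULL,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  isnp_positions <- as.integer(isnp_positions)
  if (any(isnp_positions < region$start | isnp_positions > region$end))
    stop("iSNP position outside region")
  if (anyDuplicated(isnp_positions)) stop("duplicated iSNP positions")
  n <- length(isnp_positions)
  if (!is.null(schemes) && length(schemes) != n)
    stop("schemes must be parallel to isnp_positions")
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    pos <- isnp_positions[k]
    ref <- ref_base(region, pos)
    if (is.null(schemes)) {
      alt <- sample(setdiff(BASES, ref), 1L)
      if (stats::runif(1) < 0.5) {
        fa <- c(ref, ref); mo <- c(alt, alt)
      } else {
        fa <- c(alt, alt); mo <- c(ref, ref)
      }
    } else {
      fa <- toupper(schemes[[k]]$father); mo <- toupper(schemes[[k]]$mother)
      stopifnot(length(fa) == 2L, length(mo) == 2L,
                all(c(fa, mo) %in% BASES))
    }
    # choose a heterozygous transmission, then demand unique attribution
    trans <- expand.grid(p = unique(fa), m = unique(mo),
                         stringsAsFactors = FALSE)
    trans <- trans[trans$p != trans$m, , drop = FALSE]
    if (!nrow(trans))
      stop("site ", pos, ": scheme cannot yield a heterozygous proband")
    pick <- trans[sample.int(nrow(trans), 1L), ]
    ap <- attribution_pairs(pick$p, pick$m, fa, mo)
    if (length(ap) != 1L)
      stop("site ", pos, ": proband alleles are not uniquely attributable ",
           "to one parent each")
    rows[[k]] <- data.frame(pos = pos, ref = ref,
                            fa1 = fa[1], fa2 = fa[2],
                            mo1 = mo[1], mo2 = mo[2],
                            pat_allele = pick$p, mat_allele = pick$m,
                            stringsAsFactors = FALSE)
  }
  sites <- if (n) do.call(rbind, c(rows, list(make.row.names = FALSE)))
           else data.frame(pos = integer(), ref = character(),
                           fa1 = character(), fa2 = character(),
                           mo1 = character(), mo2 = character(),
                           pat_allele = character(), mat_allele = character(),
                           stringsAsFactors = FALSE)
  sites <- sites[order(sites$pos), , drop = FALSE]
  structure(list(region = region, sites = sites, dnm = NULL),
            class = "trio_genotypes")
}

#' Place a de novo mutation on one proband haplotype
#'
#' Both parents must be homozygous reference at the DNM position (otherwise
#' the variant would not be de novo). The mutation is carried by fraction
#' `m` of the molecules of the designated parental haplotype when reads are
#' simulated; parental genotypes are unchanged.
#'
#' @param genotypes a [simulate_trio_genotypes()] result.
#' @param dnm a [dnm_truth()].
#' @return the genotypes with the DNM attached.
#' @export
place_dnm <- function(genotypes, dnm) {
  stopifnot(inherits(genotypes, "trio_genotypes"), inherits(dnm, "dnm_truth"))
  region <- genotypes$region
  if (dnm$position < region$start || dnm$position > region$end)
    stop("DNM position outside region")
  if (ref_base(region, dnm$position) != dnm$ref_base)
    stop("DNM ref_base does not match the reference sequence")
  s <- genotypes$sites
  hit <- s[s$pos == dnm$position, ]
  if (nrow(hit)) {
    par_alleles <- unlist(hit[, c("fa1", "fa2", "mo1", "mo2")])
    if (any(par_alleles != dnm$ref_base))
      stop("a parent carries a non-reference allele at the DNM position: ",
           "not a de novo mutation")
  }
  genotypes$dnm <- dnm
  genotypes
}

# character vectors of the four possible proband molecule templates
haplotype_chars <- function(genotypes, haplotype = c("paternal", "maternal"),
                            mutant = FALSE) {
  haplotype <- match.arg(haplotype)
  region <- genotypes$region
  chars <- region$ref_chars
  s <- genotypes$sites
  if (nrow(s)) {
    al <- if (haplotype == "paternal") s$pat_allele else s$mat_allele
    chars[s$pos - region$start + 1L] <- al
  }
  if (mutant) {
    if (is.null(genotypes$dnm)) stop("no DNM placed")
    chars[genotypes$dnm$position - region$start + 1L] <- genotypes$dnm$alt_base
  }
  chars
}

# parent haplotype template (allele index 1 or 2)
parent_haplotype_chars <- function(genotypes, parent = c("father", "mother"),
                                   which_allele = 1L) {
  parent <- match.arg(parent)
  region <- genotypes$region
  chars <- region$ref_chars
  s <- genotypes$sites
  if (nrow(s)) {
    col <- paste0(if (parent == "father") "fa" else "mo", which_allele)
    chars[s$pos - region$start + 1L] <- s[[col]]
  }
  chars
}

# Apply the error model to one template; returns seq chars, quals, cigar
# and the alignment start offset (1-based within the template).
corrupt_template <- function(chars, error, hp_mask) {
  L <- length(chars)
  base <- chars
  is_err <- stats::runif(L) < error$e_sub
  n_err <- sum(is_err)
  if (n_err) {
    alt3 <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                   nrow = 3L, dimnames = list(NULL, BASES))
    base[is_err] <- alt3[cbind(sample.int(3L, n_err, replace = TRUE),
                               match(chars[is_err], BASES))]
  }
  rate <- error$e_indel * ifelse(hp_mask, error$hp_multiplier, 1)
  rate <- pmin(rate, 0.5)
  ind <- which(stats::runif(L) < rate)
  is_del <- logical(L)
  ins_after <- integer(0)
  if (length(ind)) {
    type_del <- stats::runif(length(ind)) < 0.5
    is_del[ind[type_del]] <- TRUE
    ins_after <- ind[!type_del]
  }
  # assemble emitted ops in reference order; insertions (base duplication)
  # sit immediately after their anchor position
  key <- c(seq_len(L), ins_after + 0.5)
  op <- c(ifelse(is_del, "D", "M"), rep("I", length(ins_after)))
  bs <- c(base, chars[ins_after])
  qv <- c(ifelse(is_err, error$q_error, error$q_true),
          rep(error$q_error, length(ins_after)))
  o <- order(key)
  op <- op[o]; bs <- bs[o]; qv <- qv[o]
  # strip leading/trailing deletions (they are not part of an alignment)
  nlead <- 0L
  while (nlead < length(op) && op[nlead + 1L] == "D") nlead <- nlead + 1L
  ntail <- 0L
  while (ntail < length(op) - nlead && op[length(op) - ntail] == "D")
    ntail <- ntail + 1L
  keep <- seq.int(nlead + 1L, length(op) - ntail)
  op <- op[keep]; bs <- bs[keep]; qv <- qv[keep]
  emitted <- op != "D"
  r <- rle(op)
  list(seq = paste(bs[emitted], collapse = ""),
       qual = paste(rawToChar(as.raw(qv[emitted] + 33L)), collapse = ""),
       cigar = paste0(r$lengths, r$values, collapse = ""),
       start_off = nlead + 1L)
}

#' Simulate amplicon-spanning long reads for the proband
#'
#' Each molecule is drawn from one of the proband's two haplotypes with
#' equal probability; molecules of the DNM origin haplotype carry the
#' mutant base with probability `m` (the mosaic fraction). The error model
#' is applied per base and reads are emitted already aligned, with CIGARs
#' recording the simulated indels, so the simulator doubles as the
#' alignment oracle. The true haplotype and mutant status of every read is
#' returned in a separate truth table, never in the SAM fields.
#'
#' @param genotypes a [trio_genotypes] with a DNM placed (see
#'   [place_dnm()]); a DNM-free object is allowed and yields pure
#'   haplotype reads.
#' @param coverage number of reads (>= 1).
#' @param error an [error_model()].
#' @param seed optional integer seed.
#' @param span_sampler `NULL` for full-length amplicon reads (the default:
#'   amplicons are sequenced end to end), or `function(n, L)` returning an
#'   `n x 2` matrix of 1-based start/end offsets for truncated spans.
#' @param qname_prefix prefix for read names.
#' @return list of class `sim_reads`: `reads` (an [aligned_reads()]
#'   data.frame) and `truth` (`qname`, `haplotype`, `mutant`).
#' @export
simulate_long_reads <- function(genotypes, coverage, error = error_model(),
                                seed = NULL, span_sampler = NULL,
                                qname_prefix = "lr") {
  stopifnot(inherits(genotypes, "trio_genotypes"))
  coverage <- as.integer(coverage)
  if (is.na(coverage) || coverage < 1L) stop("coverage must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  region <- genotypes$region
  L <- region_length(region)
  hp <- homopolymer_mask(region, error$hp_min_run)
  dnm <- genotypes$dnm
  tmpl <- list(paternal = haplotype_chars(genotypes, "paternal"),
               maternal = haplotype_chars(genotypes, "maternal"))
  if (!is.null(dnm))
    tmpl$mutant <- haplotype_chars(genotypes, dnm$origin, mutant = TRUE)
  hap <- ifelse(stats::runif(coverage) < 0.5, "paternal", "maternal")
  mutant <- if (is.null(dnm)) rep(FALSE, coverage) else
    hap == dnm$origin & stats::runif(coverage) < dnm$m
  spans <- if (is.null(span_sampler)) cbind(rep(1L, coverage), rep(L, coverage))
           else span_sampler(coverage, L)
  qname <- sprintf("%s_%05d", qname_prefix, seq_len(coverage))
  recs <- vector("list", coverage)
  for (i in seq_len(coverage)) {
    sl <- spans[i, 1]:spans[i, 2]
    chars <- if (mutant[i]) tmpl$mutant[sl] else tmpl[[hap[i]]][sl]
    cr <- corrupt_template(chars, error, hp[sl])
    recs[[i]] <- list(pos = region$start + spans[i, 1] - 1L + cr$start_off - 1L,
                      cigar = cr$cigar, seq = cr$seq, qual = cr$qual)
  }
  reads <- aligned_reads(
    qname = qname, flag = 0L, rname = region$contig,
    pos = vapply(recs, `[[`, 0, "pos"),
    mapq = 60L,
    cigar = vapply(recs, `[[`, "", "cigar"),
    seq = vapply(recs, `[[`, "", "seq"),
    qual = vapply(recs, `[[`, "", "qual"))
  truth <- data.frame(qname = qname, haplotype = hap, mutant = mutant,
                      stringsAsFactors = FALSE)
  structure(list(reads = reads, truth = truth), class = "sim_reads")
}

#' Simulate parental long reads over the target
#'
#' Used for category-3 targets, where intronic informative SNPs must be
#' typed from parental long-read data. Each read is drawn from one of the
#' parent's two haplotypes with equal probability.
#'
#' @inheritParams simulate_long_reads
#' @param parent `"father"` or `"mother"`.
#' @return a `sim_reads` list as in [simulate_long_reads()].
#' @export
simulate_parent_long_reads <- function(genotypes, parent = c("father", "mother"),
                                       coverage, error = error_model(),
                                       seed = NULL) {
  parent <- match.arg(parent)
  stopifnot(inherits(genotypes, "trio_genotypes"))
  coverage <- as.integer(coverage)
  if (is.na(coverage) || coverage < 1L) stop("coverage must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  region <- genotypes$region
  hp <- homopolymer_mask(region, error$hp_min_run)
  tmpl <- list(parent_haplotype_chars(genotypes, parent, 1L),
               parent_haplotype_chars(genotypes, parent, 2L))
  which_al <- sample.int(2L, coverage, replace = TRUE)
  qname <- sprintf("%s_%05d", substr(parent, 1, 2), seq_len(coverage))
  recs <- vector("list", coverage)
  for (i in seq_len(coverage)) {
    cr <- corrupt_template(tmpl[[which_al[i]]], error, hp)
    recs[[i]] <- list(pos = region$start + cr$start_off - 1L,
                      cigar = cr$cigar, seq = cr$seq, qual = cr$qual)
  }
  reads <- aligned_reads(
    qname = qname, flag = 0L, rname = region$contig,
    pos = vapply(recs, `[[`, 0, "pos"), mapq = 60L,
    cigar = vapply(recs, `[[`, "", "cigar"),
    seq = vapply(recs, `[[`, "", "seq"),
    qual = vapply(recs, `[[`, "", "qual"))
  truth <- data.frame(qname = qname, haplotype = paste0("allele", which_al),
                      mutant = FALSE, stringsAsFactors = FALSE)
  structure(list(reads = reads, truth = truth), class = "sim_reads")
}

#' Construct trio exome (WES-like) evidence
#'
#' `wes_evidence()` assembles the container directly from a `sites`
#' data.frame; `simulate_wes_evidence()` derives it from simulated trio
#' genotypes: per-sample depths are Poisson around `coverage_short`,
#' genotypes are reported error-free (exome short reads are treated as
#' high-accuracy orthogonal evidence), and positions listed in `uncovered`
#' are absent from the output, emulating intronic exome gaps. The proband's
#' base counts at the DNM position are recorded separately as
#' `dnm_support`.
#'
#' @param sites data.frame with columns `pos`, `ref`, `alt`, `gt_fa`,
#'   `gt_mo`, `gt_pr` (genotypes as base strings, e.g. `"A/G"`), `dp_fa`,
#'   `dp_mo`, `dp_pr`.
#' @param depth optional per-position coverage table (`pos`, `dp_fa`,
#'   `dp_mo`, `dp_pr`) describing the exome footprint, including
#'   non-variant positions; positions absent from it count as uncovered.
#'   When `NULL`, only the variant sites themselves are treated as covered.
#' @param dnm_support optional list with `pos`, `ref`, `alt`, `depth`,
#'   `alt_count` describing proband exome evidence at the DNM itself.
#' @return list of class `wes_evidence`.
#' @export
wes_evidence <- function(sites, depth = NULL, dnm_support = NULL) {
  need <- c("pos", "ref", "alt", "gt_fa", "gt_mo", "gt_pr",
            "dp_fa", "dp_mo", "dp_pr")
  stopifnot(all(need %in% names(sites)))
  if (!is.null(depth))
    stopifnot(all(c("pos", "dp_fa", "dp_mo", "dp_pr") %in% names(depth)))
  structure(list(sites = sites, depth = depth, dnm_support = dnm_support),
            class = "wes_evidence")
}

#' @rdname wes_evidence
#' @param genotypes a [trio_genotypes] (DNM optional).
#' @param coverage_short mean exome depth; `0` models a complete exome gap.
#' @param uncovered positions to drop from the evidence (exome-uncovered,
#'   e.g. intronic informative SNPs).
#' @param seed optional integer seed.
#' @export
simulate_wes_evidence <- function(genotypes, coverage_short = 72,
                                  uncovered = integer(0), seed = NULL) {
  stopifnot(inherits(genotypes, "trio_genotypes"), coverage_short >= 0)
  if (!is.null(seed)) set.seed(seed)
  region <- genotypes$region
  pos_all <- setdiff(seq.int(region$start, region$end), as.integer(uncovered))
  depth <- if (coverage_short > 0 && length(pos_all))
    data.frame(pos = pos_all,
               dp_fa = stats::rpois(length(pos_all), coverage_short),
               dp_mo = stats::rpois(length(pos_all), coverage_short),
               dp_pr = stats::rpois(length(pos_all), coverage_short))
  else NULL
  dp_at <- function(pos, who) {
    if (is.null(depth)) return(0L)
    hit <- match(pos, depth$pos)
    ifelse(is.na(hit), 0L, depth[[who]][hit])
  }
  s <- genotypes$sites
  keep <- !(s$pos %in% uncovered) & coverage_short > 0
  s <- s[keep, , drop = FALSE]
  n <- nrow(s)
  gt <- function(a, b) paste(a, b, sep = "/")
  alt <- character(n)
  for (k in seq_len(n)) {
    nonref <- setdiff(unique(unlist(s[k, c("fa1","fa2","mo1","mo2")])), s$ref[k])
    alt[k] <- if (length(nonref)) paste(nonref, collapse = ",") else "."
  }
  sites <- data.frame(pos = s$pos, ref = s$ref, alt = alt,
                      gt_fa = gt(s$fa1, s$fa2), gt_mo = gt(s$mo1, s$mo2),
                      gt_pr = gt(s$pat_allele, s$mat_allele),
                      dp_fa = dp_at(s$pos, "dp_fa"),
                      dp_mo = dp_at(s$pos, "dp_mo"),
                      dp_pr = dp_at(s$pos, "dp_pr"),
                      stringsAsFactors = FALSE)
  dnm_support <- NULL
  dnm <- genotypes$dnm
  if (!is.null(dnm) && coverage_short > 0 && !(dnm$position %in% uncovered)) {
    dpr <- dp_at(dnm$position, "dp_pr")
    alt_count <- stats::rbinom(1L, dpr, dnm$m / 2)
    dnm_support <- list(pos = dnm$position, ref = dnm$ref_base,
                        alt = dnm$alt_base, depth = dpr,
                        alt_count = alt_count)
    if (alt_count > 0L)
      sites <- rbind(sites, data.frame(
        pos = dnm$position, ref = dnm$ref_base, alt = dnm$alt_base,
        gt_fa = gt(dnm$ref_base, dnm$ref_base),
        gt_mo = gt(dnm$ref_base, dnm$ref_base),
        gt_pr = gt(dnm$ref_base, dnm$alt_base),
        dp_fa = dp_at(dnm$position, "dp_fa"),
        dp_mo = dp_at(dnm$position, "dp_mo"),
        dp_pr = dpr, stringsAsFactors = FALSE))
  }
  sites <- sites[order(sites$pos), , drop = FALSE]
  wes_evidence(sites, depth, dnm_support)
}

#' Simulate proband exome-like paired short reads
#'
#' Fragments of normally distributed length are placed uniformly over the
#' region; the two 150 bp mates share a read name so that fragment-level
#' base lookups (used by the WES-only phasing control) can combine them.
#' Substitution error only; qualities are constant and high.
#'
#' @param genotypes a [trio_genotypes] with DNM placed.
#' @param coverage target mean depth.
#' @param read_len mate length (bp).
#' @param frag_mean,frag_sd fragment length distribution.
#' @param e_sub per-base substitution error.
#' @param seed optional integer seed.
#' @return a `sim_reads` list; `truth` has one row per fragment.
#' @export
simulate_wes_reads <- function(genotypes, coverage = 60, read_len = 150L,
                               frag_mean = 350, frag_sd = 50,
                               e_sub = 0.001, seed = NULL) {
  stopifnot(inherits(genotypes, "trio_genotypes"))
  if (!is.null(seed)) set.seed(seed)
  region <- genotypes$region
  L <- region_length(region)
  dnm <- genotypes$dnm
  err <- error_model(e_sub = e_sub, e_indel = 0, q_true = 35L, q_error = 35L)
  n_frag <- max(1L, round(coverage * L / (2 * read_len)))
  flen <- pmin(L, pmax(read_len, round(stats::rnorm(n_frag, frag_mean, frag_sd))))
  fstart <- floor(stats::runif(n_frag, 1, L - flen + 1 + 1))
  tmpl <- list(paternal = haplotype_chars(genotypes, "paternal"),
               maternal = haplotype_chars(genotypes, "maternal"))
  if (!is.null(dnm))
    tmpl$mutant <- haplotype_chars(genotypes, dnm$origin, mutant = TRUE)
  hap <- ifelse(stats::runif(n_frag) < 0.5, "paternal", "maternal")
  mutant <- if (is.null(dnm)) rep(FALSE, n_frag) else
    hap == dnm$origin & stats::runif(n_frag) < dnm$m
  hpz <- rep(FALSE, L)  # no indel error: mask irrelevant
  rows <- vector("list", 2L * n_frag)
  qn <- sprintf("frag_%05d", seq_len(n_frag))
  for (i in seq_len(n_frag)) {
    chars <- if (mutant[i]) tmpl$mutant else tmpl[[hap[i]]]
    m1 <- fstart[i]:(fstart[i] + min(read_len, flen[i]) - 1L)
    m2 <- (fstart[i] + flen[i] - min(read_len, flen[i])):(fstart[i] + flen[i] - 1L)
    c1 <- corrupt_template(chars[m1], err, hpz[m1])
    c2 <- corrupt_template(chars[m2], err, hpz[m2])
    rows[[2L * i - 1L]] <- list(qn = qn[i], flag = 99L,
                                pos = region$start + m1[1] - 1L, c = c1)
    rows[[2L * i]] <- list(qn = qn[i], flag = 147L,
                           pos = region$start + m2[1] - 1L, c = c2)
  }
  reads <- aligned_reads(
    qname = vapply(rows, `[[`, "", "qn"),
    flag = vapply(rows, `[[`, 0L, "flag"),
    rname = region$contig,
    pos = vapply(rows, `[[`, 0, "pos"),
    mapq = 60L,
    cigar = vapply(rows, function(r) r$c$cigar, ""),
    seq = vapply(rows, function(r) r$c$seq, ""),
    qual = vapply(rows, function(r) r$c$qual, ""))
  truth <- data.frame(qname = qn, haplotype = hap, mutant = mutant,
                      stringsAsFactors = FALSE)
  structure(list(reads = reads, truth = truth), class = "sim_reads")
}

#' Simulate a complete single-target dataset
#'
#' One-stop generator for a phaseable amplicon target: random reference,
#' trio genotypes with one (or more) informative SNPs, a DNM of mosaic
#' fraction `m` on the chosen parental haplotype, deep proband long reads,
#' and trio exome evidence. Ground truth is retained for every component.
#' A seed is mandatory: one RNG stream drives the whole dataset and
#' identical seeds give identical datasets.
#'
#' @param seed integer seed (required).
#' @param region_length amplicon length (bp).
#' @param contig,region_start coordinates of the amplicon.
#' @param isnp_offsets offsets of informative SNPs relative to the DNM
#'   position (bp, signed).
#' @param coverage long-read depth.
#' @param m mosaic fraction of the DNM (1 = prezygotic).
#' @param origin parental haplotype carrying the DNM.
#' @param error an [error_model()].
#' @param wes_coverage mean exome depth for the trio evidence.
#' @param wes_uncovered_isnps if `TRUE` the informative SNP positions are
#'   omitted from the exome evidence (intronic scenario, category 3).
#' @return list of class `dnm_sim` with elements `region`, `genotypes`,
#'   `dnm` (a [dnm_record()]), `truth` (a [dnm_truth()]), `lr`
#'   (proband long reads, `sim_reads`), `wes` (a [wes_evidence()]).
#' @export
simulate_dnm_target <- function(seed,
                                region_length = 1500L,
                                contig = "ampl1", region_start = 1L,
                                isnp_offsets = 500L,
                                coverage = 1000L,
                                m = 1, origin = c("paternal", "maternal"),
                                error = error_model(),
                                wes_coverage = 72,
                                wes_uncovered_isnps = FALSE) {
  if (missing(seed)) stop("a seed is required")
  origin <- match.arg(origin)
  set.seed(as.integer(seed))
  region <- region_spec(contig, region_start,
                        region_start + region_length - 1L,
                        random_reference(region_length))
  dnm_pos <- region_start + region_length %/% 2L
  isnp_pos <- dnm_pos + as.integer(isnp_offsets)
  if (any(isnp_pos < region$start | isnp_pos > region$end))
    stop("isnp_offsets place an iSNP outside the region")
  geno <- simulate_trio_genotypes(region, isnp_pos)
  ref <- ref_base(region, dnm_pos)
  alt <- sample(setdiff(BASES, ref), 1L)
  truth <- dnm_truth(dnm_pos, ref, alt, origin = origin, m = m)
  geno <- place_dnm(geno, truth)
  lr <- simulate_long_reads(geno, coverage, error)
  wes <- simulate_wes_evidence(
    geno, coverage_short = wes_coverage,
    uncovered = if (wes_uncovered_isnps) isnp_pos else integer(0))
  structure(list(region = region, genotypes = geno,
                 dnm = dnm_record(contig, dnm_pos, ref, alt),
                 truth = truth, lr = lr, wes = wes),
            class = "dnm_sim")
}

#' Write a simulated dataset to files
#'
#' Emits the region FASTA, the proband SAM, the trio genotypes as a
#' minimal VCF (GT and DP fields) and the ground truth as JSON.
#'
#' @param sim a [simulate_dnm_target()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "dnm_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "region.fasta"),
             sam = file.path(dir, "proband.sam"),
             vcf = file.path(dir, "trio.vcf"),
             depth = file.path(dir, "wes_depth.tsv"),
             truth = file.path(dir, "truth.json"))
  write_region_fasta(sim$region, paths[["fasta"]])
  write_sam(sim$lr$reads, sim$region, paths[["sam"]])
  write_trio_vcf(sim$wes, sim$region, paths[["vcf"]])
  if (!is.null(sim$wes$depth))
    utils::write.table(sim$wes$depth, paths[["depth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  tr <- sim$truth
  jsonlite::write_json(list(
    dnm = list(contig = sim$region$contig, position = tr$position,
               ref = tr$ref_base, alt = tr$alt_base,
               origin = tr$origin, mosaic_fraction = tr$m),
    reads = sim$lr$truth), paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
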