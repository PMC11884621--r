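#' Define founder haplotypes for the gamma-like fragment
#'
#' Population structure for the simulator: `k` founder haplotypes over
#' `n_loci` biallelic background SNVs inside the gamma-like amplicon.
#' Each simulated haplotype descends from one founder with a small
#' per-locus mutation probability, which is what makes haplogroup
#' clustering recover the founders as groups.
#'
#' @param mini a [build_mini_reference()] result.
#' @param n_loci number of background SNV loci.
#' @param k number of founders.
#' @param founder_freqs founder sampling probabilities (length `k`, sums to 1).
#' @param mut_rate per-locus flip probability applied to each haplotype copy.
#' @param seed integer seed.
#' @return object of class `founder_set`: loci table (contig, pos, ref, alt)
#'   and a `k x n_loci` 0/1 founder matrix.
#' @export
make_founders <- function(mini, n_loci = 12L, k = 3L,
                          founder_freqs = NULL, mut_rate = 0.01, seed = 1L) {
  if (is.null(founder_freqs)) founder_freqs <- rep(1 / k, k)
  stopifnot(length(founder_freqs) == k, abs(sum(founder_freqs) - 1) < 1e-8)
  L <- mini$layout
  pp <- mini$paralog_pairs$gammaC
  with_seed(seed, {
    lo <- L$gamma_start + L$margin + 30L
    hi <- L$gamma_end - L$margin - 30L
    forbidden <- c(pp$unit_a[1] + pp$diagnostic$offset,
                   pp$unit_b[1] + pp$diagnostic$offset)
    pos <- integer(0)
    while (length(pos) < n_loci) {
      p <- sample(seq.int(lo, hi), n_loci * 2L)
      p <- setdiff(p, c(forbidden, pos))
      pos <- c(pos, p)[seq_len(min(n_loci, length(pos) + length(p)))]
    }
    pos <- sort(pos)
    ref <- vapply(pos, function(p) substr(mini$contigs[["gammaC"]], p + 1L, p + 1L), "")
    alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1), "")
    # founder 0/1 patterns: distinct, each locus polymorphic across founders
    repeat {
      fm <- matrix(stats::rbinom(k * n_loci, 1L, 0.5), nrow = k)
      if (!anyDuplicated(apply(fm, 1, paste, collapse = "")) &&
          all(colSums(fm) > 0L & colSums(fm) < k)) break
    }
    structure(list(loci = data.frame(contig = "gammaC", pos = pos, ref = ref,
                                     alt = alt, stringsAsFactors = FALSE),
                   founders = fm, founder_freqs = founder_freqs,
                   mut_rate = mut_rate),
              class = "founder_set")
  })
}

#' Simulate a diploid cohort with thalassemia-like alleles and phenotypes
#'
#' Draws diploid genotypes per catalogued allele (independent Bernoulli per
#' haplotype at the configured frequency), optionally layers founder-derived
#' background haplotypes on the gamma-like fragment, resolves event overlaps
#' per haplotype (larger events win), and generates phenotypes under an
#' additive model: `phenotype = intercept + sum(effect * dosage) + noise`.
#' Transfusion-free survival times are exponential with a genotype-scaled
#' hazard and right-censored at the follow-up age.
#'
#' Reads are not materialised here; use [cohort_sample_reads()] (streaming)
#' or [write_cohort()] (FASTQ + truth files on disk).
#'
#' @param mini a [build_mini_reference()] result.
#' @param pnl the matching [mini_panel()].
#' @param catalog allele catalog, see [default_catalog()].
#' @param n_samples number of diploid samples.
#' @param allele_freqs named vector of per-haplotype allele frequencies
#'   (names from `catalog$name`; alleles absent from the vector have
#'   frequency 0).
#' @param founders optional [make_founders()] result.
#' @param phenotype_model list with `intercept` (g/L), `sd` (residual SD),
#'   `effects` (named per-allele additive effect on HbF, g/L per allele
#'   copy), `founder_effects` (per-founder additive effect of carrying that
#'   founder haplotype), `surv_base_rate`, `surv_effects`,
#'   `surv_founder_effects` (log-hazard scale), `followup_age` (years),
#'   `ferritin_intercept`, `ferritin_sd`.
#' @param depth,sub_rate,ins_rate,del_rate,depth_model sequencing parameters
#'   forwarded to [simulate_ccs_reads()].
#' @param seed master seed; every per-sample stream is derived from it.
#' @return object of class `sim_cohort` with `$genotypes` (per-sample event
#'   names per haplotype), `$dosages` (samples x catalog alleles),
#'   `$founder_of` (samples x 2 founder index, NA without founders),
#'   `$truth_small` (phased truth SNV/indel table), `$phenotypes`, `$params`.
#' @export
simulate_cohort <- function(mini, pnl, catalog, n_samples, allele_freqs,
                            founders = NULL, phenotype_model = list(),
                            depth = 50L, sub_rate = 0.003, ins_rate = 0.001,
                            del_rate = 0.001,
                            depth_model = "fixed", seed = 1L) {
  stopifnot(all(allele_freqs >= 0 & allele_freqs <= 1))
  pm <- utils::modifyList(list(
    intercept = 5, sd = 3, effects = numeric(0), founder_effects = NULL,
    surv_base_rate = 0.25, surv_effects = numeric(0),
    surv_founder_effects = NULL, followup_age = 18,
    ferritin_intercept = 1500, ferritin_sd = 400), phenotype_model)

  freqs <- stats::setNames(rep(0, nrow(catalog)), catalog$name)
  known <- intersect(names(allele_freqs), catalog$name)
  if (length(setdiff(names(allele_freqs), catalog$name)))
    stop_with("allele_freqs names absent from catalog: %s",
              paste(setdiff(names(allele_freqs), catalog$name), collapse = ", "))
  freqs[known] <- allele_freqs[known]

  genotypes <- vector("list", n_samples)
  founder_of <- matrix(NA_integer_, n_samples, 2)
  dosages <- matrix(0L, n_samples, nrow(catalog),
                    dimnames = list(NULL, catalog$name))
  truth_small <- list()

  with_seed(derive_seed(seed, 0L), {
    for (i in seq_len(n_samples)) {
      haps <- list()
      for (h in 1:2) {
        carried <- catalog$name[stats::runif(nrow(catalog)) < freqs]
        evs <- lapply(carried, function(nm)
          catalog_event(catalog[catalog$name == nm, ]))
        fl <- NULL
        if (!is.null(founders)) {
          fidx <- sample.int(nrow(founders$founders), 1,
                             prob = founders$founder_freqs)
          founder_of[i, h] <- fidx
          alle <- founders$founders[fidx, ]
          flips <- stats::runif(length(alle)) < founders$mut_rate
          alle <- ifelse(flips, 1L - alle, alle)
          fl <- lapply(which(alle == 1L), function(j)
            allele_event("SNV", "gammaC", founders$loci$pos[j],
                         founders$loci$pos[j] + 1L, founders$loci$alt[j],
                         name = sprintf("bg_%d", j)))
        }
        haps[[h]] <- resolve_overlaps(c(evs, fl))
      }
      # a deletion that removes an entire amplicon makes loci there
      # hemizygous: the remaining haplotype's alleles read as homozygous.
      # Such diplotypes are not simulated, so truth zygosity is always
      # observable from read fractions.
      is_sv <- function(e) e$kind %in% c("large_deletion", "duplication",
                                         "crossover")
      dropped_amps <- function(evs) {
        del <- Filter(function(e) e$kind == "large_deletion", evs)
        unlist(lapply(del, function(s)
          vapply(Filter(function(a) a$contig == s$contig &&
                          s$start <= a$start && a$end <= s$end,
                        pnl$amplicons), `[[`, "", "id")))
      }
      for (h in 1:2) {
        gone <- dropped_amps(haps[[3L - h]])
        if (length(gone) == 0L) next
        amps <- pnl$amplicons[gone]
        haps[[h]] <- Filter(function(e) {
          if (is_sv(e)) return(TRUE)
          !any(vapply(amps, function(a)
            a$contig == e$contig && e$start >= a$start && e$start < a$end,
            TRUE))
        }, haps[[h]])
      }
      for (h in 1:2) {
        kept <- haps[[h]]
        keptn <- vapply(kept, `[[`, "", "name")
        hit <- intersect(keptn, catalog$name)
        dosages[i, hit] <- dosages[i, hit] + 1L
        small <- kept[vapply(kept, function(e)
          e$kind %in% c("SNV", "small_indel"), TRUE)]
        if (length(small))
          truth_small[[length(truth_small) + 1L]] <- data.frame(
            sample_id = sprintf("S%04d", i), hap = h,
            contig = vapply(small, `[[`, "", "contig"),
            name = vapply(small, `[[`, "", "name"),
            start = vapply(small, `[[`, 0L, "start"),
            end = vapply(small, `[[`, 0L, "end"),
            alt_seq = vapply(small, `[[`, "", "alt_seq"),
            stringsAsFactors = FALSE)
      }
      genotypes[[i]] <- haps
    }

    # phenotypes under the additive model
    eff <- stats::setNames(rep(0, nrow(catalog)), catalog$name)
    eff[names(pm$effects)] <- pm$effects
    g_hbf <- as.numeric(dosages %*% eff)
    s_eff <- stats::setNames(rep(0, nrow(catalog)), catalog$name)
    s_eff[names(pm$surv_effects)] <- pm$surv_effects
    g_surv <- as.numeric(dosages %*% s_eff)
    if (!is.null(founders) && !is.null(pm$founder_effects)) {
      fcount <- t(vapply(seq_len(n_samples), function(i)
        tabulate(founder_of[i, ], nbins = nrow(founders$founders)),
        numeric(nrow(founders$founders))))
      g_hbf <- g_hbf + as.numeric(fcount %*% pm$founder_effects)
      if (!is.null(pm$surv_founder_effects))
        g_surv <- g_surv + as.numeric(fcount %*% pm$surv_founder_effects)
    }
    age <- round(stats::runif(n_samples, 3, 40), 1)
    sex <- sample(c("F", "M"), n_samples, replace = TRUE)
    hbf <- pmax(0, pm$intercept + g_hbf + stats::rnorm(n_samples, 0, pm$sd))
    tt <- stats::rexp(n_samples, rate = pm$surv_base_rate * exp(-g_surv))
    transfused <- tt <= pm$followup_age
    aft <- round(pmin(tt, pm$followup_age), 2)
    ferritin <- pmax(10, pm$ferritin_intercept +
                       stats::rnorm(n_samples, 0, pm$ferritin_sd))
    phen <- data.frame(sample_id = sprintf("S%04d", seq_len(n_samples)),
                       hbf = round(hbf, 2), age_first_transfusion = aft,
                       transfused = transfused, ferritin = round(ferritin, 1),
                       age = age, sex = sex, stringsAsFactors = FALSE)
  })

  structure(list(
    genotypes = genotypes, dosages = dosages, founder_of = founder_of,
    truth_small = if (length(truth_small)) do.call(rbind, truth_small) else
      data.frame(sample_id = character(), hap = integer(), contig = character(),
                 name = character(), start = integer(), end = integer(),
                 alt_seq = character()),
    phenotypes = phen, founders = founders, catalog = catalog,
    params = list(seed = seed, n_samples = n_samples, depth = depth,
                  sub_rate = sub_rate, ins_rate = ins_rate,
                  del_rate = del_rate, depth_model = depth_model,
                  allele_freqs = freqs, phenotype_model = pm)),
    class = "sim_cohort")
}

# Keep a maximal non-overlapping subset of events on one haplotype,
# larger events first (an SV swallows any small event inside it).
resolve_overlaps <- function(events) {
  if (length(events) <= 1L) return(events)
  span <- vapply(events, function(e) e$end - e$start, 0L)
  ord <- order(-span, vapply(events, `[[`, 0L, "start"))
  kept <- list()
  for (i in ord) {
    e <- events[[i]]
    clash <- any(vapply(kept, function(k)
      k$contig == e$contig && e$start < k$end && k$start < e$end &&
        !(insertion_event(e) && insertion_event(k) && e$start != k$start),
      TRUE))
    if (!clash) kept[[length(kept) + 1L]] <- e
  }
  kept[order(vapply(kept, `[[`, 0L, "start"))]
}

#' Materialise the reads of one simulated sample
#'
#' Deterministic given the cohort's master seed and the sample index, so a
#' pipeline can stream samples without holding the cohort's reads in memory.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param i sample index.
#' @param mini,pnl the mini-reference and panel the cohort was built over.
#' @param wild optional precomputed wild-type product table
#'   (`in_silico_pcr(mini$contigs, pnl)`), reused across samples.
#' @return list with `reads` (data.frame `read_id`, `amplicon_id` (truth),
#'   `seq`, `qual`, `hap`), `products` (per-haplotype product table) and
#'   `hap_seqs`.
#' @export
cohort_sample_reads <- function(cohort, i, mini, pnl, wild = NULL) {
  p <- cohort$params
  haps <- cohort$genotypes[[i]]
  if (is.null(wild)) wild <- in_silico_pcr(mini$contigs, pnl)
  amp_contig <- vapply(pnl$amplicons, `[[`, "", "contig")
  prods <- list()
  for (h in 1:2) {
    mut_ct <- unique(vapply(haps[[h]], `[[`, "", "contig"))
    hseq <- mini$contigs[intersect(mut_ct, names(mini$contigs))]
    for (ct in names(hseq)) {
      evs <- haps[[h]][vapply(haps[[h]], `[[`, "", "contig") == ct]
      hseq[[ct]] <- apply_events(mini$contigs[[ct]], evs)$seq
    }
    pr_mut <- if (length(hseq)) in_silico_pcr(hseq, pnl) else
      wild[0, , drop = FALSE]
    keep_wild <- names(amp_contig)[!amp_contig %in% mut_ct]
    pr <- rbind(pr_mut, wild[wild$amplicon_id %in% keep_wild, , drop = FALSE])
    if (nrow(pr)) { pr$hap <- h; prods[[h]] <- pr }
  }
  prods <- if (length(prods)) do.call(rbind, prods) else
    data.frame(amplicon_id = character(), seq = character(),
               length = integer(), hap = integer())
  reads <- simulate_ccs_reads(
    prods, depth = ceiling(p$depth / 2), sub_rate = p$sub_rate,
    ins_rate = p$ins_rate, del_rate = p$del_rate,
    seed = derive_seed(p$seed, i), depth_model = p$depth_model,
    read_prefix = sprintf("S%04d", i))
  list(reads = reads, products = prods)
}

#' Write a simulated cohort to disk
#'
#' Emits one FASTQ per sample, a phased truth VCF (1-based, `GT` with `|`),
#' a truth BED of SV intervals, the phenotype TSV and a JSON run manifest
#' recording the seed and parameters.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param mini,pnl mini-reference and panel.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, mini, pnl, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- cohort$params$n_samples
  for (i in seq_len(n)) {
    sr <- cohort_sample_reads(cohort, i, mini, pnl)
    write_fastq(sr$reads, file.path(dir, sprintf("S%04d.fastq", i)))
  }
  write_truth_vcf(cohort, mini, file.path(dir, "truth.vcf"))
  write_truth_bed(cohort, file.path(dir, "truth_sv.bed"))
  utils::write.table(cohort$phenotypes, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- cohort$params
  manifest$allele_freqs <- as.list(manifest$allele_freqs)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Phased truth small-variant VCF for a simulated cohort
#' @param cohort a [simulate_cohort()] result.
#' @param mini the mini-reference the cohort was simulated over.
#' @param path output VCF path.
#' @export
write_truth_vcf <- function(cohort, mini, path) {
  ts <- cohort$truth_small
  samples <- cohort$phenotypes$sample_id
  hdr <- c("##fileformat=VCFv4.3",
           "##source=globintyper-simulator",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  if (nrow(ts) == 0L) { writeLines(hdr, path); return(invisible(path)) }
  ts$key <- paste(ts$contig, ts$start, ts$end, ts$alt_seq, sep = "|")
  recs <- unique(ts[, c("contig", "name", "start", "end", "alt_seq", "key")])
  recs <- recs[order(recs$contig, recs$start), ]
  lines <- vapply(seq_len(nrow(recs)), function(r) {
    rr <- recs[r, ]
    v <- event_vcf_alleles(mini$contigs[[rr$contig]], rr$start, rr$end,
                           rr$alt_seq)
    gt <- vapply(samples, function(s) {
      h1 <- any(ts$sample_id == s & ts$hap == 1 & ts$key == rr$key)
      h2 <- any(ts$sample_id == s & ts$hap == 2 & ts$key == rr$key)
      sprintf("%d|%d", h1, h2)
    }, "")
    paste(c(rr$contig, v$pos1, rr$name, v$ref, v$alt, ".", "PASS", ".",
            "GT", gt), collapse = "\t")
  }, "")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

# VCF (1-based, anchored) alleles for a raw replacement of [start, end)
event_vcf_alleles <- function(ref_seq, start, end, alt_seq) {
  if (end - start == 1L && nchar(alt_seq) == 1L)            # SNV
    return(list(pos1 = start + 1L,
                ref = substr(ref_seq, start + 1L, start + 1L),
                alt = alt_seq))
  anchor <- substr(ref_seq, start, start)                   # base before event
  if (nchar(alt_seq) == 0L)                                 # deletion
    return(list(pos1 = start, ref = paste0(anchor, substr(ref_seq, start + 1L, end)),
                alt = anchor))
  if (end == start)                                         # insertion
    return(list(pos1 = start, ref = anchor, alt = paste0(anchor, alt_seq)))
  list(pos1 = start + 1L, ref = substr(ref_seq, start + 1L, end),
       alt = alt_seq)                                       # block substitution
}

#' Truth BED of structural-variant intervals
#' @param cohort a [simulate_cohort()] result.
#' @param path output BED path.
#' @export
write_truth_bed <- function(cohort, path) {
  cat <- cohort$catalog
  svr <- cat[cat$type %in% c("deletion", "duplication"), ]
  rows <- character(0)
  for (i in seq_len(nrow(cohort$dosages))) {
    for (a in svr$name) {
      d <- cohort$dosages[i, a]
      if (d > 0) {
        r <- svr[svr$name == a, ]
        rows <- c(rows, sprintf("%s\t%d\t%d\t%s;%s;dosage=%d", r$contig,
                                r$event_start, r$event_end,
                                cohort$phenotypes$sample_id[i], a, d))
      }
    }
  }
  writeLines(rows, path)
  invisible(path)
}
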