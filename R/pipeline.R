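#' Default pipeline configuration
#'
#' Every threshold the assay does not pin down is collected here with its
#' default; a YAML file with the same structure can override any subset
#' (see [load_config()]).
#'
#' @return named list of parameters.
#' @export
default_config <- function() {
  list(
    primer_window = 50L,          # bp scanned at each read end
    length_tolerance = 100L,      # bp, SV length clustering
    sv_min_depth = 10L,           # reads per amplicon for SV calling
    min_sv_reads = 5L,            # reads supporting a shifted cluster
    min_split_reads = 3L,         # reads for breakpoint refinement
    min_depth = 20L,              # depth filter for small-variant PASS calls
    het_window = c(0.25, 0.75),   # allele/read fraction window for het
    hom_min = 0.9,                # fraction for hom
    min_alt_frac = 0.2,
    min_alt_reads = 5L,
    min_identity = 0.7,           # alignment identity floor
    band_extra = 60L,             # alignment band half-width
    min_reads_per_cluster = 3L,   # phasing support
    conversion_min_run = 3L,      # diagnostic sites per conversion tract
    maf_min = 0.01,               # LD / association MAF floor
    r2_threshold = 0.8)           # LD block threshold
}

#' Load a run configuration from YAML
#' @param path YAML file; missing keys fall back to [default_config()].
#' @return named list.
#' @export
load_config <- function(path) {
  utils::modifyList(default_config(), yaml::read_yaml(path))
}

#' Genotype one sample's reads over a panel
#'
#' Runs the per-sample pipeline: primer-based read assignment, SV calling
#' from primer-pair identity and read length (with split-read breakpoint
#' refinement of deletions), alignment and pileup of REF-like reads, diploid
#' SNV/indel calling with the depth filter, MEC phasing, and catalog
#' annotation.
#'
#' @param reads data.frame with `read_id`, `seq`.
#' @param pnl a [panel()].
#' @param catalog optional allele catalog for annotation.
#' @param config see [default_config()].
#' @param mini optional mini-reference for conversion detection.
#' @return list with `assignments`, `sv_calls` (incl. `breakpoints`),
#'   `small_calls` (contig coordinates), `phase` (per amplicon),
#'   `annotation`, `log` (per-stage counts).
#' @export
genotype_sample <- function(reads, pnl, catalog = NULL,
                            config = default_config(), mini = NULL) {
  if (nrow(reads) == 0L) stop_with("no reads supplied")
  asn <- assign_reads(reads, pnl, window = config$primer_window)
  sv <- call_svs(asn, pnl, length_tolerance = config$length_tolerance,
                 min_depth = config$sv_min_depth,
                 het_window = config$het_window, hom_min = config$hom_min,
                 min_sv_reads = config$min_sv_reads)
  # split-read refinement of deletion calls
  sv$bp_left <- rep(NA_integer_, nrow(sv))
  sv$bp_right <- rep(NA_integer_, nrow(sv))
  sv$bp_microhomology <- rep(NA_integer_, nrow(sv))
  for (k in seq_len(nrow(sv))) {
    if (is.na(sv$length_shift[k]) || sv$length_shift[k] >= 0) next
    a <- pnl$amplicons[[sv$amplicon_id[k]]]
    ref_seq <- substr(pnl$reference[[a$contig]], a$start + 1L, a$end)
    rd <- asn[asn$amplicon_id == a$id, ]
    dev <- rd$read_length - a$expected_length
    supp <- rd$oriented_seq[abs(dev - sv$length_shift[k]) <=
                              config$length_tolerance]
    bp <- tryCatch(refine_breakpoint(supp, ref_seq,
                                     min_reads = config$min_split_reads),
                   error = function(e) NULL)
    if (!is.null(bp)) {
      sv$bp_left[k] <- a$start + bp$left
      sv$bp_right[k] <- a$start + bp$right
      sv$bp_microhomology[k] <- bp$microhomology_len
    }
  }
  small <- list(); phase <- list(); conversions <- list()
  for (a in pnl$amplicons) {
    rd <- asn[asn$amplicon_id == a$id, ]
    if (nrow(rd) == 0L) next
    ref_seq <- substr(pnl$reference[[a$contig]], a$start + 1L, a$end)
    pile <- pileup_reads(rd$oriented_seq, ref_seq,
                         band_extra = config$band_extra,
                         min_identity = config$min_identity)
    calls <- call_small_variants(pile, min_depth = config$min_depth,
                                 het_window = config$het_window,
                                 hom_min = config$hom_min,
                                 min_alt_frac = config$min_alt_frac,
                                 min_alt_reads = config$min_alt_reads)
    ph <- phase_amplicon(pile, calls,
                         min_reads_per_cluster = config$min_reads_per_cluster)
    if (nrow(calls)) {
      calls$contig <- a$contig
      calls$pos <- calls$pos + a$start     # amplicon offset -> contig coords
      calls$amplicon_id <- a$id
      calls$paralog <- vapply(calls$pos, function(p)
        paste(assign_paralog(p, a), collapse = ","), "")
      small[[a$id]] <- calls
    }
    if (nrow(ph$loci)) ph$loci$pos <- ph$loci$pos + a$start
    phase[[a$id]] <- ph
    # conversion tracts on paralog pairs
    if (!is.null(mini) && a$contig %in% names(mini$paralog_pairs) &&
        ph$phased && nrow(ph$loci)) {
      pair <- mini$paralog_pairs[[a$contig]]
      for (h in 1:2) for (un in c("unit_a", "unit_b")) {
        tr <- detect_conversion(ph$haplotypes[h, ], ph$loci, pair, unit = un,
                                min_run = config$conversion_min_run)
        if (nrow(tr)) {
          tr$amplicon_id <- a$id; tr$haplotype_index <- h
          conversions[[length(conversions) + 1L]] <- tr
        }
      }
    }
  }
  small_calls <- if (length(small)) do.call(rbind, small) else {
    x <- empty_small_calls(); x$contig <- character(0)
    x$amplicon_id <- character(0); x$paralog <- character(0); x
  }
  rownames(small_calls) <- NULL
  ann <- if (!is.null(catalog)) annotate_alleles(small_calls, sv, catalog)
         else NULL
  list(assignments = asn, sv_calls = sv, small_calls = small_calls,
       phase = phase,
       conversions = if (length(conversions)) do.call(rbind, conversions)
                     else NULL,
       annotation = ann,
       log = c(reads_in = nrow(reads),
               reads_assigned = sum(asn$amplicon_id != "UNASSIGNED"),
               sv_calls = nrow(sv), small_variants = nrow(small_calls),
               amplicons_phased = sum(vapply(phase, `[[`, TRUE, "phased"))))
}

#' Run the genotyping pipeline over a cohort
#'
#' Orchestrates per-sample genotyping over either simulated samples
#' (streamed from a [simulate_cohort()] object so reads never accumulate in
#' memory) or a list of FASTQ files. Writes VCF/TSV outputs and a JSON
#' manifest when `out_dir` is given.
#'
#' @param input a `sim_cohort` or a named character vector of FASTQ paths
#'   (names = sample ids).
#' @param pnl a [panel()].
#' @param mini mini-reference (required for simulated input and conversion
#'   detection).
#' @param catalog allele catalog for annotation.
#' @param config see [default_config()].
#' @param out_dir optional output directory.
#' @return list of per-sample [genotype_sample()] results (named by sample),
#'   with attribute `manifest`.
#' @export
run_genotyping <- function(input, pnl, mini = NULL, catalog = NULL,
                           config = default_config(), out_dir = NULL) {
  results <- list()
  if (inherits(input, "sim_cohort")) {
    if (is.null(mini)) stop_with("simulated input needs the mini-reference")
    ids <- input$phenotypes$sample_id
    wild <- in_silico_pcr(mini$contigs, pnl)
    for (i in seq_along(ids)) {
      sr <- cohort_sample_reads(input, i, mini, pnl, wild = wild)
      results[[ids[i]]] <- genotype_sample(sr$reads, pnl, catalog, config,
                                           mini = mini)
    }
  } else {
    ids <- names(input)
    if (is.null(ids)) ids <- sub("\\.fastq$", "", basename(input))
    for (i in seq_along(input)) {
      reads <- read_fastq(input[[i]])
      if (nrow(reads) == 0L) stop_with("empty FASTQ: %s", input[[i]])
      results[[ids[i]]] <- genotype_sample(reads, pnl, catalog, config,
                                           mini = mini)
    }
  }
  manifest <- list(samples = length(results), config = config,
                   package_version = as.character(utils::packageVersion("globintyper")))
  attr(results, "manifest") <- manifest
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_small_vcf(results, file.path(out_dir, "small_variants.vcf"))
    write_sv_vcf(results, pnl, file.path(out_dir, "svs.vcf"))
    write_haplotype_tsv(results, file.path(out_dir, "haplotypes.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  results
}

#' Population analytics over genotyped samples
#'
#' Builds the 0/1 haplotype matrix for one amplicon, clusters haplogroups,
#' computes LD and TF motif alterations, and runs the genotype-phenotype
#' battery: per-variant association with BH-FDR, per-haplogroup phenotype
#' comparisons and transfusion-free survival.
#'
#' @param geno [run_genotyping()] results.
#' @param phenotypes phenotype table (columns `sample_id`, `hbf`,
#'   `age_first_transfusion`, `transfused`, `ferritin`, `age`, `sex`).
#' @param amplicon_id amplicon to analyse (haplotype matrix and groups).
#' @param pnl,mini panel and mini-reference.
#' @param k haplogroup count (`NULL` = automatic).
#' @param config see [default_config()].
#' @return list with `matrix`, `clusters`, `ld`, `tfbs`, `assoc`,
#'   `group_tests`, `survival`, `excluded`.
#' @export
run_population <- function(geno, phenotypes, amplicon_id, pnl, mini = NULL,
                           k = NULL, config = default_config()) {
  ids <- names(geno)
  unknown <- setdiff(phenotypes$sample_id, ids)
  matched <- intersect(ids, phenotypes$sample_id)
  if (length(matched) == 0L)
    stop_with("no phenotype sample ids match genotyped samples; unmatched: %s",
              paste(utils::head(unknown, 5), collapse = ", "))
  phen <- phenotypes[match(matched, phenotypes$sample_id), ]
  phase_results <- lapply(geno[matched], function(g) {
    p <- g$phase[[amplicon_id]]
    if (is.null(p)) list(phased = FALSE, flag = "no_reads") else p
  })
  bm <- build_matrix(phase_results)
  cl <- dedup_and_cluster(bm$matrix, k = k)
  ld <- compute_ld(bm$matrix, maf_min = config$maf_min,
                   r2_threshold = config$r2_threshold)
  amp <- pnl$amplicons[[amplicon_id]]
  region <- pnl$reference[[amp$contig]]
  tf <- scan_tfbs(region, bm$loci)

  # per-variant dosages from the haplotype matrix rows (2 per sample)
  sample_of_row <- sub("_h[12]$", "", rownames(bm$matrix))
  dos <- rowsum(bm$matrix, group = sample_of_row)
  phen2 <- phen[match(rownames(dos), phen$sample_id), ]
  covar <- data.frame(age = phen2$age, sex = as.factor(phen2$sex))
  assoc <- gwas_glm(dos, phen2$hbf, covariates = covar,
                    maf_min = config$maf_min)

  # haplogroup carrier analyses
  grp_of_row <- cl$groups
  carrier <- vapply(levels(grp_of_row), function(g)
    tapply(grp_of_row == g, sample_of_row, any)[rownames(dos)],
    logical(nrow(dos)))
  group_tests <- list(); survival_res <- NULL
  if (length(levels(grp_of_row)) >= 2L) {
    for (g in levels(grp_of_row)) {
      gt <- tryCatch(group_compare(
        phen2$hbf, factor(ifelse(carrier[, g], g, "other"),
                          levels = c(g, "other")), test = "unpaired_t"),
        error = function(e) NULL)
      if (!is.null(gt))
        group_tests[[g]] <- data.frame(
          group = g, carriers = sum(carrier[, g]),
          mean_hbf_carrier = mean(phen2$hbf[carrier[, g]]),
          mean_hbf_other = mean(phen2$hbf[!carrier[, g]]),
          t = gt$statistic, p = gt$p)
    }
    group_tests <- do.call(rbind, group_tests)
    top <- levels(grp_of_row)[1]
    survival_res <- tryCatch(
      km_logrank(phen2$age_first_transfusion, phen2$transfused,
                 ifelse(carrier[, top], top, "other")),
      error = function(e) list(error = conditionMessage(e)))
  }
  list(matrix = bm$matrix, loci = bm$loci, clusters = cl, ld = ld, tfbs = tf,
       assoc = assoc, group_tests = group_tests, survival = survival_res,
       excluded = list(unphased = bm$n_excluded, unmatched_ids = unknown))
}
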