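#' Specify a synthetic study + reference cohort
#'
#' Describes a synthetic dataset with the statistical structure the test
#' battery assumes: per-SNP baseline allele frequencies, binomial reference
#' counts, per-individual genotypes drawn under Hardy-Weinberg proportions in
#' case and control, optional control/case-vs-reference stratification,
#' planted effect SNPs (case frequency multiplied), and planted HWE-violating
#' SNPs (heterozygote probability scaled by a deficit factor, then
#' renormalized). No linkage disequilibrium is simulated: SNPs are
#' independent.
#'
#' @param n_case,n_control,n_ref Group sizes in individuals.
#' @param n_snps Number of SNPs.
#' @param freq_range Baseline reference allele-frequency range; each SNP's
#'   `q_ref` is drawn uniformly from it. A vector of explicit frequencies of
#'   length `n_snps` is also accepted.
#' @param strat_shift Multiplicative shift applied to the case and control
#'   frequencies relative to the reference (1 = no stratification; 1.1
#'   emulates mild control-reference differentiation).
#' @param effect_snps Data frame with columns `index` and `multiplier`:
#'   the case frequency at each listed SNP is `multiplier` times its control
#'   frequency. An optional `q_ref` column pins the baseline frequency of the
#'   planted SNP (otherwise it is drawn from `freq_range` like any other),
#'   which keeps strong effects feasible at rare baselines.
#' @param hwe_snps Data frame with columns `index` and `het_deficit`: the
#'   heterozygote probability at each listed SNP (case and control genotypes)
#'   is scaled by `het_deficit` (0 = no heterozygotes) and the genotype
#'   distribution renormalized.
#' @param seed Integer seed.
#' @return A `cohort_spec` list, validated: every resulting frequency must
#'   lie strictly inside (0, 1) and all indices in range, otherwise an error
#'   is thrown before any data are generated.
#' @export
cohort_spec <- function(n_case = 500, n_control = 500, n_ref = 10000,
                        n_snps = 1000, freq_range = c(0.05, 0.5),
                        strat_shift = 1, effect_snps = NULL,
                        hwe_snps = NULL, seed = 1L) {
  stopifnot(n_case >= 1, n_control >= 1, n_ref >= 1, n_snps >= 1)
  if (any(freq_range <= 0) || any(freq_range >= 1)) {
    stop("frequencies must lie strictly inside (0, 1)")
  }
  if (length(freq_range) == 2) {
    if (freq_range[1] > freq_range[2]) {
      stop("freq_range must be an increasing (lo, hi) pair")
    }
  } else if (length(freq_range) != n_snps) {
    stop("freq_range must be a (lo, hi) pair or one frequency per SNP")
  }
  check_idx <- function(df, what) {
    if (is.null(df)) return(tibble::tibble(index = integer()))
    df <- tibble::as_tibble(df)
    if (any(df$index < 1 | df$index > n_snps)) {
      stop(what, " indices out of range 1..", n_snps)
    }
    df
  }
  effect_snps <- check_idx(effect_snps, "effect_snps")
  hwe_snps <- check_idx(hwe_snps, "hwe_snps")
  max_q <- if (length(freq_range) == 2) freq_range[2] else max(freq_range)
  if (max_q * strat_shift >= 1) {
    stop("infeasible spec: a shifted control frequency reaches 1")
  }
  if (nrow(effect_snps)) {
    eff_q <- if ("q_ref" %in% names(effect_snps)) {
      ifelse(is.na(effect_snps$q_ref), max_q, effect_snps$q_ref)
    } else {
      rep(max_q, nrow(effect_snps))
    }
    if (any(eff_q <= 0) || any(eff_q * strat_shift *
                                 effect_snps$multiplier >= 1)) {
      stop("infeasible spec: a planted case frequency reaches 1 ",
           "(pin q_ref for strong effects)")
    }
  }
  if (nrow(hwe_snps) && any(hwe_snps$het_deficit < 0)) {
    stop("het_deficit must be >= 0")
  }
  structure(list(n_case = n_case, n_control = n_control, n_ref = n_ref,
                 n_snps = n_snps, freq_range = freq_range,
                 strat_shift = strat_shift, effect_snps = effect_snps,
                 hwe_snps = hwe_snps, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws the dataset described by a [cohort_spec()]: reference alt-allele
#' counts `Binomial(2 n_ref, q_ref)` per SNP, and case/control genotype
#' counts sampled from (possibly deficit-adjusted) Hardy-Weinberg genotype
#' proportions. Returns the cohort in memory; use [write_cohort()] to
#' materialize VCF/TSV files.
#'
#' @param spec A `cohort_spec`.
#' @return An `rrpat_cohort` list with elements `snps` (per-SNP study counts
#'   and genotype triples, ready for [hwe_filter()] / [join_reference()]),
#'   `reference` (chrom/pos/ref/alt/ac/an), `group_map`, `truth` (the
#'   generating frequencies and flags per SNP) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n_snps <- spec$n_snps
  q_ref <- if (length(spec$freq_range) == 2) {
    runif(n_snps, spec$freq_range[1], spec$freq_range[2])
  } else {
    spec$freq_range
  }
  if (nrow(spec$effect_snps) && "q_ref" %in% names(spec$effect_snps)) {
    pin <- !is.na(spec$effect_snps$q_ref)
    q_ref[spec$effect_snps$index[pin]] <- spec$effect_snps$q_ref[pin]
  }
  q_control <- q_ref * spec$strat_shift
  q_case <- q_control
  effect_mult <- rep(1, n_snps)
  if (nrow(spec$effect_snps)) {
    effect_mult[spec$effect_snps$index] <- spec$effect_snps$multiplier
  }
  q_case <- q_case * effect_mult
  het_deficit <- rep(1, n_snps)
  if (nrow(spec$hwe_snps)) {
    het_deficit[spec$hwe_snps$index] <- spec$hwe_snps$het_deficit
  }
  # alleles: avoid strand-ambiguous pairs so every SNP is joinable
  ref_allele <- sample(c("A", "C", "G", "T"), n_snps, replace = TRUE)
  alt_allele <- ifelse(ref_allele %in% c("A", "T"),
                       sample(c("C", "G"), n_snps, replace = TRUE),
                       sample(c("A", "T"), n_snps, replace = TRUE))
  chrom <- as.character(rep_len(1:22, n_snps))
  pos <- 10000L + 100L * seq_len(n_snps)
  rsid <- sprintf("rs%07d", seq_len(n_snps))
  ca <- draw_genotype_counts(spec$n_case, q_case, het_deficit)
  co <- draw_genotype_counts(spec$n_control, q_control, het_deficit)
  snps <- tibble::tibble(
    chrom = chrom, pos = pos, rsid = rsid,
    ref = ref_allele, alt = alt_allele,
    case_alt = 2 * ca$hom_alt + ca$het,
    case_total = 2L * spec$n_case,
    case_hom_ref = ca$hom_ref, case_het = ca$het, case_hom_alt = ca$hom_alt,
    control_alt = 2 * co$hom_alt + co$het,
    control_total = 2L * spec$n_control,
    control_hom_ref = co$hom_ref, control_het = co$het,
    control_hom_alt = co$hom_alt
  )
  reference <- tibble::tibble(
    chrom = chrom, pos = pos, ref = ref_allele, alt = alt_allele,
    ac = rbinom(n_snps, 2 * spec$n_ref, q_ref),
    an = 2 * spec$n_ref
  )
  group_map <- tibble::tibble(
    sample = c(sprintf("case_%04d", seq_len(spec$n_case)),
               sprintf("ctrl_%04d", seq_len(spec$n_control))),
    group = rep(c("case", "control"), c(spec$n_case, spec$n_control))
  )
  truth <- tibble::tibble(
    index = seq_len(n_snps), rsid = rsid, chrom = chrom, pos = pos,
    q_ref = q_ref, q_control = q_control, q_case = q_case,
    effect_multiplier = effect_mult, het_deficit = het_deficit,
    is_effect = effect_mult != 1, is_hwe_violating = het_deficit != 1
  )
  structure(list(snps = snps, reference = reference, group_map = group_map,
                 truth = truth, spec = spec),
            class = "rrpat_cohort")
}

# genotype counts for n individuals at each SNP: HW proportions
# (p^2, 2pq, q^2) with the het term scaled by the deficit, renormalized
draw_genotype_counts <- function(n, q, het_deficit) {
  p <- 1 - q
  w_hom_ref <- p^2
  w_het <- 2 * p * q * het_deficit
  w_hom_alt <- q^2
  tot <- w_hom_ref + w_het + w_hom_alt
  pr_hom_alt <- w_hom_alt / tot
  pr_het <- w_het / tot
  hom_alt <- rbinom(length(q), n, pr_hom_alt)
  het <- rbinom(length(q), n - hom_alt, pr_het / (1 - pr_hom_alt))
  tibble::tibble(hom_ref = n - hom_alt - het, het = het, hom_alt = hom_alt)
}

#' Write a synthetic cohort to disk
#'
#' Materializes a cohort from [generate_cohort()] as the pipeline's input
#' files: `study.vcf` (per-individual GT genotypes), `groups.tsv`,
#' `reference.vcf` (sites-only with `AC`/`AN` INFO) and `truth.tsv`.
#'
#' @param cohort An `rrpat_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rrpat_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(study = file.path(dir, "study.vcf"),
             groups = file.path(dir, "groups.tsv"),
             reference = file.path(dir, "reference.vcf"),
             truth = file.path(dir, "truth.tsv"))
  s <- cohort$snps
  gts <- purrr::pmap_chr(
    list(s$case_hom_ref, s$case_het, s$case_hom_alt,
         s$control_hom_ref, s$control_het, s$control_hom_alt),
    function(chr_, che, cha, xhr, xhe, xha) {
      paste(c(rep("0/0", chr_), rep("0/1", che), rep("1/1", cha),
              rep("0/0", xhr), rep("0/1", xhe), rep("1/1", xha)),
            collapse = "\t")
    }
  )
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rrpat_synthetic_cohort",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$group_map$sample), collapse = "\t")
  )
  body <- paste(s$chrom, s$pos, s$rsid, s$ref, s$alt, ".", "PASS", ".",
                "GT", gts, sep = "\t")
  writeLines(c(header, body), paths["study"])
  readr::write_tsv(cohort$group_map, paths["groups"])
  r <- cohort$reference
  ref_header <- c(
    "##fileformat=VCFv4.2",
    "##source=rrpat_synthetic_reference",
    '##INFO=<ID=AC,Number=A,Type=Integer,Description="Alt allele count">',
    '##INFO=<ID=AN,Number=1,Type=Integer,Description="Total alleles">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t")
  )
  ref_body <- paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS",
                    sprintf("AC=%d;AN=%d", r$ac, r$an), sep = "\t")
  writeLines(c(ref_header, ref_body), paths["reference"])
  readr::write_tsv(cohort$truth, paths["truth"])
  invisible(paths)
}
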