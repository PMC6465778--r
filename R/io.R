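# Strict TSV reader shared by all tabular inputs: every line must have the
# same field count (catches truncation and ragged rows), required columns must
# be present, and parser problems abort with the offending line.
read_tsv_strict <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) < 1) stop("empty file: ", path)
  if (length(unique(nf)) != 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("malformed TSV %s: line %d has %d fields, expected %d",
                 path, bad, nf[bad], nf[1]))
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  pr <- readr::problems(df)
  if (nrow(pr) > 0) {
    stop(sprintf("malformed TSV %s: parse problem at line %d (%s)",
                 path, pr$row[1] + 1L, pr$expected[1]))
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s: missing required columns: %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  df
}

#' Read a sample-to-group map
#'
#' TSV with columns `sample` and `group`; every group label must be `case`
#' or `control` and both groups must be non-empty.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `sample` and `group`.
#' @export
read_group_map <- function(path) {
  df <- read_tsv_strict(path, c("sample", "group"))
  bad <- setdiff(unique(df$group), c("case", "control"))
  if (length(bad) > 0) {
    stop("invalid group labels (must be 'case' or 'control'): ",
         paste(bad, collapse = ", "))
  }
  if (!all(c("case", "control") %in% df$group)) {
    stop("group map must contain at least one case and one control sample")
  }
  if (anyDuplicated(df$sample)) stop("duplicate sample ids in group map")
  df
}

#' Read a study VCF into per-SNP group counts
#'
#' Reads a VCF with GT genotypes, assigns samples to case/control via the
#' group map, and tallies per-SNP allele and genotype counts per group.
#' Multi-allelic records are skipped (logged in the `drop_log` attribute);
#' missing genotypes (`./.`) are excluded from that SNP's counts only.
#'
#' @param path Path to the VCF (plain text or bgzipped).
#' @param groups Group map tibble from [read_group_map()], or a path to one.
#' @return A tibble with one row per biallelic SNP: `chrom`, `pos`, `rsid`,
#'   `ref`, `alt`, and per group `*_alt`, `*_total` allele counts plus
#'   `*_hom_ref`, `*_het`, `*_hom_alt` genotype counts. Attribute
#'   `drop_log` records skipped records.
#' @export
read_study_vcf <- function(path, groups) {
  if (is.character(groups)) groups <- read_group_map(groups)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF ", path, ": ",
                                           conditionMessage(e)))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no variant records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT genotypes: ", path)
  samples <- colnames(gt)
  unknown <- setdiff(samples, groups$sample)
  if (length(unknown) > 0) {
    stop("samples in VCF absent from group map: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  grp <- setNames(groups$group, groups$sample)[samples]
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT) | fix$ALT == fix$REF
  drop_log <- tibble::tibble(
    chrom = fix$CHROM[multi], pos = as.integer(fix$POS[multi]),
    rsid = fix$ID[multi],
    reason = ifelse(grepl(",", fix$ALT[multi]), "multiallelic",
                    "invalid_alleles")
  )
  keep <- !multi
  # dosage of the alt allele per genotype; NA for missing
  dose <- gt_to_dose(gt[keep, , drop = FALSE])
  count_group <- function(g) {
    d <- dose[, grp == g, drop = FALSE]
    tibble::tibble(
      alt = unname(rowSums(d, na.rm = TRUE)),
      total = unname(2 * rowSums(!is.na(d))),
      hom_ref = unname(rowSums(d == 0, na.rm = TRUE)),
      het = unname(rowSums(d == 1, na.rm = TRUE)),
      hom_alt = unname(rowSums(d == 2, na.rm = TRUE))
    )
  }
  ca <- count_group("case")
  co <- count_group("control")
  out <- tibble::tibble(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    rsid = fix$ID[keep],
    ref = fix$REF[keep],
    alt = fix$ALT[keep],
    case_alt = ca$alt, case_total = ca$total,
    case_hom_ref = ca$hom_ref, case_het = ca$het, case_hom_alt = ca$hom_alt,
    control_alt = co$alt, control_total = co$total,
    control_hom_ref = co$hom_ref, control_het = co$het,
    control_hom_alt = co$hom_alt
  )
  attr(out, "drop_log") <- drop_log
  out
}

# GT string matrix -> alt-allele dosage matrix (0/1/2, NA for missing)
gt_to_dose <- function(gt) {
  g <- gsub("\\|", "/", gt)
  d <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
              dimnames = dimnames(gt))
  d[g %in% c("0/0")] <- 0
  d[g %in% c("0/1", "1/0")] <- 1
  d[g %in% c("1/1")] <- 2
  bad <- !is.na(g) & !(g %in% c("0/0", "0/1", "1/0", "1/1", "./.", "."))
  if (any(bad)) {
    stop("unsupported GT value(s): ", paste(head(unique(g[bad]), 3),
                                            collapse = ", "))
  }
  d
}

#' Read a per-SNP counts table
#'
#' TSV alternative to the VCF study input: one row per SNP with columns
#' `chrom`, `pos`, `rsid`, `ref`, `alt`, `case_alt`, `case_total`,
#' `control_alt`, `control_total`, and optionally the control genotype triple
#' `control_hom_ref`, `control_het`, `control_hom_alt` (needed for HWE
#' filtering).
#'
#' @param path Path to the TSV.
#' @return A tibble of SNP records.
#' @export
read_study_counts <- function(path) {
  read_tsv_strict(path, c("chrom", "pos", "rsid", "ref", "alt",
                          "case_alt", "case_total",
                          "control_alt", "control_total"))
}

#' Read a reference allele-count table
#'
#' Accepts a sites-only VCF whose INFO field carries allele counts (gnomAD
#' style, default keys `AC`/`AN`) or an equivalent TSV with columns `chrom`,
#' `pos`, `ref`, `alt`, `ac`, `an`. Multi-allelic VCF records are split into
#' biallelic rows (`AN` shared, one `AC` per alternate allele). Records
#' missing either key or with `AN = 0` are skipped and logged in the
#' `drop_log` attribute.
#'
#' @param path Path to the VCF (`.vcf`/`.vcf.gz`) or TSV.
#' @param ac_key,an_key INFO keys for the alt-allele count and total allele
#'   number.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `ac`, `an`.
#' @export
read_reference <- function(path, ac_key = "AC", an_key = "AN") {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    read_reference_vcf(path, ac_key, an_key)
  } else {
    df <- read_tsv_strict(path, c("chrom", "pos", "ref", "alt", "ac", "an"))
    keep <- !is.na(df$ac) & !is.na(df$an) & df$an > 0
    out <- df[keep, c("chrom", "pos", "ref", "alt", "ac", "an")]
    out$chrom <- as.character(out$chrom)
    attr(out, "drop_log") <- df[!keep, ] |>
      dplyr::mutate(reason = "missing_or_zero_counts") |>
      dplyr::select("chrom", "pos", "reason")
    out
  }
}

read_reference_vcf <- function(path, ac_key, an_key) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF ", path, ": ",
                                           conditionMessage(e)))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no variant records in ", path)
  ac_raw <- vcfR::extract.info(vcf, element = ac_key)
  an_raw <- vcfR::extract.info(vcf, element = an_key)
  rows <- purrr::pmap(
    list(fix$CHROM, fix$POS, fix$REF, fix$ALT, ac_raw, an_raw),
    function(chrom, pos, ref, alt, ac, an) {
      alts <- strsplit(alt, ",", fixed = TRUE)[[1]]
      acs <- suppressWarnings(as.numeric(strsplit(
        if (is.na(ac)) "" else ac, ",", fixed = TRUE)[[1]]))
      an <- suppressWarnings(as.numeric(an))
      if (length(acs) != length(alts) || anyNA(acs) || is.na(an) || an <= 0) {
        return(tibble::tibble(chrom = chrom, pos = as.integer(pos),
                              ref = ref, alt = NA_character_,
                              ac = NA_real_, an = NA_real_))
      }
      tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref,
                     alt = alts, ac = acs, an = an)
    }
  ) |> purrr::list_rbind()
  bad <- is.na(rows$alt)
  out <- rows[!bad, ]
  attr(out, "drop_log") <- rows[bad, c("chrom", "pos")] |>
    dplyr::mutate(reason = "missing_or_zero_counts")
  out
}

#' Write and re-read per-SNP results
#'
#' `write_results()` writes the per-SNP table of an [run_rrpat()] result (or
#' any SNP tibble) as TSV with full double precision — every numeric field
#' round-trips bit-exactly through `read_results()`.
#'
#' @param result An `rrpat_result` or a data frame.
#' @param path Output TSV path.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns the tibble.
#' @export
write_results <- function(result, path) {
  df <- if (inherits(result, "rrpat_result")) result$snps else
    tibble::as_tibble(result)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: directory does not exist: ",
                             dir)
  # 17 significant digits guarantee bit-exact double round-trips
  out <- dplyr::mutate(df, dplyr::across(
    dplyr::where(is.double),
    function(x) sprintf("%.17g", x)
  ))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  # base strtod parsing is correctly rounded, preserving the bit-exact
  # round-trip of the 17-digit output
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  tibble::as_tibble(df)
}
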