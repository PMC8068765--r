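#' Parse a somatic SNV VCF into a call tibble
#'
#' Reads one pipeline's VCF for one tumor sample and normalizes it into the
#' long call-table representation used throughout the package: one row per
#' biallelic SNV ALT allele. Multiallelic records are split into one row per
#' ALT; indels, MNVs and symbolic alleles are dropped (and counted in the
#' `n_dropped` attribute) because the whole analysis is SNV-only.
#'
#' Depth is taken from the tumor sample's `FORMAT/DP` (falling back to
#' `INFO/DP`), alt-supporting reads from `FORMAT/AD` (entry k+1 for the k-th
#' ALT), and VAF from `FORMAT/AF` when present, else `alt_reads / depth`.
#' A record whose AD exceeds DP is kept with a warning and its VAF recorded
#' as missing.
#'
#' @param path Path to a VCF 4.x file (plain or gzipped).
#' @param pipeline_id Pipeline identifier, `"<mapper>_<caller>"`.
#' @param sample_id Sample identifier.
#' @param sample_type One of `"parental"`, `"invivo_polyclone"`,
#'   `"invitro_polyclone"`, `"monoclone"`, `"secondary_monoclone"`.
#' @param tumor_sample Name of the tumor genotype column. Default `NULL` uses
#'   the last sample column (the tumor-last convention); callers order
#'   tumor/normal columns differently, so set this when the convention does
#'   not hold.
#' @param strip_chr_prefix Drop a leading `"chr"` from contig names. Contigs
#'   are otherwise compared verbatim; mixed naming conventions across
#'   pipelines would silently zero every overlap.
#' @return A tibble with columns `pipeline_id`, `sample_id`, `sample_type`,
#'   `chrom`, `pos`, `ref`, `alt`, `key`, `depth`, `alt_reads`, `vaf`,
#'   `filter`, carrying attribute `n_dropped` (count of non-SNV ALT alleles
#'   removed).
#' @seealso [apply_filters()], [write_vcf()], [read_callsets()]
#' @export
parse_vcf <- function(path, pipeline_id, sample_id,
                      sample_type = "parental",
                      tumor_sample = NULL,
                      strip_chr_prefix = FALSE) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  sample_type <- match.arg(sample_type, sample_type_levels())
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) {
      abort(paste0("Failed to parse VCF header/records in '", path, "': ",
                   conditionMessage(e)))
    }
  )
  empty <- tibble(
    pipeline_id = character(), sample_id = character(),
    sample_type = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), key = character(),
    depth = integer(), alt_reads = integer(), vaf = double(),
    filter = character()
  )
  if (nrow(vcf@fix) == 0) {
    attr(empty, "n_dropped") <- 0L
    return(empty)
  }

  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n_rec <- nrow(fix)

  has_gt <- ncol(vcf@gt) >= 2
  if (has_gt) {
    samples <- colnames(vcf@gt)[-1]
    tumor <- tumor_sample %||% samples[length(samples)]
    if (!tumor %in% samples) {
      abort(paste0("tumor sample column '", tumor, "' not in VCF (has: ",
                   paste(samples, collapse = ", "), ")"))
    }
    dp_m <- suppressWarnings(vcfR::extract.gt(vcf, "DP", as.numeric = TRUE))
    ad_m <- suppressWarnings(vcfR::extract.gt(vcf, "AD"))
    af_m <- suppressWarnings(vcfR::extract.gt(vcf, "AF", as.numeric = TRUE))
    dp <- if (!is.null(dp_m)) as.numeric(dp_m[, tumor]) else rep(NA_real_, n_rec)
    ad <- if (!is.null(ad_m)) as.character(ad_m[, tumor]) else rep(NA_character_, n_rec)
    af <- if (!is.null(af_m)) as.numeric(af_m[, tumor]) else rep(NA_real_, n_rec)
  } else {
    dp <- rep(NA_real_, n_rec)
    ad <- rep(NA_character_, n_rec)
    af <- rep(NA_real_, n_rec)
  }
  # INFO/DP fallback where FORMAT/DP is absent
  info_dp <- suppressWarnings(as.numeric(
    stringr::str_match(fix$INFO %||% rep(NA_character_, n_rec),
                       "(?:^|;)DP=([0-9]+)")[, 2]
  ))
  dp <- ifelse(is.na(dp), info_dp, dp)

  rows <- vector("list", n_rec)
  n_dropped <- 0L
  for (i in seq_len(n_rec)) {
    alts <- strsplit(fix$ALT[i] %||% "", ",", fixed = TRUE)[[1]]
    if (length(alts) == 0) next
    ref_i <- fix$REF[i]
    ad_i <- suppressWarnings(as.integer(strsplit(ad[i] %||% "", ",")[[1]]))
    snv <- nchar(ref_i) == 1 & nchar(alts) == 1 &
      ref_i %in% c("A", "C", "G", "T") & alts %in% c("A", "C", "G", "T") &
      alts != ref_i
    n_dropped <- n_dropped + sum(!snv)
    if (!any(snv)) next
    k <- which(snv)
    alt_reads <- if (length(ad_i) >= 2) ad_i[pmin(k + 1L, length(ad_i))] else rep(NA_integer_, length(k))
    alt_reads[k + 1L > length(ad_i)] <- NA_integer_
    rows[[i]] <- tibble(
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      ref = ref_i, alt = alts[k],
      depth = as.integer(dp[i]), alt_reads = as.integer(alt_reads),
      af = af[i], filter = fix$FILTER[i] %||% NA_character_
    )
  }
  calls <- bind_rows(rows)
  if (nrow(calls) == 0) {
    attr(empty, "n_dropped") <- n_dropped
    return(empty)
  }

  bad_ad <- !is.na(calls$alt_reads) & !is.na(calls$depth) &
    calls$alt_reads > calls$depth
  if (any(bad_ad)) {
    warn(paste0(sum(bad_ad), " record(s) in '", basename(path),
                "' have AD > DP; kept with VAF set to missing"))
  }
  calls <- calls %>%
    mutate(
      vaf = dplyr::case_when(
        bad_ad ~ NA_real_,
        !is.na(.data$af) ~ .data$af,
        !is.na(.data$alt_reads) & !is.na(.data$depth) & .data$depth > 0 ~
          .data$alt_reads / .data$depth,
        TRUE ~ NA_real_
      ),
      chrom = if (strip_chr_prefix) sub("^chr", "", .data$chrom) else .data$chrom,
      pipeline_id = pipeline_id, sample_id = sample_id,
      sample_type = sample_type,
      key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt)
    ) %>%
    select("pipeline_id", "sample_id", "sample_type", "chrom", "pos",
           "ref", "alt", "key", "depth", "alt_reads", "vaf", "filter") %>%
    distinct(.data$key, .keep_all = TRUE)
  attr(calls, "n_dropped") <- n_dropped
  calls
}

#' Filter a call table by depth and FILTER status
#'
#' Applies the study's fairness filter: a minimum tumor read depth (default
#' 10) and, optionally, FILTER == PASS (or "."). Records with missing depth
#' fail the depth filter — an unknowable depth cannot satisfy a depth floor.
#'
#' @param calls A call tibble from [parse_vcf()] or [read_callsets()]; may
#'   hold many (pipeline, sample) call sets at once.
#' @param min_depth Minimum tumor depth, inclusive (`depth >= min_depth`).
#' @param pass_only Keep only records whose FILTER is `PASS` or `"."`
#'   (missing FILTER counts as `"."`).
#' @return The surviving rows, with attribute `filter_report`: a tibble of
#'   per-(pipeline, sample) removal counts by reason (`low_depth`,
#'   `missing_depth`, `non_pass`).
#' @examples
#' calls <- tibble::tibble(
#'   pipeline_id = "Bwa_Mutect2", sample_id = "s1", sample_type = "parental",
#'   chrom = "c1", pos = 1:3, ref = "A", alt = "T",
#'   key = variant_key("c1", 1:3, "A", "T"),
#'   depth = c(9L, 10L, 11L), alt_reads = 2L, vaf = 0.2, filter = "PASS"
#' )
#' nrow(apply_filters(calls))  # 2: depth-10 boundary is inclusive
#' @export
apply_filters <- function(calls, min_depth = 10, pass_only = TRUE) {
  if (min_depth < 0) abort("min_depth must be >= 0")
  if (nrow(calls) == 0) {
    attr(calls, "filter_report") <- tibble(
      pipeline_id = character(), sample_id = character(),
      reason = character(), n = integer()
    )
    return(calls)
  }
  depth_known <- !is.na(calls$depth)
  keep_depth <- depth_known & calls$depth >= min_depth
  keep_pass <- if (pass_only) {
    is.na(calls$filter) | calls$filter %in% c("PASS", ".")
  } else {
    rep(TRUE, nrow(calls))
  }
  if (any(!depth_known)) {
    files <- unique(paste(calls$pipeline_id[!depth_known],
                          calls$sample_id[!depth_known]))
    inform(paste0("records with missing depth failed the depth filter in: ",
                  paste(files, collapse = ", ")))
  }
  reason <- dplyr::case_when(
    !depth_known ~ "missing_depth",
    !keep_depth ~ "low_depth",
    !keep_pass ~ "non_pass",
    TRUE ~ NA_character_
  )
  report <- tibble(
    pipeline_id = calls$pipeline_id, sample_id = calls$sample_id,
    reason = reason
  ) %>%
    filter(!is.na(.data$reason)) %>%
    count(.data$pipeline_id, .data$sample_id, .data$reason, name = "n")
  out <- calls[keep_depth & keep_pass, , drop = FALSE]
  attr(out, "filter_report") <- report
  attr(out, "n_dropped") <- attr(calls, "n_dropped")
  out
}

#' Write a call table as a minimal VCF 4.2
#'
#' Emits records sorted by (contig, position) with `FORMAT` fields `DP`, `AD`
#' (ref,alt) and `AF` under a single `TUMOR` column, so that
#' `parse_vcf(write_vcf(x))` is the identity on variant keys, depths and
#' alt-read counts. Missing metadata is written as `"."`.
#'
#' @param calls A call tibble (or any tibble with `chrom`, `pos`, `ref`,
#'   `alt`, optionally `depth`, `alt_reads`, `vaf`, `filter`).
#' @param path Output path (plain text; use a `.vcf` extension).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path) {
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(calls))) {
    abort("calls must have columns chrom, pos, ref, alt")
  }
  calls <- as_tibble(calls) %>% arrange(.data$chrom, .data$pos, .data$alt)
  depth <- if ("depth" %in% names(calls)) calls$depth else rep(NA_integer_, nrow(calls))
  altr <- if ("alt_reads" %in% names(calls)) calls$alt_reads else rep(NA_integer_, nrow(calls))
  vaf <- if ("vaf" %in% names(calls)) calls$vaf else rep(NA_real_, nrow(calls))
  filt <- if ("filter" %in% names(calls)) calls$filter else rep("PASS", nrow(calls))
  fmt_int <- function(x) ifelse(is.na(x), ".", as.character(x))
  ad <- ifelse(is.na(depth) | is.na(altr), ".",
               paste0(depth - altr, ",", altr))
  af <- ifelse(is.na(vaf), ".", formatC(vaf, format = "g", digits = 6))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=snvconcord",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", "TUMOR"),
                      collapse = "\t"))
  )
  body <- paste(
    calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
    ifelse(is.na(filt), ".", filt), ".", "GT:DP:AD:AF",
    paste0("0/1:", fmt_int(depth), ":", ad, ":", af),
    sep = "\t"
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Read a study manifest
#'
#' The manifest is a TSV with columns `pipeline_id`, `sample_id`,
#' `sample_type`, `vcf_path` and an optional logical `scored` column (default
#' `TRUE`) marking the sample subset used for metrics; validation always uses
#' all samples. Duplicate (pipeline, sample) pairs are a configuration error.
#'
#' @param path Path to the manifest TSV.
#' @return A tibble of call-set descriptors.
#' @export
read_manifest <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("pipeline_id", "sample_id", "sample_type", "vcf_path")
  miss <- setdiff(need, names(m))
  if (length(miss)) abort(paste0("manifest lacks columns: ", paste(miss, collapse = ", ")))
  if (!"scored" %in% names(m)) m$scored <- TRUE
  dup <- duplicated(m[c("pipeline_id", "sample_id")])
  if (any(dup)) {
    abort(paste0("duplicate (pipeline_id, sample_id) pairs in manifest: ",
                 paste(unique(paste(m$pipeline_id[dup], m$sample_id[dup])),
                       collapse = "; ")))
  }
  bad <- !m$sample_type %in% sample_type_levels()
  if (any(bad)) abort(paste0("unknown sample_type: ",
                             paste(unique(m$sample_type[bad]), collapse = ", ")))
  as_tibble(m)
}

#' Parse and filter every call set listed in a manifest
#'
#' @param manifest A manifest tibble from [read_manifest()] (or a path to one).
#' @param min_depth,pass_only Filter settings, see [apply_filters()].
#' @param ... Passed to [parse_vcf()] (e.g. `strip_chr_prefix`,
#'   `tumor_sample`).
#' @return One long call tibble covering all (pipeline, sample) pairs, with a
#'   combined `filter_report` attribute.
#' @export
read_callsets <- function(manifest, min_depth = 10, pass_only = TRUE, ...) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  parts <- purrr::pmap(
    list(manifest$vcf_path, manifest$pipeline_id, manifest$sample_id,
         manifest$sample_type),
    function(p, pid, sid, st) {
      apply_filters(parse_vcf(p, pid, sid, st, ...),
                    min_depth = min_depth, pass_only = pass_only)
    }
  )
  report <- purrr::map(parts, attr, "filter_report") %>% bind_rows()
  out <- bind_rows(parts)
  attr(out, "filter_report") <- report
  out
}

#' Summarise filtering losses as a tidy report
#'
#' @param calls A filtered call tibble carrying a `filter_report` attribute.
#' @return A tibble (pipeline_id, sample_id, reason, n).
#' @export
filter_report <- function(calls) {
  rep <- attr(calls, "filter_report")
  if (is.null(rep)) {
    abort("calls carry no filter_report; run apply_filters()/read_callsets() first")
  }
  rep
}
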