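#' Read variant calls from a VCF file
#'
#' Reads a VCF 4.x file (plain or gzipped) into a pooled-call table.
#' Multi-allelic records are decomposed into one biallelic row per
#' alternative allele. Depth evidence is taken from the first sample's `AD`
#' field (per-allele depths; their sum is the total when `DP` is absent) and
#' `INFO/DP` or the sample `DP` otherwise; calls without any depth field are
#' loaded evidence-free (`NA` depths) and are rejected by downstream stages
#' that need depth. Coordinates stay 1-based.
#'
#' @param path VCF file path.
#' @param strain when non-`NULL`, return a [strain_variant_set()] of that
#'   name (site identities only) instead of a pooled-call table.
#' @return a [pooled_calls()] data.frame, or a [strain_variant_set()].
#' @export
read_vcf <- function(path, strain = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (n == 0L) {
    empty <- pooled_calls(character(), integer(), character(), character(),
                          numeric(), numeric(), numeric())
    if (!is.null(strain))
      return(strain_variant_set(strain, empty[, c("contig", "pos", "ref",
                                                  "alt", "type")]))
    return(empty)
  }
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  info_dp <- suppressWarnings(
    as.numeric(vcfR::extract.info(vcf, "DP", as.numeric = TRUE)))
  ad <- gt_dp <- rep(NA_character_, n)
  if (!is.null(vcf@gt) && length(dim(vcf@gt)) == 2L && ncol(vcf@gt) >= 2L) {
    gt_all <- vcf@gt
    fmt <- strsplit(gt_all[, 1L], ":", fixed = TRUE)
    smp <- strsplit(gt_all[, 2L], ":", fixed = TRUE)
    pick <- function(field) vapply(seq_len(n), function(i) {
      j <- match(field, fmt[[i]])
      if (is.na(j) || j > length(smp[[i]])) NA_character_ else smp[[i]][j]
    }, "")
    ad <- pick("AD")
    gt_dp <- pick("DP")
  }

  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  row_i <- rep(seq_len(n), n_alt)
  alt_j <- sequence(n_alt)

  ad_counts <- lapply(strsplit(ad, ",", fixed = TRUE),
                      function(v) suppressWarnings(as.numeric(v)))
  # Total high-quality depth: the AD sum when AD is present (the allele
  # depths are the filtered read counts), otherwise DP.
  total <- vapply(seq_len(n), function(i) {
    a <- ad_counts[[i]]
    if (length(a) && !anyNA(a)) return(sum(a))
    if (!is.na(info_dp[i])) return(info_dp[i])
    d <- suppressWarnings(as.numeric(gt_dp[i]))
    if (!is.na(d)) return(d)
    NA_real_
  }, 0)
  alt_depth <- vapply(seq_along(row_i), function(k) {
    a <- ad_counts[[row_i[k]]]
    j <- alt_j[k] + 1L
    if (length(a) >= j && !is.na(a[j])) a[j] else NA_real_
  }, 0)

  out <- data.frame(
    contig = fix$CHROM[row_i],
    pos = as.integer(fix$POS[row_i]),
    ref = toupper(fix$REF[row_i]),
    alt = toupper(unlist(alts)),
    stringsAsFactors = FALSE)
  out$type <- ifelse(nchar(out$ref) == 1L & nchar(out$alt) == 1L,
                     "SNV", "INDEL")
  out$qual <- ifelse(is.na(qual[row_i]), 0, qual[row_i])
  out$total_depth <- total[row_i]
  out$alt_depth <- alt_depth
  rownames(out) <- NULL
  if (!is.null(strain))
    return(strain_variant_set(
      strain, out[!duplicated(variant_key(out)),
                  c("contig", "pos", "ref", "alt", "type")]))
  out
}

#' Write pooled calls as VCF 4.2
#'
#' Emits one biallelic record per call with `INFO/DP` and a single `POOL`
#' sample carrying `AD` (reference depth, alternative depth), sorted by
#' `(contig, position)`. The output round-trips through [read_vcf()].
#'
#' @param calls a [pooled_calls()] data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path) {
  calls <- calls[order(calls$contig, calls$pos), , drop = FALSE]
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=segmapper",
    paste0("##contig=<ID=", unique(calls$contig), ">"),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "POOL", sep = "\t"))
  if (nrow(calls)) {
    dp <- calls$total_depth
    ad <- paste0(dp - calls$alt_depth, ",", calls$alt_depth)
    rows <- paste(calls$contig, calls$pos, ".", calls$ref, calls$alt,
                  ifelse(is.na(calls$qual), ".", format(calls$qual,
                                                        trim = TRUE)),
                  "PASS", paste0("DP=", dp), "AD", ad, sep = "\t")
  } else rows <- character()
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a strain's variant sites from a 4-column TSV
#'
#' Tab-separated `contig`, `pos`, `ref`, `alt` with a header row, as written
#' by [write_strain_tsv()].
#'
#' @param path TSV path.
#' @param strain strain name for the returned set.
#' @return a [strain_variant_set()].
#' @export
read_strain_tsv <- function(path, strain) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "integer", "character",
                                  "character"))
  strain_variant_set(strain, variant_sites(df$contig, df$pos, df$ref, df$alt))
}

#' @rdname read_strain_tsv
#' @param sites a [strain_variant_set()] or site data.frame to write.
#' @export
write_strain_tsv <- function(sites, path) {
  write.table(sites[, c("contig", "pos", "ref", "alt")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Read a variant set from VCF or TSV by extension.
read_strain_any <- function(path, strain) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE))
    read_strain_tsv(path, strain)
  else read_vcf(path, strain = strain)
}

#' Write a bulk segregant mapping report
#'
#' The per-variant report as TSV (one row per variant, one column per
#' cascade stage flag, `.` for missing values) and, optionally, the stage
#' survivor counts as JSON.
#'
#' @param fit a [bsa_map()] object.
#' @param path output TSV path.
#' @param json_path optional path for the JSON stage-count summary.
#' @return `path`, invisibly.
#' @export
write_report <- function(fit, path, json_path = NULL) {
  stopifnot(inherits(fit, "bsa_map"))
  write.table(fit$report, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  if (!is.null(json_path))
    jsonlite::write_json(
      list(stage_counts = as.list(fit$stage_counts),
           n_candidates = nrow(fit$candidates),
           n_low_coverage = nrow(fit$low_coverage)),
      json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' JSON record of the configuration, seed and package version of a run,
#' sufficient to reproduce it exactly.
#'
#' @param path output JSON path.
#' @param config a configuration object (list-like).
#' @param seed the seed used.
#' @param extra optional named list of extra fields.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, extra = list()) {
  payload <- c(list(
    tool = "segmapper",
    version = as.character(utils::packageVersion("segmapper")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass(config)), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
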