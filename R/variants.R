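#' Construct a table of variant sites
#'
#' A variant site is a biallelic genomic lesion identified by
#' `(contig, pos, ref, alt)`. Multi-allelic records must be decomposed into
#' one row per alternative allele before construction (the VCF reader
#' [read_vcf()] does this automatically). The variant type (`"SNV"` or
#' `"INDEL"`) is inferred from allele lengths unless supplied.
#'
#' @param contig character vector of contig/supercontig identifiers.
#' @param pos integer vector of 1-based positions (VCF convention).
#' @param ref,alt reference and alternative alleles; `ref` over `A,C,G,T,N`,
#'   `alt` over `A,C,G,T`. `ref` and `alt` must differ at every site.
#' @param type optional character vector `"SNV"`/`"INDEL"`; inferred if `NULL`.
#' @return data.frame with columns `contig`, `pos`, `ref`, `alt`, `type`.
#' @examples
#' variant_sites("1", c(100, 200), c("A", "AT"), c("G", "A"))
#' @export
variant_sites <- function(contig, pos, ref, alt, type = NULL) {
  n <- max(length(contig), length(pos), length(ref), length(alt))
  contig <- rep_len(as.character(contig), n)
  pos <- rep_len(as.integer(pos), n)
  ref <- rep_len(toupper(as.character(ref)), n)
  alt <- rep_len(toupper(as.character(alt)), n)
  if (any(pos < 1L)) stop("positions must be >= 1 (1-based coordinates)")
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  if (is.null(type)) {
    type <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV", "INDEL")
  } else {
    type <- rep_len(as.character(type), n)
    if (!all(type %in% c("SNV", "INDEL"))) stop("type must be 'SNV' or 'INDEL'")
  }
  data.frame(contig = contig, pos = pos, ref = ref, alt = alt, type = type,
             stringsAsFactors = FALSE)
}

#' Construct a pooled variant call table
#'
#' Pooled calls carry the sequencing evidence for each site from the pooled
#' mutant-phenotype F1 DNA: the phred-scaled site quality, the total
#' high-quality read depth and the count of reads supporting the alternative
#' allele.
#'
#' @inheritParams variant_sites
#' @param qual nonnegative phred-scaled site quality.
#' @param total_depth total high-quality read depth (`>= 0`).
#' @param alt_depth reads supporting the alternative allele
#'   (`0 <= alt_depth <= total_depth`).
#' @return data.frame with the site columns plus `qual`, `total_depth`,
#'   `alt_depth`.
#' @examples
#' pooled_calls("1", 1919681, "T", "C", qual = 228, total_depth = 180,
#'              alt_depth = 180)
#' @export
pooled_calls <- function(contig, pos, ref, alt, qual, total_depth, alt_depth,
                         type = NULL) {
  sites <- variant_sites(contig, pos, ref, alt, type)
  n <- nrow(sites)
  qual <- rep_len(as.numeric(qual), n)
  total_depth <- rep_len(as.numeric(total_depth), n)
  alt_depth <- rep_len(as.numeric(alt_depth), n)
  if (any(qual < 0, na.rm = TRUE)) stop("qual must be nonnegative")
  if (any(total_depth < 0, na.rm = TRUE)) stop("total_depth must be nonnegative")
  if (any(alt_depth < 0 | alt_depth > total_depth, na.rm = TRUE))
    stop("alt_depth must satisfy 0 <= alt_depth <= total_depth")
  sites$qual <- qual
  sites$total_depth <- total_depth
  sites$alt_depth <- alt_depth
  sites
}

#' Construct a strain variant set
#'
#' The set of variant sites called in one strain, used for the
#' intersection/subtraction stages of the filter cascade. Site identity is
#' `(contig, pos, ref, alt)`; duplicate identities are an error.
#'
#' @param strain strain name.
#' @param sites a data.frame of variant sites (see [variant_sites()]); extra
#'   columns are kept.
#' @return the `sites` data.frame with class `strain_variant_set` and a
#'   `strain` attribute.
#' @examples
#' strain_variant_set("Jumble", variant_sites("1", 1919681, "T", "C"))
#' @export
strain_variant_set <- function(strain, sites) {
  stopifnot(is.character(strain), length(strain) == 1L)
  if (!all(c("contig", "pos", "ref", "alt") %in% names(sites)))
    stop("sites must have columns contig, pos, ref, alt")
  if (anyDuplicated(variant_key(sites)))
    stop("duplicate variant identities in strain '", strain, "'")
  attr(sites, "strain") <- strain
  class(sites) <- unique(c("strain_variant_set", class(sites)))
  sites
}

# Identity key for set operations: (contig, pos, ref, alt).
variant_key <- function(x) {
  paste(x$contig, x$pos, x$ref, x$alt, sep = "\r")
}
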