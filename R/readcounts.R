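#' Per-colony variant read counts
#'
#' The raw observation of the pipeline: for each candidate variant and each
#' colony, the number of reads supporting the alternate allele and the total
#' sequencing depth at the site.
#'
#' @param variants Data frame of variant records with at least columns
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`; optional `channel_96`
#'   (0-95), `gene`, `consequence`, `is_sex_chrom`.
#' @param colonies Character vector of colony ids.
#' @param alt Integer matrix (variants x colonies) of alt-read counts.
#' @param depth Integer matrix (variants x colonies) of total depths.
#'
#' @return An object of class `read_counts`.
#' @export
read_counts <- function(variants, colonies, alt, depth) {
  stopifnot(is.data.frame(variants), "variant_id" %in% names(variants))
  alt <- as.matrix(alt)
  depth <- as.matrix(depth)
  if (!all(dim(alt) == dim(depth))) stop("alt and depth dimensions disagree")
  if (nrow(alt) != nrow(variants)) stop("alt rows must match variants")
  if (ncol(alt) != length(colonies)) stop("alt columns must match colonies")
  if (any(alt < 0) || any(depth < 0)) stop("negative counts")
  if (any(alt > depth)) stop("alt exceeds depth")
  if (is.null(variants$is_sex_chrom)) {
    variants$is_sex_chrom <- variants$chrom %in% c("X", "Y")
  }
  rownames(alt) <- rownames(depth) <- variants$variant_id
  colnames(alt) <- colnames(depth) <- colonies
  structure(
    list(variants = variants, colonies = colonies, alt = alt, depth = depth),
    class = "read_counts"
  )
}

#' @export
print.read_counts <- function(x, ...) {
  cat("read_counts:", nrow(x$variants), "variants x", length(x$colonies), "colonies\n")
  invisible(x)
}

#' Variant allele fractions
#'
#' @param counts A [read_counts] object.
#' @return Numeric matrix of alt/depth (NaN where depth is 0).
#' @export
vaf_matrix <- function(counts) {
  counts$alt / counts$depth
}

#' Write a read-count pair of TSV files
#'
#' Writes `<prefix>_alt.tsv`, `<prefix>_depth.tsv` (variants x colonies)
#' and `<prefix>_variants.tsv` (the variant annotation table).
#' @param counts A [read_counts] object.
#' @param prefix Path prefix.
#' @export
write_read_counts <- function(counts, prefix) {
  utils::write.table(counts$alt, paste0(prefix, "_alt.tsv"),
    sep = "\t", quote = FALSE, col.names = NA
  )
  utils::write.table(counts$depth, paste0(prefix, "_depth.tsv"),
    sep = "\t", quote = FALSE, col.names = NA
  )
  utils::write.table(counts$variants, paste0(prefix, "_variants.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(prefix)
}

#' Read a read-count pair of TSV files written by [write_read_counts()]
#'
#' @param prefix Path prefix used at write time.
#' @return A [read_counts] object.
#' @export
read_read_counts <- function(prefix) {
  alt <- as.matrix(utils::read.delim(paste0(prefix, "_alt.tsv"), row.names = 1, check.names = FALSE))
  depth <- as.matrix(utils::read.delim(paste0(prefix, "_depth.tsv"), row.names = 1, check.names = FALSE))
  variants <- utils::read.delim(paste0(prefix, "_variants.tsv"), stringsAsFactors = FALSE)
  variants$chrom <- as.character(variants$chrom)
  read_counts(variants, colnames(alt), alt, depth)
}
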