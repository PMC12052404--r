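#' Genotype matrix container
#'
#' An individuals-by-SNPs dosage matrix (counts of the alternate allele:
#' 0, 1, 2 or `NA` for missing) together with per-SNP metadata. This is the
#' central data structure of breedkit; every analysis stage consumes it.
#'
#' @param dosages numeric/integer matrix, individuals in rows, SNPs in
#'   columns. Entries must be 0, 1, 2 or `NA`. Row names are individual IDs,
#'   column names SNP IDs (taken from `snps$id` if absent).
#' @param snps data frame with columns `id`, `chrom`, `pos`, `ref`, `alt`
#'   (one row per SNP column). `pos` is 1-based. `alt` may be `NA` for a
#'   monomorphic SNP whose second allele is unknown.
#' @return An object of class `genotype_matrix` with elements `dosages` and
#'   `snps`.
#' @export
genotype_matrix <- function(dosages, snps) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  req <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(snps))
  if (length(miss))
    stop("snps table lacks column(s): ", paste(miss, collapse = ", "))
  if (ncol(dosages) != nrow(snps))
    stop("dosages has ", ncol(dosages), " columns but snps has ",
         nrow(snps), " rows")
  if (is.null(rownames(dosages))) {
    if (nrow(dosages) > 0)
      stop("dosages must have individual IDs as row names")
    dimnames(dosages) <- list(character(0), colnames(dosages))
  }
  if (anyDuplicated(rownames(dosages)))
    stop("duplicate individual IDs: ",
         paste(unique(rownames(dosages)[duplicated(rownames(dosages))]),
               collapse = ", "))
  if (anyDuplicated(snps$id))
    stop("duplicate SNP IDs: ",
         paste(unique(snps$id[duplicated(snps$id)]), collapse = ", "))
  colnames(dosages) <- snps$id
  bad <- dosages[!is.na(dosages) & !(dosages %in% 0:2)]
  if (length(bad))
    stop("dosage entries outside {0,1,2,NA}: ", paste(unique(bad), collapse = ", "))
  if (any(!is.na(snps$pos) & snps$pos < 1))
    stop("SNP positions must be >= 1 (1-based)")
  poly <- !is.na(snps$alt)
  if (any(poly & snps$ref == snps$alt))
    stop("ref and alt allele identical for SNP(s): ",
         paste(snps$id[poly & snps$ref == snps$alt], collapse = ", "))
  structure(list(dosages = dosages, snps = snps), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- x$dosages
  cat("genotype_matrix:", nrow(d), "individuals x", ncol(d), "SNPs\n")
  nm <- sum(is.na(d))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", nm, 100 * nm / length(d)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Individual IDs of a genotype matrix
#' @param G a `genotype_matrix`
#' @return character vector of individual IDs
#' @export
individual_ids <- function(G) rownames(G$dosages)

#' SNP IDs of a genotype matrix
#' @param G a `genotype_matrix`
#' @return character vector of SNP IDs
#' @export
snp_ids <- function(G) G$snps$id

#' Remove individuals from a dataset
#'
#' Used for iterative outlier curation between embedding / tree rounds: the
#' named individuals are removed and downstream analyses simply re-run on the
#' returned objects. Pure: the inputs are not modified.
#'
#' @param G a `genotype_matrix`
#' @param breeds a breed table (see [read_breed_table()]), or `NULL`
#' @param ids character vector of individual IDs to drop (may be empty)
#' @return list with elements `genotypes` and `breeds`
#' @export
drop_individuals <- function(G, breeds = NULL, ids = character()) {
  stopifnot(inherits(G, "genotype_matrix"))
  ids <- as.character(ids)
  unknown <- setdiff(ids, individual_ids(G))
  if (length(unknown))
    stop("unknown individual ID(s): ", paste(unknown, collapse = ", "))
  keep <- setdiff(individual_ids(G), ids)
  G2 <- genotype_matrix(G$dosages[keep, , drop = FALSE], G$snps)
  b2 <- if (!is.null(breeds)) breeds[breeds$ID %in% keep, , drop = FALSE] else NULL
  if (!is.null(b2)) rownames(b2) <- NULL
  list(genotypes = G2, breeds = b2)
}

# breed factor aligned to the rows of G; errors on unlabelled individuals
breed_factor <- function(G, breeds) {
  idx <- match(individual_ids(G), breeds$ID)
  if (anyNA(idx))
    stop("individual(s) missing from breed table: ",
         paste(individual_ids(G)[is.na(idx)], collapse = ", "))
  factor(breeds$breed[idx])
}
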