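# HapMap / table input-output.
#
# HapMap files are tab-delimited with 11 fixed metadata columns followed by
# one column per individual. Genotype calls come in two dialects: two-letter
# ("AA", "AG", "NN") or single-character IUPAC ("A", "R", "N"). Dosage is
# the count of the alternate allele, the second allele of the `alleles`
# column ("A/G" -> alt G).

HAPMAP_COLS <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                 "center", "protLSID", "assayLSID", "panelLSID", "QCcode")

IUPAC_HET <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

MISSING_CODES <- c("NN", "N", "--", "-", "")

#' Read a HapMap genotype file
#'
#' Parses a tab-delimited HapMap file into a [genotype_matrix()]. The
#' alternate allele is the second allele listed in the `alleles` column;
#' when that column entry is malformed the minor allele observed in the data
#' is used (ASCII order breaking ties). Genotypes are encoded as alternate
#' allele dosage 0/1/2; `NN`, `N`, `--` and `-` become missing. Monomorphic
#' SNPs are retained (downstream per-SNP statistics exclude them). The
#' `strand` column is ignored; alleles are taken as written.
#'
#' @param path path to the HapMap text file
#' @param dialect `"two-letter"` ("AG"-style calls), `"iupac"`
#'   (single-character calls, heterozygotes as IUPAC ambiguity codes), or
#'   `"auto"` (default; sniffed from call width)
#' @return a `genotype_matrix`
#' @export
read_hapmap <- function(path, dialect = c("auto", "two-letter", "iupac")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (!length(lines)) stop("empty HapMap file: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  hit <- match(tolower(HAPMAP_COLS), tolower(header))
  if (anyNA(hit))
    stop("HapMap header lacks required column(s): ",
         paste(HAPMAP_COLS[is.na(hit)], collapse = ", "))
  ind_cols <- setdiff(seq_along(header), hit)
  ids <- header[ind_cols]
  if (anyDuplicated(ids))
    stop("duplicate individual IDs in HapMap header: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- lines[-1]
  body <- body[nzchar(body)]
  cells <- strsplit(body, "\t", fixed = TRUE)
  nc <- lengths(cells)
  if (any(nc != length(header)))
    stop("HapMap row(s) with wrong field count: line(s) ",
         paste(which(nc != length(header)) + 1L, collapse = ", "))
  M <- do.call(rbind, cells)
  meta <- data.frame(
    id      = M[, hit[1]],
    alleles = M[, hit[2]],
    chrom   = M[, hit[3]],
    pos     = suppressWarnings(as.integer(M[, hit[4]])),
    stringsAsFactors = FALSE)
  calls <- M[, ind_cols, drop = FALSE]

  if (dialect == "auto") {
    w <- nchar(calls[!(calls %in% MISSING_CODES)])
    dialect <- if (length(w) && max(w) >= 2) "two-letter" else "iupac"
  }

  m <- nrow(meta); n <- length(ids)
  dos <- matrix(NA_integer_, n, m, dimnames = list(ids, meta$id))
  ref <- alt <- character(m)
  for (j in seq_len(m)) {
    al <- parse_alleles(meta$alleles[j])
    cj <- calls[j, ]
    pairs <- decode_calls(cj, dialect, j)
    if (is.null(al)) al <- infer_alleles(pairs)
    ref[j] <- al[1]; alt[j] <- al[2]
    ok <- !is.na(pairs)
    seen <- unique(unlist(strsplit(pairs[ok], "", fixed = TRUE)))
    bad <- setdiff(seen, al[!is.na(al)])
    if (length(bad)) {
      col <- which(ok & grepl(paste(bad, collapse = "|"), pairs))[1]
      stop(sprintf(
        "genotype allele(s) %s not among declared alleles %s at SNP '%s' (row %d, individual '%s')",
        paste(bad, collapse = ","), paste(al, collapse = "/"),
        meta$id[j], j + 1L, ids[col]))
    }
    if (!is.na(al[2]))
      dos[ok, j] <- vapply(pairs[ok], function(p)
        sum(strsplit(p, "", fixed = TRUE)[[1]] == al[2]), integer(1))
    else
      dos[ok, j] <- 0L
  }
  genotype_matrix(dos, data.frame(id = meta$id, chrom = meta$chrom,
                                  pos = meta$pos, ref = ref, alt = alt,
                                  stringsAsFactors = FALSE))
}

# "A/G" -> c("A","G"); NULL when malformed (triggers inference from data)
parse_alleles <- function(s) {
  if (grepl("^[ACGT]/[ACGT]$", s)) {
    al <- strsplit(s, "/", fixed = TRUE)[[1]]
    if (al[1] != al[2]) return(al)
  }
  NULL
}

# decode raw genotype strings into two-letter pairs ("AG"), NA for missing
decode_calls <- function(cj, dialect, row) {
  out <- rep(NA_character_, length(cj))
  missing <- cj %in% MISSING_CODES
  if (dialect == "two-letter") {
    ok <- !missing & grepl("^[ACGT]{2}$", cj)
    bad <- !missing & !ok
    if (any(bad))
      stop(sprintf("unparseable two-letter genotype '%s' at HapMap row %d, column %d",
                   cj[which(bad)[1]], row + 1L, which(bad)[1]))
    out[ok] <- cj[ok]
  } else {
    hom <- !missing & cj %in% c("A", "C", "G", "T")
    het <- !missing & cj %in% names(IUPAC_HET)
    bad <- !missing & !hom & !het
    if (any(bad))
      stop(sprintf("unparseable IUPAC genotype '%s' at HapMap row %d, column %d",
                   cj[which(bad)[1]], row + 1L, which(bad)[1]))
    out[hom] <- paste0(cj[hom], cj[hom])
    out[het] <- IUPAC_HET[cj[het]]
  }
  out
}

# infer (ref, alt) from observed calls: alt = minor allele; on a count tie
# the ASCII-greater allele is alt (deterministic)
infer_alleles <- function(pairs) {
  counts <- table(unlist(strsplit(pairs[!is.na(pairs)], "", fixed = TRUE)))
  if (!length(counts)) return(c(NA_character_, NA_character_))
  al <- sort(names(counts))                  # ASCII order
  if (length(al) == 1) return(c(al, NA_character_))
  if (length(al) > 2)
    stop("more than two alleles observed while inferring from data: ",
         paste(al, collapse = ","))
  if (counts[al[1]] < counts[al[2]]) c(al[2], al[1]) else c(al[1], al[2])
}

#' Write a genotype matrix as a HapMap file
#'
#' Two-letter dialect; heterozygotes written ref-then-alt, missing as `NN`.
#' `read_hapmap(write_hapmap(G))` round-trips exactly.
#'
#' @param G a `genotype_matrix`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_hapmap <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  s <- G$snps
  alt <- ifelse(is.na(s$alt), s$ref, s$alt)
  header <- c(HAPMAP_COLS, individual_ids(G))
  rows <- vapply(seq_len(nrow(s)), function(j) {
    g <- G$dosages[, j]
    call <- c(paste0(s$ref[j], s$ref[j]), paste0(s$ref[j], alt[j]),
              paste0(alt[j], alt[j]))[g + 1L]
    call[is.na(g)] <- "NN"
    paste(c(s$id[j], paste0(s$ref[j], "/", alt[j]), s$chrom[j], s$pos[j],
            "+", "NA", "NA", "NA", "NA", "NA", "NA", call), collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  invisible(path)
}

# sniff TSV vs CSV from the header line
read_delim_sniff <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (lengths(gregexpr("\t", first, fixed = TRUE)) >=
             lengths(gregexpr(",", first, fixed = TRUE)) &&
             grepl("\t", first, fixed = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"", comment.char = "")
}

match_columns <- function(df, required, what) {
  idx <- match(tolower(required), tolower(names(df)))
  if (anyNA(idx))
    stop(what, " lacks required column(s): ",
         paste(required[is.na(idx)], collapse = ", "))
  out <- df[, idx, drop = FALSE]
  names(out) <- required
  out
}

#' Read the breed table
#'
#' Tab- or comma-delimited with columns `ID` and `breed` (case-insensitive).
#'
#' @param path file path
#' @return data frame with columns `ID`, `breed`
#' @export
read_breed_table <- function(path) {
  df <- match_columns(read_delim_sniff(path), c("ID", "breed"), "breed table")
  df$ID <- as.character(df$ID); df$breed <- as.character(df$breed)
  if (anyDuplicated(df$ID))
    stop("duplicate ID(s) in breed table: ",
         paste(unique(df$ID[duplicated(df$ID)]), collapse = ", "))
  if (any(is.na(df$breed) | !nzchar(df$breed)))
    stop("empty breed label for ID(s): ",
         paste(df$ID[is.na(df$breed) | !nzchar(df$breed)], collapse = ", "))
  df
}

#' Read the geography table
#'
#' Tab- or comma-delimited with columns `breed`, `Latitude`, `Longitude`,
#' `Location` (case-insensitive). Coordinates are validated against valid
#' degree ranges.
#'
#' @param path file path
#' @return data frame with the four columns
#' @export
read_geo_table <- function(path) {
  df <- match_columns(read_delim_sniff(path),
                      c("breed", "Latitude", "Longitude", "Location"),
                      "geography table")
  df$breed <- as.character(df$breed)
  df$Latitude <- as.numeric(df$Latitude)
  df$Longitude <- as.numeric(df$Longitude)
  if (anyDuplicated(df$breed))
    stop("duplicate breed(s) in geography table: ",
         paste(unique(df$breed[duplicated(df$breed)]), collapse = ", "))
  bad <- is.na(df$Latitude) | abs(df$Latitude) > 90
  if (any(bad))
    stop("Latitude out of [-90, 90] for breed(s): ",
         paste(df$breed[bad], collapse = ", "))
  bad <- is.na(df$Longitude) | abs(df$Longitude) > 180
  if (any(bad))
    stop("Longitude out of [-180, 180] for breed(s): ",
         paste(df$breed[bad], collapse = ", "))
  df
}

#' Validate a dataset before analysis
#'
#' Report-only cross-check of the three inputs: ID concordance both ways,
#' per-breed individual counts, per-SNP missing rates, and breeds present in
#' the breed table but absent from the geography table. In training mode the
#' pipeline is considered blocked when any genotyped individual lacks a
#' breed label.
#'
#' @param G a `genotype_matrix`
#' @param breeds breed table
#' @param geo geography table or `NULL`
#' @param training logical; whether unlabelled genotyped individuals block
#'   downstream training
#' @return a `validation_report` list
#' @export
validate_dataset <- function(G, breeds, geo = NULL, training = TRUE) {
  gids <- individual_ids(G)
  unlabelled <- setdiff(gids, breeds$ID)
  ungenotyped <- setdiff(breeds$ID, gids)
  labelled <- breeds[breeds$ID %in% gids, , drop = FALSE]
  counts <- table(labelled$breed)
  counts <- stats::setNames(as.integer(counts), names(counts))
  miss_rate <- colMeans(is.na(G$dosages))
  geo_missing <- if (!is.null(geo)) setdiff(unique(breeds$breed), geo$breed)
                 else character()
  structure(list(
    n_individuals = length(gids),
    n_snps = ncol(G$dosages),
    unlabelled = unlabelled,
    ungenotyped = ungenotyped,
    breed_counts = counts,
    snp_missing_rate = miss_rate,
    geo_missing_breeds = geo_missing,
    blocking = training && length(unlabelled) > 0
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation report:", x$n_individuals, "individuals,", x$n_snps, "SNPs\n")
  cat("  breeds:", length(x$breed_counts), " (",
      paste(names(x$breed_counts), x$breed_counts, sep = "=", collapse = ", "),
      ")\n", sep = "")
  if (length(x$unlabelled))
    cat("  genotyped but unlabelled:", paste(x$unlabelled, collapse = ", "), "\n")
  if (length(x$ungenotyped))
    cat("  labelled but not genotyped:", paste(x$ungenotyped, collapse = ", "), "\n")
  cat("  mean per-SNP missing rate:",
      sprintf("%.4f", mean(x$snp_missing_rate)), "\n")
  if (x$blocking) cat("  BLOCKING: unlabelled individuals present (training mode)\n")
  invisible(x)
}

#' Serialize a tree as a Newick string
#'
#' @param tree an `ape::phylo` tree with uniquely labelled leaves; internal
#'   node labels (e.g. bootstrap support) are written when present
#' @param path optional file path; when given the string is also written out
#' @return the Newick string
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (any(is.na(tree$tip.label)) || any(!nzchar(tree$tip.label)))
    stop("tree has unlabelled leaves")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (length(tree$tip.label) == 1) {          # degenerate: ape cannot print it
    len <- if (!is.null(tree$edge.length) && length(tree$edge.length))
      tree$edge.length[1] else 0
    s <- paste0(tree$tip.label, ":", format(len, digits = 10), ";")
  } else s <- ape::write.tree(tree)
  if (!is.null(path)) writeLines(s, path)
  s
}

#' Write a result table as TSV
#'
#' @param rows data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_table <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
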