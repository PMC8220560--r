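# Allele names, aligned protein catalogs and residue motifs.

#' Parse an HLA allele name
#'
#' Accepts names of the form \code{GENE*FF:FF} or \code{GENE*FF:FF:FF}
#' (1 to 3 numeric fields).  Field strings are kept exactly as written,
#' including zero padding.
#'
#' @param text Character scalar, e.g. \code{"DRB1*04:01"}.
#' @return An object of class \code{allele_name}: a list with elements
#'   \code{gene}, \code{fields} (character vector) and \code{canonical}.
#' @examples
#' parse_allele_name("DRB1*04:01:01")$canonical
#' @export
parse_allele_name <- function(text) {
  if (length(text) != 1L || !is.character(text)) {
    stop("expected a single character string", call. = FALSE)
  }
  txt <- trimws(text)
  m <- regmatches(txt, regexec("^([A-Z][A-Za-z0-9]*)\\*([0-9]+(?::[0-9]+){0,2})$",
                               txt, perl = TRUE))[[1]]
  if (length(m) == 0L) {
    stop("malformed allele name: '", text, "'", call. = FALSE)
  }
  fields <- strsplit(m[3], ":", fixed = TRUE)[[1]]
  structure(
    list(gene = m[2], fields = fields,
         canonical = paste0(m[2], "*", paste(fields, collapse = ":"))),
    class = "allele_name"
  )
}

#' @export
print.allele_name <- function(x, ...) {
  cat("<allele_name>", x$canonical, "\n")
  invisible(x)
}

#' Collapse an allele name to a lower field resolution
#'
#' Analyses in this package key on 2-field names; higher-resolution typing
#' (3-field) is collapsed by truncation.
#'
#' @param name An \code{allele_name} or character scalar.
#' @param n_fields Number of fields to keep (default 2).
#' @return Canonical character name at the requested resolution.
#' @export
collapse_allele <- function(name, n_fields = 2L) {
  if (is.character(name)) name <- parse_allele_name(name)
  k <- min(length(name$fields), n_fields)
  paste0(name$gene, "*", paste(name$fields[seq_len(k)], collapse = ":"))
}

# vectorized collapse over a character vector of names
collapse_alleles <- function(x, n_fields = 2L) {
  map_chr(x, function(a) collapse_allele(a, n_fields))
}

#' Construct an allele catalog
#'
#' A catalog stores one aligned residue vector per allele over a shared,
#' ordered set of beta-chain positions.  Residues are single upper-case
#' letters from the 20-letter amino-acid code; anything else is recorded
#' as missing (\code{NA}).
#'
#' @param sequences Character matrix (alleles x positions) of single
#'   letters, rownames = canonical allele names, or a named character
#'   vector of strings of equal length.
#' @param positions Integer vector of beta positions, one per column.
#' @return Object of class \code{allele_catalog} with elements \code{seq}
#'   (character matrix with \code{NA} for missing), \code{positions} and
#'   \code{labels}.
#' @export
allele_catalog <- function(sequences, positions) {
  positions <- check_positions(as.integer(positions))
  if (is.character(sequences) && is.null(dim(sequences))) {
    if (is.null(names(sequences))) stop("sequences must be named", call. = FALSE)
    nc <- unique(nchar(sequences))
    if (length(nc) != 1L) {
      stop("aligned sequences must have equal length", call. = FALSE)
    }
    sequences <- do.call(rbind, strsplit(sequences, ""))
  }
  if (ncol(sequences) != length(positions)) {
    stop("sequence length (", ncol(sequences), ") does not match position map (",
         length(positions), ")", call. = FALSE)
  }
  if (anyDuplicated(rownames(sequences))) {
    stop("duplicate allele name in catalog: ",
         rownames(sequences)[duplicated(rownames(sequences))][1], call. = FALSE)
  }
  sequences <- toupper(sequences)
  sequences[!sequences %in% AA_CODE] <- NA_character_
  colnames(sequences) <- position_label(positions)
  structure(list(seq = sequences, positions = positions,
                 labels = position_label(positions)),
            class = "allele_catalog")
}

#' @export
print.allele_catalog <- function(x, ...) {
  cat("<allele_catalog> ", nrow(x$seq), " alleles x ", length(x$positions),
      " positions (", x$labels[1], "..", x$labels[length(x$labels)], ")\n",
      sep = "")
  invisible(x)
}

#' Alleles present in a catalog
#' @param catalog An \code{allele_catalog}.
#' @return Character vector of canonical allele names.
#' @export
catalog_alleles <- function(catalog) rownames(catalog$seq)

#' Load an aligned protein FASTA plus position map into a catalog
#'
#' The FASTA must contain aligned (equal-length) protein records named by
#' allele.  The position map is a TSV with a single integer column
#' \code{beta_position}, one row per alignment column.
#'
#' @param fasta_path Path to the aligned FASTA.
#' @param posmap_path Path to the position-map TSV.
#' @return An \code{allele_catalog}.
#' @export
load_alignment <- function(fasta_path, posmap_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  posmap <- utils::read.delim(posmap_path, header = TRUE)
  if (!"beta_position" %in% names(posmap)) {
    stop("position map must have a 'beta_position' column", call. = FALSE)
  }
  positions <- as.integer(posmap$beta_position)
  lens <- unique(Biostrings::width(seqs))
  if (length(lens) != 1L || lens != length(positions)) {
    stop("alignment length (", paste(lens, collapse = ","),
         ") does not match position map (", length(positions), " rows)",
         call. = FALSE)
  }
  mat <- as.matrix(seqs)
  rownames(mat) <- vapply(names(seqs), function(n) {
    parse_allele_name(strsplit(n, "\\s+")[[1]][1])$canonical
  }, character(1), USE.NAMES = FALSE)
  allele_catalog(mat, positions)
}

#' Serialize a catalog back to aligned FASTA (+ position map)
#'
#' Missing residues are written as \code{"X"}.
#'
#' @param catalog An \code{allele_catalog}.
#' @param fasta_path Output FASTA path.
#' @param posmap_path Optional output position-map TSV path.
#' @param width Line-wrap width for sequences.
#' @return Invisibly, \code{fasta_path}.
#' @export
write_catalog_fasta <- function(catalog, fasta_path, posmap_path = NULL,
                                width = 60L) {
  mat <- catalog$seq
  mat[is.na(mat)] <- "X"
  con <- file(fasta_path, "w")
  on.exit(close(con))
  for (a in rownames(mat)) {
    s <- paste0(mat[a, ], collapse = "")
    writeLines(paste0(">", a), con)
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  if (!is.null(posmap_path)) {
    utils::write.table(data.frame(beta_position = catalog$positions),
                       posmap_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(fasta_path)
}

#' Write the catalog as an allele x position residue grid
#' @param catalog An \code{allele_catalog}.
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
write_catalog_grid <- function(catalog, path) {
  df <- data.frame(allele = rownames(catalog$seq), catalog$seq,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the residues an allele carries at chosen positions (its motif)
#'
#' @param catalog An \code{allele_catalog}.
#' @param allele Canonical allele name (or \code{allele_name}); 3-field
#'   names are collapsed to the catalog's 2-field resolution if needed.
#' @param positions Integer vector of beta positions (ordered).
#' @return Character scalar motif, e.g. \code{"KAG"}; \code{""} for an
#'   empty position list.
#' @examples
#' cat4 <- dr4_fixture_catalog()
#' motif_of(cat4, "DRB1*04:01", c(71, 74, 86))  # "KAG"
#' @export
motif_of <- function(catalog, allele, positions) {
  if (inherits(allele, "allele_name")) allele <- allele$canonical
  if (!allele %in% rownames(catalog$seq)) {
    allele2 <- collapse_allele(allele)
    if (!allele2 %in% rownames(catalog$seq)) {
      stop("allele not in catalog: ", allele, call. = FALSE)
    }
    allele <- allele2
  }
  if (length(positions) == 0L) return("")
  idx <- match(as.integer(positions), catalog$positions)
  if (anyNA(idx)) {
    stop("position(s) not in catalog: ",
         paste(positions[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  res <- catalog$seq[allele, idx]
  if (anyNA(res)) {
    stop("allele ", allele, " has missing residue at ",
         paste(position_label(positions[is.na(res)]), collapse = ", "),
         call. = FALSE)
  }
  paste0(res, collapse = "")
}

#' Motifs of every allele in a cluster
#'
#' @param catalog An \code{allele_catalog}.
#' @param cluster Character vector of allele names (default: all).
#' @param positions Integer vector of beta positions.
#' @return Named character vector, allele -> motif.
#' @export
cluster_motifs <- function(catalog, cluster = NULL, positions) {
  cluster <- cluster %||% catalog_alleles(catalog)
  vapply(cluster, function(a) motif_of(catalog, a, positions), character(1))
}
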