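# Readers and writers for the study's text formats:
# GeneNetwork-style .geno genotype tables, per-condition trait CSVs, QTL TSVs.

#' Read a GeneNetwork-style .geno genotype file
#'
#' The dialect is line-oriented: comment lines (default prefix `"#"`) and
#' metadata lines (default prefix `"@"`, e.g. `@type:riset`) are skipped; the
#' first remaining line is a tab-separated header whose trailing fields name
#' the strains; each data row gives chromosome, marker id, position and one
#' genotype code per strain. Codes are mapped onto the package's internal
#' `"A"`/`"B"` convention via `allele_labels`; any other code (heterozygous
#' `"H"`, unknown `"U"`, ...) becomes a no-call and the total is reported in
#' a message.
#'
#' @param path Path to the file.
#' @param panel_id Panel label for the returned object (default: file stem).
#' @param allele_labels Length-2 character vector: the file codes meaning the
#'   first and second parental allele, e.g. `c("B", "D")` for a BXD file.
#' @param comment_prefix,meta_prefix Line prefixes to skip.
#' @param pos_col Name of the header column holding positions in Mb
#'   (`"Mb"` by default; falls back to `"cM"` with a warning if absent —
#'   positions are taken as given, no unit conversion is attempted).
#' @return A [geno_matrix()] with markers sorted by (chromosome, position).
#' @export
read_geno <- function(path, panel_id = NULL,
                      allele_labels = c("B", "D"),
                      comment_prefix = "#", meta_prefix = "@",
                      pos_col = "Mb") {
  stopifnot(length(allele_labels) == 2)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, comment_prefix) & !startsWith(lines, meta_prefix) &
    nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2) stop("no genotype rows in ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  fixed_cols <- c("Chr", "Locus", "cM", "Mb")
  n_fixed <- sum(header %in% fixed_cols)
  if (n_fixed < 3 || !all(header[seq_len(n_fixed)] %in% fixed_cols)) {
    stop("unrecognized .geno header: ", lines[[1]])
  }
  strains <- header[-seq_len(n_fixed)]
  if (!length(strains)) stop("header names no strains")
  if (!pos_col %in% header) {
    if ("cM" %in% header) {
      warning("no '", pos_col, "' column; using 'cM' positions as given")
      pos_col <- "cM"
    } else stop("no position column ('", pos_col, "' or 'cM') in header")
  }
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  len <- lengths(rows)
  if (any(len != length(header))) {
    bad <- which(len != length(header))[1]
    stop("line ", lineno[-1][bad], ": expected ", length(header),
         " fields, found ", len[bad])
  }
  tab <- do.call(rbind, rows)
  colnames(tab) <- header
  marker <- tab[, "Locus"]
  if (anyDuplicated(marker)) {
    stop("duplicate marker id(s): ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "))
  }
  map <- marker_map(marker, tab[, "Chr"], as.numeric(tab[, pos_col]))
  raw <- tab[, strains, drop = FALSE]
  rownames(raw) <- marker
  codes <- matrix(NA_character_, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  codes[raw == allele_labels[1]] <- "A"
  codes[raw == allele_labels[2]] <- "B"
  n_nocall <- sum(is.na(codes))
  if (n_nocall > 0) {
    message("read_geno: ", n_nocall,
            " cell(s) with non-parental or missing codes mapped to no-call")
  }
  if (is.null(panel_id)) panel_id <- tools::file_path_sans_ext(basename(path))
  geno_matrix(panel_id, t(codes), map)
}

#' Write a genotype matrix as a .geno file
#'
#' Inverse of [read_geno()]: internal `"A"`/`"B"` codes are written back with
#' the supplied labels, no-calls as `"U"`.
#'
#' @param geno A [geno_matrix()].
#' @param path Output path.
#' @param allele_labels File codes for the A and B alleles.
#' @return `path`, invisibly.
#' @export
write_geno <- function(geno, path, allele_labels = c("B", "D")) {
  codes <- t(geno$codes)   # markers x strains
  out <- codes
  out[which(is.na(codes))] <- "U"
  out[which(codes == "A")] <- allele_labels[1]
  out[which(codes == "B")] <- allele_labels[2]
  header <- c("Chr", "Locus", "Mb", geno$strains)
  body <- cbind(geno$markers$chr, geno$markers$marker,
                format(geno$markers$pos_mb, trim = TRUE, digits = 10),
                out[geno$markers$marker, , drop = FALSE])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("@name:%s", geno$panel_id), con)
  writeLines(paste(header, collapse = "\t"), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read one condition's trait matrix from CSV
#'
#' Expects trait ids in the first column and strain ids in the header; blank
#' cells become missing values (never zero).
#'
#' @param path CSV path.
#' @return Numeric trait x strain matrix.
#' @export
read_trait_table <- function(path) {
  if (file.size(path) == 0) stop("empty trait table: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0 || ncol(raw) < 2) stop("no trait rows in ", path)
  traits <- raw[[1]]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  cells[!nzchar(trimws(cells))] <- NA_character_
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(vals) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at trait '%s', strain '%s' in %s",
                 traits[bad[1, 1]], colnames(cells)[bad[1, 2]], path))
  }
  dimnames(vals) <- list(traits, colnames(cells))
  vals
}

#' Write a trait matrix as CSV
#'
#' @param mat Numeric trait x strain matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(mat, path) {
  df <- data.frame(trait_id = rownames(mat), mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write QTL hits as a tab-separated table
#'
#' One row per hit: trait, marker, chromosome, position, LRS (6 significant
#' digits), effect sign, eQTL class, significance flag. Rows are ordered by
#' trait, then chromosome (canonical order), then position.
#'
#' @param hits A `data.frame` of QTL hits (as produced by
#'   [chromosome_max_qtls()] / [classify_eqtls()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qtl_table <- function(hits, path) {
  cols <- c("trait_id", "marker", "chr", "pos_mb", "lrs", "effect_sign",
            "eqtl_class", "significant")
  if (nrow(hits) == 0) {
    out <- stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  } else {
    for (cc in setdiff(cols, names(hits))) hits[[cc]] <- NA
    ord <- order(hits$trait_id, chrom_factor(hits$chr), hits$pos_mb)
    out <- hits[ord, cols, drop = FALSE]
    out$lrs <- signif(out$lrs, 6)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a QTL table written by [write_qtl_table()]
#' @param path TSV path.
#' @return `data.frame` of hits.
#' @export
read_qtl_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chr = "character"))
}

#' Read a SNP panel CSV
#'
#' Columns: `chr`, `pos_mb`, `conserved` (0/1 or TRUE/FALSE flag meaning the
#' SNP segregates in both panels' parental contrasts). Rows are sorted by
#' position within chromosome.
#'
#' @param path CSV path.
#' @return `data.frame` with columns `chr`, `pos_mb`, `conserved` (logical).
#' @export
read_snp_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(chr = "character"))
  stopifnot(all(c("chr", "pos_mb", "conserved") %in% names(df)))
  df$conserved <- as.logical(df$conserved)
  df <- df[genome_order(df$chr, df$pos_mb), , drop = FALSE]
  rownames(df) <- NULL
  df
}
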