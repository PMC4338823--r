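#' Read editing-site positions from a BED-like file
#'
#' Reads single-base records (end = start + 1) from a BED file on the usual
#' 0-based, half-open convention. Column 6, when present, gives the strand;
#' records without one default to the forward strand. The returned catalogue
#' is sorted by (chrom, pos) and exact duplicates (same chrom, pos, strand)
#' are collapsed to one record with a warning, since public editing
#' catalogues often carry redundant entries.
#'
#' @param path Path to a BED-like file. Lines starting with `#`, `track` or
#'   `browser` and blank lines are skipped.
#' @return A data.frame with columns `chrom` (character), `pos` (integer,
#'   0-based) and `strand` (`"+"` or `"-"`).
#' @seealso [write_sites()], [read_snp_positions()]
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$|^#|^track\\b|^browser\\b", lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- idx[which(nf < 3L)[1]]
    abort(sprintf("malformed BED record at line %d: fewer than 3 fields", bad),
          "parse_error")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- idx[which(is.na(start) | is.na(end))[1]]
    abort(sprintf("malformed BED record at line %d: non-numeric coordinates",
                  bad), "parse_error")
  }
  if (any(end != start + 1L)) {
    bad <- idx[which(end != start + 1L)[1]]
    abort(sprintf(
      "record at line %d spans %d bases; site records must have end = start + 1",
      bad, end[which(end != start + 1L)[1]] - start[which(end != start + 1L)[1]]),
      "rejected_record_error")
  }
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) f[6L], ""), "+")
  strand[!strand %in% c("+", "-")] <- "+"
  sites <- data.frame(chrom = chrom, pos = start, strand = strand,
                      stringsAsFactors = FALSE)
  key <- paste(sites$chrom, sites$pos, sites$strand)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate site record(s) collapsed",
            call. = FALSE)
    sites <- sites[!duplicated(key), , drop = FALSE]
  }
  sites <- sites[order(sites$chrom, sites$pos, sites$strand), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Write sites as BED6
#'
#' Emits one single-base record per site with the strand in column 6, so that
#' [read_sites()] round-trips the catalogue.
#'
#' @param sites Site data.frame (`chrom`, `pos`, `strand`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sites <- function(sites, path) {
  validate_sites(sites)
  lines <- sprintf("%s\t%d\t%d\t.\t0\t%s",
                   sites$chrom, sites$pos, sites$pos + 1L, sites$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read SNP positions from a VCF or BED file
#'
#' Positions are returned on the internal 0-based convention: VCF `POS` is
#' 1-based and converted on read; BED starts are taken as-is. Only simple
#' SNVs are retained from a VCF (single-base REF and ALT); indels and
#' multi-allelic records are skipped. The result is used to purge editing
#' sites that are actually genomic polymorphisms.
#'
#' @param path Path to a `.vcf` file or a BED file of single positions.
#' @return A data.frame with columns `chrom` and `pos` (0-based), one row per
#'   distinct position.
#' @export
read_snp_positions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_vcf <- grepl("\\.vcf$", path, ignore.case = TRUE) ||
    any(startsWith(lines, "##fileformat"))
  if (is_vcf) {
    if (!any(startsWith(lines, "#CHROM"))) {
      abort("VCF header line (#CHROM ...) not found", "format_error")
    }
    body <- lines[!startsWith(lines, "#") & !grepl("^\\s*$", lines)]
    if (length(body) == 0) {
      return(data.frame(chrom = character(), pos = integer(),
                        stringsAsFactors = FALSE))
    }
    fields <- strsplit(body, "\t")
    if (any(lengths(fields) < 5L)) {
      abort("VCF data line with fewer than 5 columns", "format_error")
    }
    ref <- vapply(fields, `[[`, "", 4L)
    alt <- vapply(fields, `[[`, "", 5L)
    snv <- nchar(ref) == 1L & nchar(alt) == 1L &
      ref %in% NUCS & alt %in% NUCS
    chrom <- vapply(fields, `[[`, "", 1L)[snv]
    pos <- as.integer(vapply(fields, `[[`, "", 2L)[snv]) - 1L
  } else {
    keep <- !grepl("^\\s*$|^#|^track\\b|^browser\\b", lines)
    body <- lines[keep]
    if (length(body) == 0) {
      return(data.frame(chrom = character(), pos = integer(),
                        stringsAsFactors = FALSE))
    }
    fields <- strsplit(trimws(body), "\\s+")
    if (any(lengths(fields) < 2L)) {
      abort("BED position line with fewer than 2 columns", "format_error")
    }
    chrom <- vapply(fields, `[[`, "", 1L)
    pos <- as.integer(vapply(fields, `[[`, "", 2L))
  }
  out <- unique(data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Read a genome FASTA
#'
#' @param path FASTA file of contigs.
#' @return A `DNAStringSet` with names stripped to the first token.
#' @export
read_genome <- function(path) {
  as_genome(Biostrings::readDNAStringSet(path))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Extract an A-centered sequence window around a site
#'
#' Returns the `(2 * radius + 1)`-nt window centered on the site. For a
#' forward-strand site the reference slice is returned directly; for a
#' reverse-strand site the slice is reverse complemented, so the window is
#' always read in the orientation in which the central base is the edited
#' adenosine. Sites whose reference base is not A (forward) or T (reverse),
#' windows crossing a contig boundary, and windows containing ambiguity
#' codes are rejected with distinct error classes (`center_base_error`,
#' `boundary_error`, `ambiguity_error`).
#'
#' @param genome `DNAStringSet` or named character vector of contigs.
#' @param site A one-row site data.frame or a list with `chrom`, `pos`
#'   (0-based) and `strand`.
#' @param radius Flank length in nt on each side of the central adenosine.
#' @return An uppercase character string of length `2 * radius + 1`.
#' @examples
#' g <- c(chr1 = "CCCACCC")
#' extract_window(g, list(chrom = "chr1", pos = 3, strand = "+"), radius = 2)
#' @export
extract_window <- function(genome, site, radius) {
  genome <- as_genome(genome)
  chrom <- as.character(site$chrom)
  pos <- as.integer(site$pos)
  strand <- as.character(site$strand)
  if (!chrom %in% names(genome)) {
    abort(paste0("contig not in genome: ", chrom), "boundary_error")
  }
  clen <- Biostrings::nchar(genome[[chrom]])
  if (pos - radius < 0L || pos + radius >= clen) {
    abort(sprintf("window [%d, %d] crosses the boundary of %s (length %d)",
                  pos - radius, pos + radius, chrom, clen),
          "boundary_error")
  }
  slice <- toupper(as.character(
    Biostrings::subseq(genome[[chrom]], start = pos - radius + 1L,
                       width = 2L * radius + 1L)
  ))
  if (grepl("[^ACGT]", slice)) {
    abort(sprintf("window at %s:%d contains ambiguous bases", chrom, pos),
          "ambiguity_error")
  }
  window <- if (strand == "-") revcomp(slice) else slice
  if (substr(window, radius + 1L, radius + 1L) != "A") {
    abort(sprintf(
      "central base at %s:%d (%s) is not an adenosine in window orientation",
      chrom, pos, strand), "center_base_error")
  }
  window
}

#' Extract windows for a site catalogue
#'
#' Vectorized companion of [extract_window()]. With `skip_invalid = TRUE`
#' sites whose window cannot be built (boundary, non-A center, ambiguity)
#' are dropped with a single summary warning instead of raising an error --
#' the usual choice when windowing a large catalogue against a draft genome.
#'
#' @inheritParams extract_window
#' @param sites Site data.frame (`chrom`, `pos`, `strand`).
#' @param skip_invalid Drop failing sites instead of erroring.
#' @return Character vector of windows; with `skip_invalid = TRUE` the
#'   attribute `"kept"` holds the row indices of the surviving sites.
#' @export
extract_windows <- function(genome, sites, radius, skip_invalid = FALSE) {
  validate_sites(sites)
  genome <- as_genome(genome)
  out <- character(nrow(sites))
  ok <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    w <- tryCatch(extract_window(genome, sites[i, ], radius),
                  airliner_error = function(e) e)
    if (is.character(w)) {
      out[i] <- w
      ok[i] <- TRUE
    } else if (!skip_invalid) {
      stop(w)
    }
  }
  if (skip_invalid && any(!ok)) {
    warning(sum(!ok), " site(s) skipped during window extraction",
            call. = FALSE)
  }
  res <- out[ok]
  attr(res, "kept") <- which(ok)
  res
}
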