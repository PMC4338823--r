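#' Breakpoint distance between consecutive editing sites
#'
#' Computes the gap threshold delta used to segment a site catalogue into
#' edited regions: the weighted average distance between consecutive sites,
#' i.e. the pooled mean of all consecutive-site gaps across (chrom, strand)
#' groups. Groups with a single site contribute no gaps; equivalently, delta
#' is the mean gap per group weighted by that group's gap count.
#'
#' @param sites Site data.frame (`chrom`, `pos`, `strand`).
#' @param stranded Group sites by (chrom, strand) (default) or by chrom only.
#' @return An object of class `"delta_estimate"`: a list with `delta`,
#'   `n_gaps` and a `per_group` data.frame of gap counts and sums.
#' @examples
#' s <- data.frame(chrom = "chr1", pos = c(0, 100, 300), strand = "+")
#' compute_breakpoint_delta(s)$delta  # gaps 100, 200 -> 150
#' @export
compute_breakpoint_delta <- function(sites, stranded = TRUE) {
  validate_sites(sites)
  groups <- site_groups(sites, stranded)
  per_group <- lapply(groups, function(g) {
    p <- sort(g$pos)
    gaps <- diff(p)
    data.frame(chrom = g$chrom[1],
               strand = if (stranded) g$strand[1] else "*",
               n_sites = length(p), n_gaps = length(gaps),
               gap_sum = sum(gaps), stringsAsFactors = FALSE)
  })
  per_group <- do.call(rbind, per_group)
  n_gaps <- sum(per_group$n_gaps)
  if (n_gaps == 0) {
    abort("delta is undefined: no (chrom, strand) group has >= 2 sites",
          "undefined_delta_error")
  }
  structure(list(delta = sum(per_group$gap_sum) / n_gaps,
                 n_gaps = n_gaps, per_group = per_group),
            class = "delta_estimate")
}

#' @export
print.delta_estimate <- function(x, ...) {
  cat("Breakpoint estimate: delta =", format(x$delta),
      "nt over", x$n_gaps, "consecutive-site gaps in",
      nrow(x$per_group), "group(s)\n")
  invisible(x)
}

site_groups <- function(sites, stranded = TRUE) {
  key <- if (stranded) paste(sites$chrom, sites$strand) else sites$chrom
  split(sites, key)
}

#' Segment a site catalogue into edited regions
#'
#' Greedy left-to-right segmentation within each (chrom, strand) group:
#' starting from a site, the next site is included in the current edited
#' region (ER) while its distance from the previous one is at most `delta`;
#' a gap greater than `delta` closes the region and starts a new one. Every
#' input site belongs to exactly one ER. The ER span runs from its first to
#' its last member site with no flank padding.
#'
#' @param sites Site data.frame (`chrom`, `pos`, `strand`).
#' @param delta Gap threshold in nt (>= 0), typically from
#'   [compute_breakpoint_delta()].
#' @param stranded Segment per (chrom, strand) group (default) or per chrom.
#' @return A data.frame of regions with columns `er_id`, `chrom`, `strand`,
#'   `start`, `end`, `n_sites`, `length` (`end - start + 1`) and a list
#'   column `site_pos` of member site positions.
#' @examples
#' s <- data.frame(chrom = "chr1", pos = c(0, 30, 60, 200), strand = "+")
#' build_edited_regions(s, delta = 50)
#' @export
build_edited_regions <- function(sites, delta, stranded = TRUE) {
  validate_sites(sites)
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0) {
    stop("`delta` must be a single non-negative number", call. = FALSE)
  }
  groups <- site_groups(sites, stranded)
  rows <- list()
  for (g in groups) {
    p <- sort(g$pos)
    if (length(p) == 0) next
    breaks <- which(diff(p) > delta)
    starts_idx <- c(1L, breaks + 1L)
    ends_idx <- c(breaks, length(p))
    for (k in seq_along(starts_idx)) {
      member <- p[starts_idx[k]:ends_idx[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom[1],
        strand = if (stranded) g$strand[1] else "*",
        start = member[1], end = member[length(member)],
        n_sites = length(member), length = member[length(member)] - member[1] + 1,
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$site_pos <- I(list(member))
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      n_sites = integer(), length = integer())
    out$site_pos <- I(list())
    out$er_id <- character()
    return(out[, c("er_id", setdiff(names(out), "er_id"))])
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$strand, out$start), , drop = FALSE]
  out <- cbind(er_id = sprintf("ER%05d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "delta") <- delta
  out
}

#' Flag edited regions overlapping repeat annotations
#'
#' An ER is repetitive when its span `[start, end + 1)` overlaps any repeat
#' interval on the same chromosome by at least one base. Repeat intervals
#' follow the BED convention (0-based, half-open); their ordering and any
#' overlap among them do not affect the result.
#'
#' @param regions ER data.frame from [build_edited_regions()].
#' @param repeats data.frame with columns `chrom`, `start`, `end` (half-open).
#' @return Logical vector, one element per region.
#' @export
classify_repetitive <- function(regions, repeats) {
  if (nrow(regions) == 0) return(logical(0))
  if (is.null(repeats) || nrow(repeats) == 0) return(rep(FALSE, nrow(regions)))
  out <- rep(FALSE, nrow(regions))
  for (chrom in unique(regions$chrom)) {
    ri <- which(regions$chrom == chrom)
    rep_i <- repeats[repeats$chrom == chrom, , drop = FALSE]
    if (nrow(rep_i) == 0) next
    # 0-based closed span [start, end] -> 1-based closed IRanges
    er_rng <- IRanges::IRanges(start = regions$start[ri] + 1L,
                               end = regions$end[ri] + 1L)
    rep_rng <- IRanges::IRanges(start = rep_i$start + 1L, end = rep_i$end)
    out[ri] <- IRanges::overlapsAny(er_rng, rep_rng)
  }
  out
}

#' Select edited regions suitable for motif discovery
#'
#' Keeps regions whose span length lies in `[min_len, max_len]` and which
#' contain at least `min_sites` editing sites. Defaults follow the training
#' criteria used when assembling non-repetitive ERs for motif search:
#' 2,000-6,000 nt and at least 10 sites.
#'
#' @param regions ER data.frame.
#' @param min_len,max_len Inclusive span-length bounds in nt.
#' @param min_sites Minimum member-site count.
#' @return The filtered ER data.frame.
#' @export
filter_training_ers <- function(regions, min_len = 2000, max_len = 6000,
                                min_sites = 10) {
  if (min_len > max_len) {
    abort("`min_len` must not exceed `max_len`", "parameter_error")
  }
  keep <- regions$length >= min_len & regions$length <= max_len &
    regions$n_sites >= min_sites
  out <- regions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove sites that coincide with known SNPs
#'
#' Editing calls at genomic polymorphisms are indistinguishable from
#' A/G variants, so catalogued sites whose (chrom, pos) appears in the SNP
#' set are dropped before any downstream analysis.
#'
#' @param sites Site data.frame (`chrom`, `pos`, `strand`).
#' @param snps data.frame with `chrom` and 0-based `pos`, e.g. from
#'   [read_snp_positions()].
#' @return The surviving sites, with attribute `"n_removed"`.
#' @export
filter_snp_sites <- function(sites, snps) {
  validate_sites(sites)
  if (is.null(snps) || nrow(snps) == 0) {
    out <- sites
    attr(out, "n_removed") <- 0L
    return(out)
  }
  keep <- !(paste(sites$chrom, sites$pos) %in% paste(snps$chrom, snps$pos))
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Write edited regions as BED6+
#'
#' Columns: chrom, span start, span end + 1 (half-open), ER id, site count,
#' strand, length, repetitive flag (if present).
#'
#' @param regions ER data.frame; an optional logical `repetitive` column is
#'   emitted as a seventh field.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_regions <- function(regions, path) {
  rep_col <- if ("repetitive" %in% names(regions)) {
    ifelse(regions$repetitive, "\trepetitive", "\tnon-repetitive")
  } else ""
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d%s",
                   regions$chrom, regions$start, regions$end + 1L,
                   regions$er_id, regions$n_sites, regions$strand,
                   regions$length, rep_col)
  writeLines(lines, path)
  invisible(path)
}
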