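# Independent oracles: deliberately naive re-derivations of the quantities
# the package computes, used to cross-check the implementation.

# character-by-character reverse complement
oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# IUPAC-aware reverse complement, naive lookup table
oracle_revcomp_iupac <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# brute-force ER segmentation: walk each (chrom, strand) group and check,
# for every consecutive site pair, membership in one region iff gap <= delta
oracle_segment <- function(sites, delta, stranded = TRUE) {
  key <- if (stranded) paste(sites$chrom, sites$strand) else sites$chrom
  out <- list()
  for (g in split(sites, key)) {
    p <- sort(g$pos)
    regions <- list(p[1])
    if (length(p) > 1) {
      for (i in 2:length(p)) {
        if (p[i] - p[i - 1] <= delta) {
          regions[[length(regions)]] <- c(regions[[length(regions)]], p[i])
        } else {
          regions[[length(regions) + 1]] <- p[i]
        }
      }
    }
    for (r in regions) {
      out[[length(out) + 1]] <- list(chrom = g$chrom[1],
                                     strand = if (stranded) g$strand[1] else "*",
                                     pos = r)
    }
  }
  out
}

# per-base interval overlap
oracle_overlaps <- function(span_start, span_end_incl, intervals) {
  # intervals: data.frame(start, end) half-open, 0-based
  if (nrow(intervals) == 0) return(FALSE)
  for (i in seq_len(nrow(intervals))) {
    bases <- seq(intervals$start[i], intervals$end[i] - 1)
    if (any(bases >= span_start & bases <= span_end_incl)) return(TRUE)
  }
  FALSE
}

# Mann-Whitney concordance with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# generic numerical minimizer of the identical penalized objective
oracle_ridge_logistic <- function(X, y, lambda) {
  Xa <- cbind(1, X)
  pen <- c(0, rep(lambda, ncol(X)))
  l1pe <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
  obj <- function(th) {
    eta <- drop(Xa %*% th)
    sum(l1pe(eta)) - sum(y * eta) + sum(pen * th^2) / 2
  }
  gr <- function(th) {
    eta <- drop(Xa %*% th)
    drop(crossprod(Xa, plogis(eta) - y)) + pen * th
  }
  fit <- optim(numeric(ncol(Xa)), obj, gr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  fit$par
}

# naive position-by-position IUPAC scan (single strand)
oracle_scan <- function(sequence, consensus) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  s <- strsplit(sequence, "")[[1]]
  m <- strsplit(consensus, "")[[1]]
  w <- length(m)
  if (length(s) < w) return(0L)
  hits <- 0L
  for (i in seq_len(length(s) - w + 1L)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      if (!(s[i + j - 1L] %in% sets[[m[j]]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- hits + 1L
  }
  hits
}

# random site catalogue over a couple of contigs and both strands
random_sites <- function(n, max_pos = 5000) {
  data.frame(chrom = sample(c("c1", "c2"), n, replace = TRUE),
             pos = sample.int(max_pos, n),
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# canonical string form of a region set, for oracle comparison
regions_as_strings <- function(regions) {
  sort(vapply(seq_len(nrow(regions)), function(i) {
    paste(regions$chrom[i], regions$strand[i],
          paste(regions$site_pos[[i]], collapse = ","))
  }, ""))
}

oracle_as_strings <- function(oracle_out) {
  sort(vapply(oracle_out, function(r) {
    paste(r$chrom, r$strand, paste(r$pos, collapse = ","))
  }, ""))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}
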